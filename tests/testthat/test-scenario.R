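test_that("population is parity-balanced, spatially anchored, deterministic", {
  pop <- make_population(scenario_config(n_individuals = 10, rng_seed = 1))
  expect_equal(unname(table(pop$parity)["odd"]), 5)
  expect_equal(unname(table(pop$parity)["even"]), 5)

  # parity really is the last tag digit
  expect_equal(pop$parity, tag_parity(pop$tag_id))

  # odd sizes differ by at most one
  pop11 <- make_population(scenario_config(n_individuals = 11, rng_seed = 3))
  expect_lte(abs(diff(table(pop11$parity))), 1)

  # home sites: 1-3 sites each, all valid
  cfg <- scenario_config(n_individuals = 50, n_sites = 6, rng_seed = 2)
  pop50 <- make_population(cfg)
  ns <- vapply(pop50$home_sites, length, integer(1))
  expect_true(all(ns >= 1 & ns <= 3))
  expect_true(all(unlist(pop50$home_sites) %in% 1:6))

  # full-design population size
  expect_equal(nrow(make_population(scenario_config(n_individuals = 339))),
               339)

  # determinism under the seed
  expect_identical(make_population(cfg), make_population(cfg))
  expect_false(identical(
    make_population(cfg)$tag_id,
    make_population(scenario_config(n_individuals = 50, n_sites = 6,
                                    rng_seed = 99))$tag_id
  ))

  expect_error(scenario_config(n_individuals = 0))
})

test_that("preference updates blend row-normalised co-memberships", {
  pop <- make_population(scenario_config(n_individuals = 6, rng_seed = 1))
  P <- init_preferences(pop)
  t1 <- pop$tag_id[1]; t2 <- pop$tag_id[2]; t3 <- pop$tag_id[3]
  P[t1, t2] <- P[t2, t1] <- 0.4

  # rate 0 is the identity
  expect_identical(update_preferences(P, list(c(t1, t3)), 0), P)

  # rate 1 wipes never-co-occurring dyads
  P1 <- update_preferences(P, list(c(t1, t3)), 1)
  expect_equal(P1[t1, t2], 0)
  expect_gt(P1[t1, t3], 0)

  # symmetry and zero diagonal preserved, asymmetric input rejected
  ev <- list(c(t1, t2, t3), c(t2, t3))
  P2 <- update_preferences(P, ev, 0.5)
  expect_equal(P2, t(P2))
  expect_true(all(diag(P2) == 0))
  Pbad <- P; Pbad[t1, t2] <- 0.9
  expect_error(update_preferences(Pbad, ev, 0.5), "symmetric")
})

test_that("feeder periods respect access rules and parity segregation", {
  cfg <- tiny_config(seed = 7, denied_visit_rate = 0)
  pop <- make_population(cfg)
  P <- init_preferences(pop)

  pre <- simulate_period(pop, cfg, "pre", P)
  expect_true(all(pre$detections$access_granted))
  expect_true(all(pre$detections$context == "selective_feeder"))

  dur <- simulate_period(pop, cfg, "during", pre$P, home = pre$home)
  # with no denied visits, every event at a restricted feeder is
  # single-parity among granted records (here: all records)
  expect_true(all(dur$detections$access_granted))
  par_by_event <- tapply(
    as.character(tag_parity(dur$detections$tag_id)),
    dur$detections$true_event_id,
    function(p) length(unique(p))
  )
  expect_true(all(par_by_event == 1))
  # feeder location ids encode the allowed parity
  odd_recs <- dur$detections[grepl("O$", dur$detections$location_id), ]
  expect_true(all(tag_parity(odd_recs$tag_id) == "odd"))

  expect_error(simulate_period(pop, cfg, "middle", P), "period")
})

test_that("denied visits are recorded but granted reads stay single-parity", {
  cfg <- tiny_config(seed = 8, denied_visit_rate = 0.3)
  pop <- make_population(cfg)
  res <- simulate_period(pop, cfg, "during", init_preferences(pop))
  det <- res$detections
  expect_true(any(!det$access_granted))
  granted <- det[det$access_granted, ]
  par_by_event <- tapply(
    as.character(tag_parity(granted$tag_id)),
    granted$true_event_id,
    function(p) length(unique(p))
  )
  expect_true(all(par_by_event == 1))
  # denied reads occur only at mismatched-parity feeders
  denied <- det[!det$access_granted, ]
  allow <- ifelse(grepl("O$", denied$location_id), "odd", "even")
  expect_true(all(as.character(tag_parity(denied$tag_id)) != allow))
})

test_that("realised flock sizes and durations match the configured means", {
  cfg <- demo_config(rng_seed = 11, n_individuals = 80,
                     period_lengths_days = c(8, 2, 1),
                     event_rate_per_site_day = 25)
  pop <- make_population(cfg)
  res <- simulate_period(pop, cfg, "pre", init_preferences(pop))
  sizes <- vapply(res$events$members, length, integer(1))
  expect_gte(length(sizes), 500)
  expect_lt(abs(mean(sizes) - cfg$mean_flock_size),
            0.1 * cfg$mean_flock_size)
  # ground-truth durations: configured mean within 3 Monte-Carlo SE
  durs <- res$events$duration_s
  se <- sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - cfg$event_duration_s), 3 * se)
})

test_that("simulation is deterministic and streams are independent", {
  cfg <- tiny_config(seed = 21)
  r1 <- simulate_experiment(cfg)
  r2 <- simulate_experiment(cfg)
  expect_identical(r1$detections, r2$detections)
  expect_identical(r1$truth$events$members, r2$truth$events$members)

  # context child streams never perturb the feeder stream
  pop <- make_population(cfg)
  pre <- simulate_period(pop, cfg, "pre", init_preferences(pop))
  invisible(simulate_context(pop, pre$P, "ephemeral_patch", cfg, days = 0:1))
  pre2 <- simulate_period(pop, cfg, "pre", init_preferences(pop))
  expect_identical(pre$detections, pre2$detections)
})

test_that("during-period co-foraging raises within-parity preference", {
  cfg <- tiny_config(seed = 5, denied_visit_rate = 0)
  pop <- make_population(cfg)
  res <- simulate_period(pop, cfg, "during", init_preferences(pop))
  P <- res$P
  same <- outer(pop$parity, pop$parity, "==")
  diag(same) <- NA
  expect_gt(mean(P[same & !is.na(same)]), mean(P[!same & !is.na(same)]))
  # and between-parity preference is exactly zero: no cross co-foraging
  expect_equal(mean(P[!same & !is.na(same)]), 0)
})

test_that("unmanipulated contexts have no access rules and expected traffic", {
  cfg <- demo_config(rng_seed = 9)
  pop <- make_population(cfg)
  P <- init_preferences(pop)

  expect_error(simulate_context(pop, P, "selective_feeder", cfg, days = 0),
               "context")

  nb <- simulate_context(pop, P, "nest_box", cfg, days = 0:9)
  det <- nb$detections
  expect_true(all(det$access_granted))
  # mean distinct visitors per box per day over all monitored box-days
  visitors <- sum(vapply(nb$events$members, length, integer(1)))
  mean_per_boxday <- visitors / (cfg$n_nestboxes * 10)
  expect_lt(abs(mean_per_boxday - cfg$nestbox_mean_visitors), 0.35)

  pat <- simulate_context(pop, P, "ephemeral_patch", cfg, days = 0:3)
  expect_true(all(pat$detections$access_granted))
  expect_true(all(pat$detections$context == "ephemeral_patch"))
  # events carry both parities when preferences are flat
  par_mix <- vapply(pat$events$members[
    vapply(pat$events$members, length, integer(1)) >= 4
  ], function(m) length(unique(as.character(tag_parity(m)))), integer(1))
  expect_true(any(par_mix == 2))
})
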