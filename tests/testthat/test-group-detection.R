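make_burst <- function(centre, n, sd, tags, loc = "F1") {
  data.frame(
    tag_id = sample(tags, n, replace = TRUE),
    timestamp = round(rnorm(n, centre, sd)),
    location_id = loc,
    context = "selective_feeder",
    stringsAsFactors = FALSE
  )
}

test_that("well-separated bursts are recovered with exact memberships", {
  set.seed(101)
  tagsA <- c("00011", "00022", "00033")
  tagsB <- c("00044", "00055")
  b1 <- make_burst(20000, 20, 60, tagsA)
  b2 <- make_burst(30000, 20, 60, tagsB)
  ev <- segment_stream(rbind(b1, b2))
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$member_tags[[1]], sort(unique(b1$tag_id)))
  expect_setequal(ev$member_tags[[2]], sort(unique(b2$tag_id)))
  expect_true(all(ev$start_s <= ev$end_s))
})

test_that("degenerate streams segment sensibly", {
  expect_equal(nrow(segment_stream(data.frame(
    tag_id = character(), timestamp = numeric(),
    location_id = character(), stringsAsFactors = FALSE
  ))), 0)

  one <- data.frame(tag_id = "00011", timestamp = 5000, location_id = "F1",
                    stringsAsFactors = FALSE)
  ev <- segment_stream(one)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$member_tags[[1]], "00011")
  expect_equal(ev$n_detections, 1L)

  bad <- one; bad$timestamp <- NA_real_
  expect_error(segment_stream(bad))
  two_locs <- rbind(one, transform(one, location_id = "F2"))
  expect_error(segment_stream(two_locs), "single location")
})

test_that("segmentation partitions detections and ignores input order", {
  set.seed(42)
  tags <- sprintf("%05d", 1:8)
  det <- do.call(rbind, lapply(1:5, function(k) {
    make_burst(6000 * k, 15, 40, tags)
  }))
  ev <- segment_stream(det)
  expect_equal(sum(ev$n_detections), nrow(det))

  shuf <- det[sample.int(nrow(det)), ]
  ev2 <- segment_stream(shuf)
  expect_equal(ev$start_s, ev2$start_s)
  expect_identical(ev$member_tags, ev2$member_tags)

  # min-size filter drops sparse events from the partition: a tight
  # 3-read mini-burst far from the others gets its own component, then
  # falls below the size threshold
  cfgmin <- segmentation_config(min_event_detections = 5)
  mini <- data.frame(tag_id = "99999", timestamp = c(59960, 60000, 60040),
                     location_id = "F1", context = "selective_feeder",
                     stringsAsFactors = FALSE)
  evf <- segment_stream(rbind(det, mini), cfgmin)
  expect_false("99999" %in% unlist(evf$member_tags))
  expect_true(all(evf$n_detections >= 5))
})

test_that("burst count is recovered once gaps exceed 20 sigma", {
  set.seed(7)
  sigma <- 30
  tags <- sprintf("%05d", 1:6)
  for (k in c(2, 4)) {
    centres <- 10000 + (0:(k - 1)) * (20 * sigma * 1.5)
    det <- do.call(rbind, lapply(centres, function(cc) {
      make_burst(cc, 25, sigma, tags)
    }))
    ev <- segment_stream(det)
    expect_equal(nrow(ev), k)
  }
})

test_that("nest-box events group distinct visitors by box and day", {
  day <- 86400
  det <- data.frame(
    tag_id = c("00011", "00022", rep("00011", 50), "00033"),
    timestamp = c(3.2 * day, 3.6 * day, runif(50, 3 * day, 4 * day - 1),
                  4.5 * day),
    location_id = "B7",
    context = "nest_box",
    stringsAsFactors = FALSE
  )
  ev <- daily_nestbox_groups(det)
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$member_tags[[1]], c("00011", "00022"))
  expect_equal(ev$member_tags[[2]], "00033")

  # event count equals box-day pairs with traffic (synthetic stream)
  cfg <- demo_config(rng_seed = 3)
  pop <- make_population(cfg)
  nb <- simulate_context(pop, init_preferences(pop), "nest_box", cfg,
                         days = 0:4)
  ev2 <- daily_nestbox_groups(nb$detections)
  key <- unique(paste(nb$detections$location_id,
                      nb$detections$timestamp %/% day))
  expect_equal(nrow(ev2), length(key))

  expect_error(daily_nestbox_groups(transform(det, context = "feeder")),
               "nest_box")
})

test_that("group-by-individual matrices mirror event memberships", {
  ev <- data.frame(event_id = c("e1", "e2"), stringsAsFactors = FALSE)
  ev$member_tags <- list(c("A", "B"), c("B", "C"))
  gbi <- events_to_gbi(ev, roster = c("A", "B", "C"))
  expect_equal(unname(gbi), rbind(c(1L, 1L, 0L), c(0L, 1L, 1L)))

  # roster inferred as sorted union
  gbi2 <- events_to_gbi(ev)
  expect_equal(colnames(gbi2), c("A", "B", "C"))

  # empty events give a 0-row matrix
  e0 <- data.frame(event_id = character(), stringsAsFactors = FALSE)
  e0$member_tags <- list()
  expect_equal(nrow(events_to_gbi(e0, roster = c("A", "B"))), 0)

  dup <- ev; dup$event_id <- c("e1", "e1")
  expect_error(events_to_gbi(dup), "duplicate")

  # row sums equal member counts on random synthetic events
  set.seed(99)
  tags <- sprintf("%05d", 1:12)
  evr <- data.frame(event_id = sprintf("e%d", 1:30),
                    stringsAsFactors = FALSE)
  evr$member_tags <- lapply(1:30, function(i) {
    sample(tags, sample(1:6, 1))
  })
  g <- events_to_gbi(evr)
  expect_equal(unname(rowSums(g)),
               vapply(evr$member_tags, length, integer(1)) * 1)
})

test_that("detect_groups routes contexts and covers every location-day", {
  cfg <- tiny_config(seed = 13)
  run <- simulate_experiment(cfg)
  det <- run$detections[run$detections$timestamp %/% 86400 < 2, ]
  ev <- detect_groups(det)
  expect_true(all(c("selective_feeder") %in% ev$context))
  # every (location, day) with traffic produced at least one event
  key_in <- unique(paste(det$location_id, det$timestamp %/% 86400))
  key_out <- unique(paste(ev$location_id, ev$start_s %/% 86400))
  expect_setequal(key_in, key_out)
  expect_false(anyDuplicated(ev$event_id) > 0)
})
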