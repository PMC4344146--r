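#' Schedule of patch deployments and nest-box recording
#'
#' Derives, from the period lengths, when ephemeral food patches are
#' deployed (one deployment late in the pre period; up to four during the
#' manipulation, separated by a fixed interval) and when nest-box
#' recording runs (starting shortly before the end of the manipulation and
#' continuing through the post period).
#'
#' @param config a [scenario_config()].
#' @param patch_interval_days gap in days between consecutive during-period
#'   patch deployments (end to start).
#' @return list with `patch_deployments` (data frame: id, period,
#'   start_day, end_day) and `nestbox_days` (integer vector of 0-based
#'   recording days).
#' @export
experiment_schedule <- function(config, patch_interval_days = 10L) {
  b <- period_bounds(config)
  dur <- config$patch_duration_days
  # pre: one deployment, late enough that a feeder reference window of the
  # same length fits before it (skipped when the pre period is too short)
  pre_start <- max(b$pre[1] + dur, b$pre[2] - dur - 3L)
  starts <- integer()
  periods <- character()
  if (pre_start + dur <= b$pre[2]) {
    starts <- pre_start
    periods <- "pre"
  }
  step <- dur + patch_interval_days
  d_starts <- if (b$during[1] + dur <= b$during[2] - dur) {
    seq.int(b$during[1] + dur, b$during[2] - dur, by = step)
  } else integer()
  if (length(d_starts) > 4) d_starts <- utils::tail(d_starts, 4)
  starts <- c(starts, d_starts)
  periods <- c(periods, rep("during", length(d_starts)))
  pd <- data.frame(
    id = seq_along(starts),
    period = periods,
    start_day = as.integer(starts),
    end_day = as.integer(starts + dur - 1L),
    stringsAsFactors = FALSE
  )
  lead <- min(12L, config$period_lengths_days[["during"]] %/% 2L)
  nb <- seq.int(b$during[2] - lead, b$post[2] - 1L)
  list(patch_deployments = pd, nestbox_days = as.integer(nb))
}

#' Simulate the full selective-feeder experiment
#'
#' Runs the pre, during and post feeder periods in sequence (the latent
#' preference matrix carries over and is updated daily from feeder
#' co-foraging), deploys ephemeral food patches per the schedule, and
#' records nest-box prospecting using the daily preference snapshots, so
#' that any structure imposed at the feeders can carry over into the
#' unmanipulated contexts.
#'
#' @param config a [scenario_config()].
#' @param patch_interval_days passed to [experiment_schedule()].
#' @return Object of class `flock_scenario`: list with `population`,
#'   `config`, `schedule`, `detections` (all contexts pooled), `truth`
#'   (ground-truth events and per-period preference snapshots).
#' @examples
#' \donttest{
#' run <- simulate_experiment(demo_config(rng_seed = 1))
#' head(run$detections)
#' }
#' @export
simulate_experiment <- function(config, patch_interval_days = 10L) {
  stopifnot(inherits(config, "scenario_config"))
  pop <- make_population(config)
  sched <- experiment_schedule(config, patch_interval_days)
  b <- period_bounds(config)
  P <- init_preferences(pop)

  pd <- sched$patch_deployments
  snap_pre <- pd$start_day[pd$period == "pre"]
  snap_during <- c(pd$start_day[pd$period == "during"],
                   sched$nestbox_days[sched$nestbox_days < b$during[2]])
  snap_post <- sched$nestbox_days[sched$nestbox_days >= b$post[1]]

  res_pre <- simulate_period(pop, config, "pre", P,
                             snapshot_days = snap_pre,
                             event_id_offset = 0L)
  res_during <- simulate_period(pop, config, "during", res_pre$P,
                                snapshot_days = snap_during,
                                event_id_offset = 1000000L,
                                home = res_pre$home)
  res_post <- simulate_period(pop, config, "post", res_during$P,
                              snapshot_days = snap_post,
                              event_id_offset = 2000000L,
                              home = res_during$home)
  snaps <- c(res_pre$snapshots, res_during$snapshots, res_post$snapshots)

  det <- list(res_pre$detections, res_during$detections, res_post$detections)
  evs <- list(res_pre$events, res_during$events, res_post$events)

  for (i in seq_len(nrow(pd))) {
    days <- seq.int(pd$start_day[i], pd$end_day[i])
    Pd <- snaps[[as.character(pd$start_day[i])]]
    if (is.null(Pd)) Pd <- list(P = init_preferences(pop),
                                home = pop$home_sites)
    r <- simulate_context(pop, Pd, "ephemeral_patch", config, days,
                          deployment_id = pd$id[i],
                          event_id_offset = 3000000L + 10000L * i)
    det[[length(det) + 1L]] <- r$detections
    evs[[length(evs) + 1L]] <- r$events
  }

  if (length(sched$nestbox_days) > 0) {
    r <- simulate_context(pop, snaps, "nest_box", config,
                          days = sched$nestbox_days,
                          event_id_offset = 4000000L)
    det[[length(det) + 1L]] <- r$detections
    evs[[length(evs) + 1L]] <- r$events
  }

  detections <- do.call(rbind, det)
  detections <- detections[order(detections$timestamp, detections$tag_id), ,
                           drop = FALSE]
  rownames(detections) <- NULL
  events <- do.call(rbind, evs)
  # tag ground-truth context events with the period they fall in
  events$period <- ifelse(
    !is.na(events$period), events$period,
    period_of_day(events$day, config)
  )
  out <- list(
    population = pop,
    config = config,
    schedule = sched,
    detections = detections,
    truth = list(
      events = events,
      P_end = list(pre = res_pre$P, during = res_during$P, post = res_post$P),
      P_snapshots = snaps
    )
  )
  class(out) <- "flock_scenario"
  out
}

#' @export
print.flock_scenario <- function(x, ...) {
  cat("Simulated selective-feeder experiment\n")
  cat(sprintf("  %d individuals, %d detections, %d ground-truth events\n",
              nrow(x$population), nrow(x$detections), nrow(x$truth$events)))
  tab <- table(x$detections$context)
  for (nm in names(tab)) cat(sprintf("    %s: %d records\n", nm, tab[[nm]]))
  invisible(x)
}

#' Period containing a given experiment day
#'
#' @param day integer 0-based day(s).
#' @param config a [scenario_config()].
#' @return character vector among pre/during/post (NA outside the span).
#' @export
period_of_day <- function(day, config) {
  b <- period_bounds(config)
  out <- rep(NA_character_, length(day))
  out[day >= b$pre[1] & day < b$pre[2]] <- "pre"
  out[day >= b$during[1] & day < b$during[2]] <- "during"
  out[day >= b$post[1] & day < b$post[2]] <- "post"
  out
}

#' Map a location id to its parent feeder site
#'
#' During the manipulation the two parity-restricted feeders `F<s>O` /
#' `F<s>E` of a pair map back to their original site `s`; ordinary feeders
#' `F<s>` map to `s`. Non-feeder locations return `NA`.
#'
#' @param location_id character vector of location identifiers.
#' @return integer vector of site ids.
#' @export
location_site <- function(location_id) {
  m <- regmatches(location_id, regexec("^F([0-9]+)[OE]?$", location_id))
  vapply(m, function(g) {
    if (length(g) == 2) as.integer(g[2]) else NA_integer_
  }, integer(1))
}
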