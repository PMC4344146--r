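# Full-experiment analysis: assortment per context and period,
# 6-day-window network consistency curves against pre/post references,
# and lagged cross-context Mantel + MRQAP comparisons separating social
# from spatial effects.

#' Analysis plan for a selective-feeder experiment
#'
#' @param window_days consistency-window length (days).
#' @param n_perm permutations for assortment/Mantel/MRQAP nulls.
#' @param n_boot bootstrap resamples for Mantel 95% ranges.
#' @param seed integer root seed for all permutation streams.
#' @param include_denied_visits whether access-denied antenna reads enter
#'   network construction (the antennas record all visits; the denied
#'   birds were present, so the default is to include them).
#' @param patch_lag_days the feeder reference network for a patch
#'   deployment covers this many days immediately before the deployment.
#' @param box_split_days length of the simultaneous feeder/nest-box
#'   comparison windows at the end of the manipulation and in the post
#'   period.
#' @param contexts contexts to analyse.
#' @param min_nodes smallest roster for which an assortment or matrix test
#'   is attempted.
#' @param seg_config a [segmentation_config()].
#' @return list of class `analysis_plan`.
#' @export
analysis_plan <- function(window_days = 6L, n_perm = 1000L, n_boot = 200L,
                          seed = 1L, include_denied_visits = TRUE,
                          patch_lag_days = 4L, box_split_days = 3L,
                          contexts = c("selective_feeder", "ephemeral_patch",
                                       "nest_box"),
                          min_nodes = 5L,
                          seg_config = segmentation_config()) {
  stopifnot(window_days >= 1, n_perm >= 1, n_boot >= 0,
            patch_lag_days >= 1, box_split_days >= 1, min_nodes >= 3)
  structure(
    list(window_days = as.integer(window_days), n_perm = as.integer(n_perm),
         n_boot = as.integer(n_boot), seed = as.integer(seed),
         include_denied_visits = isTRUE(include_denied_visits),
         patch_lag_days = as.integer(patch_lag_days),
         box_split_days = as.integer(box_split_days),
         contexts = contexts, min_nodes = as.integer(min_nodes),
         seg_config = seg_config),
    class = "analysis_plan"
  )
}

# HWI network from a detection subset (NULL when below min size).
subset_network <- function(detections, plan, provenance = list()) {
  if (nrow(detections) == 0) return(NULL)
  if (!plan$include_denied_visits) {
    detections <- detections[detections$access_granted, , drop = FALSE]
  }
  if (nrow(detections) == 0) return(NULL)
  ev <- detect_groups(detections, plan$seg_config)
  net_from_events(ev, plan, provenance)
}

# HWI network from pre-detected gathering events (NULL when below min size).
net_from_events <- function(events, plan, provenance = list()) {
  if (is.null(events) || nrow(events) == 0) return(NULL)
  net <- hwi(events_to_gbi(events), provenance = provenance)
  if (length(net$roster) < plan$min_nodes) return(NULL)
  net
}

day_of <- function(detections) detections$timestamp %/% DAY_S

#' Run the full experiment analysis
#'
#' Executes the complete inference chain on a simulated scenario (or a
#' detection data frame): gathering-event detection, half-weight-index
#' networks per context and period, weighted assortment by tag parity with
#' node-permutation nulls, windowed Mantel consistency curves against the
#' final pre-manipulation window and the post window, and lagged
#' feeder-versus-patch / feeder-versus-nest-box Mantel + MRQAP comparisons
#' with a binary spatial range-overlap control.
#'
#' @param x a `flock_scenario` (from [simulate_experiment()]), a
#'   `scenario_config` (simulated first), or a detection data frame.
#' @param plan an [analysis_plan()].
#' @param config required when `x` is a raw detection data frame: the
#'   [scenario_config()] describing period boundaries.
#' @return object of class `flock_analysis`: list with data-frame
#'   `assortment`, `consistency`, `comparisons`, `overlap` tables, the
#'   underlying test objects in `tests`, and the plan.
#' @export
run_full_analysis <- function(x, plan = analysis_plan(), config = NULL) {
  if (inherits(x, "scenario_config")) x <- simulate_experiment(x)
  if (inherits(x, "flock_scenario")) {
    detections <- x$detections
    config <- x$config
  } else {
    detections <- x
    if (is.null(config)) stop("config required with raw detections")
  }
  stopifnot(inherits(plan, "analysis_plan"))
  b <- period_bounds(config)
  day <- day_of(detections)
  span <- range(day)
  if (span[1] < 0 || span[2] >= b$post[2]) {
    stop("detections fall outside the plan's periods")
  }
  period <- period_of_day(day, config)

  # detect gathering events once over the full stream; all downstream
  # networks are built from subsets of this event table
  det_used <- if (plan$include_denied_visits) {
    detections
  } else {
    detections[detections$access_granted, , drop = FALSE]
  }
  events <- detect_groups(det_used, plan$seg_config)
  events$day <- events$start_s %/% DAY_S
  events$period <- period_of_day(events$day, config)

  tests <- list()
  rows <- list()
  seed_i <- plan$seed
  for (ctx in plan$contexts) {
    for (per in c("pre", "during", "post")) {
      sel <- events$context == ctx & events$period == per
      if (!any(sel)) next
      net <- net_from_events(events[sel, , drop = FALSE], plan,
                             provenance = list(context = ctx, period = per))
      if (is.null(net)) next
      seed_i <- seed_i + 1L
      at <- node_permutation_null(net, n_perm = plan$n_perm, seed = seed_i)
      key <- paste(ctx, per, sep = ".")
      tests[[key]] <- at
      rows[[key]] <- data.frame(
        context = ctx, period = per, r = at$r, se = at$se,
        null_lo = at$null_lo, null_hi = at$null_hi, p = at$p,
        n_nodes = at$n_nodes, stringsAsFactors = FALSE
      )
    }
  }
  assortment <- if (length(rows)) {
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  } else NULL

  feeder_ev <- events[events$context == "selective_feeder", , drop = FALSE]
  feeder_det <- det_used[det_used$context == "selective_feeder", ,
                         drop = FALSE]
  consistency <- consistency_table(feeder_ev, config, plan)
  comparisons <- comparison_table(events, feeder_det, config, plan)
  overlap <- overlap_table(detections, config)

  structure(
    list(assortment = assortment, consistency = consistency$table,
         comparisons = comparisons, overlap = overlap,
         tests = tests, windows = consistency$windows, plan = plan,
         config = config),
    class = "flock_analysis"
  )
}

# Windowed networks per period from the pre-detected feeder event table
# (windows restart at each period boundary).
period_windows <- function(feeder_ev, config, plan) {
  b <- period_bounds(config)
  out <- list()
  for (per in c("pre", "during", "post")) {
    sel <- feeder_ev$period == per
    if (!any(sel)) next
    ev <- feeder_ev[sel, , drop = FALSE]
    win <- (ev$day - b[[per]][1]) %/% plan$window_days
    for (w in sort(unique(win))) {
      prov <- list(
        window = w, period = per,
        day_start = b[[per]][1] + w * plan$window_days,
        day_end = b[[per]][1] + (w + 1) * plan$window_days - 1
      )
      net <- net_from_events(ev[win == w, , drop = FALSE], plan, prov)
      if (is.null(net)) {
        net <- assoc_net(matrix(0, 0, 0), provenance = prov)
      }
      out[[length(out) + 1L]] <- net
    }
  }
  out
}

consistency_table <- function(feeder_ev, config, plan) {
  if (nrow(feeder_ev) == 0) return(list(table = NULL, windows = list()))
  b <- period_bounds(config)
  windows <- period_windows(feeder_ev, config, plan)
  if (length(windows) < 2) return(list(table = NULL, windows = windows))
  # references: final window-length days of pre, and the post window
  ref_pre <- net_from_events(
    feeder_ev[feeder_ev$day >= b$pre[2] - plan$window_days &
                feeder_ev$day < b$pre[2], , drop = FALSE],
    plan, provenance = list(reference = "final_pre")
  )
  ref_post <- net_from_events(
    feeder_ev[feeder_ev$day >= b$post[1] &
                feeder_ev$day < b$post[1] + plan$window_days, , drop = FALSE],
    plan, provenance = list(reference = "post")
  )
  if (is.null(ref_pre) && is.null(ref_post)) {
    return(list(table = NULL, windows = windows))
  }
  tab <- consistency_curves(windows, ref_pre, ref_post,
                            n_perm = plan$n_perm, n_boot = plan$n_boot,
                            seed = plan$seed + 5000L)
  list(table = tab, windows = windows)
}

#' Windowed Mantel consistency against pre/post reference networks
#'
#' Compares each windowed network with the reference network from the
#' final pre-manipulation window and with the post-manipulation reference,
#' aligning each pair to its common individuals.
#'
#' @param windows list of `assoc_net` from [window_networks()] (each with
#'   `window`, `day_start`, `period` provenance).
#' @param reference_pre,reference_post `assoc_net` references (either may
#'   be `NULL`, yielding NA columns).
#' @param n_perm,n_boot,seed passed to [mantel_test()].
#' @param min_common smallest common roster for which a comparison is made.
#' @return data frame, one row per window: period, day range, Mantel r
#'   with bootstrap 95% limits and p against each reference, and common
#'   roster sizes.
#' @export
consistency_curves <- function(windows, reference_pre, reference_post,
                               n_perm = 1000, n_boot = 200, seed = 1L,
                               min_common = 5L) {
  if (length(windows) < 2) stop("need at least 2 windows")
  if (is.null(reference_pre) && is.null(reference_post)) {
    stop("at least one reference network is required")
  }
  one_ref <- function(net, ref, seed) {
    blank <- list(r = NA_real_, lo = NA_real_, hi = NA_real_, p = NA_real_,
                  n = NA_integer_)
    if (is.null(ref) || length(net$roster) == 0) return(blank)
    common <- intersect(net$roster, ref$roster)
    if (length(common) < max(3L, min_common)) return(blank)
    al <- align_common(net, ref)
    mt <- mantel_test(al[[1]], al[[2]], n_perm = n_perm, n_boot = n_boot,
                      seed = seed)
    list(r = mt$r, lo = mt$ci_lo, hi = mt$ci_hi, p = mt$p,
         n = length(common))
  }
  rows <- lapply(seq_along(windows), function(i) {
    net <- windows[[i]]
    a <- one_ref(net, reference_pre, seed + 2L * i)
    b <- one_ref(net, reference_post, seed + 2L * i + 1L)
    data.frame(
      window = i,
      period = net$provenance$period %||% NA_character_,
      day_start = net$provenance$day_start %||% NA_real_,
      day_end = net$provenance$day_end %||% NA_real_,
      n_nodes = length(net$roster),
      r_pre = a$r, pre_lo = a$lo, pre_hi = a$hi, p_pre = a$p,
      n_common_pre = a$n,
      r_post = b$r, post_lo = b$lo, post_hi = b$hi, p_post = b$p,
      n_common_post = b$n,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Mantel + MRQAP row comparing a context network with the feeder
# network (social) and the spatial range-overlap matrix over a feeder
# reference window. `dep_ev` / `feeder_ev` are pre-detected events;
# `feeder_det` carries the raw reads for the spatial overlap matrix.
compare_context_window <- function(dep_ev, feeder_ev, feeder_det, plan,
                                   context, period, days_label, seed) {
  blank <- data.frame(
    context = context, period = period, days = days_label,
    mantel_lo = NA_real_, mantel_r = NA_real_, mantel_hi = NA_real_,
    mantel_p = NA_real_, social_coeff = NA_real_, social_p = NA_real_,
    spatial_coeff = NA_real_, spatial_p = NA_real_,
    F = NA_real_, r2 = NA_real_, n = NA_integer_, stringsAsFactors = FALSE
  )
  dep <- net_from_events(dep_ev, plan,
                         provenance = list(context = context,
                                           period = period))
  soc <- net_from_events(feeder_ev, plan,
                         provenance = list(context = "selective_feeder"))
  if (is.null(dep) || is.null(soc)) return(list(row = blank, tests = NULL))
  common <- sort(intersect(dep$roster, soc$roster))
  if (length(common) < plan$min_nodes) return(list(row = blank, tests = NULL))
  al <- align_common(dep, soc)
  spat <- spatial_overlap(feeder_det, roster = common)
  mt <- mantel_test(al[[1]], al[[2]], n_perm = plan$n_perm,
                    n_boot = plan$n_boot, seed = seed)
  preds <- list(social = al[[2]]$W)
  if (sd(lower_vec(spat)) > 0) preds$spatial <- spat
  mq <- tryCatch(
    mrqap_dsp(al[[1]], preds, n_perm = plan$n_perm, seed = seed + 1L),
    error = function(e) NULL
  )
  row <- blank
  row$mantel_lo <- mt$ci_lo; row$mantel_r <- mt$r; row$mantel_hi <- mt$ci_hi
  row$mantel_p <- mt$p; row$n <- length(common)
  if (!is.null(mq)) {
    row$social_coeff <- unname(coef(mq)["social"])
    row$social_p <- unname(mq$p_dsp["social"])
    if ("spatial" %in% names(mq$p_dsp)) {
      row$spatial_coeff <- unname(coef(mq)["spatial"])
      row$spatial_p <- unname(mq$p_dsp["spatial"])
    }
    row$F <- mq$F_full; row$r2 <- mq$r2_full
  }
  list(row = row, tests = list(mantel = mt, mrqap = mq))
}

comparison_table <- function(events, feeder_det, config, plan) {
  feeder_ev <- events$context == "selective_feeder"
  fday <- day_of(feeder_det)
  rows <- list()
  seed <- plan$seed + 9000L

  # patches: each contiguous deployment vs the feeder window lag days before
  pat <- events$context == "ephemeral_patch"
  if (any(pat)) {
    pdays <- sort(unique(events$day[pat]))
    splits <- split(pdays, cumsum(c(1, diff(pdays) > 1)))
    for (dep_days in splits) {
      ref_days <- seq.int(min(dep_days) - plan$patch_lag_days,
                          min(dep_days) - 1L)
      per <- period_of_day(min(dep_days), config)
      seed <- seed + 10L
      cmp <- compare_context_window(
        events[pat & events$day %in% dep_days, , drop = FALSE],
        events[feeder_ev & events$day %in% ref_days, , drop = FALSE],
        feeder_det[fday %in% ref_days, , drop = FALSE],
        plan, "ephemeral_patch", per,
        sprintf("%d-%d", min(dep_days) + 1L, max(dep_days) + 1L), seed
      )
      rows[[length(rows) + 1L]] <- cmp$row
    }
  }

  # nest-boxes: simultaneous split windows at the end of the manipulation
  # and in the post period
  nb <- events$context == "nest_box"
  if (any(nb)) {
    b <- period_bounds(config)
    s <- plan$box_split_days
    starts <- c(b$during[2] - 2L * s, b$during[2] - s,
                b$post[1], b$post[1] + s)
    for (st in starts) {
      wdays <- seq.int(st, st + s - 1L)
      dep_sel <- nb & events$day %in% wdays
      ref_sel <- feeder_ev & events$day %in% wdays
      if (!any(dep_sel) || !any(ref_sel)) next
      seed <- seed + 10L
      cmp <- compare_context_window(
        events[dep_sel, , drop = FALSE],
        events[ref_sel, , drop = FALSE],
        feeder_det[fday %in% wdays, , drop = FALSE],
        plan, "nest_box", period_of_day(st, config),
        sprintf("%d-%d", st + 1L, st + s), seed
      )
      rows[[length(rows) + 1L]] <- cmp$row
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

overlap_table <- function(detections, config) {
  day <- day_of(detections)
  per <- period_of_day(day, config)
  feeder_during <- unique(
    detections$tag_id[detections$context == "selective_feeder" &
                        per == "during"]
  )
  rows <- list()
  for (ctx in c("ephemeral_patch", "nest_box")) {
    sel <- detections$context == ctx & per == "during"
    if (!any(sel)) next
    ov <- roster_overlap(unique(detections$tag_id[sel]), feeder_during)
    rows[[ctx]] <- data.frame(
      context = ctx, n_shared = ov$n_shared, n_context = ov$n_context,
      percent = ov$percent, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.flock_analysis <- function(x, digits = 3, ...) {
  cat("Selective-feeder experiment analysis\n\n")
  if (!is.null(x$assortment)) {
    cat("Assortment by tag parity (node-permutation null):\n")
    df <- x$assortment
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits)
    print(df, row.names = FALSE)
  }
  if (!is.null(x$overlap)) {
    cat("\nRoster overlap with during-period feeder network:\n")
    print(x$overlap, row.names = FALSE)
  }
  if (!is.null(x$comparisons)) {
    cat("\nCross-context consistency (Mantel + MRQAP-DSP):\n")
    df <- x$comparisons
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits)
    print(df, row.names = FALSE)
  }
  if (!is.null(x$consistency)) {
    cat(sprintf("\nConsistency curves: %d windows (see $consistency)\n",
                nrow(x$consistency)))
  }
  invisible(x)
}

#' @export
plot.flock_analysis <- function(x, ...) {
  df <- x$assortment
  if (is.null(df)) stop("no assortment results to plot")
  df$period <- factor(df$period, levels = c("pre", "during", "post"))
  df <- df[order(df$period), ]
  cols <- c(selective_feeder = "#7570B3", ephemeral_patch = "#1B9E77",
            nest_box = "#377EB8")
  xpos <- seq_len(nrow(df))
  ylim <- range(c(df$r, df$null_lo, df$null_hi), na.rm = TRUE)
  plot(xpos, df$r, pch = 19, col = cols[df$context], xaxt = "n",
       xlab = "", ylab = "assortativity r", ylim = ylim, ...)
  segments(xpos, df$null_lo, xpos, df$null_hi, col = cols[df$context])
  graphics::abline(h = 0, lty = 3)
  graphics::axis(1, at = xpos,
                 labels = paste(df$period, sub("_.*", "", df$context)),
                 las = 2, cex.axis = 0.7)
  invisible(x)
}
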