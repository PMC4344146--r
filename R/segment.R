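# Gathering-event detection: a 1-D Gaussian mixture over detection times
# at one location on one day. Bursts of antenna reads, as a flock feeds,
# form mixture components; each read is assigned to its highest-
# responsibility component, which defines the gathering events used as
# sampling units for associations.

#' Segmentation settings for gathering-event detection
#'
#' @param max_components_per_day upper bound on mixture components fitted
#'   per location-day (>= 1).
#' @param min_event_detections events with fewer detections are discarded.
#' @param model_selection `"BIC"` selects the number of components by BIC
#'   over 1..max; `"prune"` fits the largest supported mixture once and
#'   keeps only components that receive detections.
#' @param merge_overlap_threshold components whose assigned time spans
#'   overlap by more than this fraction of the shorter span are merged.
#' @return list of class `segmentation_config`.
#' @export
segmentation_config <- function(max_components_per_day = 50L,
                                min_event_detections = 1L,
                                model_selection = c("BIC", "prune"),
                                merge_overlap_threshold = 0.25) {
  model_selection <- match.arg(model_selection)
  stopifnot(max_components_per_day >= 1, min_event_detections >= 1,
            merge_overlap_threshold >= 0, merge_overlap_threshold <= 1)
  structure(
    list(
      max_components_per_day = as.integer(max_components_per_day),
      min_event_detections = as.integer(min_event_detections),
      model_selection = model_selection,
      merge_overlap_threshold = merge_overlap_threshold
    ),
    class = "segmentation_config"
  )
}

empty_events <- function() {
  df <- data.frame(
    event_id = character(), location_id = character(),
    start_s = numeric(), end_s = numeric(),
    n_members = integer(), n_detections = integer(),
    stringsAsFactors = FALSE
  )
  df$member_tags <- list()
  df
}

#' Segment one location-day of detections into gathering events
#'
#' Fits a one-dimensional Gaussian mixture to the detection timestamps,
#' chooses the number of components per the configured selection rule,
#' assigns every detection to its maximum-responsibility component (ties
#' broken towards the earlier component in time), merges components whose
#' assigned time spans overlap beyond the configured threshold, and drops
#' events below the minimum size. Repeated reads of one tag within an
#' event all contribute to the fit but count once for membership.
#'
#' @param detections data frame with at least `tag_id`, `timestamp`,
#'   `location_id`; all rows must share one location and one calendar day.
#' @param config a [segmentation_config()].
#' @return data frame of gathering events (`event_id`, `location_id`,
#'   `start_s`, `end_s`, `n_members`, `n_detections`, list-column
#'   `member_tags`), ordered by start time.
#' @export
segment_stream <- function(detections, config = segmentation_config()) {
  if (nrow(detections) == 0) return(empty_events())
  if (!is.numeric(detections$timestamp)) stop("timestamps must be numeric")
  if (anyNA(detections$timestamp)) stop("timestamps must not be NA")
  loc <- unique(detections$location_id)
  if (length(loc) != 1) stop("segment_stream expects a single location")
  day <- unique(detections$timestamp %/% DAY_S)
  if (length(day) != 1) stop("segment_stream expects a single day")

  ord <- order(detections$timestamp, detections$tag_id)
  detections <- detections[ord, , drop = FALSE]
  x <- as.numeric(detections$timestamp)

  cls <- fit_time_mixture(x, config)

  # merge components whose time supports overlap too much
  cls <- merge_overlapping(x, cls, config$merge_overlap_threshold)

  # relabel chronologically by component start
  starts <- tapply(x, cls, min)
  relab <- match(cls, names(sort(starts)))
  events <- lapply(sort(unique(relab)), function(k) {
    sel <- relab == k
    list(
      start_s = min(x[sel]), end_s = max(x[sel]),
      member_tags = sort(unique(detections$tag_id[sel])),
      n_detections = sum(sel)
    )
  })
  events <- Filter(function(e) e$n_detections >= config$min_event_detections,
                   events)
  if (length(events) == 0) return(empty_events())
  df <- data.frame(
    event_id = sprintf("%s_d%d_e%d", loc, day, seq_along(events)),
    location_id = loc,
    start_s = vapply(events, `[[`, numeric(1), "start_s"),
    end_s = vapply(events, `[[`, numeric(1), "end_s"),
    n_members = vapply(events, function(e) length(e$member_tags), integer(1)),
    n_detections = vapply(events, `[[`, integer(1), "n_detections"),
    stringsAsFactors = FALSE
  )
  df$member_tags <- lapply(events, `[[`, "member_tags")
  df
}

# Fit the 1-D mixture and return an integer component label per point.
fit_time_mixture <- function(x, config) {
  n <- length(x)
  if (n == 1 || length(unique(x)) == 1) return(rep(1L, n))
  gmax <- min(config$max_components_per_day, length(unique(x)), n - 1L)
  g_grid <- if (config$model_selection == "BIC") seq_len(gmax) else gmax
  fit <- suppressWarnings(tryCatch(
    mclust::Mclust(x, G = g_grid, modelNames = "V", verbose = FALSE),
    error = function(e) NULL
  ))
  if (is.null(fit)) {
    fit <- suppressWarnings(tryCatch(
      mclust::Mclust(x, G = g_grid, modelNames = "E", verbose = FALSE),
      error = function(e) NULL
    ))
  }
  if (is.null(fit)) return(rep(1L, n))
  z <- fit$z
  if (is.null(z)) return(rep(1L, n))
  # order components by mean so responsibility ties break towards the
  # earlier component in time
  mu <- fit$parameters$mean
  z <- z[, order(mu), drop = FALSE]
  max.col(z, ties.method = "first")
}

merge_overlapping <- function(x, cls, threshold) {
  repeat {
    labs <- sort(unique(cls))
    if (length(labs) <= 1) return(cls)
    lo <- vapply(labs, function(k) min(x[cls == k]), numeric(1))
    hi <- vapply(labs, function(k) max(x[cls == k]), numeric(1))
    ord <- order(lo)
    labs <- labs[ord]; lo <- lo[ord]; hi <- hi[ord]
    merged <- FALSE
    for (i in seq_len(length(labs) - 1)) {
      ov <- min(hi[i], hi[i + 1]) - max(lo[i], lo[i + 1])
      shorter <- max(min(hi[i] - lo[i], hi[i + 1] - lo[i + 1]), 1e-9)
      if (ov > threshold * shorter && ov > 0) {
        cls[cls == labs[i + 1]] <- labs[i]
        merged <- TRUE
        break
      }
    }
    if (!merged) return(cls)
  }
}

#' Detect gathering events across a whole detection stream
#'
#' Splits a multi-location, multi-day stream into per-(location, day)
#' slices, segments feeder and patch slices with the Gaussian mixture, and
#' groups nest-box records by box and calendar day (see
#' [daily_nestbox_groups()]).
#'
#' @param detections detection data frame (columns `tag_id`, `timestamp`,
#'   `location_id`, `context`).
#' @param config a [segmentation_config()].
#' @return combined gathering-event data frame with a `context` column.
#' @export
detect_groups <- function(detections, config = segmentation_config()) {
  if (nrow(detections) == 0) {
    out <- empty_events(); out$context <- character(); return(out)
  }
  if (is.null(detections$context)) detections$context <- "selective_feeder"
  nb <- detections$context == "nest_box"
  out <- list()
  if (any(!nb)) {
    d <- detections[!nb, , drop = FALSE]
    key <- paste(d$location_id, d$timestamp %/% DAY_S)
    for (slice in split(d, key)) {
      ev <- segment_stream(slice, config)
      if (nrow(ev) > 0) {
        ev$context <- slice$context[1]
        out[[length(out) + 1L]] <- ev
      }
    }
  }
  if (any(nb)) {
    ev <- daily_nestbox_groups(detections[nb, , drop = FALSE])
    if (nrow(ev) > 0) {
      ev$context <- "nest_box"
      out[[length(out) + 1L]] <- ev
    }
  }
  if (length(out) == 0) {
    res <- empty_events(); res$context <- character(); return(res)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start_s, res$location_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Nest-box gathering events by calendar day
#'
#' At nest-boxes only a few individuals prospect per day, so a gathering
#' event is simply the set of distinct individuals detected on the same
#' box during the same day.
#'
#' @param detections nest-box detection data frame.
#' @return gathering-event data frame (one event per box-day with
#'   visitors), as in [segment_stream()].
#' @export
daily_nestbox_groups <- function(detections) {
  if (nrow(detections) == 0) return(empty_events())
  if (!all(detections$context == "nest_box")) {
    stop("daily_nestbox_groups expects nest_box records")
  }
  day <- detections$timestamp %/% DAY_S
  key <- paste(detections$location_id, day, sep = "@")
  slices <- split(seq_len(nrow(detections)), key)
  rows <- lapply(names(slices), function(k) {
    sel <- slices[[k]]
    list(
      event_id = sprintf("%s_nb", sub("@", "_d", k)),
      location_id = detections$location_id[sel[1]],
      start_s = min(detections$timestamp[sel]),
      end_s = max(detections$timestamp[sel]),
      member_tags = sort(unique(detections$tag_id[sel])),
      n_detections = length(sel)
    )
  })
  df <- data.frame(
    event_id = vapply(rows, `[[`, character(1), "event_id"),
    location_id = vapply(rows, `[[`, character(1), "location_id"),
    start_s = vapply(rows, `[[`, numeric(1), "start_s"),
    end_s = vapply(rows, `[[`, numeric(1), "end_s"),
    n_members = vapply(rows, function(r) length(r$member_tags), integer(1)),
    n_detections = vapply(rows, `[[`, integer(1), "n_detections"),
    stringsAsFactors = FALSE
  )
  df$member_tags <- lapply(rows, `[[`, "member_tags")
  df <- df[order(df$start_s, df$location_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Group-by-individual matrix from gathering events
#'
#' @param events gathering-event data frame (needs `event_id` and
#'   list-column `member_tags`).
#' @param roster optional character vector of tag ids defining the
#'   columns; defaults to the sorted union of all members.
#' @return K x N binary matrix, one row per event, with event-id rownames
#'   and tag-id colnames.
#' @export
events_to_gbi <- function(events, roster = NULL) {
  if (anyDuplicated(events$event_id)) stop("duplicate event_ids")
  members <- events$member_tags
  if (is.null(roster)) roster <- sort(unique(unlist(members)))
  gbi <- matrix(0L, nrow = nrow(events), ncol = length(roster),
                dimnames = list(events$event_id, roster))
  for (k in seq_len(nrow(events))) {
    idx <- match(members[[k]], roster)
    if (anyNA(idx)) stop("event member not in roster")
    gbi[k, idx] <- 1L
  }
  gbi
}
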