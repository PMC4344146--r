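# Plain-text serialisation: detection streams and gathering events as
# CSV, networks as sorted weighted edge lists and GraphML, GBIs as
# MatrixMarket sparse matrices with a roster sidecar, results and
# provenance as JSON.

#' Write / read a detection stream CSV
#'
#' Columns `tag_id,timestamp,location_id,context,access_granted` (header
#' mandatory, UTF-8, integer-second timestamps). Ground-truth event ids,
#' if present, are kept in an extra column.
#'
#' @param detections detection data frame.
#' @param path file path.
#' @return `read_detections` returns the data frame; tags are character.
#' @export
write_detections <- function(detections, path) {
  cols <- c("tag_id", "timestamp", "location_id", "context",
            "access_granted")
  if ("true_event_id" %in% names(detections)) {
    cols <- c(cols, "true_event_id")
  }
  df <- detections[, cols, drop = FALSE]
  df$timestamp <- as.integer(round(df$timestamp))
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(tag_id = "character"))
  df$access_granted <- as.logical(df$access_granted)
  df
}

#' Write gathering events as CSV
#'
#' One row per event; member tags are semicolon-joined.
#'
#' @param events gathering-event data frame.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  df <- events[, c("event_id", "location_id", "start_s", "end_s",
                   "n_detections")]
  df$member_tags <- vapply(events$member_tags, paste, character(1),
                           collapse = ";")
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a group-by-individual matrix (MatrixMarket + roster file)
#'
#' @param gbi binary K x N matrix with tag colnames.
#' @param path path of the `.mtx` file; the roster goes to
#'   `<path>.roster.txt`, one tag per line.
#' @export
write_gbi <- function(gbi, path) {
  Matrix::writeMM(Matrix::Matrix(gbi * 1.0, sparse = TRUE), path)
  writeLines(colnames(gbi), paste0(path, ".roster.txt"))
  invisible(path)
}

#' Write a network as an edge list and GraphML
#'
#' The edge-list CSV has columns `tag_a,tag_b,weight` with
#' `tag_a < tag_b` lexicographically; the GraphML copy carries the parity
#' node attribute.
#'
#' @param net an `assoc_net`.
#' @param path base path; `<path>.csv` and `<path>.graphml` are written.
#' @export
write_network <- function(net, path) {
  W <- net$W
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  el <- data.frame(
    tag_a = rownames(W)[idx[, 1]],
    tag_b = colnames(W)[idx[, 2]],
    weight = W[idx],
    stringsAsFactors = FALSE
  )
  swap <- el$tag_a > el$tag_b
  tmp <- el$tag_a[swap]; el$tag_a[swap] <- el$tag_b[swap]
  el$tag_b[swap] <- tmp
  el <- el[order(el$tag_a, el$tag_b), , drop = FALSE]
  write.csv(el, paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$parity <- as.character(net$node_attrs)
  igraph::write_graph(g, paste0(path, ".graphml"), format = "graphml")
  invisible(path)
}

#' Write an analysis results bundle as JSON
#'
#' @param analysis a `flock_analysis`.
#' @param path file path.
#' @export
write_analysis <- function(analysis, path) {
  out <- list(
    assortment = analysis$assortment,
    consistency = analysis$consistency,
    comparisons = analysis$comparisons,
    overlap = analysis$overlap,
    plan = analysis$plan[c("window_days", "n_perm", "n_boot", "seed",
                           "include_denied_visits", "patch_lag_days",
                           "box_split_days")]
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write ground truth (events and preference snapshots) as JSON
#'
#' Event memberships are lists of tag ids keyed by context and period;
#' preference matrices are stored as dense lower-triangle arrays.
#'
#' @param truth the `truth` element of a `flock_scenario`.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  ev <- truth$events
  key <- paste(ev$context, ev$period, sep = ".")
  events <- lapply(split(ev$members, key), unname)
  prefs <- lapply(truth$P_end, function(P) {
    list(roster = rownames(P), lower_triangle = P[lower.tri(P)])
  })
  jsonlite::write_json(list(events = events, preferences = prefs), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scenario configuration from a flat JSON file
#'
#' @param path JSON file whose keys mirror [scenario_config()] arguments.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown scenario fields: ", paste(unknown, collapse = ", "))
  }
  do.call(scenario_config, vals)
}

# JSON provenance sidecar written next to every CLI output file.
write_provenance <- function(path, inputs, params, seed) {
  jsonlite::write_json(
    list(
      file = basename(path),
      inputs = inputs,
      parameters = params,
      seed = seed,
      package = "flocknet",
      version = as.character(utils::packageVersion("flocknet")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    paste0(path, ".prov.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
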