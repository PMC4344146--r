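# Association networks from group-by-individual matrices via the
# half-weight index: HWI(a,b) = x / (x + (yA + yB)/2) = 2x / (nA + nB),
# where x counts events containing both individuals and nA, nB the events
# containing each. Each gathering event is its own sampling unit, so the
# "both seen but apart" term of the general index is zero by construction.

#' Construct an association-network object
#'
#' @param W symmetric nonnegative matrix with zero diagonal, tag dimnames.
#' @param node_attrs optional named factor/character of node types (e.g.
#'   tag parity) for the roster; defaults to parity inferred from tag ids.
#' @param provenance optional list (context, period, window, ...).
#' @return object of class `assoc_net`: list(W, roster, node_attrs,
#'   provenance).
#' @export
assoc_net <- function(W, node_attrs = NULL, provenance = list()) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (nrow(W) > 0) {
    stopifnot(!is.null(rownames(W)), identical(rownames(W), colnames(W)))
    if (!isTRUE(all.equal(W, t(W), check.attributes = FALSE))) {
      stop("W must be symmetric")
    }
    if (any(diag(W) != 0)) stop("W must have zero diagonal")
    if (any(W < 0)) stop("W must be nonnegative")
  }
  roster <- rownames(W)
  if (is.null(roster)) roster <- character()
  if (is.null(node_attrs)) {
    node_attrs <- tag_parity(roster)
    names(node_attrs) <- roster
  } else {
    node_attrs <- node_attrs[roster]
  }
  structure(
    list(W = W, roster = roster, node_attrs = node_attrs,
         provenance = provenance),
    class = "assoc_net"
  )
}

#' @export
print.assoc_net <- function(x, ...) {
  nz <- sum(x$W[upper.tri(x$W)] > 0)
  cat(sprintf("Association network: %d nodes, %d nonzero dyads\n",
              length(x$roster), nz))
  if (length(x$provenance)) {
    keep <- vapply(x$provenance, function(v) length(v) == 1, logical(1))
    cat("  ", paste(names(x$provenance)[keep], unlist(x$provenance[keep]),
                    sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' @export
plot.assoc_net <- function(x, ...) {
  g <- igraph::graph_from_adjacency_matrix(x$W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cols <- c(odd = "#7570B3", even = "#1B9E77")
  vc <- cols[as.character(x$node_attrs)]
  vc[is.na(vc)] <- "grey60"
  igraph::plot.igraph(
    g, vertex.color = vc, vertex.label = NA, vertex.size = 6,
    edge.width = 1 + 4 * igraph::E(g)$weight / max(igraph::E(g)$weight, 1e-9),
    ...
  )
  invisible(x)
}

#' Half-weight index network from a group-by-individual matrix
#'
#' For each dyad, with `x` the number of events containing both and
#' `nA`, `nB` the numbers containing each individual, the half-weight
#' index is `2x / (nA + nB)`; dyads with `nA + nB = 0` score 0. Values lie
#' in `[0, 1]`, with 1 for a pair always seen together.
#'
#' @param gbi binary K x N matrix (events by individuals) with tag-id
#'   colnames.
#' @param node_attrs,provenance passed to [assoc_net()].
#' @return an `assoc_net`.
#' @examples
#' gbi <- rbind(e1 = c(A = 1, B = 1, C = 0), e2 = c(A = 0, B = 1, C = 1))
#' hwi(gbi)$W
#' @export
hwi <- function(gbi, node_attrs = NULL, provenance = list()) {
  if (!all(gbi %in% c(0, 1))) stop("gbi must be binary")
  gbi <- as.matrix(gbi)
  storage.mode(gbi) <- "double"
  x <- crossprod(gbi)              # co-occurrence counts
  n <- colSums(gbi)                # events per individual
  denom <- outer(n, n, "+")
  W <- ifelse(denom > 0, 2 * x / denom, 0)
  diag(W) <- 0
  ord <- order(colnames(W))
  W <- W[ord, ord, drop = FALSE]
  assoc_net(W, node_attrs = node_attrs, provenance = provenance)
}

#' Association networks in consecutive time windows
#'
#' Partitions a detection stream into consecutive non-overlapping windows
#' of `window_days` days counted from `origin_day`, runs each window
#' through event detection, GBI construction and the half-weight index,
#' and returns one network per window. Individuals unobserved in a window
#' are absent from that window's roster; windows without events yield
#' empty networks.
#'
#' @param detections detection data frame.
#' @param window_days window length in days (>= 1).
#' @param origin_day 0-based day the first window starts at; defaults to
#'   the first detection's day.
#' @param seg_config a [segmentation_config()].
#' @return list of `assoc_net`, with window start/end days in provenance.
#' @export
window_networks <- function(detections, window_days = 6L, origin_day = NULL,
                            seg_config = segmentation_config()) {
  stopifnot(window_days >= 1)
  if (nrow(detections) == 0) return(list())
  day <- detections$timestamp %/% DAY_S
  if (is.null(origin_day)) origin_day <- min(day)
  win <- (day - origin_day) %/% window_days
  out <- list()
  for (w in sort(unique(win))) {
    slice <- detections[win == w, , drop = FALSE]
    ev <- detect_groups(slice, seg_config)
    prov <- list(
      window = w,
      day_start = origin_day + w * window_days,
      day_end = origin_day + (w + 1) * window_days - 1
    )
    if (nrow(ev) == 0) {
      net <- assoc_net(matrix(0, 0, 0), provenance = prov)
    } else {
      net <- hwi(events_to_gbi(ev), provenance = prov)
    }
    out[[length(out) + 1L]] <- net
  }
  out
}

#' Binary spatial range-overlap matrix
#'
#' Scores a dyad 1 when both individuals were detected at at least one
#' common selective-feeder *site* within the considered detections; during
#' the manipulation the two parity feeders of a pair collapse onto their
#' parent site.
#'
#' @param detections feeder-context detections (rows at other contexts are
#'   rejected).
#' @param roster optional tag-id vector for the matrix order; default the
#'   sorted set of detected tags.
#' @return symmetric binary matrix with zero diagonal and tag dimnames.
#' @export
spatial_overlap <- function(detections, roster = NULL) {
  if (!is.null(detections$context) &&
      !all(detections$context == "selective_feeder")) {
    stop("spatial_overlap expects selective_feeder detections")
  }
  site <- location_site(detections$location_id)
  if (anyNA(site)) stop("unknown location -> site mapping")
  if (is.null(roster)) roster <- sort(unique(detections$tag_id))
  inc <- table(factor(detections$tag_id, levels = roster), site) > 0
  B <- (tcrossprod(inc * 1) > 0) * 1
  diag(B) <- 0
  dimnames(B) <- list(roster, roster)
  B
}

#' Restrict two matrices or networks to their common roster
#'
#' Matrix comparisons are run on the individuals observed in both of the
#' matrices being compared; both inputs are restricted to the sorted
#' intersection of their rosters, in the same order. Surviving dyad values
#' are unchanged.
#'
#' @param a,b `assoc_net` objects or square matrices with tag dimnames.
#' @return list of the two aligned objects (same classes as inputs).
#' @export
align_common <- function(a, b) {
  ra <- if (inherits(a, "assoc_net")) a$roster else rownames(a)
  rb <- if (inherits(b, "assoc_net")) b$roster else rownames(b)
  common <- sort(intersect(ra, rb))
  if (length(common) < 3) stop("fewer than 3 individuals in common")
  cut <- function(x) {
    if (inherits(x, "assoc_net")) {
      assoc_net(x$W[common, common, drop = FALSE],
                node_attrs = x$node_attrs[common],
                provenance = x$provenance)
    } else {
      x[common, common, drop = FALSE]
    }
  }
  list(cut(a), cut(b))
}

#' Percentage of one context's roster shared with another
#'
#' Reported as the integer-rounded percentage of the context roster that
#' also appears in the reference roster.
#'
#' @param context_roster,reference_roster character tag-id vectors.
#' @return list with `n_shared`, `n_context`, `percent`.
#' @export
roster_overlap <- function(context_roster, reference_roster) {
  n_shared <- length(intersect(context_roster, reference_roster))
  n_context <- length(unique(context_roster))
  list(
    n_shared = n_shared,
    n_context = n_context,
    percent = as.integer(round(100 * n_shared / n_context))
  )
}
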