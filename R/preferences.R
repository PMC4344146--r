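#' Initialise a social preference matrix
#'
#' The latent preference matrix `P` holds, for each dyad, the propensity of
#' two individuals to join the same foraging flock beyond chance. It starts
#' at zero (no prior ties) and is updated daily from observed feeder
#' co-memberships with [update_preferences()]; the same matrix then drives
#' recruitment at unmanipulated contexts, which is what carries imposed
#' feeder-level structure over to patches and nest-boxes.
#'
#' @param population a `flock_population`.
#' @return N x N zero matrix with tag-id dimnames.
#' @export
init_preferences <- function(population) {
  n <- nrow(population)
  P <- matrix(0, n, n, dimnames = list(population$tag_id, population$tag_id))
  P
}

#' Update the preference matrix from observed co-memberships
#'
#' Blends the current preference matrix towards the (row-normalised,
#' symmetrised) co-membership counts of a batch of gathering events:
#' `P' = (1 - rate) * P + rate * C`, where `C` is derived from the number
#' of events in which each dyad co-occurred. Symmetry and the zero
#' diagonal are preserved; with `rate = 0` the matrix is unchanged, with
#' `rate = 1` it is replaced by the normalised counts.
#'
#' @param P symmetric numeric matrix with zero diagonal, tag-id dimnames.
#' @param events list of character vectors of member tag ids (one vector
#'   per gathering event). Tags absent from `P`'s roster are ignored.
#' @param rate learning rate in `[0, 1]`.
#' @return Updated matrix of the same shape.
#' @export
update_preferences <- function(P, events, rate) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (!isTRUE(all.equal(P, t(P), check.attributes = FALSE))) {
    stop("P must be symmetric")
  }
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0 || length(events) == 0) {
    if (rate == 1 && length(events) == 0) {
      P[] <- 0
    }
    return(P)
  }
  roster <- rownames(P)
  n <- nrow(P)
  C <- matrix(0, n, n)
  for (ev in events) {
    idx <- match(unique(ev), roster)
    idx <- idx[!is.na(idx)]
    if (length(idx) >= 2) C[idx, idx] <- C[idx, idx] + 1
  }
  diag(C) <- 0
  rs <- rowSums(C)
  Cn <- C / pmax(rs, 1)
  Cn <- (Cn + t(Cn)) / 2
  out <- (1 - rate) * P + rate * Cn
  diag(out) <- 0
  out
}
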