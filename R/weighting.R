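# Sequence reweighting: identity-based neighbour counts and Meff.
#
# Phylogenetic relatedness violates the independence assumption of the
# Gaussian model; near-duplicate sequences are down-weighted by
# w(n) = 1/m_n, where m_n counts the sequences (self included) within an
# identity cutoff of sequence n.  Meff, the effective number of sequences,
# is the sum of the weights.

#' Pairwise sequence identity
#'
#' Fraction of positions at which two sequences carry the same non-gap
#' amino acid (gap-gap matches do not count as identical), over the
#' alignment length L.  The diagonal is set to 1 by convention, so that a
#' sequence is always its own neighbour.
#'
#' @param x an [msa()] object.
#' @return A symmetric N x N matrix of identity fractions.
#' @export
pairwise_identity <- function(x) {
  stopifnot(inherits(x, "msa"))
  M <- msa_int_matrix(x)
  counts <- matrix(0, x$N, x$N)
  for (a in 1:20) {
    Xa <- matrix(as.numeric(M == a), x$N, x$L)
    counts <- counts + tcrossprod(Xa)
  }
  id <- counts / x$L
  diag(id) <- 1
  id
}

#' Similarity cutoff for reweighting
#'
#' In \code{"fixed"} mode returns \code{fixed_r} (default 0.8).  In
#' \code{"auto"} mode the cutoff is inversely proportional to the mean
#' off-diagonal pairwise identity, \code{rho / mean_identity}, clipped to
#' \code{[r_min, r_max]}; with a single sequence there are no pairs and the
#' fixed default is returned.
#'
#' @param x an [msa()] object.
#' @param mode \code{"fixed"} or \code{"auto"}.
#' @param fixed_r cutoff used in fixed mode (and the N = 1 fallback).
#' @param rho proportionality constant for auto mode.
#' @param r_min,r_max clipping bounds for auto mode.
#' @return A single identity fraction in (0, 1].
#' @export
similarity_cutoff <- function(x, mode = c("fixed", "auto"), fixed_r = 0.8,
                              rho = 0.32, r_min = 0.5, r_max = 0.9) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    stopifnot(fixed_r > 0, fixed_r <= 1)
    return(fixed_r)
  }
  if (x$N == 1L) return(fixed_r)
  id <- pairwise_identity(x)
  mean_id <- mean(id[upper.tri(id)])
  if (mean_id <= 0) return(r_max)
  min(max(rho / mean_id, r_min), r_max)
}

#' Identity-based sequence weights and Meff
#'
#' For each sequence counts the number \code{m_n} of sequences (itself
#' included) sharing at least \code{r * L} identical amino acids with it,
#' assigns weight \code{w(n) = 1/m_n}, and sums the weights into the
#' effective sequence number Meff.
#'
#' @param x an [msa()] object.
#' @param r identity cutoff in (0, 1]; see [similarity_cutoff()].
#' @return An object of class \code{"seq_weights"}: list with
#'   \code{weights}, neighbour counts \code{m}, \code{r}, \code{meff},
#'   \code{N}.
#' @export
sequence_weights <- function(x, r = 0.8) {
  stopifnot(inherits(x, "msa"), r > 0, r <= 1)
  id <- pairwise_identity(x)
  # id * L is an integer count up to rounding; compare with a small slack
  m <- as.integer(rowSums(id * x$L >= r * x$L - 1e-9))
  w <- 1 / m
  structure(list(weights = w, m = m, r = r, meff = sum(w), N = x$N),
            class = "seq_weights")
}

#' Uniform (unit) weights
#'
#' The no-reweighting case: every sequence gets weight 1 and Meff = N,
#' reducing the weighted mean and covariance to their unweighted forms.
#'
#' @param x an [msa()] object (or an \code{"encoded_msa"}).
#' @return A \code{"seq_weights"} object with all weights 1.
#' @export
uniform_weights <- function(x) {
  n <- x$N
  structure(list(weights = rep(1, n), m = rep(1L, n), r = NA_real_,
                 meff = n, N = n),
            class = "seq_weights")
}

#' @export
print.seq_weights <- function(x, ...) {
  cat(sprintf("sequence weights: N = %d, r = %s, Meff = %.2f\n",
              x$N, format(x$r), x$meff))
  invisible(x)
}

#' Bin an alignment by effective size
#'
#' Standard Meff strata used when summarising performance across protein
#' families: small (Meff < 500), medium (500 <= Meff < 1000), large
#' (Meff >= 1000).
#'
#' @param meff numeric vector of effective sequence numbers.
#' @return Factor with levels \code{small}, \code{medium}, \code{large}.
#' @export
meff_bin <- function(meff) {
  cut(meff, breaks = c(-Inf, 500, 1000, Inf),
      labels = c("small", "medium", "large"), right = FALSE)
}
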