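# From coupling matrix to ranked contact predictions.
#
# Each s x s coupling block J(i,j) is summarised by the squared Frobenius
# norm of its double-centered (zero-sum gauge) form, the L x L score
# matrix gets the average product correction (APC), and pairs separated by
# more than min_separation positions are ranked by decreasing score.

#' Gauge-corrected pair score of a coupling block
#'
#' Double-centers the block (subtract row means and column means, add the
#' grand mean) and returns the sum of squared centered entries, i.e. the
#' squared Frobenius norm in the zero-sum gauge.  The score is invariant
#' under additive row/column shifts \code{J(k,l) -> J(k,l) + a(k) + b(l)},
#' which is the point of the centering: the raw Frobenius norm depends on
#' the gauge choice.
#'
#' @param block a square s x s numeric matrix.
#' @return A non-negative number.
#' @export
pair_score <- function(block) {
  block <- as.matrix(block)
  stopifnot(nrow(block) == ncol(block))
  centered <- sweep(sweep(block, 1L, rowMeans(block)),
                    2L, colMeans(block)) + mean(block)
  sum(centered ^ 2)
}

#' Pair score matrix of a coupling matrix
#'
#' Applies [pair_score()] to every s x s position-pair block of the
#' L*s x L*s coupling matrix, returning the L x L matrix of raw (pre-APC)
#' scores.  The diagonal is zero: the self-block J(i,i) is a
#' within-position term, not a pair coupling, and for near-singular models
#' its inverse-scale magnitude would otherwise drown the APC row sums.
#' Implemented with block-aggregation matrix algebra; identical to looping
#' [pair_score()] over the off-diagonal blocks.
#'
#' @param J coupling matrix of size L*s x L*s (or a \code{"gauss_model"}).
#' @param s encoding dimension (taken from the model if one is given).
#' @return Symmetric L x L matrix of non-negative scores.
#' @export
frobenius_scores <- function(J, s = NULL) {
  if (inherits(J, "gauss_model")) {
    s <- J$s
    J <- J$J
  }
  stopifnot(!is.null(s), nrow(J) == ncol(J), nrow(J) %% s == 0L)
  L <- nrow(J) %/% s
  U <- kronecker(diag(L), rep(1, s))            # Ls x L block aggregator
  S2 <- crossprod(U, (J * J) %*% U)             # sum of squared entries
  R <- J %*% U                                  # within-block row sums
  C <- crossprod(U, J)                          # within-block column sums
  B <- crossprod(U, R)                          # block totals
  # sum of squared double-centered entries:
  #   S2 - s * sum_k rowmean^2 - s * sum_l colmean^2 + s^2 * grandmean^2
  P <- S2 - crossprod(U, R * R) / s - (C * C) %*% U / s + (B * B) / s ^ 2
  P <- pmax(P, 0)
  P <- (P + t(P)) / 2
  diag(P) <- 0
  P
}

#' Average product correction
#'
#' Subtracts the separable background \code{rowsum(i) * colsum(j) / total}
#' from each entry of the score matrix, suppressing per-position signal
#' strength (entropic/phylogenetic) effects.  Applied to the full matrix
#' as stated, diagonal included; set \code{mask_diagonal = TRUE} to zero
#' the diagonal before computing the sums.
#'
#' @param P square score matrix.
#' @param mask_diagonal zero out the diagonal before the correction.
#' @return The APC-corrected matrix (same shape).
#' @export
apc_correct <- function(P, mask_diagonal = FALSE) {
  P <- as.matrix(P)
  stopifnot(nrow(P) == ncol(P))
  if (mask_diagonal) diag(P) <- 0
  tot <- sum(P)
  if (tot == 0) {
    warning("score matrix sums to zero; APC correction is a no-op")
    return(P)
  }
  P - outer(rowSums(P), colSums(P)) / tot
}

#' Rank position pairs into contact predictions
#'
#' Keeps pairs \code{(i, j)} with \code{i < j} and
#' \code{j - i > min_separation}, sorts them by decreasing score with ties
#' broken lexicographically on \code{(i, j)}, and truncates to the top
#' \code{top_k}.
#'
#' @param P_apc square (APC-corrected) score matrix; positions are
#'   1-based.
#' @param min_separation minimum sequence separation; pairs must satisfy
#'   \code{j - i > min_separation} (default 4).
#' @param top_k maximum number of pairs returned (default 200).
#' @param P_raw optional matching matrix of raw scores to carry along.
#' @return An object of class \code{"contact_prediction"}: a data.frame
#'   with columns \code{rank}, \code{i}, \code{j}, \code{score} (and
#'   \code{raw_score} when \code{P_raw} is given), plus attributes
#'   \code{min_separation}, \code{L}.
#' @export
rank_contacts <- function(P_apc, min_separation = 4, top_k = 200,
                          P_raw = NULL) {
  P_apc <- as.matrix(P_apc)
  L <- nrow(P_apc)
  stopifnot(ncol(P_apc) == L, L >= 2)
  idx <- which(upper.tri(P_apc), arr.ind = TRUE)
  keep <- (idx[, 2L] - idx[, 1L]) > min_separation
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) == 0L) {
    warning("no eligible pairs: L <= min_separation + 1")
    df <- data.frame(rank = integer(), i = integer(), j = integer(),
                     score = numeric())
  } else {
    sc <- P_apc[idx]
    ord <- order(-sc, idx[, 1L], idx[, 2L])
    ord <- utils::head(ord, top_k)
    df <- data.frame(rank = seq_along(ord),
                     i = as.integer(idx[ord, 1L]),
                     j = as.integer(idx[ord, 2L]),
                     score = sc[ord])
    if (!is.null(P_raw)) df$raw_score <- as.matrix(P_raw)[idx[ord, , drop = FALSE]]
  }
  structure(df, class = c("contact_prediction", "data.frame"),
            min_separation = min_separation, L = L)
}

#' Write ranked contacts to TSV
#'
#' @param prediction a \code{"contact_prediction"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_contacts <- function(prediction, path) {
  utils::write.table(as.data.frame(prediction), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranked-contact TSV
#'
#' @param path TSV with at least columns \code{i} and \code{j} (1-based).
#' @return A data.frame of class \code{"contact_prediction"}.
#' @export
read_contacts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("i", "j") %in% names(df)))
  if (is.null(df$rank)) df$rank <- seq_len(nrow(df))
  structure(df, class = c("contact_prediction", "data.frame"),
            min_separation = NA_integer_, L = NA_integer_)
}
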