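# The multivariate Gaussian model of an encoded MSA.
#
# Each encoded sequence X_n (length L*s) is modelled as a draw from a
# multivariate Gaussian.  The empirical covariance is blended with a
# block-diagonal prior derived from a uniform amino-acid composition, and
# the inverse of the blended covariance -- the precision matrix -- carries
# the position-pair couplings used for contact prediction.

#' Weighted empirical mean and covariance
#'
#' Computes the weighted mean row vector and the weighted (population-type)
#' covariance of the encoded sequences:
#' \code{Xbar = sum(w_n X_n) / sum(w_n)} and
#' \code{Cbar = sum(w_n (X_n - Xbar)' (X_n - Xbar)) / sum(w_n)}.
#' Uniform weights reduce these to the plain empirical mean/covariance.
#'
#' @param encoded an \code{"encoded_msa"} (see [encode_msa()]) or a plain
#'   numeric matrix with one sequence per row.
#' @param weights a \code{"seq_weights"} object, a numeric vector of
#'   positive weights, or \code{NULL} for uniform weights.
#' @return List with \code{xbar} (length L*s) and \code{cbar}
#'   (L*s x L*s, symmetric positive semi-definite).
#' @export
weighted_mean_cov <- function(encoded, weights = NULL) {
  X <- if (inherits(encoded, "encoded_msa")) encoded$X else as.matrix(encoded)
  w <- .weights_vector(weights, nrow(X))
  sw <- sum(w)
  stopifnot(sw > 0)
  xbar <- colSums(X * w) / sw
  Xc <- sweep(X, 2L, xbar)
  cbar <- crossprod(Xc * sqrt(w)) / sw
  cbar <- (cbar + t(cbar)) / 2
  list(xbar = xbar, cbar = cbar)
}

.weights_vector <- function(weights, n) {
  if (is.null(weights)) return(rep(1, n))
  w <- if (inherits(weights, "seq_weights")) weights$weights else weights
  stopifnot(length(w) == n, all(w > 0))
  as.numeric(w)
}

#' Uniform-composition prior for the Gaussian model
#'
#' The prior assumes every position draws its amino acid uniformly from
#' the 20 types: \code{rbar} is the mean of the 20 encoding vectors and
#' \code{Cr} their population covariance.  The whole-alignment prior mean
#' is L copies of \code{rbar} and the prior covariance is block-diagonal
#' with \code{Cr} on each position block -- positions are independent under
#' the prior, so by itself it carries no coupling information.
#'
#' @param encoding an [aa_encoding()].
#' @param L alignment length.
#' @return An object of class \code{"gauss_prior"}: list with \code{rbar}
#'   (s), \code{Cr} (s x s), \code{mu} (L*s), \code{CP} (L*s x L*s),
#'   \code{s}, \code{L}.
#' @export
build_prior <- function(encoding, L) {
  stopifnot(inherits(encoding, "aa_encoding"), L >= 1)
  V <- encoding$vectors
  rbar <- colMeans(V)
  Vc <- sweep(V, 2L, rbar)
  Cr <- crossprod(Vc) / 20
  Cr <- (Cr + t(Cr)) / 2
  structure(list(rbar = rbar, Cr = Cr,
                 mu = rep(rbar, L),
                 CP = kronecker(diag(L), Cr),
                 s = encoding$s, L = as.integer(L)),
            class = "gauss_prior")
}

#' Prior-corrected covariance
#'
#' Blends the empirical covariance with the prior covariance:
#' \code{CM = lambda * CP + (1 - lambda) * Cbar +
#'   lambda * (1 - lambda) * (Xbar - muP)' (Xbar - muP)}.
#' At \code{lambda = 0} this is exactly \code{Cbar}; at \code{lambda = 1}
#' exactly \code{CP}.
#'
#' @param xbar weighted empirical mean (length L*s).
#' @param cbar weighted empirical covariance (L*s x L*s).
#' @param prior a \code{"gauss_prior"} (see [build_prior()]).
#' @param lambda prior weight in [0, 1].
#' @return The corrected covariance matrix CM.
#' @export
corrected_covariance <- function(xbar, cbar, prior, lambda) {
  stopifnot(inherits(prior, "gauss_prior"),
            lambda >= 0, lambda <= 1,
            length(xbar) == length(prior$mu),
            all(dim(cbar) == dim(prior$CP)))
  d <- xbar - prior$mu
  lambda * prior$CP + (1 - lambda) * cbar +
    (lambda * (1 - lambda)) * tcrossprod(d)
}

#' Invert the corrected covariance into the coupling matrix
#'
#' Computes \code{J = (CM + eps * I)^(-1)} by Cholesky factorization.
#' \code{eps} is 0 when CM factorizes as is; otherwise the smallest value
#' from a geometric ladder (\code{ridge_start_rel * mean(diag(CM))},
#' growing by \code{ridge_factor} up to \code{ridge_max_rel * mean(diag)})
#' that makes the factorization succeed.  With \code{ridge = "none"} a
#' singular CM is an error: the 20-dimensional binary encoding without
#' gaps is provably singular at \code{lambda < 1} (each position block has
#' an all-ones null direction), which the prior or the ridge must absorb.
#'
#' @param CM corrected covariance (symmetric).
#' @param ridge \code{"auto"} (ladder) or \code{"none"} (fail if singular).
#' @param ridge_start_rel,ridge_max_rel,ridge_factor ladder geometry,
#'   relative to \code{mean(diag(CM))}.
#' @return List with \code{J} (the precision / coupling matrix) and
#'   \code{epsilon} (the ridge actually applied).
#' @export
coupling_matrix <- function(CM, ridge = c("auto", "none"),
                            ridge_start_rel = 1e-8, ridge_max_rel = 1e-2,
                            ridge_factor = 10) {
  ridge <- match.arg(ridge)
  d <- ncol(CM)
  scale <- mean(diag(CM))
  if (!is.finite(scale) || scale <= 0)
    stop("corrected covariance has non-positive diagonal; ",
         "raise lambda or check the encoding")
  eps_ladder <- if (ridge == "none") 0 else
    c(0, ridge_start_rel * scale *
        ridge_factor ^ (0:ceiling(log(ridge_max_rel / ridge_start_rel,
                                      ridge_factor))))
  for (eps in eps_ladder) {
    ch <- tryCatch(chol(CM + diag(eps, d)), error = function(e) NULL)
    if (!is.null(ch)) {
      J <- chol2inv(ch)
      J <- (J + t(J)) / 2
      return(list(J = J, epsilon = eps))
    }
  }
  stop("corrected covariance is singular even after ridging up to ",
       signif(max(eps_ladder), 3),
       "; raise lambda or the ridge ceiling")
}

#' Gaussian log-likelihood of encoded sequences
#'
#' Sum over sequences of the log multivariate normal density with mean
#' \code{mu} and covariance \code{sigma}.
#'
#' @param encoded an \code{"encoded_msa"} or numeric matrix (rows =
#'   sequences).
#' @param mu mean vector.
#' @param sigma positive-definite covariance matrix.
#' @return The log-likelihood (a single number).
#' @export
gaussian_log_likelihood <- function(encoded, mu, sigma) {
  X <- if (inherits(encoded, "encoded_msa")) encoded$X else as.matrix(encoded)
  d <- length(mu)
  stopifnot(ncol(X) == d, all(dim(sigma) == d))
  ch <- tryCatch(chol(sigma),
                 error = function(e) stop("sigma is not positive definite"))
  logdet <- 2 * sum(log(diag(ch)))
  Z <- backsolve(ch, t(sweep(X, 2L, mu)), transpose = TRUE)
  quad <- colSums(Z ^ 2)
  -0.5 * (nrow(X) * d * log(2 * pi) + nrow(X) * logdet + sum(quad))
}

#' Fit the full Gaussian model of an alignment
#'
#' Convenience wrapper: encodes nothing itself but chains
#' [weighted_mean_cov()], [build_prior()], [corrected_covariance()] and
#' [coupling_matrix()] on an already-encoded MSA.
#'
#' @param encoded an \code{"encoded_msa"}.
#' @param weights a \code{"seq_weights"} or numeric vector; \code{NULL}
#'   for uniform.
#' @param lambda prior weight in [0, 1] (default 0.8, the optimum for the
#'   20-dimensional binary encoding).
#' @param ridge,ridge_start_rel,ridge_max_rel,ridge_factor passed to
#'   [coupling_matrix()].
#' @return An object of class \code{"gauss_model"}: list with \code{xbar},
#'   \code{lambda}, \code{J}, \code{epsilon}, \code{meff}, \code{L},
#'   \code{s}, \code{encoding_label}.
#' @export
gaussian_model <- function(encoded, weights = NULL, lambda = 0.8,
                           ridge = "auto", ridge_start_rel = 1e-8,
                           ridge_max_rel = 1e-2, ridge_factor = 10) {
  stopifnot(inherits(encoded, "encoded_msa"))
  mc <- weighted_mean_cov(encoded, weights)
  prior <- build_prior(encoded$encoding, encoded$L)
  CM <- corrected_covariance(mc$xbar, mc$cbar, prior, lambda)
  cp <- coupling_matrix(CM, ridge = ridge,
                        ridge_start_rel = ridge_start_rel,
                        ridge_max_rel = ridge_max_rel,
                        ridge_factor = ridge_factor)
  meff <- if (inherits(weights, "seq_weights")) weights$meff
          else sum(.weights_vector(weights, encoded$N))
  structure(list(xbar = mc$xbar, lambda = lambda, J = cp$J,
                 epsilon = cp$epsilon, meff = meff,
                 L = encoded$L, s = encoded$s,
                 encoding_label = encoded$encoding$label),
            class = "gauss_model")
}

#' @export
print.gauss_model <- function(x, ...) {
  cat(sprintf(
    "Gaussian MSA model: L = %d, s = %d, encoding '%s'\n  lambda = %g, ridge eps = %g, Meff = %.2f\n",
    x$L, x$s, x$encoding_label, x$lambda, x$epsilon, x$meff))
  invisible(x)
}
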