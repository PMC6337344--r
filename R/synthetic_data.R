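# Seeded synthetic alignments with planted coupled column pairs.
#
# The generator is the download-free test bed for the pipeline: background
# columns are i.i.d. from a 20-letter composition, planted pairs covary
# through a matched-type joint draw, chained triples create indirect
# correlations, gaps are sprinkled i.i.d., and a fraction of rows are
# exact duplicates to exercise the reweighting.

#' Specify a synthetic alignment
#'
#' @param L alignment length.
#' @param N number of sequences.
#' @param planted_pairs two-column matrix of coupled column pairs with
#'   \code{j - i > 4}; pairs must not share columns.  \code{NULL} for
#'   none; see [spaced_pairs()] for a deterministic layout.
#' @param coupling probability in [0, 1] that a planted pair is drawn
#'   jointly (matched types) rather than independently.
#' @param background length-20 frequency vector over the amino acids
#'   (canonical order); defaults to uniform.
#' @param gap_rate i.i.d. per-cell gap probability.
#' @param duplicate_rate fraction of sequences emitted as exact copies of
#'   earlier sequences.
#' @param chained_triples list of integer triples \code{c(i, j, k)}: i-j
#'   and j-k are planted (direct), i-k is left to arise only indirectly.
#'   All gaps between consecutive members must exceed 4; columns must be
#'   disjoint from \code{planted_pairs} and other triples.
#' @param seed integer seed governing every draw.
#' @return An object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(L, N, planted_pairs = NULL, coupling = 0.8,
                           background = NULL, gap_rate = 0,
                           duplicate_rate = 0, chained_triples = NULL,
                           seed = 1L) {
  if (is.null(background)) background <- rep(1 / 20, 20)
  stopifnot(L >= 1, N >= 1,
            coupling >= 0, coupling <= 1,
            gap_rate >= 0, gap_rate <= 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            length(background) == 20, all(background >= 0),
            abs(sum(background) - 1) < 1e-8)
  if (!is.null(planted_pairs)) {
    planted_pairs <- as.matrix(planted_pairs)[, 1:2, drop = FALSE]
    storage.mode(planted_pairs) <- "integer"
    if (any(planted_pairs < 1L | planted_pairs > L))
      stop("planted pair positions outside 1..L")
    if (any(planted_pairs[, 2L] - planted_pairs[, 1L] <= 4L))
      stop("planted pairs must satisfy j - i > 4")
  } else {
    planted_pairs <- matrix(integer(), 0L, 2L)
  }
  chain_cols <- unlist(chained_triples)
  if (!is.null(chained_triples)) {
    for (tr in chained_triples) {
      stopifnot(length(tr) == 3L)
      if (any(diff(sort(tr)) <= 4L) || any(tr < 1L | tr > L))
        stop("chained triples need pairwise separation > 4 within 1..L")
    }
  }
  used <- c(as.vector(planted_pairs), chain_cols)
  if (anyDuplicated(used))
    stop("planted pairs / chained triples share columns")
  structure(list(L = as.integer(L), N = as.integer(N),
                 planted_pairs = planted_pairs, coupling = coupling,
                 background = background, gap_rate = gap_rate,
                 duplicate_rate = duplicate_rate,
                 chained_triples = chained_triples,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Deterministic layout of disjoint planted pairs
#'
#' Pair m is \code{(7m - 6, 7m - 1)}: separation 5 (> 4), pairwise
#' disjoint, packed from the left.
#'
#' @param L alignment length.
#' @param n_pairs number of pairs; must fit in L.
#' @return An \code{n_pairs} x 2 integer matrix.
#' @export
spaced_pairs <- function(L, n_pairs) {
  i <- 7L * seq_len(n_pairs) - 6L
  j <- i + 5L
  if (any(j > L)) stop(n_pairs, " spaced pairs do not fit in L = ", L)
  cbind(i = i, j = j)
}

#' Generate a synthetic alignment with known coupled pairs
#'
#' Non-planted cells are i.i.d. draws from the background composition.
#' For each planted pair, with probability \code{coupling} the two
#' residues are drawn jointly from the matched-type pair table (both equal
#' to one background draw), otherwise independently.  Each chained triple
#' (i, j, k) couples i and k to the middle column j the same way, so i-k
#' correlate only indirectly.  Gaps then overwrite cells i.i.d. at
#' \code{gap_rate}, and \code{duplicate_rate * N} of the rows are replaced
#' by exact copies of earlier rows.  Fully reproducible from the seed.
#'
#' @param spec a [synthetic_spec()].
#' @return List of class \code{"synthetic_msa"} with \code{msa} (an
#'   [msa()]), and \code{truth}: list with \code{planted_pairs} (direct
#'   pairs, chained ones included), \code{indirect_pairs} (the i-k pairs
#'   of chained triples) and the generator \code{spec}.
#' @export
generate_msa <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  N <- spec$N
  L <- spec$L
  M <- matrix(sample.int(20L, N * L, replace = TRUE, prob = spec$background),
              N, L)
  plant <- function(from, to) {
    joint <- stats::runif(N) < spec$coupling
    M[joint, to] <<- M[joint, from]
  }
  pp <- spec$planted_pairs
  for (q in seq_len(nrow(pp))) plant(pp[q, 1L], pp[q, 2L])
  direct <- pp
  indirect <- matrix(integer(), 0L, 2L)
  for (tr in spec$chained_triples) {
    i <- tr[[1L]]; j <- tr[[2L]]; k <- tr[[3L]]
    plant(j, i)
    plant(j, k)
    direct <- rbind(direct, c(min(i, j), max(i, j)), c(min(j, k), max(j, k)))
    indirect <- rbind(indirect, c(min(i, k), max(i, k)))
  }
  if (spec$gap_rate > 0)
    M[stats::runif(N * L) < spec$gap_rate] <- 0L
  n_dup <- round(spec$duplicate_rate * N)
  if (n_dup > 0L) {
    originals <- seq_len(N - n_dup)
    copies <- sample(originals, n_dup, replace = TRUE)
    M[(N - n_dup + 1L):N, ] <- M[copies, , drop = FALSE]
  }
  letters21 <- c(.GAP, aa_alphabet())
  seqs <- apply(M, 1L, function(row) paste(letters21[row + 1L], collapse = ""))
  out <- msa(seqs, ids = sprintf("synth_%05d", seq_len(N)))
  structure(list(msa = out,
                 truth = list(planted_pairs = direct,
                              indirect_pairs = indirect,
                              spec = spec)),
            class = "synthetic_msa")
}

#' Write a synthetic alignment and its truth to disk
#'
#' Writes the alignment as FASTA and the planted (direct) pairs as a
#' two-column TSV directly usable as a contact-map file.
#'
#' @param x a \code{"synthetic_msa"}.
#' @param fasta_path,truth_path output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_synthetic <- function(x, fasta_path, truth_path) {
  stopifnot(inherits(x, "synthetic_msa"))
  write_msa(x$msa, fasta_path)
  write_contact_tsv(contact_map(x$truth$planted_pairs,
                                n_residues = x$msa$L),
                    truth_path)
  invisible(list(fasta = fasta_path, truth = truth_path))
}
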