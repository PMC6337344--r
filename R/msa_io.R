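# MSA input/output and cleanup.

#' Canonical amino-acid alphabet
#'
#' The 20 standard amino acids in the order used throughout the package
#' (the AAindex / substitution-matrix row order), plus \code{"-"} for gaps.
#' All encodings, frequency vectors and integer representations index amino
#' acids in this order.
#'
#' @format Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

.GAP <- "-"
# ambiguity / non-standard codes collapsed to gap (zero vector downstream)
.AMBIGUOUS <- c("B", "Z", "X", "J", "O", "U")

#' Construct a multiple sequence alignment object
#'
#' @param sequences character vector of equal-length aligned sequences over
#'   the canonical alphabet (see [aa_alphabet()]) plus \code{"-"}.
#' @param ids per-sequence identifiers; defaults to \code{seq_1 ...}.
#' @return An object of class \code{"msa"}: a list with \code{sequences},
#'   \code{ids}, \code{N} (sequence count) and \code{L} (alignment length).
#' @export
msa <- function(sequences, ids = NULL) {
  if (length(sequences) < 1L) stop("empty alignment: no sequences")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths differ (",
         paste(unique(lens), collapse = ", "), ")")
  L <- lens[[1L]]
  if (L < 1L) stop("empty alignment: zero-length sequences")
  if (is.null(ids)) ids <- paste0("seq_", seq_along(sequences))
  bad <- setdiff(unique(unlist(strsplit(sequences, "", fixed = TRUE))),
                 c(aa_alphabet(), .GAP))
  if (length(bad) > 0L)
    stop("unknown symbol(s) after mapping: ", paste(bad, collapse = ", "))
  structure(list(sequences = unname(sequences), ids = unname(as.character(ids)),
                 N = length(sequences), L = L),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("MSA: %d sequences of length %d\n", x$N, x$L))
  invisible(x)
}

# map raw residue symbols to the canonical 21-letter alphabet:
# uppercase; '.' and '-' -> gap; ambiguity codes (B,Z,X,J,O,U) -> gap
.canonicalize <- function(seqs) {
  seqs <- toupper(seqs)
  gsub(paste0("[.", paste(.AMBIGUOUS, collapse = ""), "]"), .GAP, seqs)
}

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or A2M file.  Sequences are uppercased; \code{.}
#' and \code{-} map to the gap symbol; the ambiguity codes B, Z, X, J, O and
#' U also map to gap, so that they contribute zero vectors downstream.
#' A2M lowercase (insert) columns are uppercased and kept.
#'
#' @param path path to the alignment file.
#' @param format \code{"fasta"} or \code{"a2m"} (both are FASTA-shaped;
#'   the distinction is documentary).
#' @return An [msa()] object.
#' @export
read_msa <- function(path, format = c("fasta", "a2m")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("empty alignment file: ", path)
  seqs <- .canonicalize(as.character(set))
  msa(seqs, ids = names(set))
}

#' Write an alignment to FASTA
#'
#' @param x an [msa()] object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_msa <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  set <- Biostrings::AAStringSet(stats::setNames(x$sequences, x$ids))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Remove overly gapped sequences
#'
#' Drops every sequence whose gap fraction strictly exceeds
#' \code{max_gap_fraction} (a sequence sitting exactly on the bound is
#' retained).  Order is preserved.
#'
#' @param x an [msa()] object.
#' @param max_gap_fraction maximum tolerated gap fraction (default 0.9).
#' @return A filtered [msa()] object.
#' @export
clean_msa <- function(x, max_gap_fraction = 0.9) {
  stopifnot(inherits(x, "msa"))
  gap_frac <- .gap_fraction(x)
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep))
    stop("all sequences removed: every gap fraction exceeds ",
         max_gap_fraction)
  msa(x$sequences[keep], ids = x$ids[keep])
}

.gap_fraction <- function(x) {
  (nchar(gsub("[^-]", "", x$sequences))) / x$L
}

# integer representation: N x L matrix, 0 = gap, 1..20 = canonical index
msa_int_matrix <- function(x) {
  stopifnot(inherits(x, "msa"))
  codes <- match(
    unlist(strsplit(x$sequences, "", fixed = TRUE)),
    aa_alphabet(), nomatch = 0L)
  matrix(codes, nrow = x$N, ncol = x$L, byrow = TRUE)
}
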