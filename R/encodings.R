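# Amino-acid -> numeric-vector encodings and MSA numerization.
#
# An encoding maps each of the 20 amino acids to a length-s real vector;
# the gap symbol always maps to the zero vector, so gapped positions carry
# no signal into the Gaussian model.

#' Construct an amino-acid encoding
#'
#' @param vectors numeric matrix with 20 rows (one per amino acid, in
#'   [aa_alphabet()] order) and \code{s} columns.
#' @param label provenance string, e.g. \code{"binary20"},
#'   \code{"aaindex:KYTJ820101"}, \code{"blosum62:pca:11"}.
#' @return An object of class \code{"aa_encoding"} with fields \code{s},
#'   \code{vectors} (20 x s, rownames = amino acids) and \code{label}.
#' @export
aa_encoding <- function(vectors, label = "custom") {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != 20L)
    stop("encoding must have exactly 20 amino-acid rows")
  if (!all(is.finite(vectors)))
    stop("encoding contains non-finite values")
  rownames(vectors) <- aa_alphabet()
  structure(list(s = ncol(vectors), vectors = vectors, label = label),
            class = "aa_encoding")
}

#' @export
print.aa_encoding <- function(x, ...) {
  cat(sprintf("amino-acid encoding '%s' (s = %d)\n", x$label, x$s))
  invisible(x)
}

# 21 x s matrix with the gap zero-vector as first row; row index = code + 1
.encoding_table21 <- function(enc) {
  rbind(matrix(0, 1L, enc$s), enc$vectors)
}

#' 20-dimensional binary (one-hot) encoding
#'
#' Amino acid i maps to the indicator vector with 1 at its own alphabet
#' index and 0 elsewhere; the gap maps to 20 zeros.  This is the encoding
#' used by classical Gaussian/precision-matrix contact predictors.
#'
#' @return An [aa_encoding()] with \code{s = 20}.
#' @export
binary20_encoding <- function() {
  aa_encoding(diag(20), label = "binary20")
}

#' Parse an AAindex1 flat file
#'
#' Reads the standard AAindex1 record structure (\code{H} accession,
#' \code{D} description, \code{I} index line followed by two rows of ten
#' values in ARNDCQEGHI / LKMFPSTWYV order, records terminated by
#' \code{//}).  Entries with any missing (\code{NA}) value are flagged
#' unusable rather than imputed.
#'
#' @param path path to an AAindex1-format flat file.
#' @param clusters optional named character vector mapping accessions to
#'   one of the six property clusters (A, B, C, H, P, O); entries absent
#'   from the map get cluster \code{"unknown"}.
#' @return A list of objects of class \code{"aaindex_entry"} with fields
#'   \code{accession}, \code{description}, \code{values} (named numeric of
#'   length 20, may contain \code{NA}), \code{cluster}, \code{usable}.
#' @export
load_aaindex1 <- function(path, clusters = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//", lines)
  if (length(ends) == 0L) stop("no AAindex records (missing '//') in ", path)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- vector("list", length(ends))
  for (r in seq_along(ends)) {
    rec <- lines[starts[r]:ends[r]]
    acc <- sub("^H\\s+", "", grep("^H\\s", rec, value = TRUE)[1])
    desc <- sub("^D\\s+", "", grep("^D\\s", rec, value = TRUE)[1])
    ipos <- grep("^I\\s", rec)
    if (length(ipos) != 1L || ipos + 2L > length(rec))
      stop("malformed I record in AAindex entry ", r)
    toks <- unlist(strsplit(trimws(rec[(ipos + 1L):(ipos + 2L)]), "\\s+"))
    if (length(toks) != 20L)
      stop("AAindex entry ", r, ": expected 20 values, got ", length(toks))
    vals <- suppressWarnings(as.numeric(toks))
    vals[toupper(toks) == "NA"] <- NA_real_
    if (any(is.na(vals) & toupper(toks) != "NA"))
      stop("AAindex entry ", r, ": unparseable value(s)")
    # I-record order is ARNDCQEGHI then LKMFPSTWYV == canonical order
    names(vals) <- aa_alphabet()
    cl <- "unknown"
    if (!is.null(clusters) && !is.na(acc) && acc %in% names(clusters))
      cl <- unname(clusters[[acc]])
    out[[r]] <- structure(
      list(accession = acc, description = desc, values = vals,
           cluster = cl, usable = all(is.finite(vals))),
      class = "aaindex_entry")
  }
  out
}

#' One-dimensional property encoding
#'
#' Encodes each amino acid by a single real property value (a Gauss1D
#' encoding); the gap maps to 0.  Values are used raw: the final contact
#' ranking is invariant under affine rescaling of the scale.
#'
#' @param index an \code{"aaindex_entry"} (see [load_aaindex1()]) or a
#'   named numeric vector with one value per amino acid.
#' @return An [aa_encoding()] with \code{s = 1}.
#' @export
property_encoding <- function(index) {
  if (inherits(index, "aaindex_entry")) {
    if (!index$usable)
      stop("AAindex entry ", index$accession,
           " has missing values and cannot be used as an encoding")
    vals <- index$values
    label <- paste0("aaindex:", index$accession)
  } else {
    vals <- index
    label <- "property1d"
  }
  if (is.null(names(vals))) names(vals) <- aa_alphabet()
  vals <- vals[aa_alphabet()]
  if (any(is.na(vals))) stop("property index must cover all 20 amino acids")
  aa_encoding(matrix(vals, ncol = 1L), label = label)
}

#' Load a BLOSUM substitution matrix
#'
#' Returns the 20 x 20 amino-acid block of a BLOSUM matrix (canonical
#' alphabet order) from the matrices distributed with Biostrings
#' (BLOSUM45, 50, 62, 80, 100).  Other matrices can be supplied as files
#' through [read_substitution_matrix()].
#'
#' @param name matrix name (\code{"BLOSUM62"}) or clustering id (\code{62}).
#' @return A symmetric 20 x 20 numeric matrix with dim names, and a
#'   \code{"name"} attribute.
#' @export
blosum_matrix <- function(name = "BLOSUM62") {
  if (is.numeric(name)) name <- paste0("BLOSUM", name)
  name <- toupper(name)
  avail <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100")
  if (!name %in% avail)
    stop(name, " not available; choose one of ",
         paste(avail, collapse = ", "),
         " or load a matrix file with read_substitution_matrix()")
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- get(name, envir = env)[aa_alphabet(), aa_alphabet()]
  m <- matrix(as.numeric(m), 20L, 20L,
              dimnames = list(aa_alphabet(), aa_alphabet()))
  attr(m, "name") <- name
  m
}

#' Read a substitution matrix from a square text file
#'
#' Parses the standard square matrix text format: optional \code{#}
#' comment lines, a header row of residue letters, then one row per
#' residue starting with its letter.  Only the 20 standard amino acids are
#' kept, reordered canonically.
#'
#' @param path path to the matrix file.
#' @param name label stored on the result.
#' @param tol symmetry tolerance.
#' @return A symmetric 20 x 20 numeric matrix (canonical order).
#' @export
read_substitution_matrix <- function(path, name = basename(path),
                                     tol = 1e-8) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- grep("^\\s*#", readLines(path, warn = FALSE),
                value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a square matrix file: ", path)
  header <- unlist(strsplit(trimws(lines[1L]), "\\s+"))
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  rlet <- vapply(body, `[[`, "", 1L)
  vals <- lapply(body, function(x) as.numeric(x[-1L]))
  if (any(lengths(vals) != length(header)))
    stop("matrix rows do not match header width in ", path)
  m <- do.call(rbind, vals)
  dimnames(m) <- list(rlet, header)
  missing <- setdiff(aa_alphabet(), intersect(rlet, header))
  if (length(missing) > 0L)
    stop("matrix lacks amino acid(s): ", paste(missing, collapse = ", "))
  m <- m[aa_alphabet(), aa_alphabet()]
  if (max(abs(m - t(m))) > tol)
    stop("substitution matrix is asymmetric beyond tolerance ", tol)
  attr(m, "name") <- name
  m
}

# PCA of a point configuration: rows are points.  Columns are centered,
# eigenvectors of the (1/n) covariance are ordered by descending eigenvalue
# with the largest-magnitude loading of each component made positive, and
# coordinates are raw projections (not whitened).
pca_coords <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  centered <- sweep(points, 2L, colMeans(points))
  covm <- crossprod(centered) / n
  e <- eigen(covm, symmetric = TRUE)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(coords = centered %*% V[, seq_len(k), drop = FALSE],
       sdev = sqrt(pmax(e$values, 0)))
}

#' Principal-component embedding of a substitution matrix
#'
#' Treats each amino acid's row of a (symmetric) substitution matrix as a
#' point in 20-dimensional space and assigns each amino acid its
#' coordinates along the top \code{k} principal components of that point
#' cloud.  Components are ordered by descending variance; each component's
#' sign is fixed so that its largest-magnitude loading is positive, making
#' the embedding reproducible.  The gap maps to \code{k} zeros.
#'
#' @param matrix a symmetric 20 x 20 substitution matrix
#'   (see [blosum_matrix()] / [read_substitution_matrix()]).
#' @param k embedding dimension, between 1 and 20.
#' @param tol symmetry tolerance.
#' @return An [aa_encoding()] with \code{s = k}.
#' @export
blosum_pca_encoding <- function(matrix, k, tol = 1e-8) {
  m <- base::as.matrix(matrix)
  if (!all(dim(m) == c(20L, 20L)))
    stop("substitution matrix must be 20 x 20")
  if (max(abs(m - t(m))) > tol)
    stop("substitution matrix is asymmetric beyond tolerance ", tol)
  if (length(k) != 1L || k != as.integer(k) || k < 1L || k > 20L)
    stop("k must be an integer in 1..20")
  name <- attr(matrix, "name")
  if (is.null(name)) name <- "submat"
  p <- pca_coords(m, as.integer(k))
  aa_encoding(p$coords, label = sprintf("%s:pca:%d", tolower(name), k))
}

#' Numerize an alignment under an encoding
#'
#' Replaces each residue of each sequence by its encoding vector, giving
#' one real-valued row of length \code{L * s} per sequence; position p of
#' sequence n occupies columns \code{(p-1)*s + 1 .. p*s}.  Gaps contribute
#' zero vectors.
#'
#' @param x an [msa()] object.
#' @param encoding an [aa_encoding()].
#' @return An object of class \code{"encoded_msa"}: list with the numeric
#'   matrix \code{X} (N x L*s), \code{encoding}, \code{N}, \code{L},
#'   \code{s} and the source \code{ids}.
#' @export
encode_msa <- function(x, encoding) {
  stopifnot(inherits(x, "msa"), inherits(encoding, "aa_encoding"))
  M <- msa_int_matrix(x)
  tab <- .encoding_table21(encoding)
  s <- encoding$s
  A <- tab[as.vector(M) + 1L, , drop = FALSE]      # (N*L) x s, rows (n, p)
  arr <- array(A, dim = c(x$N, x$L, s))            # arr[n, p, k]
  X <- matrix(aperm(arr, c(1L, 3L, 2L)), nrow = x$N, ncol = x$L * s)
  structure(list(X = X, encoding = encoding, N = x$N, L = x$L, s = s,
                 ids = x$ids),
            class = "encoded_msa")
}

#' @export
print.encoded_msa <- function(x, ...) {
  cat(sprintf("encoded MSA: %d x (%d x %d) under '%s'\n",
              x$N, x$L, x$s, x$encoding$label))
  invisible(x)
}
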