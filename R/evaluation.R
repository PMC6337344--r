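# Evaluation against a reference structure: contact maps, PPV curves,
# AUC200, and per-k two-sample comparison across families.

#' Construct a contact map
#'
#' @param pairs two-column matrix / data.frame of residue index pairs in
#'   contact (order within a pair does not matter; self-pairs are
#'   rejected).
#' @param n_residues number of residues in the reference.
#' @param threshold the distance threshold (Angstrom) the map was built
#'   with, for the record.
#' @return An object of class \code{"contact_map"}: list with
#'   \code{pairs} (k < l, deduplicated), \code{n_residues},
#'   \code{threshold}.
#' @export
contact_map <- function(pairs, n_residues, threshold = 8) {
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  storage.mode(pairs) <- "integer"
  if (nrow(pairs) > 0L) {
    if (any(pairs[, 1L] == pairs[, 2L]))
      stop("contact map contains self-pairs")
    pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]),
                   pmax(pairs[, 1L], pairs[, 2L]))
    pairs <- unique(pairs)
    colnames(pairs) <- c("k", "l")
  }
  structure(list(pairs = pairs, n_residues = as.integer(n_residues),
                 threshold = threshold),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact map: %d contacts over %d residues (< %g A)\n",
              nrow(x$pairs), x$n_residues, x$threshold))
  invisible(x)
}

.pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))

#' Contact map from atomic coordinates
#'
#' Two residues are in contact when the minimum Euclidean distance between
#' any of their (heavy) atoms is strictly below \code{threshold}.
#'
#' @param atoms data.frame with columns \code{resno}, \code{x}, \code{y},
#'   \code{z}; one row per heavy atom.  Residues are indexed 1..n in order
#'   of first appearance of their \code{resno}.
#' @param threshold distance threshold in Angstrom (default 8; strict
#'   \code{<}).
#' @return A [contact_map()].
#' @export
contact_map_from_coords <- function(atoms, threshold = 8) {
  stopifnot(all(c("resno", "x", "y", "z") %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("empty structure: no atoms")
  res <- match(atoms$resno, unique(atoms$resno))
  n <- max(res)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  D <- as.matrix(stats::dist(xyz))
  idx <- split(seq_len(nrow(atoms)), res)
  hits <- list()
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      if (min(D[idx[[a]], idx[[b]]]) < threshold)
        hits[[length(hits) + 1L]] <- c(a, b)
    }
  }
  pairs <- if (length(hits)) do.call(rbind, hits) else
    matrix(integer(), 0L, 2L)
  contact_map(pairs, n_residues = n, threshold = threshold)
}

#' Contact map from a PDB file
#'
#' Reads ATOM records (first model, first alternate location, single
#' chain) with \pkg{bio3d}, drops hydrogens by element symbol, and builds
#' the minimum-heavy-atom-distance contact map.  Residues are renumbered
#' 1..n in order of appearance so that they align with the columns of an
#' alignment built around the structure's sequence.
#'
#' @param path path to a PDB file.
#' @param threshold distance threshold in Angstrom (default 8).
#' @param chain optional chain identifier; defaults to the first chain.
#' @return A [contact_map()].
#' @export
contact_map_from_structure <- function(path, threshold = 8, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[[1L]]
  at <- at[at$chain == chain, , drop = FALSE]
  elem <- at$elesy
  if (all(is.na(elem) | elem == ""))
    elem <- substr(trimws(at$elety), 1L, 1L)
  at <- at[toupper(trimws(elem)) != "H", , drop = FALSE]
  if (nrow(at) == 0L) stop("no heavy atoms left in ", path)
  contact_map_from_coords(
    data.frame(resno = at$resno, x = at$x, y = at$y, z = at$z),
    threshold = threshold)
}

#' Read a contact list TSV as a contact map
#'
#' A two-column (or more) whitespace/tab-separated file of residue index
#' pairs; a header line is auto-detected.
#'
#' @param path path to the TSV.
#' @param n_residues number of residues; defaults to the largest index
#'   seen.
#' @param threshold recorded threshold (default 8).
#' @return A [contact_map()].
#' @export
read_contact_tsv <- function(path, n_residues = NULL, threshold = 8) {
  first <- readLines(path, n = 1L)
  header <- !grepl("^\\s*\\d", first)
  df <- utils::read.table(path, header = header)
  if (is.null(n_residues)) n_residues <- max(df[, 1:2])
  contact_map(df[, 1:2], n_residues = n_residues, threshold = threshold)
}

#' Write a contact map to TSV
#'
#' @param map a [contact_map()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_contact_tsv <- function(map, path) {
  utils::write.table(as.data.frame(map$pairs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Positive-predictive-value curve and AUC200
#'
#' \code{PPV(k)} is the fraction of the top-k predicted pairs present in
#' the reference contact map; \code{AUC200} is the sum of \code{PPV(k)}
#' over \code{k = 1..200} (200 for a perfect prediction).  When fewer than
#' 200 predictions are available the sum runs over the available ranks
#' only and the result is flagged \code{short = TRUE}.
#'
#' @param prediction a \code{"contact_prediction"} (or data.frame with
#'   \code{i}, \code{j} ordered by decreasing score).
#' @param truth a [contact_map()] or two-column matrix of true pairs.
#' @return An object of class \code{"ppv_result"}: list with \code{ppv}
#'   (length K), \code{auc200}, \code{n_predictions}, \code{short}.
#' @export
ppv_curve <- function(prediction, truth) {
  df <- as.data.frame(prediction)
  if (nrow(df) == 0L) stop("empty prediction list")
  true_pairs <- if (inherits(truth, "contact_map")) truth$pairs else
    as.matrix(truth)[, 1:2, drop = FALSE]
  truth_keys <- if (nrow(true_pairs)) .pair_key(true_pairs[, 1L], true_pairs[, 2L])
                else character()
  hit <- .pair_key(df$i, df$j) %in% truth_keys
  ppv <- cumsum(hit) / seq_along(hit)
  K <- min(200L, length(ppv))
  structure(list(ppv = ppv, auc200 = sum(ppv[seq_len(K)]),
                 n_predictions = length(ppv),
                 short = length(ppv) < 200L),
            class = "ppv_result")
}

#' @export
print.ppv_result <- function(x, ...) {
  cat(sprintf("PPV over %d predictions%s: PPV(1) = %.3f, AUC200 = %.2f\n",
              x$n_predictions,
              if (x$short) " (fewer than 200)" else "",
              x$ppv[[1L]], x$auc200))
  invisible(x)
}

#' Compare two sets of PPV curves across families
#'
#' Applies a two-tailed two-sample Student's t-test (pooled variance by
#' default; Welch optional) at every contact level k between the per-family
#' PPV values of two methods.  The two curves are declared
#' \code{"different"} only if every per-k p-value is below \code{alpha};
#' otherwise \code{"indistinguishable"}.
#'
#' @param curves_a,curves_b numeric matrices, families x k levels, same
#'   shape (same families, same k range).
#' @param alpha significance level (default 0.05).
#' @param var_equal pooled-variance t-test (default \code{TRUE}).
#' @return List with \code{statistic} and \code{p_value} (length k),
#'   \code{verdict} (\code{"different"} / \code{"indistinguishable"}),
#'   \code{alpha}.
#' @export
compare_ppv_sets <- function(curves_a, curves_b, alpha = 0.05,
                             var_equal = TRUE) {
  curves_a <- as.matrix(curves_a)
  curves_b <- as.matrix(curves_b)
  if (nrow(curves_a) != nrow(curves_b))
    stop("family counts differ between the two curve sets")
  if (ncol(curves_a) != ncol(curves_b))
    stop("k ranges differ between the two curve sets")
  K <- ncol(curves_a)
  tstat <- pval <- numeric(K)
  for (k in seq_len(K)) {
    a <- curves_a[, k]
    b <- curves_b[, k]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate: both samples constant
      tstat[k] <- if (mean(a) == mean(b)) 0 else Inf
      pval[k] <- if (mean(a) == mean(b)) 1 else 0
    } else {
      tt <- stats::t.test(a, b, var.equal = var_equal)
      tstat[k] <- unname(tt$statistic)
      pval[k] <- tt$p.value
    }
  }
  list(statistic = tstat, p_value = pval,
       verdict = if (all(pval < alpha)) "different" else "indistinguishable",
       alpha = alpha)
}

#' Map alignment columns to reference residues
#'
#' Columns are mapped to the residues of the reference sequence, taken to
#' be the first sequence of the alignment: column p maps to the running
#' index of non-gap characters of that sequence, and columns where the
#' reference has a gap map to \code{NA} (they cannot be scored against the
#' structure).
#'
#' @param x an [msa()] object.
#' @return Integer vector of length L; \code{NA} at reference-gap columns.
#' @export
reference_mapping <- function(x) {
  stopifnot(inherits(x, "msa"))
  chars <- strsplit(x$sequences[[1L]], "", fixed = TRUE)[[1L]]
  out <- cumsum(chars != .GAP)
  out[chars == .GAP] <- NA_integer_
  as.integer(out)
}

#' Translate a prediction from column space to residue space
#'
#' Drops pairs touching unmapped (\code{NA}) columns and rewrites indices
#' through the mapping.
#'
#' @param prediction a \code{"contact_prediction"}.
#' @param mapping integer vector as from [reference_mapping()], or
#'   \code{NULL} for the identity.
#' @return A \code{"contact_prediction"} in residue indices.
#' @export
map_prediction <- function(prediction, mapping = NULL) {
  if (is.null(mapping)) return(prediction)
  df <- as.data.frame(prediction)
  i2 <- mapping[df$i]
  j2 <- mapping[df$j]
  keep <- !is.na(i2) & !is.na(j2)
  df <- df[keep, , drop = FALSE]
  df$i <- i2[keep]
  df$j <- j2[keep]
  df$rank <- seq_len(nrow(df))
  structure(df, class = c("contact_prediction", "data.frame"),
            min_separation = attr(prediction, "min_separation"),
            L = attr(prediction, "L"))
}
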