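# End-to-end pipeline: MSA -> ranked contacts -> evaluation -> sweeps.

#' Predict residue contacts from an alignment
#'
#' Runs the whole pipeline: gap-heavy sequence removal, sequence
#' reweighting, numeric encoding, Gaussian model with uniform-composition
#' prior, precision-matrix extraction, gauge-corrected Frobenius scores,
#' APC, and separation-filtered ranking.
#'
#' @param x an [msa()] object or a path to a FASTA/A2M file.
#' @param encoding an [aa_encoding()] (default [binary20_encoding()]).
#' @param lambda prior weight in [0, 1]; default 0.8.
#' @param reweight \code{"fixed"} (identity cutoff \code{r}),
#'   \code{"auto"} (cutoff from mean pairwise identity) or \code{"none"}.
#' @param r identity cutoff for fixed mode (default 0.8).
#' @param max_gap_fraction sequences with a gap fraction strictly above
#'   this are dropped (default 0.9).
#' @param min_separation rank only pairs with \code{j - i} above this
#'   (default 4).
#' @param top_k number of reported pairs (default 200).
#' @param ridge ridge policy for the inversion; see [coupling_matrix()].
#' @return An object of class \code{"contact_run"}: list with
#'   \code{contacts} (a \code{"contact_prediction"} with raw and APC
#'   scores), \code{meff}, \code{lambda}, \code{epsilon},
#'   \code{encoding_label}, \code{r}, \code{N}, \code{L},
#'   \code{scores} (list with \code{raw} and \code{apc} matrices).
#' @export
predict_contacts <- function(x, encoding = binary20_encoding(),
                             lambda = 0.8,
                             reweight = c("fixed", "auto", "none"),
                             r = 0.8, max_gap_fraction = 0.9,
                             min_separation = 4, top_k = 200,
                             ridge = "auto") {
  reweight <- match.arg(reweight)
  if (is.character(x)) x <- read_msa(x)
  stopifnot(inherits(x, "msa"))
  x <- clean_msa(x, max_gap_fraction = max_gap_fraction)
  w <- switch(reweight,
    none = uniform_weights(x),
    fixed = sequence_weights(x, r = similarity_cutoff(x, "fixed",
                                                      fixed_r = r)),
    auto = sequence_weights(x, r = similarity_cutoff(x, "auto",
                                                     fixed_r = r)))
  enc <- encode_msa(x, encoding)
  model <- gaussian_model(enc, weights = w, lambda = lambda, ridge = ridge)
  P <- frobenius_scores(model)
  P_apc <- suppressWarnings(apc_correct(P))
  contacts <- rank_contacts(P_apc, min_separation = min_separation,
                            top_k = top_k, P_raw = P)
  structure(list(contacts = contacts, meff = w$meff, lambda = lambda,
                 epsilon = model$epsilon,
                 encoding_label = encoding$label, r = w$r,
                 N = x$N, L = x$L,
                 scores = list(raw = P, apc = P_apc)),
            class = "contact_run")
}

#' @export
print.contact_run <- function(x, ...) {
  cat(sprintf(
    "contact prediction: %d pairs from %d x %d MSA\n  encoding '%s', lambda = %g, Meff = %.2f, ridge eps = %g\n",
    nrow(x$contacts), x$N, x$L, x$encoding_label, x$lambda, x$meff,
    x$epsilon))
  if (nrow(x$contacts) > 0L) {
    cat("top pairs:\n")
    print(utils::head(as.data.frame(x$contacts), 5L))
  }
  invisible(x)
}

#' Evaluate a prediction against a reference
#'
#' @param run a \code{"contact_run"} (or a \code{"contact_prediction"}).
#' @param truth a [contact_map()], a two-column matrix of true pairs, or a
#'   path to a contact TSV / PDB file (dispatched on the \code{.pdb}
#'   extension).
#' @param mapping optional column-to-residue mapping (see
#'   [reference_mapping()]); \code{NULL} for identity.
#' @param threshold contact threshold in Angstrom when \code{truth} is a
#'   PDB path.
#' @return A \code{"ppv_result"}; see [ppv_curve()].
#' @export
evaluate_contacts <- function(run, truth, mapping = NULL, threshold = 8) {
  pred <- if (inherits(run, "contact_run")) run$contacts else run
  if (is.character(truth)) {
    truth <- if (grepl("\\.pdb$", truth, ignore.case = TRUE))
      contact_map_from_structure(truth, threshold = threshold)
    else read_contact_tsv(truth, threshold = threshold)
  }
  ppv_curve(map_prediction(pred, mapping), truth)
}

#' Sweep the prior weight lambda
#'
#' Runs [predict_contacts()] over a grid of lambda values and evaluates
#' each against the reference, returning one row per lambda.
#'
#' @param x an [msa()] or FASTA path.
#' @param truth reference contacts as accepted by [evaluate_contacts()].
#' @param lambdas grid of prior weights (default 0 to 1 by 0.1).
#' @param ... further arguments to [predict_contacts()].
#' @return data.frame with columns \code{lambda}, \code{auc200},
#'   \code{ppv1}, \code{meff}.
#' @export
sweep_lambda <- function(x, truth, lambdas = seq(0, 1, by = 0.1), ...) {
  if (length(lambdas) == 0L) stop("empty lambda grid")
  if (is.character(x)) x <- read_msa(x)
  rows <- lapply(lambdas, function(lam) {
    run <- predict_contacts(x, lambda = lam, ...)
    ev <- evaluate_contacts(run, truth)
    data.frame(lambda = lam, auc200 = ev$auc200, ppv1 = ev$ppv[[1L]],
               meff = run$meff)
  })
  do.call(rbind, rows)
}

#' Run metadata for a prediction
#'
#' Collects the reproducibility-relevant facts of a run (encoding, lambda,
#' ridge actually applied, Meff, sizes) into a plain list, ready for JSON
#' serialisation.
#'
#' @param run a \code{"contact_run"}.
#' @return A named list.
#' @export
run_metadata <- function(run) {
  stopifnot(inherits(run, "contact_run"))
  list(encoding = run$encoding_label, lambda = run$lambda,
       ridge_epsilon = run$epsilon, meff = run$meff,
       identity_cutoff = run$r, n_sequences = run$N,
       alignment_length = run$L, n_contacts = nrow(run$contacts))
}
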