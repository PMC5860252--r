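#' Truncate a prediction list to its top-scoring entries
#'
#' Keeps the first `min(n, available)` entries under the canonical
#' ordering (score descending, ties by ascending `i` then `j`). When fewer
#' than `n` predictions are available all of them are used and metrics are
#' computed on what is there, mirroring how sparse predictors are scored.
#'
#' @param predictions A [prediction_list()].
#' @param n Number of entries requested (`n >= 0`).
#' @return A [prediction_list()] with at most `n` entries.
#' @export
top_n <- function(predictions, n) {
  stopifnot(inherits(predictions, "prediction_list"), n >= 0)
  out <- predictions[seq_len(min(n, nrow(predictions))), , drop = FALSE]
  attr(out, "target_id") <- attr(predictions, "target_id")
  attr(out, "provenance") <- attr(predictions, "provenance")
  class(out) <- class(predictions)
  out
}

#' Precision (PPV) of predicted contacts
#'
#' The fraction of predictions whose unordered pair (i, j) is a true
#' contact; membership ignores the range class. With zero assessable
#' predictions the value is undefined and returned as `NA` (never 0).
#'
#' @param predictions A [prediction_list()] (already truncated as
#'   desired).
#' @param truth A `contact_set` from [extract_contacts()].
#' @return Numeric in `[0, 1]`, or `NA_real_` when undefined; the number
#'   of assessed entries is attached as attribute `n_considered`.
#' @export
contact_precision <- function(predictions, truth) {
  stopifnot(inherits(truth, "contact_set"))
  n <- nrow(predictions)
  if (n == 0) {
    return(structure(NA_real_, n_considered = 0L))
  }
  hits <- in_contact_set(predictions$i, predictions$j, truth)
  structure(sum(hits) / n, n_considered = n)
}

#' Spread of correctly predicted contacts
#'
#' The longest run of consecutive residues 1..L none of which takes part
#' in a correctly predicted contact, as a proportion of L. Runs include
#' the termini (residues before the first and after the last covered
#' residue count). With no correct predictions the spread is 1. Smaller
#' values mean the correct predictions cover the chain more evenly.
#'
#' @param predictions A [prediction_list()] (the same top-N used for the
#'   precision being reported).
#' @param truth A `contact_set`.
#' @param L Protein length; defaults to the length recorded in `truth`.
#' @return Numeric in `[0, 1]`.
#' @export
contact_spread <- function(predictions, truth, L = attr(truth, "L")) {
  stopifnot(L >= 1)
  covered <- logical(L)
  if (nrow(predictions)) {
    ok <- in_contact_set(predictions$i, predictions$j, truth)
    ok <- ok & predictions$i <= L & predictions$j <= L
    covered[c(predictions$i[ok], predictions$j[ok])] <- TRUE
  }
  if (!any(covered)) return(1)
  runs <- rle(!covered)
  gap <- runs$lengths[runs$values]
  if (!length(gap)) 0 else max(gap) / L
}

#' Per-secondary-structure-category precision and proportions
#'
#' Assigns each prediction and each true contact to one of the six
#' secondary-structure categories of its residue pair and reports, per
#' category, the precision of the predictions in that category and the
#' proportion of predicted and of true contacts falling in it. The two
#' proportion columns each sum to 1 (over non-empty inputs).
#'
#' @param predictions A [prediction_list()] (already truncated).
#' @param truth A `contact_set` extracted with the same `ss`.
#' @param ss An [ss_string()] for the target.
#' @return Data frame with one row per category: `category`, `precision`
#'   (`NA` where no prediction falls in the category),
#'   `predicted_proportion`, `true_proportion`, `n_predicted`, `n_true`.
#' @export
ss_breakdown <- function(predictions, truth, ss) {
  states <- ss_states(ss)
  lev <- ss_category_levels()
  pred_cat <- if (nrow(predictions)) {
    ss_category(predictions$i, predictions$j, ss)
  } else character(0)
  true_cat <- if (nrow(truth)) {
    if (!is.null(truth$ss_category)) truth$ss_category
    else ss_category(truth$i, truth$j, ss)
  } else character(0)
  hits <- if (nrow(predictions)) in_contact_set(predictions$i, predictions$j, truth) else logical(0)
  n_pred <- as.integer(table(factor(pred_cat, levels = lev)))
  n_hit <- as.integer(table(factor(pred_cat[hits], levels = lev)))
  n_true <- as.integer(table(factor(true_cat, levels = lev)))
  data.frame(
    category = lev,
    precision = ifelse(n_pred > 0, n_hit / n_pred, NA_real_),
    predicted_proportion = if (sum(n_pred)) n_pred / sum(n_pred) else rep(0, 6),
    true_proportion = if (sum(n_true)) n_true / sum(n_true) else rep(0, 6),
    n_predicted = n_pred,
    n_true = n_true,
    stringsAsFactors = FALSE
  )
}

#' Evaluate a prediction list against a native structure
#'
#' Computes the standard evaluation report for one target: precision of
#' the top `ceiling(f * L)` predictions for each fraction `f` (at least
#' one prediction per fraction), short-/long-range precision over the
#' top-L entries restricted to each range class, the spread of correct
#' contacts among the top-L entries, and (when `ss` is given) the
#' per-secondary-structure-category breakdown.
#'
#' Predictions touching residues outside the observed chain (index beyond
#' L) are excluded from both numerator and denominator by default;
#' `unresolved = "penalize"` counts them as incorrect instead.
#'
#' @param predictions A [prediction_list()].
#' @param structure The native [structure_model()].
#' @param ss Optional [ss_string()].
#' @param criteria A [contact_criteria()].
#' @param fractions Fractions of L to evaluate.
#' @param unresolved How to treat predictions involving unobserved
#'   residues.
#' @param scop_class Optional user-supplied fold-class label carried into
#'   the report as metadata (never computed from the structure).
#' @return An object of class `evaluation_report`.
#' @export
evaluate_target <- function(predictions, structure, ss = NULL,
                            criteria = contact_criteria(),
                            fractions = c(0.1, 0.2, 0.5, 1),
                            unresolved = c("exclude", "penalize"),
                            scop_class = NA_character_) {
  unresolved <- match.arg(unresolved)
  stopifnot(inherits(predictions, "prediction_list"),
            inherits(structure, "structure_model"))
  L <- model_length(structure)
  if (L < criteria$min_separation + 1) {
    stop("structure too short to host any non-trivial contact")
  }
  truth <- extract_contacts(structure, criteria, ss)
  oob <- predictions$i > L | predictions$j > L
  assessable <- predictions
  if (any(oob) && unresolved == "exclude") {
    assessable <- predictions[!oob, , drop = FALSE]
    class(assessable) <- class(predictions)
    attr(assessable, "target_id") <- attr(predictions, "target_id")
  }
  # under "penalize" out-of-range entries stay in the denominator; they can
  # never be members of the truth set, so they count as incorrect
  prec_at <- function(sub) {
    p <- contact_precision(sub, truth)
    list(value = as.numeric(p), n = attr(p, "n_considered"))
  }
  per_fraction <- lapply(fractions, function(f) {
    n <- max(1L, as.integer(ceiling(f * L)))
    sub <- top_n(assessable, n)
    c(list(fraction = f, n_requested = n), prec_at(sub))
  })
  topL <- top_n(assessable, L)
  rng <- range_class(topL$i, topL$j, criteria)
  split_prec <- function(cls) {
    sub <- topL[rng == cls, , drop = FALSE]
    class(sub) <- class(topL)
    prec_at(sub)
  }
  short_p <- split_prec("short")
  long_p <- split_prec("long")
  out <- list(
    target_id = attr(predictions, "target_id"),
    provenance = attr(predictions, "provenance"),
    L = L,
    n_true_contacts = nrow(truth),
    fractions = data.frame(
      fraction = vapply(per_fraction, `[[`, numeric(1), "fraction"),
      n_requested = vapply(per_fraction, `[[`, numeric(1), "n_requested"),
      n_considered = vapply(per_fraction, `[[`, numeric(1), "n"),
      precision = vapply(per_fraction, `[[`, numeric(1), "value")
    ),
    short_precision = short_p$value,
    n_short_considered = short_p$n,
    long_precision = long_p$value,
    n_long_considered = long_p$n,
    spread = contact_spread(topL, truth, L),
    scop_class = scop_class
  )
  if (!is.null(ss)) out$ss <- ss_breakdown(topL, truth, ss)
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation of '%s' (%s), L = %d, %d true contacts\n",
              x$target_id, x$provenance, x$L, x$n_true_contacts))
  print(x$fractions, row.names = FALSE)
  cat(sprintf("  short-range precision: %s (n = %d)\n",
              format(x$short_precision, digits = 3), x$n_short_considered))
  cat(sprintf("  long-range precision:  %s (n = %d)\n",
              format(x$long_precision, digits = 3), x$n_long_considered))
  cat(sprintf("  spread of correct contacts: %.3f\n", x$spread))
  invisible(x)
}

#' Flatten an evaluation report to a single row
#'
#' @param report An `evaluation_report`.
#' @return One-row data frame (per-fraction precisions as
#'   `precision_topL_10`-style columns).
#' @export
report_row <- function(report) {
  fr <- report$fractions
  frac_name <- function(f) {
    if (f == 1) "topL" else paste0("topL_", as.integer(round(1 / f)))
  }
  row <- data.frame(target_id = report$target_id, L = report$L,
                    n_true_contacts = report$n_true_contacts,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(fr))) {
    row[[paste0("precision_", frac_name(fr$fraction[k]))]] <- fr$precision[k]
  }
  row$short_precision <- report$short_precision
  row$long_precision <- report$long_precision
  row$spread <- report$spread
  row$scop_class <- report$scop_class
  row
}
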