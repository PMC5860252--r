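#' Satisfied-predicted-contact profile of one decoy
#'
#' A predicted contact is satisfied in a decoy when the decoy's
#' representative-atom distance for the pair is strictly below the same
#' 8 Angstrom criterion that defines true contacts. The profile reports
#' the fraction of satisfied predictions overall and split by the range
#' class of the predicted pair (fixed by `|i - j|`, not by geometry).
#' A fraction with zero predictions in its class is undefined (`NA`),
#' never coerced to 0.
#'
#' @param decoy A [structure_model()] of the target length.
#' @param predictions A [prediction_list()].
#' @param criteria A [contact_criteria()].
#' @param top_n Number of predictions considered (default: decoy length
#'   L, the usual evaluation cap).
#' @return One-row data frame: `decoy_id`, `sat_all`, `sat_short`,
#'   `sat_long`, `n_pred_all`, `n_pred_short`, `n_pred_long`.
#' @export
satisfaction_profile <- function(decoy, predictions,
                                 criteria = contact_criteria(),
                                 top_n = model_length(decoy)) {
  stopifnot(inherits(decoy, "structure_model"),
            inherits(predictions, "prediction_list"))
  L <- model_length(decoy)
  preds <- top_n(predictions, top_n)
  preds <- preds[preds$i <= L & preds$j <= L, , drop = FALSE]
  rep <- representative_coords(decoy, warn = FALSE)
  if (nrow(preds)) {
    dd <- sqrt(rowSums((rep[preds$i, , drop = FALSE] -
                        rep[preds$j, , drop = FALSE])^2))
    sat <- dd < criteria$distance_cutoff
    rng <- range_class(preds$i, preds$j, criteria)
  } else {
    sat <- logical(0); rng <- character(0)
  }
  frac <- function(keep) {
    if (!any(keep)) NA_real_ else sum(sat[keep]) / sum(keep)
  }
  data.frame(decoy_id = decoy$id,
             sat_all = frac(rep(TRUE, length(sat))),
             sat_short = frac(rng == "short"),
             sat_long = frac(rng == "long"),
             n_pred_all = length(sat),
             n_pred_short = sum(rng == "short"),
             n_pred_long = sum(rng == "long"),
             stringsAsFactors = FALSE)
}

#' Satisfaction profiles for a decoy ensemble
#'
#' @param decoys List of [structure_model()]s.
#' @param predictions A [prediction_list()].
#' @inheritParams satisfaction_profile
#' @return Data frame with one row per decoy (see
#'   [satisfaction_profile()]).
#' @export
satisfaction_profiles <- function(decoys, predictions,
                                  criteria = contact_criteria(),
                                  top_n = NULL) {
  rows <- lapply(decoys, function(d) {
    satisfaction_profile(d, predictions, criteria,
                         top_n = if (is.null(top_n)) model_length(d) else top_n)
  })
  do.call(rbind, rows)
}

# per unique satisfaction value v (ascending): counts of correct/incorrect
# decoys with satisfaction >= v, via suffix sums (keeps threshold sweeps
# O(n log n) for large ensembles)
class_counts_by_value <- function(sat, lab) {
  u <- sort(unique(sat))
  if (!length(u)) {
    return(list(values = numeric(0), pos_ge = numeric(0), neg_ge = numeric(0)))
  }
  iv <- match(sat, u)
  pos_at <- tabulate(iv[lab], nbins = length(u))
  neg_at <- tabulate(iv[!lab], nbins = length(u))
  list(values = u,
       pos_ge = rev(cumsum(rev(pos_at))),
       neg_ge = rev(cumsum(rev(neg_at))))
}

sat_column <- function(profiles, measure) {
  measure <- match.arg(measure, c("long", "short", "all"))
  profiles[[paste0("sat_", measure)]]
}

#' Threshold classification of decoys by contact satisfaction
#'
#' A decoy is kept when its satisfaction fraction for the chosen measure
#' is at least the threshold (so the threshold is the minimal kept
#' satisfaction). Decoys whose satisfaction is undefined (no predictions
#' in the measure's range class) are discarded and flagged: a quality
#' measure that cannot be computed should not pass models.
#'
#' @param profiles Profile data frame from [satisfaction_profiles()] (or
#'   [make_qa_ensemble()]).
#' @param threshold Satisfaction cutoff in `[0, 1]`.
#' @param measure `"long"` (default), `"short"` or `"all"`.
#' @return Data frame: `decoy_id`, `kept`, `undefined_measure`,
#'   `measure`, `threshold`.
#' @export
classify_decoys <- function(profiles, threshold, measure = "long") {
  threshold <- as.vector(threshold)[1]
  sat <- sat_column(profiles, measure)
  undef <- is.na(sat)
  data.frame(decoy_id = profiles$decoy_id,
             kept = !undef & sat >= threshold,
             undefined_measure = undef,
             measure = measure,
             threshold = threshold,
             stringsAsFactors = FALSE)
}

#' Error-minimizing satisfaction threshold
#'
#' Scans every candidate cutoff (the observed satisfaction values plus 0
#' and just above the maximum) and returns the one minimizing
#' classification errors: false positives (incorrect decoys kept) plus
#' false negatives (correct decoys discarded). Ties go to the smallest
#' threshold.
#'
#' With `balance = TRUE` the error *rates* are minimized instead
#' (false-positive rate + false-negative rate, i.e. the Youden-optimal
#' ROC point). On heavily imbalanced ensembles -- decoy sets where only a
#' few percent of models are correct are the norm -- the raw error count
#' is dominated by the majority class and pushes the cutoff so high that
#' most correct models are discarded; the balanced objective keeps the
#' sensitivity/specificity trade-off that the ROC analysis optimizes, so
#' the filtering workflow uses it.
#'
#' @param profiles Profile data frame.
#' @param truth_labels Logical vector, `TRUE` for correct decoys.
#' @param measure Satisfaction measure used.
#' @param balance Minimize summed error rates instead of summed error
#'   counts.
#' @return The threshold; attributes `errors`, `false_positives`,
#'   `false_negatives` describe its confusion counts.
#' @export
optimal_threshold <- function(profiles, truth_labels, measure = "long",
                              balance = FALSE) {
  sat <- sat_column(profiles, measure)
  lab <- as.logical(truth_labels)
  stopifnot(length(lab) == length(sat))
  if (!any(lab) || all(lab)) {
    stop("both correct and incorrect decoys are required to fit a threshold")
  }
  ok <- !is.na(sat)
  cnt <- class_counts_by_value(sat[ok], lab[ok])
  fn_na <- sum(lab & !ok)
  n_pos_ok <- sum(lab & ok); n_neg_ok <- sum(!lab & ok)
  # candidates: 0, every observed value, and just above the maximum;
  # kept(t) = sat >= t (undefined satisfaction is never kept)
  cand <- c(0, cnt$values, max(c(cnt$values, 0)) + 1e-9)
  pos_ge <- c(n_pos_ok, cnt$pos_ge, 0)
  neg_ge <- c(n_neg_ok, cnt$neg_ge, 0)
  if (length(cnt$values) && cnt$values[1] == 0) {
    cand <- cand[-1]; pos_ge <- pos_ge[-1]; neg_ge <- neg_ge[-1]
  }
  fp <- neg_ge
  fn <- (n_pos_ok - pos_ge) + fn_na
  err <- if (balance) fp / sum(!lab) + fn / sum(lab) else fp + fn
  k <- which.min(err)  # which.min takes the first (= smallest) on ties
  t <- cand[k]
  kept <- !is.na(sat) & sat >= t
  structure(t, errors = unname(err[k]),
            false_positives = sum(kept & !lab),
            false_negatives = sum(!kept & lab))
}

#' ROC curve of the satisfaction classifier
#'
#' Sweeps the rejection threshold over the observed satisfaction values.
#' At each threshold, sensitivity is the fraction of correct decoys kept
#' and specificity the fraction of incorrect decoys discarded. The curve
#' is returned with its trapezoidal AUC.
#'
#' @inheritParams optimal_threshold
#' @return Data frame of class `decoy_roc` with columns `threshold`,
#'   `sensitivity`, `specificity`; attribute `auc`.
#' @export
decoy_roc <- function(profiles, truth_labels, measure = "long") {
  sat <- sat_column(profiles, measure)
  lab <- as.logical(truth_labels)
  stopifnot(length(lab) == length(sat))
  if (!any(lab) || all(lab)) {
    stop("both correct and incorrect decoys are required for a ROC curve")
  }
  n_pos <- sum(lab); n_neg <- sum(!lab)
  ok <- !is.na(sat)
  cnt <- class_counts_by_value(sat[ok], lab[ok])
  # -Inf keeps every decoy with a defined measure; Inf keeps none
  thr <- c(-Inf, cnt$values, Inf)
  sens <- c(sum(lab & ok), cnt$pos_ge, 0) / n_pos
  spec <- 1 - c(sum(!lab & ok), cnt$neg_ge, 0) / n_neg
  out <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  fpr <- 1 - out$specificity
  ord <- order(fpr, out$sensitivity)
  x <- c(0, fpr[ord]); y <- c(0, out$sensitivity[ord])
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  attr(out, "auc") <- auc
  attr(out, "measure") <- measure
  class(out) <- c("decoy_roc", "data.frame")
  out
}

#' AUC of a ROC curve
#' @param x A `decoy_roc`.
#' @return Numeric in `[0, 1]`.
#' @export
roc_auc <- function(x) attr(x, "auc")

#' @export
print.decoy_roc <- function(x, ...) {
  cat(sprintf("ROC (%s-range satisfaction): %d thresholds, AUC = %.3f\n",
              attr(x, "measure"), nrow(x), attr(x, "auc")))
  invisible(x)
}

#' Summary of filtering a decoy ensemble at a threshold
#'
#' Reports the proportion of correct decoys before and after discarding
#' decoys below the satisfaction threshold, the resulting enrichment
#' factor (after/before), the number of correct decoys lost (false
#' negatives), and whether the whole ensemble was discarded -- the
#' signature of a modelling failure when no correct decoy exists.
#'
#' @inheritParams optimal_threshold
#' @param threshold Satisfaction cutoff.
#' @return List of class `ensemble_summary`.
#' @export
summarize_filtering <- function(profiles, truth_labels, threshold,
                                measure = "long") {
  lab <- as.logical(truth_labels)
  dec <- classify_decoys(profiles, threshold, measure)
  kept <- dec$kept
  n <- length(kept)
  before <- if (n) mean(lab) else NA_real_
  after <- if (any(kept)) mean(lab[kept]) else NA_real_
  structure(list(
    n_decoys = n,
    n_correct = sum(lab),
    n_kept = sum(kept),
    proportion_correct_before = before,
    proportion_correct_after = after,
    enrichment_factor = if (!is.na(before) && before > 0 && any(kept))
      after / before else NA_real_,
    false_negatives = sum(lab & !kept),
    all_discarded = !any(kept),
    threshold = threshold,
    measure = measure
  ), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Filtering at %s-range satisfaction >= %.3f: kept %d / %d decoys\n",
              x$measure, x$threshold, x$n_kept, x$n_decoys))
  cat(sprintf("  correct: %.1f%% before -> %s after (enrichment %s), %d false negatives\n",
              100 * x$proportion_correct_before,
              if (is.na(x$proportion_correct_after)) "NA"
              else sprintf("%.1f%%", 100 * x$proportion_correct_after),
              if (is.na(x$enrichment_factor)) "NA"
              else sprintf("%.2fx", x$enrichment_factor),
              x$false_negatives))
  if (x$all_discarded) cat("  ALL decoys discarded (modelling-failure signal)\n")
  invisible(x)
}

#' Impact of filtering on the best and energy-ranked top-k decoys
#'
#' Compares the best TM-score in the ensemble and the best TM-score among
#' the k decoys ranked best by the generator's scoring function
#' (energy rank), before and after discarding decoys below the
#' satisfaction threshold. If fewer than k decoys survive, all kept
#' decoys are used.
#'
#' @param profiles Profile data frame.
#' @param score_table A `decoy_score_table` (or data frame) with
#'   `decoy_id`, `tm_score` and `energy_rank` covering all decoys.
#' @param threshold Satisfaction cutoff.
#' @param measure Satisfaction measure.
#' @param k Number of top-ranked decoys (default 5).
#' @return List of class `topk_impact`: `best_tm_before`,
#'   `best_tm_after`, `topk_tm_before`, `topk_tm_after`,
#'   `best_discarded`, `n_kept`.
#' @export
top_k_impact <- function(profiles, score_table, threshold,
                         measure = "long", k = 5L) {
  st <- as.data.frame(score_table)
  stopifnot(all(c("decoy_id", "tm_score", "energy_rank") %in% names(st)))
  m <- match(profiles$decoy_id, st$decoy_id)
  if (anyNA(m)) stop("score table does not cover all decoys")
  tm <- st$tm_score[m]; rank <- st$energy_rank[m]
  dec <- classify_decoys(profiles, threshold, measure)
  kept <- dec$kept
  top_of <- function(tmv, rkv, kk) {
    if (!length(tmv)) return(NA_real_)
    sel <- order(rkv)[seq_len(min(kk, length(rkv)))]
    max(tmv[sel])
  }
  best_before <- max(tm)
  best_after <- if (any(kept)) max(tm[kept]) else NA_real_
  structure(list(
    best_tm_before = best_before,
    best_tm_after = best_after,
    topk_tm_before = top_of(tm, rank, k),
    topk_tm_after = top_of(tm[kept], rank[kept], k),
    best_discarded = is.na(best_after) || best_after < best_before,
    n_kept = sum(kept), k = k
  ), class = "topk_impact")
}

#' Rank correlation between satisfaction measures and model quality
#'
#' Spearman rank correlation between each satisfaction measure and the
#' TM-score of the decoys. Spearman is used because TM-score is bounded
#' and the claimed association is monotone, not linear. Measures that are
#' constant (or all-undefined) get `NA` with a flag.
#'
#' @param profiles Profile data frame.
#' @param tm_scores Numeric TM-scores, one per decoy.
#' @return Data frame: `measure`, `rho`, `n`, `degenerate`.
#' @export
correlation_report <- function(profiles, tm_scores) {
  stopifnot(length(tm_scores) == nrow(profiles))
  if (nrow(profiles) < 3) stop("at least 3 decoys are required")
  rows <- lapply(c("all", "short", "long"), function(mea) {
    sat <- sat_column(profiles, mea)
    ok <- !is.na(sat) & !is.na(tm_scores)
    degen <- sum(ok) < 3 || stats::sd(sat[ok]) == 0 || stats::sd(tm_scores[ok]) == 0
    rho <- if (degen) NA_real_ else
      stats::cor(sat[ok], tm_scores[ok], method = "spearman")
    data.frame(measure = mea, rho = rho, n = sum(ok), degenerate = degen,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
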