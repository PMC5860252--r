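#' Effective number of sequences (Neff) of an alignment
#'
#' Hard-clustering Neff: each sequence is weighted by the reciprocal of
#' the number of alignment rows (itself included) to which it is at least
#' `identity_threshold` identical, and the weights are summed. Pairwise
#' identity is the number of matching columns divided by the number of
#' columns where both sequences are non-gap; sequences with no overlap
#' are 0% identical, and every sequence is 100% identical to itself, so
#' every cluster has size at least 1 and `1 <= Neff <= n`.
#'
#' @param msa An [msa()].
#' @param identity_threshold Clustering identity threshold (default 0.8,
#'   the convention of pseudo-likelihood coevolution methods).
#' @return List of class `neff_result`: `neff`, `identity_threshold`,
#'   `n_sequences`, `weights`.
#' @export
compute_neff <- function(msa, identity_threshold = 0.8) {
  stopifnot(inherits(msa, "msa"))
  n <- length(msa$rows)
  if (n == 0) stop("empty alignment")
  m <- do.call(rbind, strsplit(msa$rows, ""))
  nongap <- m != "-" & m != "."
  sizes <- integer(n)
  for (s in seq_len(n)) {
    eq <- m == matrix(m[s, ], n, msa$ncol, byrow = TRUE)
    both <- nongap & matrix(nongap[s, ], n, msa$ncol, byrow = TRUE)
    matches <- rowSums(eq & both)
    denom <- rowSums(both)
    ident <- ifelse(denom > 0, matches / denom, 0)
    ident[s] <- 1  # self-identity, even for all-gap rows
    sizes[s] <- sum(ident >= identity_threshold)
  }
  w <- 1 / sizes
  structure(list(neff = sum(w), identity_threshold = identity_threshold,
                 n_sequences = n, weights = w),
            class = "neff_result")
}

#' @export
print.neff_result <- function(x, ...) {
  cat(sprintf("Neff = %.3f over %d sequences (identity threshold %.0f%%)\n",
              x$neff, x$n_sequences, 100 * x$identity_threshold))
  invisible(x)
}

#' Confidence interval for the Neff needed to reach a target precision
#'
#' Fits an ordinary least-squares regression of Neff on precision across
#' targets (Neff as the dependent variable, precision as the independent
#' variable) and returns the t-based confidence interval for the mean
#' response at the target precision -- an interval estimate of the Neff a
#' predictor typically needs to reach that precision. A prediction
#' interval for a single new target is available via
#' `interval = "prediction"`.
#'
#' @param points Data frame (or list) with numeric columns/elements
#'   `neff` and `precision`, one row per target.
#' @param target_precision Precision at which the interval is evaluated
#'   (default 0.5, the conventional usefulness threshold).
#' @param confidence Confidence level (default 0.95).
#' @param interval `"confidence"` (mean response, default) or
#'   `"prediction"`.
#' @return List of class `neff_interval`: `lower`, `upper`, `fit`
#'   (point estimate), `target_precision`, `confidence`, `n`, `model`.
#' @export
neff_at_precision_ci <- function(points, target_precision = 0.5,
                                 confidence = 0.95,
                                 interval = c("confidence", "prediction")) {
  interval <- match.arg(interval)
  d <- data.frame(neff = as.numeric(points$neff),
                  precision = as.numeric(points$precision))
  if (anyNA(d)) stop("points must not contain missing values")
  if (nrow(d) < 3) stop("at least 3 (neff, precision) points are required")
  if (stats::var(d$precision) == 0) {
    stop("degenerate design: precision has zero variance")
  }
  fit <- stats::lm(neff ~ precision, data = d)
  pr <- stats::predict(fit, newdata = data.frame(precision = target_precision),
                       interval = interval, level = confidence)
  structure(list(lower = unname(pr[1, "lwr"]), upper = unname(pr[1, "upr"]),
                 fit = unname(pr[1, "fit"]),
                 target_precision = target_precision, confidence = confidence,
                 interval = interval, n = nrow(d), model = fit),
            class = "neff_interval")
}

#' @export
print.neff_interval <- function(x, ...) {
  cat(sprintf("Neff at precision %.2f: %.1f (%.0f%% %s interval %.1f - %.1f, n = %d)\n",
              x$target_precision, x$fit, 100 * x$confidence, x$interval,
              x$lower, x$upper, x$n))
  invisible(x)
}
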