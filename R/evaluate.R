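# Cohort evaluation: case labeling, ROC/AUC with DeLong confidence
# intervals, paired DeLong comparison of two scores on the same subjects,
# and the demographic group-comparison statistics. ROC machinery is backed
# by pROC; higher scores always mean more delirium-like.

#' Clinical delirium case definition
#'
#' A subject is labeled delirious if any instrument crosses its cut-off:
#' CAM-ICU positive, Delirium Rating Scale (DRS) >= 19, Delirium
#' Observation Screening Scale (DOSS) >= 3, or chart documentation of
#' delirium. All arguments recycle.
#'
#' @param cam_icu_positive Logical.
#' @param drs,doss Non-negative instrument totals.
#' @param chart_delirium Logical; chart-review evidence.
#' @return Logical vector.
#' @export
label_delirium <- function(cam_icu_positive, drs, doss,
                           chart_delirium = FALSE) {
  stopifnot(all(drs >= 0, na.rm = TRUE), all(doss >= 0, na.rm = TRUE))
  as.logical(cam_icu_positive) | drs >= 19 | doss >= 3 |
    as.logical(chart_delirium)
}

.as_binary_label <- function(labels) {
  lab <- as.integer(as.logical(labels))
  if (anyNA(lab)) stop("labels must be TRUE/FALSE or 0/1 without NAs")
  if (length(unique(lab)) < 2L) {
    stop("degenerate cohort: both delirious and control subjects are required")
  }
  lab
}

.proc_roc <- function(scores, labels) {
  pROC::roc(response = labels, predictor = scores, levels = c(0L, 1L),
            direction = "<", quiet = TRUE)
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' AUC is the Mann-Whitney concordance estimator (ties count 1/2); the
#' 95% CI uses the DeLong structural-component variance with a normal
#' approximation, truncated to `[0, 1]`.
#'
#' @param scores Numeric; higher means more delirium-like.
#' @param labels Logical or 0/1; `TRUE`/1 = delirious.
#' @return A `roc_result`: list with `auc`, `ci_low`, `ci_high`, `var`
#'   (DeLong variance of the AUC), `n_pos`, `n_neg`, a `thresholds` data
#'   frame (threshold, sensitivity, specificity for every distinct cut),
#'   and the underlying `pROC::roc` object.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  lab <- .as_binary_label(labels)
  r <- .proc_roc(scores, lab)
  v <- as.numeric(suppressWarnings(pROC::var(r, method = "delong")))
  a <- as.numeric(pROC::auc(r))
  ci <- a + c(-1, 1) * stats::qnorm(0.975) * sqrt(v)
  co <- pROC::coords(r, "all", ret = c("threshold", "sensitivity",
                                       "specificity"), transpose = FALSE)
  structure(
    list(auc = a, ci_low = max(0, ci[1]), ci_high = min(1, ci[2]), var = v,
         n_pos = sum(lab == 1L), n_neg = sum(lab == 0L),
         thresholds = co[order(co$threshold), ], roc = r),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), %d delirious vs %d control\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(1 - x$thresholds$specificity, x$thresholds$sensitivity, type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.2f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Paired DeLong comparison of two scores
#'
#' Tests whether two delirium scores measured on the same subjects have
#' equal AUCs, using the covariance of the DeLong structural components
#' (placements). The z statistic follows the `auc_a - auc_b` convention;
#' the p-value is two-sided normal. Identical score vectors (or any pair
#' with zero variance of the AUC difference) are flagged degenerate and
#' reported as `z = 0`, `p = 1`.
#'
#' @param score_a,score_b Numeric scores for the same subjects.
#' @param labels Logical or 0/1 labels.
#' @return List: `auc_a`, `auc_b`, `z`, `p`, `degenerate`.
#' @export
delong_paired_test <- function(score_a, score_b, labels) {
  stopifnot(length(score_a) == length(score_b),
            length(score_a) == length(labels),
            !anyNA(score_a), !anyNA(score_b))
  lab <- .as_binary_label(labels)
  ra <- .proc_roc(score_a, lab)
  rb <- .proc_roc(score_b, lab)
  auc_a <- as.numeric(pROC::auc(ra))
  auc_b <- as.numeric(pROC::auc(rb))
  v <- suppressWarnings(
    as.numeric(pROC::var(ra, method = "delong")) +
      as.numeric(pROC::var(rb, method = "delong")) -
      2 * as.numeric(pROC::cov(ra, rb, method = "delong")))
  if (!is.finite(v) || v <= .Machine$double.eps) {
    return(list(auc_a = auc_a, auc_b = auc_b, z = 0, p = 1,
                degenerate = TRUE))
  }
  z <- (auc_a - auc_b) / sqrt(v)
  list(auc_a = auc_a, auc_b = auc_b, z = z,
       p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Specificity at a fixed sensitivity
#'
#' Among the ROC's realized operating points with sensitivity at least
#' `target_sensitivity`, returns the one with the highest specificity (no
#' interpolation between points, so the reported pair is an achievable
#' threshold). Sensitivity 1 is always attainable (classify everyone
#' positive), so the result is defined for any target in `[0, 1]`.
#'
#' @param roc A `roc_result` from [roc_auc()].
#' @param target_sensitivity Required sensitivity (default 0.80).
#' @return List: `threshold`, `sensitivity`, `specificity`.
#' @export
specificity_at_sensitivity <- function(roc, target_sensitivity = 0.80) {
  stopifnot(inherits(roc, "roc_result"), nrow(roc$thresholds) >= 1L)
  ok <- roc$thresholds[roc$thresholds$sensitivity >= target_sensitivity - 1e-12, ]
  best <- ok[which.max(ok$specificity), ]
  list(threshold = best$threshold, sensitivity = best$sensitivity,
       specificity = best$specificity)
}

#' Pearson chi-square statistic of a 2x2 table
#'
#' No continuity correction, matching how the demographic tables in
#' delirium cohort studies are typically reported. Arguments are the cell
#' counts row by row: `a`, `b` in group 1, `c`, `d` in group 2.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return The chi-square statistic (1 degree of freedom).
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(m < 0) || any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: every margin must be positive")
  }
  unname(suppressWarnings(
    stats::chisq.test(m, correct = FALSE)$statistic))
}

#' Unpaired pooled-variance t statistic from group summaries
#'
#' The two-sample t statistic computed directly from printed group means,
#' SDs and sizes (a − b convention).
#'
#' @param mean_a,sd_a,n_a Group a summary statistics.
#' @param mean_b,sd_b,n_b Group b summary statistics.
#' @return List: `t` (signed, a − b), `df`.
#' @export
two_sample_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop("each group needs at least 2 observations")
  if (sd_a <= 0 || sd_b <= 0) stop("group SDs must be positive")
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  list(t = (mean_a - mean_b) / (sp * sqrt(1 / n_a + 1 / n_b)),
       df = n_a + n_b - 2)
}
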