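#' ROC operating points by threshold sweep
#'
#' Sweeps the case/control decision threshold over every distinct score
#' value plus -Inf/+Inf sentinels; a sample is called a case when its score
#' is at or above the threshold.  Sensitivity is the detected fraction of
#' cases, specificity the rejected fraction of controls.
#'
#' @param scores numeric classification scores.
#' @param labels 0/1 labels (1 = case).
#' @return data.frame with `threshold`, `sensitivity`, `specificity`,
#'   ordered by increasing threshold.
#' @export
roc_points <- function(scores, labels) {
  check_two_classes(labels)
  thr <- c(-Inf, sort(unique(scores)), Inf)
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  sens <- vapply(thr, function(t) mean(cases >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(ctrls < t), numeric(1))
  data.frame(threshold = thr, sensitivity = sens, specificity = spec)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen case outscores a randomly chosen
#' control, with ties credited 1/2; identical to the trapezoidal area under
#' the threshold-sweep ROC.
#'
#' @inheritParams roc_points
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  check_two_classes(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  # rank-sum form of the pairwise comparison count (ties half-credited)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_two_classes <- function(labels) {
  if (!all(labels %in% c(0, 1)) || !all(c(0, 1) %in% labels)) {
    stop("labels must contain both classes coded 0/1", call. = FALSE)
  }
  invisible(labels)
}

proc_roc <- function(scores, labels) {
  pROC::roc(response = labels, predictor = scores, levels = c("0", "1"),
            direction = "<", quiet = TRUE)
}

#' DeLong 95% confidence interval for an AUC
#'
#' Structural-components (DeLong) variance of the empirical AUC with a
#' normal-quantile interval, clipped to [0, 1].
#'
#' @inheritParams roc_points
#' @param conf confidence level (default 0.95).
#' @return numeric `c(low, high)`.
#' @export
auc_ci_delong <- function(scores, labels, conf = 0.95) {
  check_two_classes(labels)
  ci <- suppressWarnings(
    as.numeric(pROC::ci.auc(proc_roc(scores, labels), conf.level = conf,
                            method = "delong")))  # AUC 1 gives the point CI
  c(low = max(0, ci[1]), high = min(1, ci[3]))
}

#' DeLong paired test for two correlated AUCs
#'
#' Two-sided test of equal AUC for two score vectors computed on the same
#' samples (e.g. two classifiers evaluated on one testing dataset), using
#' the structural-components covariance.
#'
#' @param scores_a,scores_b score vectors on identical samples.
#' @inheritParams roc_points
#' @return list with `auc_a`, `auc_b`, `p` (two-sided p-value; 1 for
#'   identical score vectors).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  check_two_classes(labels)
  stopifnot(length(scores_a) == length(scores_b))
  auc_a <- roc_auc(scores_a, labels)
  auc_b <- roc_auc(scores_b, labels)
  if (isTRUE(all.equal(scores_a, scores_b, tolerance = 0))) {
    return(list(auc_a = auc_a, auc_b = auc_b, p = 1))
  }
  p <- tryCatch({
    tt <- pROC::roc.test(proc_roc(scores_a, labels),
                         proc_roc(scores_b, labels),
                         method = "delong", paired = TRUE)
    as.numeric(tt$p.value)
  }, error = function(e) NA_real_)
  if (!is.finite(p)) p <- 1 # degenerate (zero-variance) comparison
  list(auc_a = auc_a, auc_b = auc_b, p = p)
}

#' Diagnostic accuracy at the equal-sensitivity/specificity point
#'
#' Walks the threshold sweep to the sign change of sensitivity minus
#' specificity; an operating point where the two are exactly equal is
#' returned as is, otherwise the crossing is interpolated linearly between
#' the bracketing operating points.  At the crossing sensitivity equals
#' specificity, and that common value is the accuracy regardless of
#' prevalence.
#'
#' @inheritParams roc_points
#' @return accuracy in [0, 1].
#' @export
acc_equal_sens_spec <- function(scores, labels) {
  rp <- roc_points(scores, labels)
  d <- rp$sensitivity - rp$specificity
  # d runs from +1 (threshold -Inf) to -1 (+Inf)
  exact <- which(d == 0)
  if (length(exact)) return(rp$sensitivity[exact[1]])
  i <- which(d[-length(d)] > 0 & d[-1] < 0)[1]
  lam <- d[i] / (d[i] - d[i + 1])
  rp$sensitivity[i] + lam * (rp$sensitivity[i + 1] - rp$sensitivity[i])
}

#' Two-sided Wilcoxon rank-sum p-value for a case/control feature
#'
#' Exact enumeration for small groups without ties; normal approximation
#' with tie and continuity correction otherwise (the behaviour of
#' [stats::wilcox.test()], which this wraps).
#'
#' @param values_cases,values_controls numeric feature values per class.
#' @return two-sided p-value (1 when every value is identical).
#' @export
ranksum_test <- function(values_cases, values_controls) {
  stopifnot(length(values_cases) >= 1, length(values_controls) >= 1)
  if (length(unique(c(values_cases, values_controls))) == 1L) return(1)
  exact <- length(values_cases) < 10 && length(values_controls) < 10 &&
    !any(duplicated(c(values_cases, values_controls)))
  suppressWarnings(
    stats::wilcox.test(values_cases, values_controls, exact = exact,
                       correct = TRUE)$p.value)
}

#' Full ROC summary of a score vector
#'
#' @inheritParams roc_points
#' @return list of class `roc_summary`: `points` (threshold sweep), `auc`,
#'   `ci95` and `acc_eq` (accuracy at equal sensitivity/specificity).
#' @export
roc_summary <- function(scores, labels) {
  structure(list(points = roc_points(scores, labels),
                 auc = roc_auc(scores, labels),
                 ci95 = auc_ci_delong(scores, labels),
                 acc_eq = acc_equal_sens_spec(scores, labels),
                 n_cases = sum(labels == 1),
                 n_controls = sum(labels == 0)),
            class = "roc_summary")
}

significance_stars <- function(p) {
  ifelse(p < 1e-3, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Per-feature quartile summary and case/control comparison of a cohort
#'
#' For each of the 13 difference features: the 50th [25th; 75th] percentiles
#' overall and per class, the two-sided rank-sum p-value for cases versus
#' controls, and significance stars (* p<0.05, ** p<0.01, *** p<1e-3).
#'
#' @param cohort labeled cohort data.frame.
#' @return data.frame with one row per feature.
#' @export
summarize_features <- function(cohort) {
  validate_cohort(cohort)
  feats <- difference_feature_names()
  q3 <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE,
                                    type = 7)
  rows <- lapply(feats, function(f) {
    v <- cohort[[f]]
    vc <- v[cohort$label == 1]
    v0 <- v[cohort$label == 0]
    p <- ranksum_test(vc, v0)
    qa <- q3(v); qco <- q3(v0); qca <- q3(vc)
    data.frame(feature = f,
               total_q1 = qa[1], total_median = qa[2], total_q3 = qa[3],
               control_q1 = qco[1], control_median = qco[2],
               control_q3 = qco[3],
               case_q1 = qca[1], case_median = qca[2], case_q3 = qca[3],
               p_value = signif(p, 3),
               stars = significance_stars(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
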