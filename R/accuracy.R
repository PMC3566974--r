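#' Two-by-two contingency table
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts (test positive/negative
#'   against disease present/absent).
#' @return An object of class `two_by_two` with derived margins `n`, `n1`
#'   (diseased) and `n0` (non-diseased). A table with an empty disease class
#'   carries `degenerate = TRUE`; downstream interval estimates are then
#'   undefined.
#' @export
two_by_two <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  n <- sum(cells)
  if (n == 0) stop("contingency table is empty", call. = FALSE)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = n,
                 n1 = tp + fn, n0 = fp + tn,
                 degenerate = (tp + fn == 0) || (fp + tn == 0)),
            class = "two_by_two")
}

#' Build a contingency table from truth and predictions
#'
#' Not-evaluable records must already have been removed upstream (complete-case
#' analysis); only `"positive"`/`"negative"` predictions are accepted.
#'
#' @param truth Logical (or 0/1) disease indicators.
#' @param pred Character classifications, `"positive"` or `"negative"`.
#' @return A `two_by_two`.
#' @export
build_contingency <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("truth and pred lengths differ", call. = FALSE)
  if (length(truth) == 0L) stop("empty input", call. = FALSE)
  if (!all(pred %in% c("positive", "negative")))
    stop("pred must be 'positive'/'negative' (remove not_evaluable upstream)", call. = FALSE)
  truth <- as.logical(truth)
  pos <- pred == "positive"
  two_by_two(tp = sum(truth & pos), fp = sum(!truth & pos),
             fn = sum(truth & !pos), tn = sum(!truth & !pos))
}

#' @keywords internal
proportion_estimate <- function(x, n, point, ci_low, ci_high, method, level) {
  structure(list(x = x, n = n, point = point,
                 ci_low = ci_low, ci_high = ci_high,
                 method = method, level = level),
            class = "proportion_estimate")
}

#' @keywords internal
z_value <- function(level) if (isTRUE(all.equal(level, 0.95))) 1.96 else stats::qnorm(1 - (1 - level) / 2)

#' Wald (normal-approximation) confidence interval for a proportion
#'
#' point +/- z * sqrt(point (1 - point) / n), bounds clipped to \[0, 1\].
#' Used for dataset prevalences, whose reported intervals follow the
#' normal approximation.
#'
#' @param x Successes. @param n Trials (>= 1). @param level Confidence level.
#' @return A `proportion_estimate`.
#' @export
wald_ci <- function(x, n, level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  p <- x / n
  half <- z_value(level) * sqrt(p * (1 - p) / n)
  proportion_estimate(x, n, p, max(0, p - half), min(1, p + half), "wald", level)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact tail-inversion bounds via the beta quantile representation:
#' lower = qbeta(alpha/2, x, n - x + 1) (0 when x = 0),
#' upper = qbeta(1 - alpha/2, x + 1, n - x) (1 when x = n).
#' Used for sensitivity, specificity and predictive values.
#'
#' @inheritParams wald_ci
#' @return A `proportion_estimate`.
#' @export
clopper_pearson_ci <- function(x, n, level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  alpha <- 1 - level
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  proportion_estimate(x, n, x / n, lo, hi, "clopper_pearson", level)
}

#' @keywords internal
ratio_estimate <- function(point, ci_low, ci_high, flagged = FALSE) {
  structure(list(point = point, ci_low = ci_low, ci_high = ci_high,
                 method = "log_normal", flagged = flagged),
            class = "ratio_estimate")
}

#' Positive and negative likelihood ratios with log-method intervals
#'
#' LR+ = sens / (1 - spec), LR- = (1 - sens) / spec. The confidence interval
#' is exp(ln LR +/- z * sqrt(1/x1 - 1/n1 + 1/x0 - 1/n0)) with x1 = tp, x0 = fp
#' for LR+ and x1 = fn, x0 = tn for LR-. When any cell is zero the zero-cell
#' policy adds 0.5 to all four cells (standard continuity correction) and the
#' estimates are flagged.
#'
#' @param t A `two_by_two`. @param level Confidence level.
#' @param zero_cell `"continuity"` (default) or `"none"` (zero cells then
#'   yield infinite/zero or undefined estimates).
#' @return List with `lr_pos` and `lr_neg`, each a `ratio_estimate`.
#' @export
likelihood_ratios <- function(t, level = 0.95, zero_cell = c("continuity", "none")) {
  zero_cell <- match.arg(zero_cell)
  stopifnot(inherits(t, "two_by_two"))
  if (t$degenerate) stop("likelihood ratios need both disease classes present", call. = FALSE)
  cells <- c(t$tp, t$fp, t$fn, t$tn)
  flagged <- any(cells == 0)
  if (flagged && zero_cell == "continuity") cells <- cells + 0.5
  tp <- cells[1]; fp <- cells[2]; fn <- cells[3]; tn <- cells[4]
  n1 <- tp + fn; n0 <- fp + tn
  sens <- tp / n1; spec <- tn / n0
  z <- z_value(level)
  one_lr <- function(point, x1, x0) {
    se <- sqrt(1 / x1 - 1 / n1 + 1 / x0 - 1 / n0)
    ratio_estimate(point, point * exp(-z * se), point * exp(z * se), flagged)
  }
  list(lr_pos = one_lr(sens / (1 - spec), tp, fp),
       lr_neg = one_lr((1 - sens) / spec, fn, tn))
}

#' Assign a prevalence stratum
#'
#' Low prevalence (LP) below 5%, intermediate (IP) 5 to 20%, high (HP) above
#' 20% pre-test probability of the target condition.
#'
#' @param prevalence Fraction in \[0, 1\].
#' @return `"LP"`, `"IP"` or `"HP"`.
#' @export
assign_stratum <- function(prevalence) {
  stopifnot(prevalence >= 0, prevalence <= 1)
  if (prevalence < 0.05) "LP" else if (prevalence <= 0.20) "IP" else "HP"
}

#' Full diagnostic-accuracy profile of a contingency table
#'
#' Sensitivity, specificity and predictive values carry exact
#' (Clopper-Pearson) intervals; prevalence carries a Wald interval;
#' likelihood ratios use the log method. For a dichotomous rule the AUC is
#' the single-threshold trapezoid (sens + spec) / 2 unless a rank-based
#' value is supplied (score rules).
#'
#' @param t A `two_by_two`.
#' @param level Confidence level.
#' @param auc Optional externally computed AUC (e.g. [auc_rank()] for a sum
#'   score); when `NULL`, the single-threshold trapezoid is used.
#' @param total_n Optional total record count including not-evaluable records;
#'   when supplied, `positive_fraction_total` reports the alternative
#'   denominator.
#' @return An object of class `accuracy_profile`.
#' @export
accuracy_profile <- function(t, level = 0.95, auc = NULL, total_n = NULL) {
  stopifnot(inherits(t, "two_by_two"))
  if (t$degenerate) stop("accuracy profile needs both disease classes present", call. = FALSE)
  sens <- clopper_pearson_ci(t$tp, t$n1, level)
  spec <- clopper_pearson_ci(t$tn, t$n0, level)
  npos <- t$tp + t$fp; nneg <- t$fn + t$tn
  ppv <- if (npos > 0) clopper_pearson_ci(t$tp, npos, level)
  npv <- if (nneg > 0) clopper_pearson_ci(t$tn, nneg, level)
  lrs <- likelihood_ratios(t, level)
  prev <- wald_ci(t$n1, t$n, level)
  structure(list(
    table = t, sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    lr_pos = lrs$lr_pos, lr_neg = lrs$lr_neg, prevalence = prev,
    auc = auc %||% (sens$point + spec$point) / 2,
    auc_method = if (is.null(auc)) "single_threshold_trapezoid" else "rank",
    stratum = assign_stratum(prev$point),
    evaluable_n = t$n,
    positive_fraction = npos / t$n,
    positive_fraction_total = if (!is.null(total_n)) npos / total_n,
    total_n = total_n,
    level = level
  ), class = "accuracy_profile")
}

#' Post-test probability from a likelihood ratio
#'
#' Converts the pre-test probability to odds, multiplies by the likelihood
#' ratio and converts back: post = (p/(1-p) * LR) / (1 + p/(1-p) * LR).
#'
#' @param pretest Pre-test probability, strictly inside (0, 1).
#' @param lr Non-negative likelihood ratio.
#' @return Post-test probability.
#' @export
post_test_probability <- function(pretest, lr) {
  stopifnot(pretest > 0, pretest < 1, lr >= 0)
  odds <- pretest / (1 - pretest) * lr
  odds / (1 + odds)
}

#' Dumbbell point: pre-test and post-test probabilities
#'
#' The three probabilities displayed per (dataset, rule) cell: disease
#' probability before testing (prevalence among evaluable records), after a
#' positive result (via LR+) and after a negative result (via LR-).
#'
#' @param profile An `accuracy_profile`.
#' @return Object of class `dumbbell_point` with `pretest`, `post_positive`,
#'   `post_negative` and the LR zero-cell `flagged` marker.
#' @export
dumbbell_point <- function(profile) {
  stopifnot(inherits(profile, "accuracy_profile"))
  p <- profile$prevalence$point
  structure(list(pretest = p,
                 post_positive = post_test_probability(p, profile$lr_pos$point),
                 post_negative = post_test_probability(p, profile$lr_neg$point),
                 flagged = profile$lr_pos$flagged || profile$lr_neg$flagged),
            class = "dumbbell_point")
}

#' Rank-based (concordance) AUC
#'
#' Probability that a randomly chosen diseased record scores higher than a
#' randomly chosen non-diseased record, ties counted half; computed from
#' mid-ranks, equivalent to the Mann-Whitney statistic.
#'
#' @param scores Numeric scores (higher = more abnormal).
#' @param truth Logical (or 0/1) disease indicators.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("scores and truth lengths differ", call. = FALSE)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rule-out adequacy of an accuracy profile
#'
#' A rule is considered adequate for ruling out the target condition when
#' sensitivity exceeds 90% and the negative likelihood ratio is at most 0.2.
#'
#' @param profile An `accuracy_profile`.
#' @return List with `rule_out` (logical) and `reasons` (character, empty when
#'   adequate) naming each failed criterion.
#' @export
rule_out_assessment <- function(profile) {
  stopifnot(inherits(profile, "accuracy_profile"))
  reasons <- character()
  if (!(profile$sensitivity$point > 0.90))
    reasons <- c(reasons, sprintf("sensitivity %.3f not > 0.90", profile$sensitivity$point))
  if (!(profile$lr_neg$point <= 0.2))
    reasons <- c(reasons, sprintf("negative likelihood ratio %.3f > 0.2", profile$lr_neg$point))
  list(rule_out = length(reasons) == 0L, reasons = reasons)
}

#' Round half away from zero
#'
#' Display rounding for report tables (prevalences to 1 decimal, sensitivity
#' and specificity to integers, likelihood ratios to 1 decimal).
#'
#' @param x Numeric. @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @export
print.accuracy_profile <- function(x, ...) {
  t <- x$table
  fmt <- function(pe, d = 0) sprintf("%s (%s to %s)", round_half_away(100 * pe$point, d),
                                     round_half_away(100 * pe$ci_low, d),
                                     round_half_away(100 * pe$ci_high, d))
  cat(sprintf("<accuracy_profile> %d/%d cases (%s), %s stratum\n",
              t$n1, t$n, fmt(x$prevalence, 1), x$stratum))
  cat(sprintf("  sens %s%%  spec %s%%  %%positive %.1f\n",
              fmt(x$sensitivity), fmt(x$specificity), 100 * x$positive_fraction))
  cat(sprintf("  LR+ %.1f (%.1f to %.1f)  LR- %.1f (%.1f to %.1f)%s\n",
              x$lr_pos$point, x$lr_pos$ci_low, x$lr_pos$ci_high,
              x$lr_neg$point, x$lr_neg$ci_low, x$lr_neg$ci_high,
              if (x$lr_pos$flagged) " [zero-cell corrected]" else ""))
  invisible(x)
}
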