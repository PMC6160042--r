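# ROC/AUC evaluation: Mann-Whitney AUC, stratified bootstrap confidence
# intervals, the balanced sensitivity/specificity threshold rule, exact
# binomial CIs, demographics-as-biomarker AUCs and rank-sum comparison of
# probability sets.

#' Area under the ROC curve
#'
#' Computed as the normalised Mann-Whitney statistic: the fraction of
#' (case, control) pairs in which the case has the higher probability, ties
#' counted one half.  Equal to the trapezoidal area under the ROC curve.
#'
#' @param labels Class labels (both classes present).
#' @param probabilities Numeric scores; higher means more case-like.
#' @return AUC in \\[0, 1\\].
#' @export
auc <- function(labels, probabilities) {
  labels <- as_class_labels(labels)
  if (length(unique(labels)) < 2L) stop("both classes required")
  is_case <- labels == "case"
  na <- sum(is_case); nb <- sum(!is_case)
  r <- rank(probabilities)
  (sum(r[is_case]) - na * (na + 1) / 2) / (na * nb)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples cases and controls independently with replacement, recomputes
#' the AUC for each replicate and returns percentile bounds.
#'
#' @param labels Class labels.
#' @param probabilities Scores.
#' @param n_boot Number of replicates (default 2000).
#' @param seed Optional integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(labels, probabilities, n_boot = 2000L, seed = NULL,
                         conf = 0.95) {
  labels <- as_class_labels(labels)
  if (length(unique(labels)) < 2L) stop("both classes required")
  ic <- which(labels == "case")
  io <- which(labels == "control")
  na <- length(ic); nb <- length(io)
  one <- function(i) {
    p <- c(probabilities[sample(ic, replace = TRUE)],
           probabilities[sample(io, replace = TRUE)])
    r <- rank(p)
    (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * nb)
  }
  run <- function() vapply(seq_len(n_boot), one, numeric(1))
  aucs <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  stats::quantile(aucs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
}

# Operating points over all candidate thresholds: midpoints of adjacent
# distinct scores plus sentinels below the minimum and above the maximum.
# Classification rule: probability >= threshold => case.
.roc_operating_points <- function(labels, probabilities) {
  is_case <- labels == "case"
  u <- sort(unique(probabilities))
  cand <- c(u[1L] - 0.5,
            if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2,
            u[length(u)] + 0.5)
  se <- sp <- numeric(length(cand))
  for (i in seq_along(cand)) {
    pred <- probabilities >= cand[i]
    se[i] <- sum(pred & is_case) / sum(is_case)
    sp[i] <- sum(!pred & !is_case) / sum(!is_case)
  }
  data.frame(threshold = cand, sensitivity = se, specificity = sp)
}

#' ROC operating points
#'
#' @param labels Class labels.
#' @param probabilities Scores.
#' @return Data frame with columns `threshold`, `sensitivity`,
#'   `specificity`, one row per candidate threshold.
#' @export
roc_points <- function(labels, probabilities) {
  labels <- as_class_labels(labels)
  if (length(unique(labels)) < 2L) stop("both classes required")
  .roc_operating_points(labels, probabilities)
}

#' Balanced sensitivity/specificity threshold
#'
#' Selects the probability cut-point maximising
#' `(SE - 1 + SP)^2 + (SP - 1 + SE)^2`, which algebraically equals
#' `2 * (SE + SP - 1)^2` and therefore picks the same operating point as
#' the squared Youden index.  Ties are broken by higher specificity, then
#' by lower threshold.
#'
#' @param labels Class labels.
#' @param probabilities Scores.
#' @return List with `threshold`, `sensitivity`, `specificity`.
#' @export
balance_threshold <- function(labels, probabilities) {
  labels <- as_class_labels(labels)
  if (length(unique(labels)) < 2L) stop("both classes required")
  op <- .roc_operating_points(labels, probabilities)
  crit <- (op$sensitivity - 1 + op$specificity)^2 +
    (op$specificity - 1 + op$sensitivity)^2
  best <- which(crit >= max(crit) - 1e-12)
  if (length(best) > 1L) {
    best <- best[order(-op$specificity[best], op$threshold[best])]
  }
  i <- best[1L]
  list(threshold = op$threshold[i], sensitivity = op$sensitivity[i],
       specificity = op$specificity[i])
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' @param successes,total Non-negative counts with `successes <= total`,
#'   `total >= 1`.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lo, hi)`.
#' @export
binomial_ci <- function(successes, total, conf = 0.95) {
  if (total < 1L) stop("total must be >= 1")
  if (successes < 0L || successes > total) {
    stop("successes must be between 0 and total")
  }
  as.vector(stats::binom.test(successes, total,
                              conf.level = conf)$conf.int)
}

#' Full ROC summary of a prediction set
#'
#' AUC with a stratified bootstrap CI, the balanced threshold, and
#' sensitivity/specificity at that threshold with exact binomial CIs.
#'
#' @param labels Class labels (or a [prediction_set()], in which case
#'   `probabilities` is ignored).
#' @param probabilities Scores.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Optional seed for the bootstrap.
#' @return A `roc_summary` list.
#' @export
roc_summary <- function(labels, probabilities = NULL, n_boot = 2000L,
                        seed = NULL) {
  model <- NULL
  if (inherits(labels, "prediction_set")) {
    model <- attr(labels, "model")
    probabilities <- labels$probability
    labels <- labels$label
  }
  labels <- as_class_labels(labels)
  bt <- balance_threshold(labels, probabilities)
  pred_case <- probabilities >= bt$threshold
  is_case <- labels == "case"
  out <- list(
    auc = auc(labels, probabilities),
    auc_ci = bootstrap_ci(labels, probabilities, n_boot, seed),
    threshold = bt$threshold,
    sensitivity = bt$sensitivity,
    sensitivity_ci = binomial_ci(sum(pred_case & is_case), sum(is_case)),
    specificity = bt$specificity,
    specificity_ci = binomial_ci(sum(!pred_case & !is_case), sum(!is_case)),
    n_case = sum(is_case), n_control = sum(!is_case),
    n_boot = n_boot, seed = seed, model = model)
  class(out) <- "roc_summary"
  out
}

#' @export
print.roc_summary <- function(x, ...) {
  hdr <- if (is.null(x$model)) "<roc_summary>" else
    sprintf("<roc_summary> %s", x$model)
  cat(sprintf(paste0(
    "%s  n = %d case / %d control\n",
    "  AUC         %.3f  (%.3f-%.3f, 95%% CI, %d stratified bootstrap reps)\n",
    "  threshold   %.4g\n",
    "  sensitivity %.3f  (%.3f-%.3f, exact binomial)\n",
    "  specificity %.3f  (%.3f-%.3f, exact binomial)\n"),
    hdr, x$n_case, x$n_control,
    x$auc, x$auc_ci[1], x$auc_ci[2], x$n_boot, x$threshold,
    x$sensitivity, x$sensitivity_ci[1], x$sensitivity_ci[2],
    x$specificity, x$specificity_ci[1], x$specificity_ci[2]))
  invisible(x)
}

#' AUC of a single demographic covariate used as a biomarker
#'
#' Treats the covariate values as classification scores.  If the raw AUC is
#' below one half the orientation is flipped (score negated) so the
#' reported AUC is `max(a, 1 - a)`; the flip is recorded in the `flipped`
#' attribute and messaged.
#'
#' @param covariate Numeric covariate values (encode sex as 0/1).
#' @param labels Class labels.
#' @param n_boot,seed Passed to the bootstrap.
#' @return A [roc_summary()] with a `flipped` attribute.
#' @export
demographic_auc <- function(covariate, labels, n_boot = 2000L, seed = NULL) {
  labels <- as_class_labels(labels)
  if (length(unique(covariate)) == 1L) {
    warning("constant covariate: AUC is 0.5")
  }
  a <- auc(labels, covariate)
  flipped <- a < 0.5
  score <- if (flipped) -covariate else covariate
  if (flipped) {
    message("demographic_auc: orientation flipped (raw AUC ",
            format(a, digits = 3), ")")
  }
  out <- roc_summary(labels, score, n_boot, seed)
  attr(out, "flipped") <- flipped
  out
}

#' Rank-sum comparison of two sets of prediction probabilities
#'
#' Two-sided Wilcoxon rank-sum test asking whether two analyses produced
#' systematically different probability sets (e.g. demographics-only versus
#' demographics plus wavelet features).
#'
#' @param probabilities_a,probabilities_b Numeric probability vectors or
#'   [prediction_set()]s.
#' @return Two-sided p-value.
#' @export
compare_predictions <- function(probabilities_a, probabilities_b) {
  get_p <- function(x) {
    if (inherits(x, "prediction_set")) x$probability else as.numeric(x)
  }
  a <- get_p(probabilities_a)
  b <- get_p(probabilities_b)
  if (length(a) == 0L || length(b) == 0L) stop("empty probability set")
  ranksum_p(a, b)
}
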