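# Statistical stage: group comparison, empirical ROC with Youden cutoffs,
# binormal closed form, maximum-likelihood classifier combination, the
# three-threshold GB/BM decision rule, and confusion metrics.

#' Two-sample t test on a biomarker
#'
#' Thin wrapper around [stats::t.test()] returning the statistic, degrees of
#' freedom and two-sided p-value. Welch (unequal variances) is the default;
#' `pooled` uses the classical equal-variance form with `n_a + n_b - 2`
#' degrees of freedom. Two constant groups with equal means return
#' `t = 0, p = 1`; constant groups with different means are degenerate and
#' flagged (`p = 0`).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2, finite.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
two_sample_t_test <- function(group_a, group_b,
                              variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L,
            all(is.finite(group_a)), all(is.finite(group_b)))
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = NA_real_, p = 0, degenerate = TRUE))
  }
  res <- stats::t.test(group_a, group_b, var.equal = variant == "pooled")
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, degenerate = FALSE)
}

#' Empirical ROC analysis
#'
#' ROC over all midpoints between adjacent distinct score values as
#' candidate cutoffs, with strict inequality (a case is called positive when
#' its score is strictly beyond the cutoff in the positive direction). The
#' AUC is the trapezoidal area,
#' identical to the Mann-Whitney statistic with ties given half credit. The
#' stored optimal cutoff maximizes the Youden index
#' `J = sensitivity + specificity - 1`, ties broken toward the pooled
#' median score.
#'
#' @param scores Numeric scores.
#' @param labels Class labels; `positive` names the positive class
#'   (glioblastoma by default).
#' @param direction `"greater_is_positive"` if positives score high,
#'   `"less_is_positive"` if they score low.
#' @param positive Positive-class label.
#' @return An object of class `roc_result` with `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `optimal_cutoff`, `direction`.
#' @export
#' @examples
#' roc <- roc_analysis(c(1, 2, 3, 4), c("BM", "BM", "GB", "GB"))
#' roc$auc # 1
roc_analysis <- function(scores, labels,
                         direction = c("greater_is_positive",
                                       "less_is_positive"),
                         positive = "GB") {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pos <- labels == positive
  n_pos <- as.numeric(sum(pos)); n_neg <- as.numeric(sum(!pos))
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present")
  s <- if (direction == "greater_is_positive") scores else -scores

  # AUC: Mann-Whitney with half credit for ties, via midranks
  r <- rank(s)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # candidate cutoffs: midpoints between adjacent distinct scores (an
  # interior cutoff separates fully separated clusters); predict positive
  # when the oriented score exceeds the cutoff
  su <- sort(unique(s))
  cs_pos <- cumsum(tabulate(match(s[pos], su), length(su)))
  cs_neg <- cumsum(tabulate(match(s[!pos], su), length(su)))
  if (length(su) > 1L) {
    thr_o <- (su[-1L] + su[-length(su)]) / 2
    cs_pos <- cs_pos[-length(su)]
    cs_neg <- cs_neg[-length(su)]
  } else {
    thr_o <- su
  }
  sens <- (n_pos - cs_pos) / n_pos   # P(score > thr | positive)
  spec <- cs_neg / n_neg             # P(score <= thr | negative)

  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  med <- stats::median(s)
  best <- best[which.min(abs(thr_o[best] - med))]
  thresholds <- if (direction == "greater_is_positive") thr_o else -thr_o
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc,
                 optimal_cutoff = thresholds[best],
                 direction = direction, positive = positive),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (%s, positive = %s): AUC %.4f, Youden cutoff %.6g\n",
              x$direction, x$positive, x$auc, x$optimal_cutoff))
  invisible(x)
}

#' Youden-optimal cutoff of an ROC curve
#'
#' Cutoff maximizing `J = sensitivity + specificity - 1` (maximizing both
#' sensitivity and specificity), ties broken toward the cutoff nearest the
#' pooled median score.
#'
#' @param roc A [roc_analysis()] result.
#' @return The optimal cutoff (numeric scalar).
#' @export
optimal_cutoff_youden <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  roc$optimal_cutoff
}

#' Closed-form AUC for two Gaussian score distributions
#'
#' `AUC = Phi(|mu_pos - mu_neg| / sqrt(sd_pos^2 + sd_neg^2))`; the analytic
#' oracle for ROC analysis on binormal cohorts.
#'
#' @param mean_pos,sd_pos Positive-class mean and SD (sd > 0).
#' @param mean_neg,sd_neg Negative-class mean and SD (sd > 0).
#' @return AUC in `[0.5, 1]`.
#' @export
#' @examples
#' binormal_auc(2.63, 1.72, 1.21, 0.64) # ~0.78
binormal_auc <- function(mean_pos, sd_pos, mean_neg, sd_neg) {
  if (sd_pos <= 0 || sd_neg <= 0) stop("sds must be > 0")
  stats::pnorm(abs(mean_pos - mean_neg) / sqrt(sd_pos^2 + sd_neg^2))
}

#' Combine biomarkers into one classifier score
#'
#' Fits a maximum-likelihood linear combiner (logistic regression on
#' standardized features) and returns the combined scores with their ROC.
#' Under perfect separation the logistic MLE diverges; the fit then falls
#' back to the linear discriminant direction (flagged in the result).
#'
#' @param features Data.frame or matrix of numeric feature columns (>= 1).
#' @param labels Class labels; `positive` as in [roc_analysis()].
#' @param positive Positive-class label.
#' @return List with `scores`, `roc` (a `roc_result`), `coefficients`
#'   (on the standardized scale) and `method` (`"logistic"` or `"lda"`).
#' @export
combine_classifiers <- function(features, labels, positive = "GB") {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (ncol(x) < 1L) stop("at least one feature required")
  y <- as.integer(labels == positive)
  if (all(y == 1L) || all(y == 0L)) stop("both classes must be present")
  xs <- scale(x)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, xs), y, family = stats::binomial()))
  p <- fit$fitted.values
  separated <- !fit$converged || all(abs(p - y) < 1e-8)
  if (separated) {
    ld <- MASS::lda(xs, grouping = factor(y))
    w <- drop(ld$scaling[, 1L])
    scores <- drop(xs %*% w)
    if (mean(scores[y == 1L]) < mean(scores[y == 0L])) {
      w <- -w; scores <- -scores
    }
    coefs <- c(`(Intercept)` = 0, w)
    method <- "lda"
    warning("perfect separation: falling back to the LDA direction")
  } else {
    coefs <- fit$coefficients
    names(coefs) <- c("(Intercept)", colnames(x))
    scores <- drop(cbind(1, xs) %*% coefs)
    method <- "logistic"
  }
  roc <- roc_analysis(scores, labels, "greater_is_positive", positive)
  list(scores = scores, roc = roc, coefficients = coefs, method = method)
}

#' Multi-threshold GB/BM decision rule
#'
#' The study's three-criterion rule: call glioblastoma when perilesional
#' rCBV max > 1.37, PSR > 75% and lesion mean ADC < 1.0e-3 mm2/s
#' (inequalities strict; boundary values do not satisfy a criterion). The
#' combination mode is configurable: `all` (conjunction, default), `any`,
#' or `majority`.
#'
#' @param criteria Data.frame with columns `feature`, `direction`
#'   (`">"` or `"<"`) and `cutoff`.
#' @param combination `"all"`, `"any"` or `"majority"`.
#' @return An object of class `decision_rule`.
#' @export
decision_rule <- function(criteria = data.frame(
                            feature = c("perilesional_rcbv_max",
                                        "psr_percent", "lesion_adc_mean"),
                            direction = c(">", ">", "<"),
                            cutoff = c(1.37, 75, 1.0e-3),
                            stringsAsFactors = FALSE),
                          combination = c("all", "any", "majority")) {
  combination <- match.arg(combination)
  stopifnot(is.data.frame(criteria),
            all(c("feature", "direction", "cutoff") %in% names(criteria)),
            all(criteria$direction %in% c(">", "<")),
            all(is.finite(criteria$cutoff)))
  structure(list(criteria = criteria, combination = combination),
            class = "decision_rule")
}

#' Apply a decision rule to a feature table
#'
#' @param features Data.frame containing the rule's feature columns (e.g.
#'   from [sample_feature_cohort()] or rows of [extract_case_features()]).
#' @param rule A [decision_rule()].
#' @return Character vector of `"GB"` / `"BM"` per case; `"undetermined"`
#'   where a required feature is missing (NA).
#' @export
#' @examples
#' prof <- data.frame(perilesional_rcbv_max = 2.63, psr_percent = 84.59,
#'                    lesion_adc_mean = 0.71e-3)
#' apply_decision_rule(prof, decision_rule()) # "GB"
apply_decision_rule <- function(features, rule = decision_rule()) {
  stopifnot(inherits(rule, "decision_rule"))
  cr <- rule$criteria
  miss <- setdiff(cr$feature, names(features))
  if (length(miss))
    stop("feature(s) missing from table: ", paste(miss, collapse = ", "))
  hits <- matrix(NA, nrow(features), nrow(cr))
  for (i in seq_len(nrow(cr))) {
    v <- features[[cr$feature[i]]]
    hits[, i] <- if (cr$direction[i] == ">") v > cr$cutoff[i]
                 else v < cr$cutoff[i]
  }
  out <- rep("undetermined", nrow(features))
  ok <- !apply(hits, 1L, anyNA)
  gb <- switch(rule$combination,
               all = apply(hits, 1L, all),
               any = apply(hits, 1L, any),
               majority = rowSums(hits) > ncol(hits) / 2)
  out[ok] <- ifelse(gb[ok], "GB", "BM")
  out
}

#' Sensitivity, specificity and accuracy of predicted labels
#'
#' Glioblastoma is the positive class: sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`. Cases predicted `"undetermined"` are excluded
#' from the metrics and counted separately.
#'
#' @param predicted Character/factor labels in `GB`, `BM`, `undetermined`.
#' @param truth True labels in `GB`, `BM`.
#' @param positive Positive-class label.
#' @return List with `sensitivity`, `specificity`, `accuracy`,
#'   `n_undetermined`; a metric is NA when its denominator class is absent.
#' @export
confusion_metrics <- function(predicted, truth, positive = "GB") {
  stopifnot(length(predicted) == length(truth))
  keep <- predicted != "undetermined"
  p <- predicted[keep]; t <- truth[keep]
  tp <- sum(p == positive & t == positive)
  fn <- sum(p != positive & t == positive)
  tn <- sum(p != positive & t != positive)
  fp <- sum(p == positive & t != positive)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = if (length(p)) (tp + tn) / length(p) else NA_real_,
       n_undetermined = sum(!keep))
}

# 95% CI for an empirical AUC: bootstrap (2000 stratified resamples) for
# small cohorts, Hanley-McNeil normal approximation for large ones
auc_ci <- function(scores, labels, positive = "GB", direction =
                     "greater_is_positive", n_boot = 2000L, seed = 1L,
                   boot_max_n = 5000L) {
  pos <- labels == positive
  n1 <- as.numeric(sum(pos)); n2 <- as.numeric(sum(!pos))
  auc <- roc_analysis(scores, labels, direction, positive)$auc
  if (n1 + n2 <= boot_max_n) {
    with_seed(seed, {
      reps <- replicate(n_boot, {
        i1 <- sample(which(pos), n1, replace = TRUE)
        i2 <- sample(which(!pos), n2, replace = TRUE)
        idx <- c(i1, i2)
        roc_analysis(scores[idx], labels[idx], direction, positive)$auc
      })
      ci <- unname(stats::quantile(reps, c(0.025, 0.975)))
    })
  } else {
    q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                  (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
    ci <- auc + c(-1.96, 1.96) * se
  }
  list(auc = auc, ci_lower = max(0, ci[1L]), ci_upper = min(1, ci[2L]))
}
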