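# statistical stage: t tests, ROC/AUC, Youden cutoffs, combined classifier,
# decision rule, confusion metrics

test_that("t test identities and the pooled closed form hold", {
  same <- c(1, 2, 3)
  res <- two_sample_t_test(same, same)
  expect_true(res$degenerate == FALSE || res$p == 1)
  expect_equal(two_sample_t_test(c(1, 1, 1), c(1, 1, 1))$p, 1)
  far <- two_sample_t_test(same, same + 100 * sd(same))
  expect_lt(far$p, 1e-6)
  a <- c(1.2, 2.9, 3.1); b <- c(4.0, 5.5, 7.2)
  got <- two_sample_t_test(a, b, variant = "pooled")
  want <- pooled_t_oracle(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df)
  expect_equal(got$p, want$p, tolerance = 1e-12)
})

test_that("lesion ADC separates simulated study-size cohorts in most draws", {
  # Monte-Carlo power at the study's group parameters and n = 20/21:
  # 0.865 for the Welch test (50000-rep oracle); 500 cohorts stay within
  # 3 binomial standard errors of that value
  spec <- default_cohort_spec()
  hits <- 0L
  for (s in 1:500) {
    tab <- sample_feature_cohort(spec, seed = s)
    p <- two_sample_t_test(tab$lesion_adc_mean[tab$group == "GB"],
                           tab$lesion_adc_mean[tab$group == "BM"])$p
    if (p < 0.001) hits <- hits + 1L
  }
  expect_gt(hits / 500, 0.865 - 3 * sqrt(0.865 * 0.135 / 500))
  expect_lt(hits / 500, 0.865 + 3 * sqrt(0.865 * 0.135 / 500))
})

test_that("empirical ROC handles separation, the null, and matches pROC", {
  roc <- roc_analysis(c(1, 2, 3, 10, 11, 12),
                      rep(c("BM", "GB"), each = 3))
  expect_equal(roc$auc, 1)
  expect_gt(roc$optimal_cutoff, 3)
  expect_lt(roc$optimal_cutoff, 10)
  set.seed(8)
  sc <- rnorm(1e5); lb <- sample(c("GB", "BM"), 1e5, replace = TRUE)
  expect_lt(abs(roc_analysis(sc, lb)$auc - 0.5), 0.01)
  # cross-check the estimator (with ties) against an independent package
  skip_if_not_installed("pROC")
  set.seed(9)
  sc2 <- sample(1:8, 300, replace = TRUE)
  lb2 <- ifelse(rbinom(300, 1, plogis(sc2 - 4)) == 1, "GB", "BM")
  got <- roc_analysis(sc2, lb2)$auc
  want <- as.numeric(pROC::auc(pROC::roc(
    response = lb2, predictor = as.numeric(sc2), levels = c("BM", "GB"),
    direction = "<", quiet = TRUE)))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("AUC and operating points are invariant under monotone transforms", {
  set.seed(10)
  sc <- c(rnorm(400, 1), rnorm(400))
  lb <- rep(c("GB", "BM"), each = 400)
  r1 <- roc_analysis(sc, lb)
  r2 <- roc_analysis(exp(sc), lb)
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
  # the transformed optimal cutoff yields identical operating
  # characteristics (cutoffs are midpoints, so the values differ)
  gb <- lb == "GB"
  c1 <- r1$optimal_cutoff
  i1 <- which(r1$thresholds == c1)
  expect_equal(mean(exp(sc)[gb] > exp(c1)), r1$sensitivity[i1])
  expect_equal(mean(exp(sc)[!gb] <= exp(c1)), r1$specificity[i1])
})

test_that("the large-sample Youden cutoff converges to the density crossing", {
  # equal-density crossing of N(0.71, 0.33) and N(1.13, 0.21) (1e-3 mm2/s
  # units), found analytically: 0.8974
  spec <- default_cohort_spec()
  spec$n_gb <- spec$n_bm <- 200000L
  tab <- sample_feature_cohort(spec, seed = 2)
  roc <- roc_analysis(tab$lesion_adc_mean, tab$group, "less_is_positive")
  expect_lt(abs(optimal_cutoff_youden(roc) * 1e3 - 0.8974), 0.03)
})

test_that("binormal closed form matches its identities and the study inputs", {
  expect_equal(binormal_auc(5, 1, 5, 2), 0.5)
  expect_equal(binormal_auc(2.63, 1.72, 1.21, 0.64),
               pnorm(1.42 / sqrt(1.72^2 + 0.64^2)))
  expect_equal(round(binormal_auc(2.63, 1.72, 1.21, 0.64), 2), 0.78)
  aucs <- sapply(c(0.5, 1, 2, 4), function(d) binormal_auc(d, 1, 0, 1))
  expect_true(all(diff(aucs) > 0))
  expect_error(binormal_auc(1, 0, 0, 1), "sds")
})

test_that("classifier combination improves on matched single features", {
  set.seed(12)
  n <- 20000
  x1 <- c(rnorm(n, 1), rnorm(n)); x2 <- c(rnorm(n, 1), rnorm(n))
  lb <- rep(c("GB", "BM"), each = n)
  single <- roc_analysis(x1, lb)$auc
  comb <- combine_classifiers(data.frame(x1, x2), lb)
  expect_equal(comb$method, "logistic")
  expect_gt(comb$roc$auc, single)
  # analytic independence bound Phi(sqrt(a1^2 + a2^2)), a_i = 1/sqrt(2)
  expect_lt(abs(comb$roc$auc - pnorm(1)), 0.01)
  # single feature: logistic is a monotone map, AUC unchanged
  one <- combine_classifiers(data.frame(x1), lb)
  expect_equal(one$roc$auc, single, tolerance = 1e-9)
})

test_that("perfect separation falls back to the LDA direction with a warning", {
  x <- data.frame(a = c(1, 2, 3, 10, 11, 12), b = c(0, 1, 0, 1, 0, 1))
  lb <- rep(c("BM", "GB"), each = 3)
  expect_warning(res <- combine_classifiers(x, lb), "separation")
  expect_equal(res$method, "lda")
  expect_equal(res$roc$auc, 1)
})

test_that("the three-threshold rule labels the group-mean profiles correctly", {
  rule <- decision_rule()
  gb_prof <- data.frame(perilesional_rcbv_max = 2.63, psr_percent = 84.59,
                        lesion_adc_mean = 0.71e-3)
  bm_prof <- data.frame(perilesional_rcbv_max = 1.21, psr_percent = 71.14,
                        lesion_adc_mean = 1.13e-3)
  at_thr <- data.frame(perilesional_rcbv_max = 1.37, psr_percent = 75,
                       lesion_adc_mean = 1.0e-3)
  expect_equal(apply_decision_rule(gb_prof, rule), "GB")
  expect_equal(apply_decision_rule(bm_prof, rule), "BM")
  # strict inequalities: an exactly-at-threshold profile is not GB
  expect_equal(apply_decision_rule(at_thr, rule), "BM")
  na_prof <- gb_prof; na_prof$psr_percent <- NA
  expect_equal(apply_decision_rule(na_prof, rule), "undetermined")
  # combination modes
  mixed <- data.frame(perilesional_rcbv_max = 2.63, psr_percent = 70,
                      lesion_adc_mean = 0.71e-3)
  expect_equal(apply_decision_rule(mixed, decision_rule(combination = "all")),
               "BM")
  expect_equal(apply_decision_rule(mixed,
                                   decision_rule(combination = "majority")),
               "GB")
  expect_equal(apply_decision_rule(mixed, decision_rule(combination = "any")),
               "GB")
})

test_that("confusion metrics reproduce identities and the ROC operating point", {
  truth <- rep(c("GB", "BM"), each = 5)
  expect_equal(unlist(confusion_metrics(truth, truth)[1:3]),
               c(sensitivity = 1, specificity = 1, accuracy = 1))
  inv <- ifelse(truth == "GB", "BM", "GB")
  expect_equal(unlist(confusion_metrics(inv, truth)[1:3]),
               c(sensitivity = 0, specificity = 0, accuracy = 0))
  set.seed(14)
  sc <- rnorm(600); lb <- ifelse(rbinom(600, 1, plogis(sc)) == 1, "GB", "BM")
  roc <- roc_analysis(sc, lb)
  i <- which(roc$thresholds == roc$optimal_cutoff)
  pred <- ifelse(sc > roc$optimal_cutoff, "GB", "BM")
  cm <- confusion_metrics(pred, lb)
  expect_equal(cm$sensitivity, roc$sensitivity[i])
  expect_equal(cm$specificity, roc$specificity[i])
  # undetermined cases are excluded and counted
  pred[1:3] <- "undetermined"
  expect_equal(confusion_metrics(pred, lb)$n_undetermined, 3)
})

test_that("single-feature sensitivity/specificity match the binormal forms at the printed cutoffs", {
  spec <- default_cohort_spec()
  spec$n_gb <- spec$n_bm <- 100000L
  tab <- sample_feature_cohort(spec, seed = 3)
  gb <- tab$group == "GB"
  sens_adc <- mean(tab$lesion_adc_mean[gb] < 1.0e-3)
  expect_lt(abs(sens_adc - pnorm((1.0 - 0.71) / 0.33)), 0.01)
  spec_adc <- mean(tab$lesion_adc_mean[!gb] >= 1.0e-3)
  expect_lt(abs(spec_adc - pnorm((1.13 - 1.0) / 0.21)), 0.01)
  sens_rcbv <- mean(tab$perilesional_rcbv_max[gb] > 1.37)
  expect_lt(abs(sens_rcbv - pnorm((2.63 - 1.37) / 1.72)), 0.01)
})
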