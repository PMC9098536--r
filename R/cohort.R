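#' Feature names of a per-case biomarker record
#'
#' Column order of the per-case feature table produced by
#' [extract_case_features()] and consumed by the statistical stage. ADC
#' statistics are in mm2/s, rCBV values are dimensionless ratios against
#' contralateral normal-appearing white matter, and PSR is in percent.
#'
#' @return Character vector of feature names (excluding `diagnosis`).
#' @export
case_feature_names <- function() {
  c("lesion_adc_min", "lesion_adc_mean",
    "lesion_rcbv_mean", "lesion_rcbv_max",
    "perilesional_adc_min", "perilesional_adc_mean",
    "perilesional_rcbv_mean", "perilesional_rcbv_max",
    "edema_adc_min", "edema_adc_mean",
    "edema_rcbv_mean", "edema_rcbv_max",
    "psr_percent")
}

#' Specify a two-group Gaussian feature cohort
#'
#' Describes, per feature and per diagnosis group (GB = glioblastoma,
#' BM = brain metastasis), the Gaussian mean and standard deviation used by
#' [sample_feature_cohort()]. Features are sampled independently unless a
#' correlation matrix is supplied (Gaussian copula; the marginals are kept).
#'
#' @param features Named list; each element is a list with components `GB`
#'   and `BM`, each a numeric vector `c(mean, sd)`. Names must come from
#'   [case_feature_names()].
#' @param n_gb,n_bm Group sizes (at least 1 each).
#' @param correlation Optional feature-by-feature correlation matrix
#'   (symmetric positive definite, unit diagonal, dimnames matching
#'   `names(features)`), shared by both groups.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [default_cohort_spec()] for the study-parameterized spec.
#' @export
cohort_spec <- function(features, n_gb, n_bm, correlation = NULL) {
  if (!is.list(features) || is.null(names(features)) ||
      any(!nzchar(names(features))))
    stop("features must be a named list")
  bad <- setdiff(names(features), case_feature_names())
  if (length(bad))
    stop("unknown feature name(s): ", paste(bad, collapse = ", "))
  for (nm in names(features)) {
    f <- features[[nm]]
    for (grp in c("GB", "BM")) {
      v <- f[[grp]]
      if (is.null(v) || length(v) != 2L || !all(is.finite(v)))
        stop(sprintf("features$%s$%s must be a finite c(mean, sd)", nm, grp))
      if (v[2L] < 0)
        stop(sprintf("features$%s$%s: sd must be >= 0", nm, grp))
    }
  }
  n_gb <- as.integer(n_gb); n_bm <- as.integer(n_bm)
  if (n_gb < 1L) stop("n_gb must be >= 1")
  if (n_bm < 1L) stop("n_bm must be >= 1")
  if (!is.null(correlation)) {
    p <- length(features)
    if (!is.matrix(correlation) || any(dim(correlation) != p))
      stop("correlation must be a ", p, "x", p, " matrix")
    if (max(abs(correlation - t(correlation))) > 1e-8 ||
        max(abs(diag(correlation) - 1)) > 1e-8)
      stop("correlation must be symmetric with unit diagonal")
    if (!is.null(dimnames(correlation)) &&
        !identical(rownames(correlation), names(features)))
      stop("correlation dimnames must match feature names")
  }
  structure(list(features = features, n_gb = n_gb, n_bm = n_bm,
                 correlation = correlation),
            class = "cohort_spec")
}

#' Study-parameterized cohort specification
#'
#' Returns the Gaussian cohort spec matching the reported group statistics of
#' the 41-patient study population (20 GB, 21 BM): lesion mean ADC
#' (GB 0.71, BM 1.13, in 1e-3 mm2/s), perilesional rCBV max (GB 2.63,
#' BM 1.21) and mean (GB 1.46, BM 0.87), and PSR (GB 84.59, BM 71.14, in
#' percent).
#'
#' @return A [cohort_spec()] object.
#' @export
#' @examples
#' spec <- default_cohort_spec()
#' spec$features$perilesional_rcbv_max
default_cohort_spec <- function() {
  cohort_spec(
    features = list(
      lesion_adc_mean        = list(BM = c(1.13e-3, 0.21e-3), GB = c(0.71e-3, 0.33e-3)),
      perilesional_rcbv_max  = list(BM = c(1.21, 0.64),       GB = c(2.63, 1.72)),
      perilesional_rcbv_mean = list(BM = c(0.87, 0.22),       GB = c(1.46, 1.08)),
      psr_percent            = list(BM = c(71.14, 13.84),     GB = c(84.59, 13.30))
    ),
    n_gb = 20L, n_bm = 21L)
}

# sample one group's feature matrix; ADC columns redrawn while negative
sample_group <- function(spec, group, n) {
  feats <- spec$features
  p <- length(feats)
  mu <- vapply(feats, function(f) f[[group]][1L], numeric(1))
  sd <- vapply(feats, function(f) f[[group]][2L], numeric(1))
  if (is.null(spec$correlation)) {
    z <- matrix(stats::rnorm(n * p), n, p)
  } else {
    z <- matrix(stats::rnorm(n * p), n, p) %*% chol(spec$correlation)
  }
  x <- sweep(sweep(z, 2L, sd, `*`), 2L, mu, `+`)
  colnames(x) <- names(feats)
  adc_cols <- grep("adc", names(feats))
  for (j in adc_cols) {
    bad <- which(x[, j] < 0)
    while (length(bad)) {
      x[bad, j] <- stats::rnorm(length(bad), mu[j], sd[j])
      bad <- bad[x[bad, j] < 0]
    }
  }
  x
}

#' Sample a synthetic feature cohort
#'
#' Draws `n_gb + n_bm` cases from the per-group Gaussians of a cohort spec.
#' ADC features are truncated at zero by redrawing; other features (including
#' PSR, which may physically exceed 100%) are not truncated. Reproducible for
#' a fixed seed; the caller's RNG state is left untouched.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A data.frame with columns `case_id`, `group` (factor GB/BM) and
#'   one column per feature in the spec.
#' @export
#' @examples
#' cohort <- sample_feature_cohort(default_cohort_spec(), seed = 1)
#' aggregate(lesion_adc_mean ~ group, cohort, mean)
sample_feature_cohort <- function(spec, seed) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  with_seed(seed, {
    xg <- sample_group(spec, "GB", spec$n_gb)
    xb <- sample_group(spec, "BM", spec$n_bm)
    out <- data.frame(
      case_id = sprintf("case%04d", seq_len(spec$n_gb + spec$n_bm)),
      group = factor(rep(c("GB", "BM"), c(spec$n_gb, spec$n_bm)),
                     levels = c("GB", "BM")),
      rbind(xg, xb),
      row.names = NULL, check.names = FALSE)
    out
  })
}
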