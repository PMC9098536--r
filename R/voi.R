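# VOI construction and feature extraction: lesion (minus necrosis), the 5 mm
# perilesional edema ring, residual edema, and per-region map statistics.

#' Construct a labelled region mask
#'
#' @param voxels Logical 3D array.
#' @param spacing_mm Voxel size per axis, millimetres.
#' @param label Region label, one of `lesion`, `necrotic_core`, `edema`,
#'   `perilesional_ring`, `residual_edema`, `reference`, `arterial`.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(voxels, spacing_mm = c(1, 1, 1), label = "lesion") {
  labels <- c("lesion", "necrotic_core", "edema", "perilesional_ring",
              "residual_edema", "reference", "arterial")
  label <- match.arg(label, labels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("mask voxels must not be NA")
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 label = label),
            class = "region_mask")
}

# accept a region_mask or a bare logical array
mask_voxels <- function(mask) {
  if (inherits(mask, "region_mask")) mask$voxels
  else {
    v <- mask
    storage.mode(v) <- "logical"
    v
  }
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("region_mask '%s': %d voxels on a %s grid, spacing %s mm\n",
              x$label, sum(x$voxels),
              paste(dim(x$voxels), collapse = "x"),
              paste(x$spacing_mm, collapse = "x")))
  invisible(x)
}

# 1D squared Euclidean distance transform (lower envelope of parabolas),
# sample positions i * step; Inf-valued entries are skipped
edt_1d <- function(f, step) {
  n <- length(f)
  idx <- which(is.finite(f))
  if (!length(idx)) return(f)
  x <- seq_len(n) * step
  v <- integer(length(idx)); z <- numeric(length(idx) + 1L)
  k <- 1L; v[1L] <- idx[1L]; z[1L] <- -Inf; z[2L] <- Inf
  isect <- function(q, p)
    ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
  if (length(idx) > 1L) {
    for (q in idx[-1L]) {
      s <- isect(q, v[k])
      while (s <= z[k]) {   # z[1] = -Inf guarantees termination at k = 1
        k <- k - 1L
        s <- isect(q, v[k])
      }
      k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
    }
  }
  d <- numeric(n)
  j <- 1L
  for (q in seq_len(n)) {
    while (z[j + 1L] < x[q]) j <- j + 1L
    p <- v[j]
    d[q] <- (x[q] - x[p])^2 + f[p]
  }
  d
}

#' Euclidean distance transform in millimetres
#'
#' Exact distance from every voxel centre to the nearest `TRUE` voxel centre
#' of a mask, respecting anisotropic voxel spacing (separable
#' lower-envelope algorithm, one pass per axis).
#'
#' @param mask A [region_mask()] or logical 3D array.
#' @param spacing_mm Voxel size per axis; taken from the mask if it is a
#'   `region_mask`.
#' @return 3D numeric array of distances in mm (0 inside the mask, Inf if
#'   the mask is empty).
#' @export
distance_to_mask_mm <- function(mask, spacing_mm = NULL) {
  vox <- mask_voxels(mask)
  if (is.null(spacing_mm))
    spacing_mm <- if (inherits(mask, "region_mask")) mask$spacing_mm else c(1, 1, 1)
  d <- dim(vox)
  f <- array(Inf, d)
  f[vox] <- 0
  f <- apply(f, c(2, 3), edt_1d, step = spacing_mm[1L])
  f <- aperm(apply(f, c(1, 3), edt_1d, step = spacing_mm[2L]), c(2, 1, 3))
  f <- aperm(apply(f, c(1, 2), edt_1d, step = spacing_mm[3L]), c(2, 3, 1))
  sqrt(f)
}

#' Lesion VOI excluding necrotic degeneration
#'
#' The solid enhancing tumour: the enhancing mask minus the necrotic/cystic
#' core mask.
#'
#' @param enhancing,necrotic [region_mask()] objects on the same grid
#'   (`necrotic` may be empty).
#' @return A `region_mask` labelled `lesion`.
#' @export
lesion_voi <- function(enhancing, necrotic) {
  e <- mask_voxels(enhancing); n <- mask_voxels(necrotic)
  stopifnot(identical(dim(e), dim(n)))
  out <- e & !n
  if (!any(out)) stop("lesion fully necrotic: empty lesion VOI")
  region_mask(out, spacing_of(enhancing), "lesion")
}

spacing_of <- function(mask, default = c(1, 1, 1)) {
  if (inherits(mask, "region_mask")) mask$spacing_mm else default
}

#' Perilesional edema ring within a physical distance of the lesion
#'
#' Morphological dilation of the lesion by a physical-distance ball of
#' radius `width_mm` (anisotropic spacing respected via the exact Euclidean
#' distance transform), minus the lesion, and by default intersected with
#' the edema mask.
#'
#' @param lesion Non-empty lesion [region_mask()].
#' @param edema Edema [region_mask()] on the same grid.
#' @param width_mm Ring width in millimetres (default 5).
#' @param restrict_to_edema If `FALSE`, the ring is not intersected with the
#'   edema mask (freehand-style perilesional band).
#' @param surface_correction_mm Midpoint correction added to the distance
#'   threshold to compensate the half-voxel sampling bias of a mask
#'   boundary: voxel centres of the lesion boundary sit inside the
#'   continuum surface, so the centre-to-centre distance overestimates the
#'   distance to the lesion surface by about a quarter voxel on average.
#'   Default `min(spacing)/4`; set to 0 for plain centre-based dilation.
#' @return A `region_mask` labelled `perilesional_ring`; empty with a
#'   warning when no edema voxel falls within the band.
#' @export
perilesional_ring <- function(lesion, edema, width_mm = 5,
                              restrict_to_edema = TRUE,
                              surface_correction_mm = NULL) {
  lv <- mask_voxels(lesion); ev <- mask_voxels(edema)
  stopifnot(identical(dim(lv), dim(ev)), width_mm > 0)
  if (!any(lv)) stop("lesion mask is empty")
  sp <- spacing_of(lesion)
  if (is.null(surface_correction_mm)) surface_correction_mm <- min(sp) / 4
  dist <- distance_to_mask_mm(lv, sp)
  out <- dist > 0 & dist <= width_mm + surface_correction_mm
  if (restrict_to_edema) out <- out & ev
  if (!any(out))
    warning("perilesional ring is empty; features undefined for this region")
  region_mask(out, sp, "perilesional_ring")
}

#' Residual edema VOI
#'
#' Edema beyond the perilesional ring: the edema mask minus the lesion and
#' minus the ring. May be empty (returned with a warning).
#'
#' @param edema,lesion,ring [region_mask()] objects on the same grid.
#' @return A `region_mask` labelled `residual_edema`.
#' @export
residual_edema <- function(edema, lesion, ring) {
  ev <- mask_voxels(edema); lv <- mask_voxels(lesion); rv <- mask_voxels(ring)
  stopifnot(identical(dim(ev), dim(lv)), identical(dim(ev), dim(rv)))
  out <- ev & !lv & !rv
  if (!any(out)) warning("residual edema is empty")
  region_mask(out, spacing_of(edema), "residual_edema")
}

#' Summary statistics of a parametric map over a VOI
#'
#' Minimum, mean and maximum of the valid (non-NA) masked voxels, plus the
#' count of valid voxels.
#'
#' @param map 3D numeric array (NA = invalid voxel).
#' @param mask [region_mask()] or logical array on the same grid.
#' @return List with `min`, `mean`, `max`, `n_voxels`.
#' @export
voi_statistics <- function(map, mask) {
  vox <- mask_voxels(mask)
  stopifnot(identical(dim(vox), dim(map)))
  if (!any(vox)) stop("mask is empty")
  vals <- map[vox]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("no valid voxels under the mask")
  list(min = min(vals), mean = mean(vals), max = max(vals),
       n_voxels = length(vals))
}

region_stats_or_na <- function(map, mask, region) {
  vox <- mask_voxels(mask)
  if (!any(vox)) return(list(min = NA_real_, mean = NA_real_, max = NA_real_))
  tryCatch(voi_statistics(map, vox),
           error = function(e) stop(region, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' Extract the per-case biomarker record
#'
#' Builds the three study VOIs from the supplied masks (lesion minus
#' necrosis, perilesional ring within `ring_width_mm` of the lesion,
#' residual edema), projects them on the ADC and rCBV maps, and summarizes
#' the lesion-averaged perfusion curve for PSR. Regions that come out empty
#' (e.g. no edema) yield NA features for that region while the rest of the
#' record is still computed.
#'
#' @param adc 3D ADC map, mm2/s.
#' @param rcbv 3D rCBV map.
#' @param dsc A [dsc_series()] (for the PSR of the lesion curve).
#' @param masks List with `region_mask` elements `lesion` (enhancing),
#'   `necrotic_core` (optional) and `edema`.
#' @param ring_width_mm Perilesional band width (default 5 mm).
#' @param diagnosis Known label, `"GB"`, `"BM"` or `"unknown"`.
#' @param restrict_ring_to_edema Passed to [perilesional_ring()].
#' @return One-row data.frame with the columns of [case_feature_names()]
#'   plus `diagnosis`.
#' @export
extract_case_features <- function(adc, rcbv, dsc, masks, ring_width_mm = 5,
                                  diagnosis = "unknown",
                                  restrict_ring_to_edema = TRUE) {
  stopifnot(is.list(masks), !is.null(masks$lesion), !is.null(masks$edema))
  necro <- masks$necrotic_core
  if (is.null(necro))
    necro <- region_mask(array(FALSE, dim(mask_voxels(masks$lesion))),
                         spacing_of(masks$lesion), "necrotic_core")
  lesion <- lesion_voi(masks$lesion, necro)
  ring <- withCallingHandlers(
    perilesional_ring(lesion, masks$edema, ring_width_mm,
                      restrict_to_edema = restrict_ring_to_edema),
    warning = function(w) invokeRestart("muffleWarning"))
  resid <- withCallingHandlers(
    residual_edema(masks$edema, lesion, ring),
    warning = function(w) invokeRestart("muffleWarning"))

  la <- region_stats_or_na(adc, lesion, "lesion")
  lr <- region_stats_or_na(rcbv, lesion, "lesion")
  pa <- region_stats_or_na(adc, ring, "perilesional_ring")
  pr <- region_stats_or_na(rcbv, ring, "perilesional_ring")
  ea <- region_stats_or_na(adc, resid, "residual_edema")
  er <- region_stats_or_na(rcbv, resid, "residual_edema")
  psr <- summarize_perfusion_curve(mean_curve_over_voi(dsc, lesion),
                                   dsc$acq)$psr_percent

  data.frame(
    lesion_adc_min = la$min, lesion_adc_mean = la$mean,
    lesion_rcbv_mean = lr$mean, lesion_rcbv_max = lr$max,
    perilesional_adc_min = pa$min, perilesional_adc_mean = pa$mean,
    perilesional_rcbv_mean = pr$mean, perilesional_rcbv_max = pr$max,
    edema_adc_min = ea$min, edema_adc_mean = ea$mean,
    edema_rcbv_mean = er$mean, edema_rcbv_max = er$max,
    psr_percent = psr,
    diagnosis = diagnosis,
    stringsAsFactors = FALSE)
}
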