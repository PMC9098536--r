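# Digital DSC/DWI phantoms: concentric spherical lesion / necrotic core /
# edema geometry with known per-region perfusion and diffusion ground truth.

#' Per-region ground truth for a phantom
#'
#' @param cbf Flow scale (1/s against the phantom AIF).
#' @param mtt_seconds Mean transit time, seconds.
#' @param psr_percent Target percentage signal recovery of the region's
#'   noiseless curve (100 = full recovery; may exceed 100).
#' @param adc_mm2_per_s Apparent diffusion coefficient, mm2/s.
#' @param s0 Baseline signal.
#' @return Named list of the five truth values.
#' @export
region_truth <- function(cbf, mtt_seconds, psr_percent, adc_mm2_per_s,
                         s0 = 100) {
  vals <- c(cbf = cbf, mtt_seconds = mtt_seconds, psr_percent = psr_percent,
            adc_mm2_per_s = adc_mm2_per_s, s0 = s0)
  if (any(!is.finite(vals))) stop("truth values must be finite")
  if (cbf < 0 || mtt_seconds <= 0 || adc_mm2_per_s <= 0 || s0 <= 0)
    stop("truth values must be positive (cbf may be 0)")
  as.list(vals)
}

#' Specify a spherical digital phantom
#'
#' Concentric geometry centred in the grid: necrotic core inside the
#' enhancing lesion inside FLAIR-hyperintense edema, plus an arterial sphere
#' (carrying the AIF) and a contralateral normal-appearing white matter
#' reference sphere placed off-centre. Region truths drive the forward DSC
#' and DWI models of [build_phantom()].
#'
#' @param grid_shape Voxel counts per axis.
#' @param spacing_mm Voxel size per axis, mm.
#' @param lesion_radius_mm Radius of the enhancing lesion.
#' @param necrotic_core_radius_mm Radius of the excluded core (0 = none).
#' @param edema_radius_mm Outer radius of the edema; must exceed the lesion
#'   radius by more than 5 mm so that both a 5 mm ring and residual edema
#'   exist.
#' @param region_truth Named list of [region_truth()] entries for `lesion`,
#'   `necrotic_core`, `edema_ring`, `edema_residual`, `reference`,
#'   `background`.
#' @param noise_sd Additive Gaussian noise SD on the signal magnitude.
#' @param aif_peak Peak arterial dR2* (1/s) of the gamma-variate AIF.
#' @param seed Integer seed for the noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40L, 40L, 40L),
                         spacing_mm = c(2, 2, 2),
                         lesion_radius_mm = 10,
                         necrotic_core_radius_mm = 4,
                         edema_radius_mm = 20,
                         region_truth = default_region_truths(),
                         noise_sd = 0,
                         aif_peak = 12,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            noise_sd >= 0, aif_peak > 0)
  if (!(necrotic_core_radius_mm < lesion_radius_mm))
    stop("necrotic core radius must be < lesion radius")
  if (!(lesion_radius_mm < edema_radius_mm))
    stop("lesion radius must be < edema radius")
  if (!(edema_radius_mm - lesion_radius_mm > 5))
    stop("edema must extend > 5 mm beyond the lesion")
  need <- c("lesion", "necrotic_core", "edema_ring", "edema_residual",
            "reference", "background")
  miss <- setdiff(need, names(region_truth))
  if (length(miss))
    stop("region_truth missing: ", paste(miss, collapse = ", "))
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 lesion_radius_mm = lesion_radius_mm,
                 necrotic_core_radius_mm = necrotic_core_radius_mm,
                 edema_radius_mm = edema_radius_mm,
                 region_truth = region_truth,
                 noise_sd = noise_sd, aif_peak = aif_peak,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default (normal-tissue-like) region truths
#'
#' Reference/background emulate normal-appearing white matter with unit CBV
#' (cbf 0.25 1/s, MTT 4 s), full signal recovery and ADC 0.85e-3 mm2/s.
#' @return Named list of [region_truth()] entries.
#' @export
default_region_truths <- function() {
  nawm <- region_truth(cbf = 0.25, mtt_seconds = 4, psr_percent = 100,
                       adc_mm2_per_s = 0.85e-3)
  list(lesion = region_truth(0.50, 6, 90, 1.0e-3),
       necrotic_core = region_truth(0.02, 4, 100, 2.5e-3),
       edema_ring = region_truth(0.30, 4, 100, 1.45e-3),
       edema_residual = region_truth(0.20, 4, 100, 1.55e-3),
       reference = nawm, background = nawm)
}

# region cbf needed for a target rCBV given MTT, against the unit-CBV
# reference (cbf 0.25, mtt 4)
cbf_for_rcbv <- function(rcbv, mtt_seconds, cbv_reference = 1.0) {
  rcbv * cbv_reference / mtt_seconds
}

#' Glioblastoma-like / metastasis-like phantom specifications
#'
#' Region truths parameterized by the study's group means: GB — lesion mean
#' ADC 0.71e-3 mm2/s, lesion PSR 84.59%, perilesional-ring rCBV 2.63,
#' residual-edema rCBV 0.88; BM — 1.13e-3, 71.14%, 1.21, 0.61. Lesional
#' rCBV uses the group means of the lesional rCBV row (GB 7.60, BM 9.71).
#'
#' @param noise_sd Additive signal noise SD.
#' @param seed Integer seed.
#' @param ... Further arguments to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
gb_phantom_spec <- function(noise_sd = 0, seed = 1L, ...) {
  tr <- default_region_truths()
  tr$lesion <- region_truth(cbf_for_rcbv(7.60, 6), 6, 84.59, 0.71e-3)
  tr$edema_ring <- region_truth(cbf_for_rcbv(2.63, 4), 4, 100, 1.43e-3)
  tr$edema_residual <- region_truth(cbf_for_rcbv(0.88, 4), 4, 100, 1.52e-3)
  phantom_spec(region_truth = tr, noise_sd = noise_sd, seed = seed, ...)
}

#' @rdname gb_phantom_spec
#' @export
bm_phantom_spec <- function(noise_sd = 0, seed = 1L, ...) {
  tr <- default_region_truths()
  tr$lesion <- region_truth(cbf_for_rcbv(9.71, 6), 6, 71.14, 1.13e-3)
  tr$edema_ring <- region_truth(cbf_for_rcbv(1.21, 4), 4, 100, 1.50e-3)
  tr$edema_residual <- region_truth(cbf_for_rcbv(0.61, 4), 4, 100, 1.57e-3)
  phantom_spec(region_truth = tr, noise_sd = noise_sd, seed = seed, ...)
}

# voxel-centre coordinates (mm) relative to the grid centre, per axis
grid_coords_mm <- function(grid_shape, spacing_mm) {
  lapply(1:3, function(a)
    (seq_len(grid_shape[a]) - (grid_shape[a] + 1) / 2) * spacing_mm[a])
}

sphere_mask <- function(grid_shape, spacing_mm, centre_mm, radius_mm) {
  co <- grid_coords_mm(grid_shape, spacing_mm)
  dx2 <- outer(outer((co[[1]] - centre_mm[1])^2,
                     (co[[2]] - centre_mm[2])^2, `+`),
               (co[[3]] - centre_mm[3])^2, `+`)
  dx2 <= radius_mm^2
}

#' Build a digital phantom case
#'
#' Assembles the DSC series (voxel curves from [dsc_signal_from_truth()] per
#' region, plus seeded Gaussian noise), the per-b DWI volumes
#' (`S_b = s0 * exp(-b * ADC)` plus noise), the region masks (lesion,
#' necrotic core, edema, arterial, reference — pairwise disjoint), the AIF,
#' and ground-truth ADC/rCBV maps and per-region scalars. Region rCBV truth
#' is computed from the noiseless forward curves with the same integral
#' definition the analysis stage uses, so round-trip recovery error measures
#' the pipeline, not model mismatch.
#'
#' @param spec A [phantom_spec()].
#' @param acq An [acq_params()] object.
#' @return An object of class `phantom_case`: list with `dsc`
#'   ([dsc_series()]), `dwi` ([dwi_stack()]), `masks` (named
#'   [region_mask()] list), `aif` (arterial dR2* curve) and `truth`
#'   (maps + per-region scalars + the spec).
#' @export
build_phantom <- function(spec, acq = acq_params()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(acq, "acq_params"))
  gs <- spec$grid_shape; sp <- spec$spacing_mm
  extent <- gs * sp

  core <- sphere_mask(gs, sp, c(0, 0, 0), spec$necrotic_core_radius_mm)
  lesion_all <- sphere_mask(gs, sp, c(0, 0, 0), spec$lesion_radius_mm)
  edema_all <- sphere_mask(gs, sp, c(0, 0, 0), spec$edema_radius_mm)
  lesion <- lesion_all & !core
  edema <- edema_all & !lesion_all
  off <- extent / 2 - spec$edema_radius_mm / 2
  art_c <- c(-off[1], -off[2], 0)
  ref_c <- c(off[1], off[2], 0)
  small_r <- min(5, spec$edema_radius_mm / 3)
  arterial <- sphere_mask(gs, sp, art_c, small_r)
  reference <- sphere_mask(gs, sp, ref_c, small_r)
  if (any((arterial | reference) & edema_all))
    stop("arterial/reference regions overlap the lesion-edema complex; ",
         "enlarge the grid")

  # split edema into the 5 mm perilesional band and the residual shell,
  # with the same surface correction the VOI stage applies
  dist <- distance_to_mask_mm(lesion, sp)
  ring <- edema & dist > 0 & dist <= 5 + min(sp) / 4
  residual <- edema & !ring

  regions <- list(necrotic_core = core, lesion = lesion, edema_ring = ring,
                  edema_residual = residual, arterial = arterial,
                  reference = reference)
  regions$background <- !Reduce(`|`, regions)

  t <- acq_times(acq)
  aif <- default_aif(acq, peak = spec$aif_peak)
  nt <- acq$n_timepoints
  nvox <- prod(gs)

  # per-region noiseless curves and truth scalars
  curves <- list()
  dt <- acq$tr_seconds
  int_ca <- trapz_uniform(pmax(aif, 0), dt)
  region_scalar <- list()
  for (nm in names(regions)) {
    tru <- spec$region_truth[[nm]]
    if (nm == "arterial") {
      sig <- spec$region_truth$reference$s0 * exp(-acq$te_seconds * aif)
      cbv <- trapz_uniform(pmax(aif, 0), dt) / int_ca
      tru <- spec$region_truth$reference
    } else {
      sig <- dsc_signal_from_truth(tru$cbf, tru$mtt_seconds, tru$psr_percent,
                                   tru$s0, aif, acq)
      conc <- signal_to_delta_r2star(sig, tru$s0, acq$te_seconds)
      cbv <- trapz_uniform(pmax(conc, 0), dt) / int_ca
    }
    curves[[nm]] <- sig
    region_scalar[[nm]] <- list(cbv = cbv, adc = tru$adc_mm2_per_s,
                                psr_percent = tru$psr_percent,
                                cbf = tru$cbf, s0 = tru$s0)
  }
  cbv_ref <- region_scalar$reference$cbv
  for (nm in names(region_scalar))
    region_scalar[[nm]]$rcbv <- region_scalar[[nm]]$cbv / cbv_ref

  # assemble volumes region by region
  sig4 <- matrix(0, nvox, nt)
  adc_map <- rcbv_map <- s0_map <- numeric(nvox)
  for (nm in names(regions)) {
    idx <- which(as.vector(regions[[nm]]))
    if (!length(idx)) next
    sig4[idx, ] <- matrix(curves[[nm]], length(idx), nt, byrow = TRUE)
    adc_map[idx] <- region_scalar[[nm]]$adc
    rcbv_map[idx] <- region_scalar[[nm]]$rcbv
    s0_map[idx] <- region_scalar[[nm]]$s0
  }
  dwi_true <- lapply(acq$b_values, function(b) s0_map * exp(-b * adc_map))

  if (spec$noise_sd > 0) {
    with_seed(spec$seed, {
      sig4 <- sig4 + matrix(stats::rnorm(nvox * nt, sd = spec$noise_sd),
                            nvox, nt)
      dwi_true <- lapply(dwi_true, function(v)
        v + stats::rnorm(nvox, sd = spec$noise_sd))
    })
    sig4[sig4 < 0] <- 0
  }

  dsc <- dsc_series(array(sig4, c(gs, nt)), acq, sp)
  dwi <- dwi_stack(lapply(dwi_true, function(v) array(v, gs)),
                   acq$b_values, sp)
  masks <- list(
    lesion = region_mask(lesion, sp, "lesion"),
    necrotic_core = region_mask(core, sp, "necrotic_core"),
    edema = region_mask(edema, sp, "edema"),
    arterial = region_mask(arterial, sp, "arterial"),
    reference = region_mask(reference, sp, "reference"))

  structure(list(
    dsc = dsc, dwi = dwi, masks = masks, aif = aif,
    truth = list(adc_map = array(adc_map, gs),
                 rcbv_map = array(rcbv_map, gs),
                 regions = region_scalar,
                 ring_mask = region_mask(ring, sp, "perilesional_ring"),
                 residual_mask = region_mask(residual, sp, "residual_edema"),
                 spec = spec)),
    class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  sp <- x$truth$spec
  cat(sprintf("phantom_case: %s grid at %s mm, lesion r=%g mm (core %g), edema r=%g mm, noise sd %g\n",
              paste(sp$grid_shape, collapse = "x"),
              paste(sp$spacing_mm, collapse = "x"),
              sp$lesion_radius_mm, sp$necrotic_core_radius_mm,
              sp$edema_radius_mm, sp$noise_sd))
  invisible(x)
}
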