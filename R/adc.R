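# ADC mapping from multi-b diffusion-weighted volumes.

#' Construct a multi-b DWI stack
#'
#' @param volumes List of 3D arrays, one per b-value, sharing one grid.
#' @param b_values Diffusion weightings in s/mm2; must contain 0 and at
#'   least two distinct values, in the order of `volumes`.
#' @param spacing_mm Voxel size per axis, millimetres.
#' @return An object of class `dwi_stack`.
#' @export
dwi_stack <- function(volumes, b_values = c(0, 500, 1000),
                      spacing_mm = c(1, 1, 1)) {
  b_values <- as.numeric(b_values)
  if (length(volumes) != length(b_values))
    stop("one volume per b-value required")
  if (!0 %in% b_values || length(unique(b_values)) < 2L)
    stop("b_values must contain 0 and at least 2 distinct values")
  d <- dim(volumes[[1L]])
  if (length(d) != 3L) stop("volumes must be 3D arrays")
  for (v in volumes)
    if (!identical(dim(v), d)) stop("all volumes must share the same grid")
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  structure(list(volumes = volumes, b_values = b_values,
                 spacing_mm = as.numeric(spacing_mm)),
            class = "dwi_stack")
}

#' Fit an ADC map by log-linear least squares
#'
#' Per voxel, ordinary least squares of `ln S(b)` against `b`; the apparent
#' diffusion coefficient is minus the slope, in mm2/s. Voxels with any
#' non-positive signal are marked invalid (NA) rather than raising an error.
#' The fit is exact (to numerical precision) on noiseless mono-exponential
#' signals.
#'
#' @param stack A [dwi_stack()].
#' @return 3D ADC array in mm2/s (NA at invalid voxels), with attribute
#'   `spacing_mm`.
#' @export
#' @examples
#' vols <- lapply(c(0, 500, 1000), function(b) array(800 * exp(-b * 7e-4), c(2, 2, 2)))
#' fit_adc_map(dwi_stack(vols))[1, 1, 1] # 7e-4 mm2/s
fit_adc_map <- function(stack) {
  stopifnot(inherits(stack, "dwi_stack"))
  d <- dim(stack$volumes[[1L]])
  b <- stack$b_values
  s <- vapply(stack$volumes, as.vector, numeric(prod(d)))
  invalid <- rowSums(s <= 0) > 0
  logs <- log(pmax(s, .Machine$double.xmin))
  bc <- b - mean(b)
  slope <- (logs %*% bc) / sum(bc^2)
  adc <- -as.vector(slope)
  adc[invalid] <- NA_real_
  structure(array(adc, d), spacing_mm = stack$spacing_mm)
}
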