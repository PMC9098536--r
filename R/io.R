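# File interfaces: NIfTI volumes (RNifti), feature-table CSV with the
# presentation conventions of the study (ADC in 1e-3 mm2/s), YAML configs.

nifti_with_spacing <- function(arr, spacing_mm, tr_seconds = NULL) {
  pd <- if (is.null(tr_seconds)) spacing_mm else c(spacing_mm, tr_seconds)
  img <- RNifti::asNifti(arr)
  RNifti::`pixdim<-`(img, pd)
}

#' Write a phantom case to NIfTI files
#'
#' Writes the 4D DSC series, one 3D volume per b-value, the region masks
#' (uint8 0/1), the truth maps, and the AIF/b-values as plain-text sidecars
#' into a directory.
#'
#' @param phantom A [build_phantom()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_phantom_nifti <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- phantom$dsc$spacing_mm
  files <- character(0)
  wr <- function(arr, name, tr = NULL) {
    path <- file.path(dir, name)
    RNifti::writeNifti(nifti_with_spacing(arr, sp, tr), path)
    files <<- c(files, path)
  }
  wr(phantom$dsc$signal, "dsc.nii.gz", tr = phantom$dsc$acq$tr_seconds)
  for (i in seq_along(phantom$dwi$b_values))
    wr(phantom$dwi$volumes[[i]],
       sprintf("dwi_b%04d.nii.gz", as.integer(phantom$dwi$b_values[i])))
  for (nm in names(phantom$masks))
    wr(array(as.integer(phantom$masks[[nm]]$voxels),
             dim(phantom$masks[[nm]]$voxels)),
       sprintf("mask_%s.nii.gz", nm))
  wr(phantom$truth$adc_map, "truth_adc.nii.gz")
  wr(phantom$truth$rcbv_map, "truth_rcbv.nii.gz")
  writeLines(format(phantom$aif, digits = 10), file.path(dir, "aif.txt"))
  writeLines(format(phantom$dwi$b_values), file.path(dir, "bvalues.txt"))
  files <- c(files, file.path(dir, c("aif.txt", "bvalues.txt")))
  invisible(files)
}

#' Read a phantom directory back into analysis objects
#'
#' Counterpart of [write_phantom_nifti()]: rebuilds the [dsc_series()],
#' [dwi_stack()], masks and AIF from a phantom directory.
#'
#' @param dir Directory written by [write_phantom_nifti()].
#' @param acq An [acq_params()] matching the stored series.
#' @return List with `dsc`, `dwi`, `masks`, `aif`.
#' @export
read_phantom_nifti <- function(dir, acq = acq_params()) {
  img <- RNifti::readNifti(file.path(dir, "dsc.nii.gz"))
  sp <- RNifti::pixdim(img)[1:3]
  dsc <- dsc_series(array(as.numeric(img), dim(img)), acq, sp)
  b <- scan(file.path(dir, "bvalues.txt"), quiet = TRUE)
  vols <- lapply(b, function(bv) {
    v <- RNifti::readNifti(file.path(dir, sprintf("dwi_b%04d.nii.gz",
                                                  as.integer(bv))))
    array(as.numeric(v), dim(v))
  })
  dwi <- dwi_stack(vols, b, sp)
  mask_names <- c("lesion", "necrotic_core", "edema", "arterial", "reference")
  masks <- lapply(mask_names, function(nm) {
    v <- RNifti::readNifti(file.path(dir, sprintf("mask_%s.nii.gz", nm)))
    region_mask(array(as.numeric(v) > 0.5, dim(v)), sp, nm)
  })
  names(masks) <- mask_names
  aif <- scan(file.path(dir, "aif.txt"), quiet = TRUE)
  list(dsc = dsc, dwi = dwi, masks = masks, aif = aif)
}

#' Write a per-case feature table as CSV
#'
#' ADC columns are presented in 1e-3 mm2/s (the study's table convention);
#' all other columns are written as stored. A comment header records the
#' tool version and seed.
#'
#' @param features Data.frame of case features (internal units).
#' @param path Output CSV path.
#' @param seed Seed to record in the header (optional).
#' @return Invisibly, `path`.
#' @export
write_features_csv <- function(features, path, seed = NULL) {
  out <- features
  adc_cols <- grep("adc", names(out), value = TRUE)
  for (cl in adc_cols) out[[cl]] <- out[[cl]] * 1e3
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("gliomark"))
  writeLines(sprintf("# gliomark %s; ADC columns in 1e-3 mm2/s%s", ver,
                     if (is.null(seed)) "" else sprintf("; seed %d",
                                                        as.integer(seed))),
             con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Read a feature-table CSV
#'
#' Converts ADC columns back from the 1e-3 mm2/s presentation convention to
#' mm2/s.
#'
#' @param path CSV written by [write_features_csv()].
#' @return Data.frame in internal units.
#' @export
read_features_csv <- function(path) {
  out <- utils::read.csv(path, comment.char = "#")
  adc_cols <- grep("adc", names(out), value = TRUE)
  for (cl in adc_cols) out[[cl]] <- out[[cl]] * 1e-3
  out
}

#' Read a YAML run configuration
#'
#' Nested key/value configuration for the command-line pipeline; unknown
#' top-level keys are rejected so typos fail loudly.
#'
#' @param path YAML file.
#' @return Named list of configuration sections.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "n_per_group", "out_dir", "cohort", "phantom",
             "acquisition", "deconvolution", "rule", "noise_sd",
             "features_csv", "phantom_dir")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  cfg
}
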