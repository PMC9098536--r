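#' Acquisition parameters for the DSC / DWI protocol
#'
#' Bundles the timing and diffusion-weighting settings of the simulated (or
#' real) acquisition. Defaults follow a 1.5 T gradient-echo EPI DSC protocol
#' (TR/TE 1490/40 ms, 50 dynamic frames with 8 pre-bolus baseline frames) and
#' a three-point DWI scheme (b = 0, 500, 1000 s/mm2).
#'
#' @param te_seconds Echo time in seconds. Must be positive.
#' @param tr_seconds Repetition time (frame spacing of the dynamic series) in
#'   seconds. Must be positive.
#' @param n_timepoints Number of dynamic frames.
#' @param n_baseline Number of pre-bolus baseline frames; at least 5 and fewer
#'   than `n_timepoints`.
#' @param b_values Diffusion weightings in s/mm2; must contain 0 and at least
#'   two distinct values.
#'
#' @return An object of class `acq_params`.
#' @export
#' @examples
#' acq <- acq_params()
#' acq$tr_seconds * acq$n_timepoints # total acquisition time, seconds
acq_params <- function(te_seconds = 0.040, tr_seconds = 1.49,
                       n_timepoints = 50L, n_baseline = 8L,
                       b_values = c(0, 500, 1000)) {
  stopifnot(is.numeric(te_seconds), length(te_seconds) == 1L,
            is.numeric(tr_seconds), length(tr_seconds) == 1L)
  if (te_seconds <= 0) stop("te_seconds must be > 0")
  if (tr_seconds <= 0) stop("tr_seconds must be > 0")
  n_timepoints <- as.integer(n_timepoints)
  n_baseline <- as.integer(n_baseline)
  if (n_baseline < 5L)
    stop("n_baseline must be >= 5 (pre-bolus baseline frames)")
  if (n_baseline >= n_timepoints)
    stop("n_baseline must be < n_timepoints")
  b_values <- sort(unique(as.numeric(b_values)))
  if (!0 %in% b_values || length(b_values) < 2L)
    stop("b_values must contain 0 and at least 2 distinct values")
  structure(list(te_seconds = te_seconds, tr_seconds = tr_seconds,
                 n_timepoints = n_timepoints, n_baseline = n_baseline,
                 b_values = b_values),
            class = "acq_params")
}

#' Frame times of a dynamic acquisition
#'
#' @param acq An [acq_params()] object.
#' @return Numeric vector of frame times in seconds, starting at 0.
#' @export
acq_times <- function(acq) {
  stopifnot(inherits(acq, "acq_params"))
  (seq_len(acq$n_timepoints) - 1) * acq$tr_seconds
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("DSC/DWI acquisition: TE %.0f ms, TR %.0f ms, %d frames (%d baseline), b = %s s/mm2\n",
              x$te_seconds * 1000, x$tr_seconds * 1000, x$n_timepoints,
              x$n_baseline, paste(x$b_values, collapse = "/")))
  invisible(x)
}

# run code with a local RNG state: seeds deterministically, restores the
# caller's .Random.seed on exit
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# trapezoidal integral on a uniform grid
trapz_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * (sum(y) - (y[1L] + y[n]) / 2)
}
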