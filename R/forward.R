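# Forward DSC signal model: tissue concentration by causal convolution of the
# AIF with an exponential residue function, plus a calibrated post-bolus
# leakage ramp that sets the percentage signal recovery of the output curve.

# discrete causal convolution: ct[k] = cbf * dt * sum_{j<=k} aif[j] R[k-j+1]
convolve_residue <- function(aif, cbf, mtt_seconds, dt) {
  n <- length(aif)
  t <- (seq_len(n) - 1) * dt
  r <- exp(-t / mtt_seconds)
  # direct (non-FFT) convolution: keeps pre-bolus samples exactly zero
  ct <- vapply(seq_len(n),
               function(k) sum(aif[seq_len(k)] * r[k:1]), numeric(1))
  cbf * dt * ct
}

# smooth post-bolus offset: logistic ramp centred on the tissue bolus peak,
# re-zeroed at bolus arrival so pre-bolus frames stay exactly at baseline
leakage_ramp <- function(l_max, times, t_peak, t_arrival, tau = 2) {
  raw <- stats::plogis((times - t_peak) / tau)
  base <- stats::plogis((t_arrival - t_peak) / tau)
  out <- l_max * pmax(0, raw - base) / (1 - base)
  out[times <= t_arrival] <- 0
  out
}

#' Simulate a DSC signal curve with known perfusion ground truth
#'
#' Forward model inverted by the perfusion stage: tissue concentration is the
#' causal convolution of the arterial input function with an exponential
#' residue `R(t) = exp(-t/mtt)`, scaled by CBF; the T2*-weighted signal is
#' `S(t) = s0 * exp(-TE * (C_t(t) + L(t)))` where `L(t)` is a smooth logistic
#' post-bolus offset calibrated (by root finding) so that the noiseless
#' curve's percentage signal recovery equals `psr_percent` (within well under
#' one percentage point). The first `n_baseline` samples equal `s0` exactly.
#'
#' @param cbf Cerebral blood flow scale (>= 0; units 1/s against the AIF).
#' @param mtt_seconds Mean transit time in seconds, > 0.
#' @param psr_percent Target percentage signal recovery of the output curve;
#'   may exceed 100 (T1-dominant leakage overshoot).
#' @param s0 Baseline signal, > 0.
#' @param aif Arterial concentration curve sampled on the acquisition's frame
#'   times (dR2* units, 1/s).
#' @param acq An [acq_params()] object.
#' @param end_window Frames in the end plateau used for PSR calibration
#'   (matches [summarize_perfusion_curve()]).
#' @return Numeric signal vector of length `acq$n_timepoints`.
#' @export
#' @examples
#' acq <- acq_params()
#' s <- dsc_signal_from_truth(0.6, 4, 75, 100, default_aif(acq), acq)
#' summarize_perfusion_curve(s, acq)$psr_percent
dsc_signal_from_truth <- function(cbf, mtt_seconds, psr_percent, s0, aif, acq,
                                  end_window = 5L) {
  stopifnot(inherits(acq, "acq_params"))
  if (mtt_seconds <= 0) stop("mtt_seconds must be > 0")
  if (cbf < 0) stop("cbf must be >= 0")
  if (s0 <= 0) stop("s0 must be > 0")
  if (length(aif) != acq$n_timepoints)
    stop("aif must be sampled on the acquisition frame times")
  times <- acq_times(acq)
  if (cbf == 0 || all(aif == 0))
    return(rep(s0, acq$n_timepoints))
  ct <- convolve_residue(aif, cbf, mtt_seconds, acq$tr_seconds)
  t_peak <- times[which.max(ct)]
  t_arrival <- times[which(ct > 0)[1L]]
  signal_for <- function(l_max) {
    lt <- leakage_ramp(l_max, times, t_peak, t_arrival)
    s0 * exp(-acq$te_seconds * (ct + lt))
  }
  # PSR is strictly decreasing in the ramp height; solve for the target
  psr_of <- function(l_max)
    summarize_perfusion_curve(signal_for(l_max), acq,
                              end_window = end_window)$psr_percent
  f <- function(l_max) psr_of(l_max) - psr_percent
  if (abs(f(0)) < 1e-9) return(signal_for(0))
  root <- stats::uniroot(f, interval = c(-1, 1) * max(ct),
                         extendInt = "downX", tol = 1e-10)$root
  signal_for(root)
}
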