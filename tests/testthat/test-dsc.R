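# DSC quantification: baseline, dR2*, deconvolution, CBV/rCBV, PSR

acq <- acq_params()
aif <- default_aif(acq)
dt <- acq$tr_seconds

test_that("baseline is the per-voxel mean of the pre-bolus frames", {
  sig <- array(100, c(2, 2, 2, acq$n_timepoints))
  ser <- dsc_series(sig, acq)
  expect_true(all(estimate_baseline(ser) == 100))
  sig[1, 1, 1, 1:8] <- rep(c(98, 102), 4)
  ser <- dsc_series(sig, acq)
  expect_equal(estimate_baseline(ser)[1, 1, 1], 100)
})

test_that("dR2* conversion follows the log relation and flags bad samples", {
  expect_equal(signal_to_delta_r2star(rep(100, 5), 100, 0.04), rep(0, 5))
  expect_equal(signal_to_delta_r2star(100 * exp(-0.4), 100, 0.04), 10)
  # overshoot above baseline gives a negative value, retained
  expect_equal(signal_to_delta_r2star(200, 100, 0.04), -log(2) / 0.04)
  out <- signal_to_delta_r2star(c(100, 0, 50), 100, 0.04)
  expect_true(is.na(out[2]))
})

test_that("block-circulant SVD recovers an identity kernel and zero flow", {
  cfg <- deconv_config(sv_threshold_fraction = 0.005)
  # tissue = dt-scaled AIF convolved with a unit impulse residue
  ct <- dt * aif
  est <- deconvolve_block_circulant_svd(ct, aif, dt, cfg)$cbf_estimate
  expect_lt(abs(est - 1), 0.02)
  est0 <- deconvolve_block_circulant_svd(rep(0, length(aif)), aif, dt,
                                         cfg)$cbf_estimate
  expect_equal(est0, 0)
  expect_error(deconvolve_block_circulant_svd(ct, rep(0, length(aif)), dt),
               "aif")
})

test_that("deconvolution inverts the forward model at study timing", {
  cfg <- deconv_config(sv_threshold_fraction = 0.005)
  ct <- forward_tissue_curve(aif, cbf = 0.6, mtt = 4, dt = dt)
  est <- deconvolve_block_circulant_svd(ct, aif, dt, cfg)$cbf_estimate
  expect_lt(abs(est - 0.6) / 0.6, 0.05)
})

test_that("deconvolution and CBV are scale-equivariant in the tissue curve", {
  cfg <- deconv_config(sv_threshold_fraction = 0.005)
  ct <- forward_tissue_curve(aif, cbf = 1.1, mtt = 6, dt = dt)
  for (k in c(0.25, 3)) {
    e1 <- deconvolve_block_circulant_svd(ct, aif, dt, cfg)$cbf_estimate
    ek <- deconvolve_block_circulant_svd(k * ct, aif, dt, cfg)$cbf_estimate
    expect_equal(ek, k * e1, tolerance = 1e-6)
    expect_equal(compute_cbv(k * ct, aif, dt), k * compute_cbv(ct, aif, dt),
                 tolerance = 1e-6)
  }
})

test_that("CBV ratios are exact for proportional curves and obey the central volume theorem", {
  expect_equal(compute_cbv(aif, aif, dt), 1)
  expect_equal(compute_cbv(2 * aif, aif, dt), 2)
  # the central volume theorem is a continuum identity: verify on a finely
  # sampled forward model (the rectangle-rule convolution carries an
  # inherent +dt/(2 mtt) relative bias at coarse frame spacing)
  fine_dt <- 0.2
  tfine <- seq(0, 120, by = fine_dt)
  ca <- gamma_variate_aif(tfine, t0 = 15, amplitude = 1)
  ct <- forward_tissue_curve(ca, cbf = 0.5, mtt = 5, dt = fine_dt)
  expect_lt(abs(compute_cbv(ct, ca, fine_dt) - 0.5 * 5) / 2.5, 0.05)
})

test_that("rCBV normalization makes the reference mean exactly 1", {
  cbv <- array(runif(27, 1, 3), c(3, 3, 3))
  ref <- array(FALSE, c(3, 3, 3)); ref[1:2, 1, 1] <- TRUE
  rcbv <- normalize_rcbv(cbv, ref)
  expect_equal(mean(rcbv[ref]), 1)
  expect_equal(normalize_rcbv(array(2, c(2, 2, 2)),
                              array(TRUE, c(2, 2, 2)))[1],
               1)
  # arithmetic: voxel 5.0 against reference mean 2.0 -> 2.5
  cbv2 <- array(5, c(2, 2, 2)); cbv2[1, 1, 1] <- 2
  ref2 <- array(FALSE, c(2, 2, 2)); ref2[1, 1, 1] <- TRUE
  expect_equal(normalize_rcbv(cbv2, ref2)[2, 2, 2], 2.5)
})

test_that("PSR follows the printed formula and its degenerate identities", {
  # s0 = 100, s_min = 40, s_end = 85 -> PH 60, SR 15, PSR 75
  sig <- c(rep(100, acq$n_baseline), seq(100, 40, length.out = 10),
           seq(40, 85, length.out = 32))
  sig <- sig[seq_len(acq$n_timepoints)]
  sig[(acq$n_timepoints - 4):acq$n_timepoints] <- 85
  sm <- summarize_perfusion_curve(sig, acq)
  expect_equal(sm$s0, 100); expect_equal(sm$ph, 60); expect_equal(sm$sr, 15)
  expect_equal(sm$psr_percent, 75)
  # full recovery -> 100
  sig2 <- sig; sig2[(acq$n_timepoints - 4):acq$n_timepoints] <- 100
  expect_equal(summarize_perfusion_curve(sig2, acq)$psr_percent, 100)
  # no recovery -> 0
  sig3 <- c(rep(100, acq$n_baseline),
            rep(40, acq$n_timepoints - acq$n_baseline))
  expect_equal(summarize_perfusion_curve(sig3, acq)$psr_percent, 0)
  # flat curve: no bolus flag, PSR 100
  sm4 <- summarize_perfusion_curve(rep(100, acq$n_timepoints), acq)
  expect_true(sm4$no_bolus)
  expect_equal(sm4$psr_percent, 100)
})

test_that("PSR is invariant under affine rescaling of the signal", {
  s <- dsc_signal_from_truth(0.5, 4, 78, 100, aif, acq)
  p0 <- summarize_perfusion_curve(s, acq)$psr_percent
  for (a in c(0.2, 7)) {
    expect_equal(summarize_perfusion_curve(a * s, acq)$psr_percent, p0,
                 tolerance = 1e-9)
  }
})

test_that("VOI-mean curves are frame-wise means", {
  sig <- array(0, c(2, 1, 1, acq$n_timepoints))
  base <- seq_len(acq$n_timepoints)
  sig[1, 1, 1, ] <- base
  sig[2, 1, 1, ] <- 3 * base
  ser <- dsc_series(sig, acq)
  one <- array(c(TRUE, FALSE), c(2, 1, 1))
  expect_equal(mean_curve_over_voi(ser, one), base)
  both <- array(TRUE, c(2, 1, 1))
  expect_equal(mean_curve_over_voi(ser, both), 2 * base)
  expect_error(mean_curve_over_voi(ser, array(FALSE, c(2, 1, 1))), "empty")
})

test_that("baseline dR2* noise averages within its standard-error bound", {
  nvox <- 500; s0 <- 100; noise_sd <- 1
  set.seed(11)
  sig <- array(s0 + rnorm(nvox * acq$n_timepoints, sd = noise_sd),
               c(nvox, 1, 1, acq$n_timepoints))
  ser <- dsc_series(sig, acq)
  s0hat <- estimate_baseline(ser)
  conc <- signal_to_delta_r2star(ser$signal, s0hat, acq$te_seconds)
  bmeans <- apply(conc[, 1, 1, seq_len(acq$n_baseline)], 1, mean)
  bound <- 3 * noise_sd / (s0 * acq$te_seconds * sqrt(acq$n_baseline))
  expect_true(all(abs(bmeans) <= bound))
})
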