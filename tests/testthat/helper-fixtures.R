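# shared fixtures and independent oracles

# spherical mask built directly from voxel-centre coordinates (independent of
# the phantom's internal geometry code)
make_sphere <- function(grid, spacing = c(1, 1, 1), radius, centre = c(0, 0, 0)) {
  co <- lapply(1:3, function(a)
    (seq_len(grid[a]) - (grid[a] + 1) / 2) * spacing[a] - centre[a])
  d2 <- outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`)
  d2 <= radius^2
}

# brute-force Euclidean distance to the nearest TRUE voxel centre (oracle for
# the separable distance transform), feasible only on tiny grids
brute_force_distance <- function(mask, spacing) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  out <- array(Inf, d)
  if (nrow(idx) == 0L) return(out)
  src <- sweep(idx, 2L, spacing, `*`)
  all_idx <- as.matrix(expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3]))
  pts <- sweep(all_idx, 2L, spacing, `*`)
  for (r in seq_len(nrow(all_idx))) {
    dif <- sweep(src, 2L, pts[r, ], `-`)
    out[all_idx[r, 1], all_idx[r, 2], all_idx[r, 3]] <-
      sqrt(min(rowSums(dif^2)))
  }
  out
}

# textbook pooled two-sample t statistic (closed-form oracle)
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# forward-convolve a residue with an AIF on a uniform grid (independent of
# the package's internal convolution)
forward_tissue_curve <- function(aif, cbf, mtt, dt) {
  n <- length(aif)
  t <- (0:(n - 1)) * dt
  r <- exp(-t / mtt)
  sapply(seq_len(n), function(k) cbf * dt * sum(aif[1:k] * r[k:1]))
}

# small phantom spec for fast tests
small_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(40L, 40L, 40L), spacing_mm = c(2, 2, 2), ...)
}
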