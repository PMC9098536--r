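# VOI morphology: distance transform, lesion/ring/residual construction,
# map statistics

test_that("the separable distance transform matches brute force", {
  set.seed(2)
  for (spacing in list(c(1, 1, 1), c(1.2, 0.8, 2.5))) {
    for (rep in 1:3) {
      mask <- array(runif(9 * 8 * 7) < 0.08, c(9, 8, 7))
      if (!any(mask)) mask[5, 4, 3] <- TRUE
      got <- distance_to_mask_mm(mask, spacing)
      want <- brute_force_distance(mask, spacing)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("lesion VOI subtracts necrosis and rejects fully necrotic input", {
  sp <- c(1, 1, 1)
  enh <- region_mask(make_sphere(c(32, 32, 32), sp, 10), sp, "lesion")
  none <- region_mask(array(FALSE, c(32, 32, 32)), sp, "necrotic_core")
  expect_equal(lesion_voi(enh, none)$voxels, enh$voxels)
  core <- region_mask(make_sphere(c(32, 32, 32), sp, 4), sp, "necrotic_core")
  shell <- lesion_voi(enh, core)
  want <- 4 / 3 * pi * (10^3 - 4^3)
  expect_lt(abs(sum(shell$voxels) - want) / want, 0.05)
  expect_error(lesion_voi(core, enh), "necrotic")
})

test_that("the 5 mm ring matches the analytic shell volume", {
  sp <- c(1, 1, 1)
  lesion <- region_mask(make_sphere(c(64, 64, 64), sp, 10), sp, "lesion")
  edema <- region_mask(array(TRUE, c(64, 64, 64)), sp, "edema")
  ring <- perilesional_ring(lesion, edema, width_mm = 5)
  want <- 4 / 3 * pi * (15^3 - 10^3)
  expect_lt(abs(sum(ring$voxels) - want) / want, 0.05)
  expect_equal(sum(ring$voxels & lesion$voxels), 0L)
})

test_that("anisotropic spacing limits the ring's reach in the thick axis", {
  sp <- c(1, 1, 5)
  grid <- c(40, 40, 15)
  lesion <- region_mask(make_sphere(grid, sp, 8), sp, "lesion")
  edema <- region_mask(array(TRUE, grid), sp, "edema")
  ring <- perilesional_ring(lesion, edema, width_mm = 5)
  # with 5 mm slices a 5 mm band can span at most one slice beyond the lesion
  lz <- range(which(apply(lesion$voxels, 3, any)))
  rz <- range(which(apply(ring$voxels, 3, any)))
  expect_lte(lz[1] - rz[1], 1)
  expect_lte(rz[2] - lz[2], 1)
})

test_that("ring voxels stay within the band of the lesion surface", {
  sp <- c(2, 2, 2)
  lesion <- region_mask(make_sphere(c(24, 24, 24), sp, 9), sp, "lesion")
  edema <- region_mask(array(TRUE, c(24, 24, 24)), sp, "edema")
  ring <- perilesional_ring(lesion, edema, width_mm = 5)
  d <- distance_to_mask_mm(lesion$voxels, sp)
  # centre-to-centre distance bounds the centre-to-surface distance
  expect_lte(max(d[ring$voxels]), 5 + sqrt(sum(sp^2)) / 2)
})

test_that("residual edema completes the partition of the edema mask", {
  sp <- c(1, 1, 1)
  grid <- c(48, 48, 48)
  lesion <- region_mask(make_sphere(grid, sp, 10), sp, "lesion")
  edema_all <- make_sphere(grid, sp, 20) & !lesion$voxels
  edema <- region_mask(edema_all, sp, "edema")
  ring <- perilesional_ring(lesion, edema, 5)
  resid <- residual_edema(edema, lesion, ring)
  want <- 4 / 3 * pi * (20^3 - 15^3)
  expect_lt(abs(sum(resid$voxels) - want) / want, 0.05)
  # exact partition identities
  expect_equal(resid$voxels, edema$voxels & !ring$voxels & !lesion$voxels)
  expect_warning(
    residual_edema(region_mask(ring$voxels, sp, "edema"), lesion, ring),
    "empty")
})

test_that("lesion, ring and residual edema are pairwise disjoint for random geometries", {
  set.seed(31)
  grid <- c(36, 36, 36)
  for (i in 1:8) {
    sp <- runif(3, 0.8, 2.5)
    rl <- runif(1, 5, 12)
    re <- rl + runif(1, 6, 14)
    centre <- runif(3, -4, 4)
    lesion <- region_mask(make_sphere(grid, sp, rl, centre), sp, "lesion")
    ed <- make_sphere(grid, sp, re, centre) & !lesion$voxels
    edema <- region_mask(ed, sp, "edema")
    ring <- suppressWarnings(perilesional_ring(lesion, edema, 5))
    resid <- suppressWarnings(residual_edema(edema, lesion, ring))
    expect_equal(sum(lesion$voxels & ring$voxels), 0L)
    expect_equal(sum(lesion$voxels & resid$voxels), 0L)
    expect_equal(sum(ring$voxels & resid$voxels), 0L)
    union <- lesion$voxels | ring$voxels | resid$voxels
    expect_true(all(union <= (lesion$voxels | edema$voxels)))
  }
})

test_that("VOI statistics report order statistics over valid voxels", {
  m <- array(2.63, c(3, 3, 3))
  all_mask <- array(TRUE, c(3, 3, 3))
  st <- voi_statistics(m, all_mask)
  expect_equal(st[c("min", "mean", "max")], list(min = 2.63, mean = 2.63,
                                                 max = 2.63))
  m2 <- array(NA_real_, c(3, 1, 1)); m2[] <- c(1, 2, 3)
  st2 <- voi_statistics(m2, array(TRUE, c(3, 1, 1)))
  expect_equal(unlist(st2), c(min = 1, mean = 2, max = 3, n_voxels = 3))
  m2[2] <- NA
  st3 <- voi_statistics(m2, array(TRUE, c(3, 1, 1)))
  expect_equal(st3$n_voxels, 2)
  expect_equal(st3$mean, 2)
  expect_error(voi_statistics(array(NA_real_, c(2, 1, 1)),
                              array(TRUE, c(2, 1, 1))),
               "valid")
})
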