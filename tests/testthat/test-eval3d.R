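test_that("voxel-wise min and mean match brute-force loops", {
  set.seed(8)
  for (trial in 1:5) {
    n <- sample(2:28, 1)
    grids <- replicate(n, random_dose_grid(), simplify = FALSE)
    vmin <- voxelwise_min(grids)
    vmean <- voxelwise_mean(grids)
    dims <- dim(grids[[1]]$data)
    for (v in sample(prod(dims), 50)) {
      vals <- vapply(grids, function(g) g$data[v], 1)
      expect_identical(vmin$data[v], min(vals))
      expect_equal(vmean$data[v], mean(vals), tolerance = 1e-12)
    }
  }
  g <- random_dose_grid()
  expect_identical(voxelwise_min(list(g))$data, g$data)
  plus1 <- dose_grid(g$data + 1, g$spacing, g$origin)
  expect_identical(voxelwise_min(list(g, plus1))$data, g$data)
  expect_equal(voxelwise_mean(list(dose_grid(0 * g$data, g$spacing),
                                   dose_grid(2 * g$data, g$spacing)))$data,
               g$data, tolerance = 1e-12)
  bad <- random_dose_grid(dims = c(4, 4, 4))
  expect_error(voxelwise_min(list(g, bad)), "geometry")
})

test_that("DVH is an exact sorted sample vector", {
  d <- dose_grid(array(30, c(5, 5, 4)))
  h <- dvh(d, array(TRUE, c(5, 5, 4)))
  expect_true(all(h$samples == 30))
  expect_equal(length(h$samples), 100L)
  half <- array(c(rep(30, 50), rep(0, 50)), c(5, 5, 4))
  hh <- dvh(dose_grid(half), array(TRUE, c(5, 5, 4)))
  expect_equal(hh$samples[50], 30)
  expect_equal(hh$samples[51], 0)
  expect_error(dvh(d, array(FALSE, c(5, 5, 4))), "empty")
})

test_that("dose-at-volume follows the conservative floor convention", {
  d <- dose_grid(array(as.numeric(1:100), c(100, 1, 1)))
  h <- dvh(d, array(TRUE, c(100, 1, 1)))
  expect_equal(dose_at_volume(h, 98), 3)   # hottest 98 voxels are 3..100
  expect_equal(dose_at_volume(h, 50), 51)
  expect_lte(dose_at_volume(h, 98), dose_at_volume(h, 50))
  u <- dvh(dose_grid(array(12.5, c(3, 3, 3))), array(TRUE, c(3, 3, 3)))
  for (v in c(1, 50, 98, 100)) expect_equal(dose_at_volume(u, v), 12.5)
  expect_error(dose_at_volume(h, 0), "out of")
  expect_error(dose_at_volume(h, 101), "out of")
  # quantile against an exhaustive sort oracle on random samples
  set.seed(2)
  for (trial in 1:50) {
    n <- sample(5:400, 1)
    x <- runif(n, 0, 60)
    hr <- dvh(dose_grid(array(x, c(n, 1, 1))), array(TRUE, c(n, 1, 1)))
    v <- runif(1, 1, 100)
    k <- max(1, ceiling(n * v / 100))
    expect_identical(dose_at_volume(hr, v), sort(x, decreasing = TRUE)[k])
  }
})

test_that("volume-at-dose counts voxels exactly in % and cm^3", {
  x <- c(rep(10, 99), 1)
  h <- dvh(dose_grid(array(x, c(100, 1, 1)), spacing = c(10, 10, 10)),
           array(TRUE, c(100, 1, 1)))
  v <- volume_at_dose(h, 5)
  expect_equal(v$pct, 99)
  expect_equal(v$cm3, 99 * 1)   # 10 mm voxels = 1 cm^3 each
  expect_equal(volume_at_dose(h, 0)$pct, 100)
  set.seed(3)
  for (trial in 1:50) {
    n <- sample(10:300, 1)
    x <- runif(n, 0, 40)
    thr <- runif(1, 0, 40)
    hr <- dvh(dose_grid(array(x, c(n, 1, 1))), array(TRUE, c(n, 1, 1)))
    expect_equal(volume_at_dose(hr, thr)$pct, 100 * mean(x >= thr))
  }
  # inverse consistency with dose-at-volume
  for (trial in 1:20) {
    x <- runif(80, 0, 40)
    hr <- dvh(dose_grid(array(x, c(80, 1, 1))), array(TRUE, c(80, 1, 1)))
    v <- runif(1, 5, 100)
    expect_gte(volume_at_dose(hr, dose_at_volume(hr, v))$pct, v - 1e-9)
  }
})

test_that("coverage gate uses strict inequalities", {
  d <- array(c(rep(30, 975), rep(28.5, 25)), c(1000, 1, 1))
  v <- coverage_verdict(dose_grid(d), array(TRUE, c(1000, 1, 1)), 30)
  expect_equal(v$d98_pct_of_rx, 95)   # boundary: exactly 95 %
  expect_false(v$pass)                # "must exceed" is strict
  d2 <- array(c(rep(30, 985), rep(28.65, 15)), c(1000, 1, 1))
  v2 <- coverage_verdict(dose_grid(d2), array(TRUE, c(1000, 1, 1)), 30)
  expect_true(v2$d98_pct_of_rx > 95 && v2$v95_pct > 98)
  expect_true(v2$pass)
})

test_that("organ metrics are linear in dose and report both units", {
  ph <- fix_avg()
  d <- random_dose_grid(dims = dim(ph$density), spacing = ph$spacing)
  m1 <- ooi_metrics(d, ph$masks, 30)
  m2 <- ooi_metrics(dose_grid(2.5 * d$data, d$spacing, d$origin),
                    ph$masks, 2.5 * 30)
  for (col in c("mhd", "mld", "mbld", "mbrd", "mtd", "med")) {
    expect_equal(m2[[col]], 2.5 * m1[[col]], tolerance = 1e-12)
  }
  # V-metrics scale-invariant when the threshold scales with prescription
  expect_equal(m2$lung_v5_pct, m1$lung_v5_pct)
  expect_equal(m1$lung_v5_cm3,
               m1$lung_v5_pct / 100 * sum(ph$masks$lungs) *
                 voxel_volume_cm3(d))
})

test_that("3D evaluation: dominance of the voxel-wise minimum", {
  res <- fix_plan5()
  avg <- fix_avg()
  r3 <- run_3drem(res$plan, avg, 5, 3, avg$masks$itv)
  expect_equal(nrow(r3$per_scenario), 28L)
  h_min <- dvh(r3$vwmin, avg$masks$itv)
  for (s in seq_len(nrow(r3$per_scenario))) {
    expect_gte(r3$per_scenario$d98_pct_of_rx[s],
               100 * dose_at_volume(h_min, 98) / 30 - 1e-9)
    expect_gte(r3$per_scenario$v95_pct[s],
               volume_at_dose(h_min, 0.95 * 30)$pct - 1e-9)
  }
  # degenerate zero-uncertainty evaluation equals the nominal dose
  r0 <- run_3drem(res$plan, avg, 0, 3, avg$masks$itv)
  expect_equal(r0$vwmin$data, r0$nominal$data, tolerance = 1e-12)
})
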