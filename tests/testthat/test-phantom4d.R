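test_that("zero motion collapses all phases onto the reference", {
  ph <- fix_phantom_static()
  ref <- ph$phases[[ph$reference_phase_index + 1L]]
  for (p in ph$phases) {
    expect_identical(p$density, ref$density)
    expect_identical(p$masks$ctv, ref$masks$ctv)
    expect_true(all(p$dvf$dx == 0) && all(p$dvf$dy == 0) &&
                  all(p$dvf$dz == 0))
  }
  st <- compute_motion_stats(ph)
  expect_equal(st$mean_motion_mm, 0)
  expect_equal(st$point_max_motion_mm, 0)
  expect_identical(build_itv(ph), ref$masks$ctv)
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- generate_phantom(coarse_config(amplitude_mm = 7), seed = 5)
  b <- generate_phantom(coarse_config(amplitude_mm = 7), seed = 5)
  expect_identical(a$phases[[1]]$density, b$phases[[1]]$density)
  expect_identical(a$phases[[3]]$dvf, b$phases[[3]]$dvf)
  expect_identical(a$phases[[7]]$masks, b$phases[[7]]$masks)
})

test_that("realized point-max motion honours the configured amplitude", {
  for (amp in c(5, 10, 20)) {
    ph <- generate_phantom(coarse_config(amplitude_mm = amp), seed = 3)
    # brute force: per target voxel, max displacement magnitude over phases
    ctv <- ph$phases[[6]]$masks$ctv
    sel <- which(ctv)
    peak <- numeric(length(sel))
    for (p in ph$phases) {
      for (i in seq_along(sel)) {
        v <- sel[i]
        m <- sqrt(p$dvf$dx[v]^2 + p$dvf$dy[v]^2 + p$dvf$dz[v]^2)
        if (m > peak[i]) peak[i] <- m
      }
    }
    st <- compute_motion_stats(ph)
    expect_equal(st$point_max_motion_mm, max(peak))
    expect_equal(st$mean_motion_mm, mean(peak))
    expect_gte(st$point_max_motion_mm, 0.9 * amp)
    expect_lte(st$point_max_motion_mm, amp + 1e-9)
    expect_true(st$mean_motion_mm <= st$point_max_motion_mm)
  }
})

test_that("a rigid uniform translation gives (mean, max) = (d, d)", {
  ph <- fix_phantom_static()
  ph2 <- ph
  dims <- dim(ph$phases[[1]]$density)
  ph2$phases[[1]]$dvf <- list(dx = array(3, dims), dy = array(0, dims),
                              dz = array(4, dims))
  st <- compute_motion_stats(ph2)
  expect_equal(st$mean_motion_mm, 5)
  expect_equal(st$point_max_motion_mm, 5)
})

test_that("ITV is the envelope of the per-phase target", {
  ph <- fix_phantom()
  itv <- build_itv(ph)
  ref_ctv <- ph$phases[[6]]$masks$ctv
  expect_true(all(itv[ref_ctv]))      # superset of the reference CTV
  for (p in ph$phases) expect_true(all(itv[p$masks$ctv]))
  # voxel-aligned translation: union equals the CTV dilated along the axis
  ph2 <- fix_phantom_static()
  dims <- dim(ref_ctv)
  shift_k <- function(m, k) {
    out <- array(FALSE, dim(m))
    if (k >= 0) out[, , (1 + k):dims[3]] <- m[, , 1:(dims[3] - k)]
    else out[, , 1:(dims[3] + k)] <- m[, , (1 - k):dims[3]]
    out
  }
  base <- ph2$phases[[6]]$masks$ctv
  for (p in 1:10) {
    k <- c(0, 1, 2, 1, 0, 0, -1, -2, -1, 0)[p]
    ph2$phases[[p]]$masks$ctv <- shift_k(base, k)
  }
  expect_identical(build_itv(ph2),
                   base | shift_k(base, 1) | shift_k(base, 2) |
                     shift_k(base, -1) | shift_k(base, -2))
})

test_that("phase CTVs mapped through their fields stay inside the ITV", {
  ph <- fix_phantom()
  itv <- build_itv(ph)
  dims <- dim(itv)
  for (p in ph$phases) {
    warped <- cpp_pullback(p$masks$ctv + 0, dims, p$spacing,
                           p$dvf$dx, p$dvf$dy, p$dvf$dz) >= 0.5
    expect_true(all(itv[array(warped, dims)]))
  }
})

test_that("displacement fields are invertible to within 0.1 voxel", {
  ph <- fix_phantom()
  cfg <- ph$config
  coords <- protonrem:::grid_coords(cfg$grid_dim, cfg$spacing,
                                    -(cfg$grid_dim - 1) / 2 * cfg$spacing)
  pf <- (1 - cos(2 * pi * (0 - cfg$reference_phase) / 10)) / 2
  dfun <- function(x) protonrem:::breathing_disp(cfg, x, pf, ph$amp_norm)
  fwd <- coords + dfun(coords)
  back <- protonrem:::invert_forward(dfun, fwd)
  err <- sqrt(rowSums((back - coords)^2))
  expect_lt(max(err) / min(cfg$spacing), 0.1)
})

test_that("average CT equals the per-voxel mean of warped phases", {
  ph <- fix_phantom()
  avg <- make_average_ct(ph)
  dims <- dim(avg$density)
  acc <- array(0, dims)
  for (p in ph$phases) {
    w <- cpp_pullback(p$density, dims, p$spacing, p$dvf$dx, p$dvf$dy,
                      p$dvf$dz)
    acc <- acc + array(w, dims)
  }
  expect_equal(avg$density, acc / 10, tolerance = 1e-12)
  # identical phases: average equals any phase
  ph0 <- fix_phantom_static()
  avg0 <- make_average_ct(ph0)
  expect_equal(avg0$density, ph0$phases[[1]]$density, tolerance = 1e-12)
  expect_true("itv" %in% names(avg$masks))
})

test_that("weekly snapshots are bounded, seeded, and collapse at zero", {
  ph0 <- generate_phantom(coarse_config(weekly_mm = 0), seed = 2)
  wk <- sample_weekly_anatomy(ph0, 3, seed = 9)
  expect_equal(wk$phases[[6]]$density, ph0$phases[[6]]$density,
               tolerance = 1e-12)
  expect_true(all(wk$phases[[6]]$dvf$dx == 0))
  ph <- fix_phantom()
  a <- sample_weekly_anatomy(ph, 2, seed = 7)
  b <- sample_weekly_anatomy(ph, 2, seed = 7)
  expect_identical(a$phases[[4]]$density, b$phases[[4]]$density)
  # at the reference phase the only displacement is the weekly drift,
  # bounded by the configured magnitude
  d <- a$phases[[a$reference_phase_index + 1L]]$dvf
  mag <- sqrt(d$dx^2 + d$dy^2 + d$dz^2)
  expect_lte(max(mag), ph$config$weekly_mm + 1e-9)
})

test_that("invalid configuration and domain errors are raised", {
  expect_error(phantom_config(grid_dim = c(0, 24, 24)), "positive")
  expect_error(phantom_config(spacing = c(-3, 3, 3)), "positive")
  expect_error(phantom_config(n_phases = 8), "10-phase")
  expect_error(sample_weekly_anatomy(fix_phantom(), 9), "week")
  ph <- fix_phantom()
  ph$phases <- ph$phases[1]
  expect_error(compute_motion_stats(ph), "phases")
})
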