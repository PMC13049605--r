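test_that("depth-dose surrogate has the contracted shape", {
  R <- 80
  grid <- seq(0, 2 * R + 20, by = 0.05)
  d <- depth_dose(grid, R)
  expect_true(all(d >= 0))
  # vanishes beyond range + falloff width
  expect_equal(depth_dose(2 * R + 9, R), 0)
  expect_true(all(d[grid > R + 9] == 0))
  # unique maximum within one falloff width of the range
  peak_at <- grid[which.max(d)]
  expect_lt(abs(peak_at - R), 9)
  # monotone non-increasing beyond the peak
  post <- d[grid >= peak_at]
  expect_true(all(diff(post) <= 1e-12))
  expect_error(depth_dose(-1, R), "negative")
  expect_error(depth_dose(10, 0), "positive")
})

test_that("plan dose is linear in spot weights and zero for a null plan", {
  ana <- uniform_anatomy()
  spots <- data.frame(u = c(-9, 0, 9), v = c(0, 0, 9),
                      range = c(40, 50, 50), weight = c(1, 2, 0.5),
                      sigma = 9)
  pl <- simple_plan(spots)
  d1 <- compute_plan_dose(pl, ana)
  d2 <- compute_plan_dose(protonrem:::scale_plan_weights(pl, 2), ana)
  expect_equal(d2$data, 2 * d1$data, tolerance = 1e-12)
  pl0 <- protonrem:::set_plan_weights(pl, c(0, 0, 0))
  expect_true(all(compute_plan_dose(pl0, ana)$data == 0))
  expect_error(beam(0, transform(spots, weight = c(-1, 1, 1))),
               "non-negative")
})

test_that("setup shifts translate the dose on a uniform medium", {
  ana <- uniform_anatomy(c(26, 26, 26), c(3, 3, 3))
  spots <- data.frame(u = c(0, 6), v = c(0, -3), range = c(30, 36),
                      weight = c(1, 0.7), sigma = 6)
  pl <- simple_plan(spots)  # beam along +y; x and z are lateral axes
  nom <- compute_plan_dose(pl, ana)$data
  for (ax in c(1, 3)) {
    k <- 2
    s <- c(0, 0, 0)
    s[ax] <- k * 3
    shifted <- compute_plan_dose(pl, ana, scenario_spec(s))$data
    # dose_s(x) = dose_nom(x + s): compare on the interior
    idx <- 1:(26 - k)
    if (ax == 1) {
      expect_lt(max(abs(shifted[idx, , ] - nom[idx + k, , ])), 1e-9)
    } else {
      expect_lt(max(abs(shifted[, , idx] - nom[, , idx + k])), 1e-9)
    }
  }
})

test_that("influence matrix reproduces the dose engine", {
  ana <- fix_avg()
  spots <- data.frame(u = seq(-9, 9, by = 9), v = 0, range = 60,
                      weight = 1, sigma = 9)
  pl <- simple_plan(spots, gantry_angle = 30)
  sc <- scenario_spec(c(2, -3, 1), 1.03)
  dims <- dim(ana$density)
  A <- dose_influence_matrix(pl, ana, sc, voxel_idx = seq_len(prod(dims)),
                             sparse = FALSE)
  set.seed(1)
  for (trial in 1:3) {
    w <- runif(nrow(spots))
    d <- compute_plan_dose(protonrem:::set_plan_weights(pl, w), ana, sc)
    expect_lt(max(abs(as.numeric(A %*% w) - as.numeric(d$data))), 1e-9)
  }
  # single spot, unit weight: column equals that spot's dose grid
  one <- protonrem:::set_plan_weights(pl, c(1, 0, 0))
  expect_lt(max(abs(A[, 1] - as.numeric(compute_plan_dose(one, ana,
                                                          sc)$data))),
            1e-12)
  # sparse full-grid variant agrees
  As <- dose_influence_matrix(pl, ana, sc)
  expect_s4_class(As, "dgCMatrix")
  expect_lt(max(abs(as.numeric(As[, 2]) - A[, 2])), 1e-12)
})

test_that("peak depth moves distally as the density scale decreases", {
  ana <- uniform_anatomy(c(20, 40, 20), c(3, 3, 3))
  spots <- data.frame(u = 0, v = 0, range = 60, weight = 1, sigma = 9)
  pl <- simple_plan(spots)
  peak_j <- sapply(c(0.97, 1.00, 1.03), function(ds) {
    d <- compute_plan_dose(pl, ana, scenario_spec(c(0, 0, 0), ds))$data
    which.max(d[10, , 10])
  })
  expect_true(all(diff(peak_j) <= 0))
})

test_that("static dose is invariant to the repaint factor", {
  ana <- uniform_anatomy()
  spots <- data.frame(u = 0, v = 0, range = 40, weight = 1, sigma = 9)
  d1 <- compute_plan_dose(simple_plan(spots, repaint_factor = 1), ana)
  d5 <- compute_plan_dose(simple_plan(spots, repaint_factor = 5), ana)
  expect_identical(d1$data, d5$data)
})

test_that("layer-lattice and per-spot deposition agree", {
  ana <- fix_avg()
  us <- seq(-18, 18, by = 9)
  grid <- expand.grid(u = us, v = us)
  set.seed(4)
  spots <- data.frame(u = grid$u, v = grid$v,
                      range = sample(c(40, 47, 54), nrow(grid), TRUE),
                      weight = runif(nrow(grid)), sigma = 9)
  pl <- simple_plan(spots, gantry_angle = -30)
  sc <- scenario_spec(c(1, 2, -2), 0.97)
  d_layer <- compute_plan_dose(pl, ana, sc)
  # per-spot path: perturb one sigma so the lattice fast path is skipped
  spots2 <- spots
  spots2$sigma[1] <- spots2$sigma[1] + 1e-12
  d_spot <- compute_plan_dose(simple_plan(spots2, gantry_angle = -30),
                              ana, sc)
  expect_lt(max(abs(d_layer$data - d_spot$data)), 1e-7)
})
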