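test_that("delivery timeline counts, ordering, and duration", {
  spots <- data.frame(u = seq(0, 45, by = 5), v = 0, range = 50,
                      weight = 1, sigma = 9)
  pl <- simple_plan(spots, repaint_factor = 5)
  tl <- simulate_timeline(pl, spot_duration_s = 0.005, layer_switch_s = 1)
  expect_equal(nrow(tl), 10 * 5)     # 1 layer, 10 spots, 5 repaints
  expect_true(all(diff(tl$t) > 0))
  expect_equal(max(tl$t), 50 * 0.005 + 4 * 1)  # switches between passes
  expect_equal(as.integer(table(tl$repaint)), rep(10L, 5))
  expect_error(simulate_timeline(pl, spot_duration_s = 0), "positive")
})

test_that("phase assignment follows the breathing cycle", {
  tl <- data.frame(t = c(0, 2.25, 4.5, 4.95))
  expect_equal(assign_phases(tl, 4.5, 0), c(0L, 5L, 0L, 1L))
  expect_equal(assign_phases(data.frame(t = 0), 4.5, 0.35), 3L)
  # long uniform timeline covers all phases near-uniformly
  tl2 <- data.frame(t = seq(0, 450, by = 0.037))
  h <- table(assign_phases(tl2, 4.5, runif(1)))
  expect_length(h, 10L)
  chi2 <- sum((h - mean(h))^2 / mean(h))
  expect_lt(chi2, 30)
  expect_error(assign_phases(tl, 0), "positive")
})

test_that("dose warping: identity, exact shifts, convex bounds", {
  d <- random_dose_grid(dims = c(10, 9, 8))
  dims <- dim(d$data)
  zero <- list(dx = array(0, dims), dy = array(0, dims),
               dz = array(0, dims))
  expect_equal(warp_dose(d, zero)$data, d$data, tolerance = 1e-15)
  # uniform one-voxel translation along x: exact grid shift
  tr <- list(dx = array(d$spacing[1], dims), dy = array(0, dims),
             dz = array(0, dims))
  w <- warp_dose(d, tr)$data
  expect_equal(w[1:(dims[1] - 1), , ], d$data[2:dims[1], , ],
               tolerance = 1e-12)
  # interpolation convexity
  rnd <- list(dx = array(runif(prod(dims), -4, 4), dims),
              dy = array(runif(prod(dims), -4, 4), dims),
              dz = array(runif(prod(dims), -4, 4), dims))
  w2 <- warp_dose(d, rnd)$data
  expect_gte(min(w2), 0)
  expect_lte(max(w2), max(d$data) + 1e-12)
})

test_that("accumulation is an equal-weight mean scaled to the course", {
  set.seed(5)
  fx <- replicate(8, random_dose_grid(), simplify = FALSE)
  acc <- accumulate_fractions(fx, 15)
  naive <- Reduce(`+`, lapply(fx, `[[`, "data")) / 8 * 15
  expect_equal(acc$data, naive, tolerance = 1e-12)
  perm <- accumulate_fractions(fx[sample(8)], 15)
  expect_equal(perm$data, acc$data, tolerance = 1e-12)
  same <- accumulate_fractions(replicate(8, fx[[1]], simplify = FALSE), 11)
  expect_equal(same$data, 11 * fx[[1]]$data, tolerance = 1e-12)
})

test_that("fraction delivery reduces to the static dose without motion", {
  ph0 <- generate_phantom(coarse_config(amplitude_mm = 0, weekly_mm = 0),
                          seed = 4)
  avg <- make_average_ct(ph0)
  itv <- avg$masks$itv
  tpl <- make_plan_template(avg, itv, su_mm = 5, prescription_dose = 30,
                            n_fractions = 15L)
  pl <- protonrem:::set_plan_weights(
    tpl, runif(protonrem:::n_spots(tpl), 0.5, 1.5))
  static <- compute_plan_dose(pl, ph0$phases[[6]])
  tl <- simulate_timeline(pl)
  attr(tl, "period_s") <- 4.5
  week <- sample_weekly_anatomy(ph0, 1, seed = 4)
  fd <- deliver_fraction(pl, week, scenario_spec(), tl, 0.37)
  rel <- max(abs(fd$data - static$data / 15)) / max(static$data / 15)
  expect_lt(rel, 1e-6)
  # linearity of delivery in the spot weights
  fd2 <- deliver_fraction(protonrem:::scale_plan_weights(pl, 2), week,
                          scenario_spec(), tl, 0.37)
  expect_equal(fd2$data, 2 * fd$data, tolerance = 1e-9)
})

test_that("full 4D evaluation is deterministic and statically consistent", {
  ph0 <- generate_phantom(coarse_config(amplitude_mm = 0, weekly_mm = 0),
                          seed = 6)
  avg <- make_average_ct(ph0)
  itv <- avg$masks$itv
  tpl <- make_plan_template(avg, itv, su_mm = 5, prescription_dose = 30,
                            n_fractions = 15L)
  obj <- objective_spec(itv, 30, list())
  res <- robust_optimize(tpl, avg, obj, optimization_scenarios(5, 3),
                         opts = list(max_iter = 40, target_cap = 400))
  em0 <- fraction_error_model(0, range_levels_pct = 0)
  r4 <- run_4drem(res$plan, ph0, em0, seed = 2, n_fractions = 2,
                  n_scenarios = 3)
  static <- compute_plan_dose(res$plan, ph0$phases[[6]])
  rel <- max(abs(r4$vwmean$data - static$data)) / max(static$data)
  expect_lt(rel, 1e-6)
  expect_equal(r4$vwmin$data, r4$vwmean$data, tolerance = 1e-9)
  r4b <- run_4drem(res$plan, ph0, em0, seed = 2, n_fractions = 2,
                   n_scenarios = 3)
  expect_identical(r4$vwmean$data, r4b$vwmean$data)
  # voxel-wise min never exceeds the mean
  ph <- fix_phantom()
  res5 <- fix_plan5()
  r4m <- run_4drem(res5$plan, ph, fraction_error_model(), seed = 3,
                   n_fractions = 2, n_scenarios = 3)
  expect_true(all(r4m$vwmin$data <= r4m$vwmean$data + 1e-12))
})
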