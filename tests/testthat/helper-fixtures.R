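# Shared fixtures, built once per test run.  Unit tests use a coarse 24^3
# grid at 6 mm spacing (the full thorax geometry, coarser lattice) so the
# mechanics under test run in seconds; the acceptance suite uses the study
# resolution.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

coarse_config <- function(...) {
  phantom_config(grid_dim = c(24, 24, 24), spacing = c(6, 6, 6), ...)
}

fix_phantom <- function() {
  fixture("phantom", function() generate_phantom(coarse_config(), seed = 11))
}

fix_phantom_static <- function() {
  fixture("phantom0", function() {
    generate_phantom(coarse_config(amplitude_mm = 0), seed = 11)
  })
}

fix_avg <- function() {
  fixture("avg", function() make_average_ct(fix_phantom()))
}

# A small optimized plan on the coarse phantom (5 mm setup uncertainty).
fix_plan5 <- function() {
  fixture("plan5", function() {
    avg <- fix_avg()
    itv <- avg$masks$itv
    tpl <- make_plan_template(avg, itv, su_mm = 5, sigma_lateral = 9,
                              layer_spacing = 7, prescription_dose = 30,
                              n_fractions = 15L)
    obj <- objective_spec(itv, 30, list(heart = avg$masks$heart,
                                        lungs = avg$masks$lungs))
    robust_optimize(tpl, avg, obj, optimization_scenarios(5, 3),
                    opts = list(max_iter = 80, target_cap = 600,
                                ooi_cap = 200))
  })
}

# Uniform-medium anatomy (density 1 everywhere) for engine oracles.
uniform_anatomy <- function(dims = c(24, 24, 24), spacing = c(6, 6, 6),
                            density = 1) {
  structure(list(
    density = array(density, dims), masks = list(),
    dvf = list(dx = array(0, dims), dy = array(0, dims),
               dz = array(0, dims)),
    spacing = spacing, origin = -(dims - 1) / 2 * spacing
  ), class = "anatomy_phase")
}

simple_plan <- function(spots, gantry_angle = 0, prescription = 30,
                        n_fractions = 15L, repaint_factor = 5L, ...) {
  proton_plan(list(beam(gantry_angle, spots, repaint_factor)),
              prescription, n_fractions, ...)
}

random_dose_grid <- function(dims = c(8, 7, 6), spacing = c(3, 3, 3)) {
  dose_grid(array(runif(prod(dims), 0, 40), dims), spacing)
}

# Brute-force two-sided exact signed-rank p-value by enumerating all 2^n
# sign assignments (average ranks for ties, zeros dropped).
wilcoxon_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  vs <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  lo <- mean(vs <= v + 1e-9)
  hi <- mean(vs >= v - 1e-9)
  min(1, 2 * min(lo, hi))
}
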