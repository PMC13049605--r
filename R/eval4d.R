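#' Simulated spot delivery timeline
#'
#' Stand-in for machine log files: spots are scheduled sequentially with a
#' fixed per-spot duration; each energy layer is delivered
#' `repaint_factor` times as full passes (repainting), with a layer-switch
#' pause between passes/layers and between beams.  Only the timing relative
#' to the breathing cycle matters downstream.
#'
#' @param plan a [proton_plan()].
#' @param spot_duration_s seconds per spot (default 0.005).
#' @param layer_switch_s seconds per layer switch / repaint pass change
#'   (default 1).
#' @return data.frame (`delivery_timeline`): `beam`, `layer`, `repaint`,
#'   `spot` (row index within the beam's spot table), `t` (s, strictly
#'   increasing).
#' @export
simulate_timeline <- function(plan, spot_duration_s = 0.005,
                              layer_switch_s = 1) {
  if (spot_duration_s <= 0 || layer_switch_s <= 0) {
    stop("durations must be positive")
  }
  if (!length(plan$beams)) stop("plan has no beams")
  rows <- list()
  t <- 0
  for (bi in seq_along(plan$beams)) {
    b <- plan$beams[[bi]]
    layers <- sort(unique(b$spots$range))
    for (L in layers) {
      spot_rows <- which(b$spots$range == L)
      for (rp in seq_len(b$repaint_factor)) {
        tt <- t + seq_along(spot_rows) * spot_duration_s
        rows[[length(rows) + 1L]] <- data.frame(
          beam = bi, layer = match(L, layers), repaint = rp,
          spot = spot_rows, t = tt)
        t <- tt[length(tt)] + layer_switch_s
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("delivery_timeline", "data.frame")
  out
}

#' Breathing phase of each delivery event
#'
#' @param timeline a [simulate_timeline()] result (or any data.frame with a
#'   time column `t` in seconds).
#' @param period_s breathing period in seconds (default 4.5).
#' @param start_phase_offset starting point in the cycle as a fraction of
#'   the period.
#' @return integer vector of phase indices 0..9:
#'   `floor(((t / period + offset) mod 1) * 10)`.
#' @export
assign_phases <- function(timeline, period_s = 4.5, start_phase_offset = 0) {
  if (period_s <= 0) stop("breathing period must be positive")
  frac <- (timeline$t / period_s + start_phase_offset) %% 1
  pmin(9L, as.integer(floor(frac * 10)))
}

#' Warp a dose grid to the reference phase
#'
#' Trilinear pull-back of a phase dose through a displacement field given on
#' the reference grid (mm): `out(x) = dose(x + dvf(x))`.  With the identity
#' field the dose is returned unchanged; interpolation is convex, so the
#' warped dose stays within the input's range.
#'
#' @param dose a [dose_grid()].
#' @param dvf list with `dx`, `dy`, `dz` arrays (mm) on the same grid.
#' @return A [dose_grid()].
#' @export
warp_dose <- function(dose, dvf) {
  dims <- dim(dose$data)
  out <- cpp_pullback(dose$data, dims, dose$spacing,
                      dvf$dx, dvf$dy, dvf$dz)
  dim(out) <- dims
  dose_grid(out, dose$spacing, dose$origin)
}

# Per-beam delivery index: the full lateral spot lattice and each spot's
# (layer, lattice) position, so a whole energy layer can be deposited in
# one kernel call.  Falls back to per-spot deposition if a beam's spots are
# not on a uniform lattice.
plan_delivery_index <- function(plan) {
  lapply(plan$beams, function(b) {
    us <- sort(unique(b$spots$u))
    vs <- sort(unique(b$spots$v))
    uniform <- function(x) {
      length(x) < 3 || max(abs(diff(diff(x)))) < 1e-9 * max(abs(x), 1)
    }
    if (!uniform(us) || !uniform(vs)) return(NULL)
    layers <- sort(unique(b$spots$range))
    list(us = us, vs = vs, layers = layers,
         layer_of = match(b$spots$range, layers),
         iu = match(b$spots$u, us), iv = match(b$spots$v, vs),
         sigma = b$spots$sigma[1],
         same_sigma = length(unique(b$spots$sigma)) == 1)
  })
}

#' Deliver one fraction with breathing interplay
#'
#' Each spot's dose is computed on the breathing phase of the weekly anatomy
#' active at its delivery time, under the fraction's setup/range scenario,
#' then warped to the planning reference phase through the ground-truth
#' fields and summed.  Without motion and errors this reduces exactly to the
#' static plan dose divided by the number of fractions.
#'
#' @param plan a [proton_plan()] (weights represent the full course).
#' @param phantom_week a `phantom4d` snapshot for this fraction's week.
#' @param scenario a [scenario_spec()] with the fraction's total setup shift
#'   and systematic range scale.
#' @param timeline a [simulate_timeline()] result.
#' @param start_phase_offset breathing start point (fraction of a cycle).
#' @param wepl_cache optional environment reused across scenarios/fractions.
#' @param delivery_index internal per-beam lattice index from
#'   `plan_delivery_index`; recomputed if NULL.
#' @return A [dose_grid()] on the planning reference frame (one fraction).
#' @export
deliver_fraction <- function(plan, phantom_week, scenario, timeline,
                             start_phase_offset = 0, wepl_cache = NULL,
                             delivery_index = NULL) {
  phase_of <- assign_phases(timeline, attr(timeline, "period_s") %||% 4.5,
                            start_phase_offset)
  dims <- dim(phantom_week$phases[[1]]$density)
  sp <- phantom_week$phases[[1]]$spacing
  org <- phantom_week$phases[[1]]$origin
  iso <- -scenario$isocenter_shift
  week_tag <- phantom_week$week %||% 0L
  if (is.null(delivery_index)) delivery_index <- plan_delivery_index(plan)
  acc <- numeric(prod(dims))
  for (p in sort(unique(phase_of))) {
    ph <- phantom_week$phases[[p + 1L]]
    phase_dose <- numeric(prod(dims))
    any_spots <- FALSE
    for (bi in seq_along(plan$beams)) {
      b <- plan$beams[[bi]]
      ev <- which(phase_of == p & timeline$beam == bi)
      if (!length(ev)) next
      any_spots <- TRUE
      w <- wepl_for_beam(ph, b$gantry_angle, wepl_cache,
                         key = sprintf("w%d_p%d_b%g", week_tag, p,
                                       b$gantry_angle))
      # merge repaint passes of the same spot landing in the same phase
      cnt <- rowsum(rep(1, length(ev)), timeline$spot[ev])
      ids <- as.integer(rownames(cnt))
      wts <- b$spots$weight[ids] * as.numeric(cnt) / b$repaint_factor
      di <- delivery_index[[bi]]
      th <- b$gantry_angle * pi / 180
      if (!is.null(di) && di$same_sigma) {
        for (L in unique(di$layer_of[ids])) {
          in_layer <- di$layer_of[ids] == L
          Wm <- matrix(0, length(di$us), length(di$vs))
          Wm[cbind(di$iu[ids[in_layer]], di$iv[ids[in_layer]])] <-
            wts[in_layer]
          cpp_add_layer_dose(phase_dose, w, dims, sp, org, th, iso,
                             di$us, di$vs, Wm, di$layers[L], di$sigma,
                             scenario$density_scale, plan$bragg_pars,
                             plan$bragg_pars[4])
        }
      } else {
        sm <- spot_matrix(b$spots[ids, , drop = FALSE])
        sm[, "weight"] <- wts
        cpp_add_spot_dose(phase_dose, w, dims, sp, org, th, iso, sm,
                          scenario$density_scale, plan$bragg_pars,
                          plan$bragg_pars[4])
      }
    }
    if (!any_spots) next
    pd <- dose_grid(array(phase_dose, dims), sp, org)
    acc <- acc + warp_dose(pd, ph$dvf)$data
  }
  dose_grid(array(acc * plan$rbe_factor / plan$n_fractions, dims), sp, org)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accumulate fraction doses into a course dose
#'
#' Equal-weight mean over the simulated fractions, scaled to the clinical
#' course total: `mean(fractions) * n_fractions_clinical`.  Simulating 8
#' fractions of an 11- or 15-fraction course and scaling up matches the
#' equal-weighting accumulation of the evaluation method.
#'
#' @param fraction_doses list of per-fraction [dose_grid()]s (one scenario).
#' @param n_fractions_clinical fractions in the clinical course.
#' @return total-course [dose_grid()].
#' @export
accumulate_fractions <- function(fraction_doses, n_fractions_clinical) {
  stopifnot(length(fraction_doses) >= 1)
  assert_same_geometry(fraction_doses)
  m <- voxelwise_mean(fraction_doses)
  dose_grid(m$data * n_fractions_clinical, m$spacing, m$origin)
}

#' 4D robustness evaluation (8 fractions x 14 scenarios)
#'
#' Full longitudinal evaluation: for each of `n_scenarios` error scenarios
#' (systematic + random setup, systematic range) and `n_fractions` simulated
#' fractions, delivery is simulated with breathing interplay on that week's
#' anatomy (fraction f uses weekly variant f), each fraction dose is warped
#' to the planning end-of-exhale reference and accumulated with equal
#' weights to the clinical course total; voxel-wise mean and minimum over
#' the scenario course doses are returned.  The coverage gate is evaluated
#' on the reference-phase CTV of the voxel-wise minimum, and
#' organ-of-interest metrics on the voxel-wise mean.
#'
#' @param plan a [proton_plan()].
#' @param phantom the planning `phantom4d`.
#' @param error_model a [fraction_error_model()].
#' @param seed integer seed driving error sampling and breathing start
#'   phases.
#' @param n_fractions,n_scenarios defaults 8 and 14.
#' @param spot_duration_s,layer_switch_s,period_s delivery timing model.
#' @param weekly optional pre-built list of weekly `phantom4d` snapshots
#'   (from [sample_weekly_anatomy()]); built on the fly if NULL.
#' @param wepl_cache optional environment shared across calls on the same
#'   phantom to reuse per-phase path-length grids.
#' @return list with `vwmean`, `vwmin` ([dose_grid()]s), `verdict` (CTV
#'   coverage of the voxel-wise minimum), `ooi` (metrics on the voxel-wise
#'   mean), `errors` (the sampled error table) and `per_scenario` coverage.
#' @export
run_4drem <- function(plan, phantom, error_model = fraction_error_model(),
                      seed = 1L, n_fractions = 8L, n_scenarios = 14L,
                      spot_duration_s = 0.005, layer_switch_s = 1,
                      period_s = 4.5, weekly = NULL, wepl_cache = NULL) {
  err <- sample_fraction_errors(error_model, n_fractions, n_scenarios, seed)
  set.seed(.lcg_seed(seed, 4242L))
  offsets <- matrix(runif(n_scenarios * n_fractions), n_scenarios,
                    n_fractions)
  timeline <- simulate_timeline(plan, spot_duration_s, layer_switch_s)
  attr(timeline, "period_s") <- period_s
  weeks <- if (is.null(weekly)) {
    lapply(seq_len(n_fractions), function(f) {
      sample_weekly_anatomy(phantom, ((f - 1L) %% 8L) + 1L,
                            seed = phantom$rng_seed)
    })
  } else {
    lapply(seq_len(n_fractions), function(f) weekly[[((f - 1L) %% 8L) + 1L]])
  }
  cache <- if (is.null(wepl_cache)) new.env(parent = emptyenv()) else
    wepl_cache
  dindex <- plan_delivery_index(plan)
  ref <- reference_phase(phantom)
  course <- vector("list", n_scenarios)
  rx <- plan$prescription_dose
  per <- vector("list", n_scenarios)
  for (s in seq_len(n_scenarios)) {
    fdoses <- vector("list", n_fractions)
    for (f in seq_len(n_fractions)) {
      row <- err[err$scenario == s & err$fraction == f, ]
      scen <- scenario_spec(c(row$dx, row$dy, row$dz), row$scale)
      fdoses[[f]] <- deliver_fraction(plan, weeks[[f]], scen, timeline,
                                      offsets[s, f], wepl_cache = cache,
                                      delivery_index = dindex)
    }
    course[[s]] <- accumulate_fractions(fdoses, plan$n_fractions)
    v <- coverage_verdict(course[[s]], ref$masks$ctv, rx)
    per[[s]] <- data.frame(scenario = s, d98_pct_of_rx = v$d98_pct_of_rx,
                           v95_pct = v$v95_pct)
  }
  vwmean <- voxelwise_mean(course)
  vwmin <- voxelwise_min(course)
  list(vwmean = vwmean, vwmin = vwmin,
       verdict = coverage_verdict(vwmin, ref$masks$ctv, rx),
       ooi = ooi_metrics(vwmean, ref$masks, rx),
       errors = err, per_scenario = do.call(rbind, per))
}
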