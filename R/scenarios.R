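#' Robust-optimization scenario set (21 scenarios)
#'
#' The worst-case optimization set: isocenter shifts {0, +/- su along each
#' axis} (7) crossed with density scalings {1 - ru, 1, 1 + ru} (3), giving
#' exactly 21 scenarios.  Ordering is deterministic: nominal shift first,
#' then x, y, z with the negative shift before the positive one, and the
#' density scale nested innermost (low, nominal, high).
#'
#' @param su_mm setup uncertainty in mm (> 0).
#' @param ru_pct range/density uncertainty in percent (>= 0; 0 collapses the
#'   density levels to the nominal one, leaving the 7 shift scenarios).
#' @return A `scenario_set` with fields `scenarios` (list of
#'   [scenario_spec()]), `setup_uncertainty_mm`, `range_uncertainty_pct`,
#'   and `kind = "optimization"`.
#' @export
optimization_scenarios <- function(su_mm, ru_pct) {
  if (su_mm <= 0) stop("setup uncertainty must be positive")
  if (ru_pct < 0) stop("range uncertainty must be >= 0")
  shifts <- rbind(c(0, 0, 0),
                  c(-su_mm, 0, 0), c(su_mm, 0, 0),
                  c(0, -su_mm, 0), c(0, su_mm, 0),
                  c(0, 0, -su_mm), c(0, 0, su_mm))
  scales <- if (ru_pct > 0) 1 + c(-ru_pct, 0, ru_pct) / 100 else 1
  scen <- list()
  for (r in seq_len(nrow(shifts))) {
    for (s in scales) {
      scen[[length(scen) + 1L]] <- scenario_spec(shifts[r, ], s)
    }
  }
  structure(list(scenarios = scen, setup_uncertainty_mm = su_mm,
                 range_uncertainty_pct = ru_pct, kind = "optimization"),
            class = "scenario_set")
}

#' Robustness-evaluation scenario set (28 scenarios)
#'
#' The voxel-wise minimum evaluation set: 14 isocenter shifts (a positive or
#' negative shift along each axis plus the 8 body diagonals, every shift of
#' Euclidean norm su) crossed with two density scalings {1 - ru, 1 + ru},
#' giving exactly 28 scenarios.
#'
#' @inheritParams optimization_scenarios
#' @param diagonal_convention `"norm"` (default): diagonals scaled to
#'   Euclidean norm su, keeping all shifts on the su sphere; `"component"`:
#'   su per component.
#' @return A `scenario_set` with `kind = "evaluation"`.
#' @export
evaluation_scenarios <- function(su_mm, ru_pct,
                                 diagonal_convention = c("norm", "component")) {
  if (su_mm <= 0) stop("setup uncertainty must be positive")
  if (ru_pct <= 0) stop("range uncertainty must be positive")
  diagonal_convention <- match.arg(diagonal_convention)
  axis <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1)) * su_mm
  sgn <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  diag_scale <- if (diagonal_convention == "norm") su_mm / sqrt(3) else su_mm
  diags <- sgn * diag_scale
  shifts <- rbind(axis, diags)
  scales <- 1 + c(-ru_pct, ru_pct) / 100
  scen <- list()
  for (r in seq_len(nrow(shifts))) {
    for (s in scales) {
      scen[[length(scen) + 1L]] <- scenario_spec(shifts[r, ], s)
    }
  }
  structure(list(scenarios = scen, setup_uncertainty_mm = su_mm,
                 range_uncertainty_pct = ru_pct, kind = "evaluation"),
            class = "scenario_set")
}

#' @exportS3Method base::print
print.scenario_set <- function(x, ...) {
  cat(sprintf("<scenario_set %s: %d scenarios, su %g mm, ru %g %%>\n",
              x$kind, length(x$scenarios), x$setup_uncertainty_mm,
              x$range_uncertainty_pct))
  invisible(x)
}

#' Scenario set as a data frame
#' @param set a `scenario_set`.
#' @return data.frame with columns dx, dy, dz (mm) and scale.
#' @export
scenario_table <- function(set) {
  do.call(rbind, lapply(set$scenarios, function(s) {
    data.frame(dx = s$isocenter_shift[1], dy = s$isocenter_shift[2],
               dz = s$isocenter_shift[3], scale = s$density_scale)
  }))
}

#' Per-fraction residual error model
#'
#' Residual setup error after daily image guidance, of total magnitude 2 mm,
#' decomposed into a systematic component (fixed per scenario across
#' fractions) and a random per-fraction component via the van Herk recipe
#' M = 2.5 Sigma + 0.7 sigma with Sigma = sigma, i.e. Sigma = sigma =
#' total / 3.2.  Range errors are systematic at -3 / 0 / +3 %.
#'
#' @param total_setup_mm total residual setup magnitude (default 2 mm).
#' @param systematic_sd_mm,random_sd_mm override the van Herk split.
#' @param range_levels_pct systematic range error levels in percent.
#' @return A `fraction_error_model`.
#' @export
fraction_error_model <- function(total_setup_mm = 2,
                                 systematic_sd_mm = NULL,
                                 random_sd_mm = NULL,
                                 range_levels_pct = c(-3, 0, 3)) {
  if (total_setup_mm < 0) stop("total setup magnitude must be >= 0")
  sdv <- total_setup_mm / 3.2
  structure(list(
    total_setup_mm = total_setup_mm,
    systematic_sd_mm = if (is.null(systematic_sd_mm)) sdv else systematic_sd_mm,
    random_sd_mm = if (is.null(random_sd_mm)) sdv else random_sd_mm,
    range_levels_pct = range_levels_pct
  ), class = "fraction_error_model")
}

#' Sample per-(scenario, fraction) errors for 4D evaluation
#'
#' Each scenario carries one isotropic Gaussian systematic setup vector
#' (fixed across its fractions), an independent random per-fraction vector,
#' and a systematic range level assigned as evenly as possible across
#' scenarios.  Reproducible under the seed.
#'
#' @param model a [fraction_error_model()].
#' @param n_fractions simulated fractions (default 8).
#' @param n_scenarios scenarios (default 14).
#' @param seed integer seed.
#' @return data.frame with one row per (scenario, fraction): columns
#'   `scenario`, `fraction`, `sys_x/y/z`, `rand_x/y/z`, `dx/dy/dz` (total),
#'   `range_pct`, `scale`.
#' @export
sample_fraction_errors <- function(model, n_fractions = 8L,
                                   n_scenarios = 14L, seed = 1L) {
  stopifnot(n_fractions >= 1, n_scenarios >= 1)
  set.seed(.lcg_seed(seed, 777L))
  nl <- length(model$range_levels_pct)
  base <- rep(floor(n_scenarios / nl), nl)
  extra <- n_scenarios - sum(base)
  if (extra > 0) {
    # spread the remainder over the outer levels first (-3 and +3 before 0)
    ord <- order(-abs(model$range_levels_pct))
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  range_by_scenario <- rep(model$range_levels_pct, times = base)
  sys <- matrix(rnorm(3 * n_scenarios, sd = model$systematic_sd_mm),
                n_scenarios, 3)
  if (model$systematic_sd_mm == 0) sys[] <- 0
  n <- n_scenarios * n_fractions
  scen <- rep(seq_len(n_scenarios), each = n_fractions)
  frac <- rep(seq_len(n_fractions), times = n_scenarios)
  # per-fraction random vectors, drawn in (scenario, fraction) order
  rnd <- matrix(rnorm(3 * n, sd = model$random_sd_mm), n, 3, byrow = TRUE)
  if (model$random_sd_mm == 0) rnd[] <- 0
  data.frame(
    scenario = scen, fraction = frac,
    sys_x = sys[scen, 1], sys_y = sys[scen, 2], sys_z = sys[scen, 3],
    rand_x = rnd[, 1], rand_y = rnd[, 2], rand_z = rnd[, 3],
    dx = sys[scen, 1] + rnd[, 1], dy = sys[scen, 2] + rnd[, 2],
    dz = sys[scen, 3] + rnd[, 3],
    range_pct = range_by_scenario[scen],
    scale = 1 + range_by_scenario[scen] / 100)
}
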