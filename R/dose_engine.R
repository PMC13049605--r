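#' Analytic Bragg-curve surrogate
#'
#' Normalized pristine depth-dose used by the pencil-beam engine: entrance
#' dose 1, a power-law build-up to a unique peak at `nominal_range`, and a
#' Gaussian distal falloff truncated continuously to zero at
#' `nominal_range + cut_sd * sigma_falloff`.
#'
#' @param depth water-equivalent depth(s), mm, must be >= 0.
#' @param nominal_range peak depth in mm water-equivalent, > 0.
#' @param peak_ratio peak-to-entrance dose ratio.
#' @param buildup_power exponent of the build-up term.
#' @param sigma_falloff distal falloff sigma in mm.
#' @param cut_sd truncation of the distal Gaussian, in sigmas.
#' @return dose per unit spot weight (unitless), same length as `depth`.
#' @export
depth_dose <- function(depth, nominal_range, peak_ratio = 4,
                       buildup_power = 6, sigma_falloff = 3, cut_sd = 3) {
  if (any(depth < 0)) stop("negative depth")
  if (nominal_range <= 0) stop("nominal_range must be positive")
  cpp_depth_dose(as.numeric(depth), nominal_range,
                 c(peak_ratio, buildup_power, sigma_falloff, cut_sd))
}

#' Perturbation scenario
#'
#' One robustness scenario: a rigid isocenter shift (mm, patient frame) and
#' a density/range scaling multiplier applied to water-equivalent depth
#' (3 % range uncertainty maps to scales 0.97 / 1.00 / 1.03).
#'
#' @param isocenter_shift numeric length-3 shift in mm.
#' @param density_scale positive multiplier.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(isocenter_shift = c(0, 0, 0), density_scale = 1) {
  if (density_scale <= 0) stop("density_scale must be positive")
  structure(list(isocenter_shift = as.numeric(isocenter_shift),
                 density_scale = density_scale), class = "scenario_spec")
}

#' Pencil-beam-scanning spot list for one beam
#'
#' @param gantry_angle gantry angle in degrees (0 = anterior, beam travels
#'   in +y; positive angles rotate toward +x).
#' @param spots data.frame/matrix with columns `u`, `v` (lateral position in
#'   the beam frame, mm), `range` (nominal water-equivalent range, mm),
#'   `weight` (>= 0) and `sigma` (lateral Gaussian sigma, mm).
#' @param repaint_factor number of repaintings of each energy layer
#'   (default 5); affects only time-resolved 4D delivery.
#' @return A `beam` object.
#' @export
beam <- function(gantry_angle, spots, repaint_factor = 5L) {
  spots <- as.data.frame(spots)
  need <- c("u", "v", "range", "weight", "sigma")
  if (!all(need %in% names(spots))) {
    stop("spots must have columns u, v, range, weight, sigma")
  }
  if (any(spots$weight < 0)) stop("spot weights must be non-negative")
  if (any(spots$sigma <= 0)) stop("spot sigma must be positive")
  if (repaint_factor < 1) stop("repaint_factor must be >= 1")
  structure(list(gantry_angle = gantry_angle, spots = spots,
                 repaint_factor = as.integer(repaint_factor)),
            class = "beam")
}

#' Treatment plan
#'
#' @param beams list of [beam()] objects.
#' @param prescription_dose total prescription in Gy(RBE).
#' @param n_fractions number of fractions (clinical courses here use 15 x
#'   2.0 or 11 x 1.8 Gy(RBE)).
#' @param rbe_factor constant RBE factor (1.1 for protons).
#' @param sigma_falloff,peak_ratio,buildup_power,lateral_cut_sd engine shape
#'   parameters, see [depth_dose()].
#' @return A `proton_plan`; spot weights represent the full treatment course.
#' @export
proton_plan <- function(beams, prescription_dose, n_fractions = 15L,
                        rbe_factor = 1.1, sigma_falloff = 3, peak_ratio = 4,
                        buildup_power = 6, lateral_cut_sd = 3) {
  if (rbe_factor <= 0) stop("rbe_factor must be positive")
  if (n_fractions < 1) stop("n_fractions must be a positive integer")
  if (prescription_dose <= 0) stop("prescription must be positive")
  structure(list(beams = beams, prescription_dose = prescription_dose,
                 n_fractions = as.integer(n_fractions),
                 rbe_factor = rbe_factor,
                 bragg_pars = c(peak_ratio, buildup_power, sigma_falloff,
                                lateral_cut_sd)),
            class = "proton_plan")
}

#' @exportS3Method base::print
print.proton_plan <- function(x, ...) {
  ns <- sum(vapply(x$beams, function(b) nrow(b$spots), 1L))
  cat(sprintf(
    "<proton_plan: %d beams, %d spots, %g Gy(RBE) in %d fx, RBE %.2f>\n",
    length(x$beams), ns, x$prescription_dose, x$n_fractions, x$rbe_factor))
  invisible(x)
}

n_spots <- function(plan) {
  sum(vapply(plan$beams, function(b) nrow(b$spots), 1L))
}

beam_direction <- function(gantry_angle) {
  th <- gantry_angle * pi / 180
  c(sin(th), cos(th), 0)
}

# WEPL grid for one beam direction on an anatomy, cached per (cache, key).
wepl_for_beam <- function(anatomy, gantry_angle, cache = NULL, key = NULL) {
  if (!is.null(cache) && !is.null(key) && !is.null(cache[[key]])) {
    return(cache[[key]])
  }
  w <- cpp_wepl(anatomy$density, dim(anatomy$density),
                anatomy$spacing, beam_direction(gantry_angle))
  if (!is.null(cache) && !is.null(key)) cache[[key]] <- w
  w
}

spot_matrix <- function(spots) {
  as.matrix(spots[, c("u", "v", "range", "weight", "sigma")])
}

#' Compute the dose of a plan on an anatomy under a perturbation scenario
#'
#' Physical dose from the analytic pencil-beam model times the RBE factor.
#' Dose is linear in spot weights.  The setup error translates the beam
#' isocenter by `-isocenter_shift` relative to the anatomy; the density
#' scale multiplies water-equivalent depth.  Beams are parallel, so only
#' shift components lateral to each beam axis perturb that beam's dose.
#'
#' @param plan a [proton_plan()].
#' @param anatomy an `anatomy_phase`.
#' @param scenario a [scenario_spec()] (default: nominal).
#' @param wepl_cache optional environment reused across scenarios to avoid
#'   recomputing per-beam water-equivalent path length.
#' @return A [dose_grid()] in Gy(RBE).
#' @export
compute_plan_dose <- function(plan, anatomy, scenario = scenario_spec(),
                              wepl_cache = NULL) {
  dims <- dim(anatomy$density)
  dose <- numeric(prod(dims))
  iso <- -scenario$isocenter_shift
  for (bi in seq_along(plan$beams)) {
    b <- plan$beams[[bi]]
    w <- wepl_for_beam(anatomy, b$gantry_angle, wepl_cache,
                       key = paste0("b", b$gantry_angle))
    th <- b$gantry_angle * pi / 180
    us <- sort(unique(b$spots$u))
    vs <- sort(unique(b$spots$v))
    uniform <- function(x) {
      length(x) < 3 || max(abs(diff(diff(x)))) < 1e-9 * max(abs(x), 1)
    }
    if (uniform(us) && uniform(vs) &&
        length(unique(b$spots$sigma)) == 1) {
      # layer-at-a-time deposition on the regular spot lattice
      iu <- match(b$spots$u, us)
      iv <- match(b$spots$v, vs)
      for (L in sort(unique(b$spots$range))) {
        sel <- b$spots$range == L
        Wm <- matrix(0, length(us), length(vs))
        Wm[cbind(iu[sel], iv[sel])] <- b$spots$weight[sel]
        cpp_add_layer_dose(dose, w, dims, anatomy$spacing, anatomy$origin,
                           th, iso, us, vs, Wm, L, b$spots$sigma[1],
                           scenario$density_scale, plan$bragg_pars,
                           plan$bragg_pars[4])
      }
    } else {
      cpp_add_spot_dose(dose, w, dims, anatomy$spacing, anatomy$origin,
                        th, iso, spot_matrix(b$spots),
                        scenario$density_scale, plan$bragg_pars,
                        plan$bragg_pars[4])
    }
  }
  dose_grid(array(dose * plan$rbe_factor, dims), anatomy$spacing,
            anatomy$origin)
}

#' Dose-influence matrix (voxels x spots)
#'
#' Per-unit-weight dose of every spot at a set of voxels, such that
#' `influence %*% weights` reproduces [compute_plan_dose()] at those voxels.
#'
#' @param plan a [proton_plan()].
#' @param anatomy an `anatomy_phase`.
#' @param scenario a [scenario_spec()].
#' @param voxel_idx integer vector of (1-based) linear voxel indices; default
#'   all voxels (returned as a sparse `Matrix`).
#' @param sparse return a sparse matrix (default when all voxels requested).
#' @param wepl_cache optional cache environment.
#' @return numeric matrix (or `dgCMatrix`), `length(voxel_idx)` x total spots,
#'   in Gy(RBE) per unit weight; columns ordered beam-by-beam.
#' @export
dose_influence_matrix <- function(plan, anatomy, scenario = scenario_spec(),
                                  voxel_idx = NULL, sparse = is.null(voxel_idx),
                                  wepl_cache = NULL) {
  dims <- dim(anatomy$density)
  force(sparse)
  if (is.null(voxel_idx)) voxel_idx <- seq_len(prod(dims))
  iso <- -scenario$isocenter_shift
  blocks <- vector("list", length(plan$beams))
  for (bi in seq_along(plan$beams)) {
    b <- plan$beams[[bi]]
    w <- wepl_for_beam(anatomy, b$gantry_angle, wepl_cache,
                       key = paste0("b", b$gantry_angle))
    blocks[[bi]] <- cpp_influence(w, dims, anatomy$spacing, anatomy$origin,
                                  b$gantry_angle * pi / 180, iso,
                                  spot_matrix(b$spots),
                                  scenario$density_scale, plan$bragg_pars,
                                  plan$bragg_pars[4],
                                  as.integer(voxel_idx))
  }
  out <- do.call(cbind, blocks) * plan$rbe_factor
  if (sparse) out <- Matrix::Matrix(out, sparse = TRUE)
  out
}

#' Generate a spot/layer template covering a target
#'
#' Places spots on a regular lateral grid (spacing one lateral sigma) and
#' energy layers whose Bragg peaks tile the target's water-equivalent depth
#' extent, for each beam.  Lateral placement margin grows with the setup
#' uncertainty the plan will be optimized for, and depth margin with the
#' range uncertainty, which is the geometric mechanism by which smaller
#' setup uncertainty spares organs at risk.
#'
#' @param anatomy planning anatomy (`anatomy_phase`, average CT).
#' @param target_mask logical array on the anatomy grid.
#' @param su_mm setup uncertainty in mm used for the lateral margin.
#' @param ru_pct range uncertainty in percent for the depth margin.
#' @param gantry_angles beam angles in degrees.
#' @param sigma_lateral lateral spot sigma in mm.
#' @param layer_spacing energy-layer spacing in mm water-equivalent.
#' @param lateral_margin_sigma lateral placement margin beyond the setup
#'   uncertainty, in units of `sigma_lateral`.
#' @param spot_spacing_sigma lateral spot spacing in units of
#'   `sigma_lateral` (default 1).
#' @param prescription_dose,n_fractions,repaint_factor,... passed to
#'   [proton_plan()].
#' @return A [proton_plan()] with uniform unit weights.
#' @export
make_plan_template <- function(anatomy, target_mask, su_mm,
                               ru_pct = 3, gantry_angles = c(-30, 0, 30),
                               sigma_lateral = 9, layer_spacing = 7,
                               lateral_margin_sigma = 0.8,
                               spot_spacing_sigma = 1,
                               prescription_dose = 30, n_fractions = 15L,
                               repaint_factor = 5L, ...) {
  if (!any(target_mask)) stop("empty target mask")
  dims <- dim(anatomy$density)
  sel <- which(target_mask)
  coords <- grid_coords(dims, anatomy$spacing, anatomy$origin)[sel, , drop = FALSE]
  margin_lat <- su_mm + lateral_margin_sigma * sigma_lateral
  beams <- vector("list", length(gantry_angles))
  for (bi in seq_along(gantry_angles)) {
    ga <- gantry_angles[bi]
    th <- ga * pi / 180
    wepl <- wepl_for_beam(anatomy, ga)[sel]
    u <- cos(th) * coords[, 1] - sin(th) * coords[, 2]
    v <- coords[, 3]
    margin_depth <- (ru_pct / 100) * max(wepl) + layer_spacing / 2
    sp_lat <- spot_spacing_sigma * sigma_lateral
    us <- seq(min(u) - margin_lat, max(u) + margin_lat, by = sp_lat)
    vs <- seq(min(v) - margin_lat, max(v) + margin_lat, by = sp_lat)
    rs <- seq(max(min(wepl) - margin_depth, layer_spacing),
              max(wepl) + margin_depth, by = layer_spacing)
    keep <- list()
    for (R in rs) {
      near_depth <- abs(wepl - R) <= layer_spacing
      if (!any(near_depth)) next
      ud <- u[near_depth]; vd <- v[near_depth]
      grid <- expand.grid(u = us, v = vs)
      ok <- vapply(seq_len(nrow(grid)), function(r) {
        any(abs(ud - grid$u[r]) <= margin_lat &
              abs(vd - grid$v[r]) <= margin_lat)
      }, logical(1))
      if (any(ok)) {
        keep[[length(keep) + 1L]] <-
          data.frame(u = grid$u[ok], v = grid$v[ok], range = R,
                     weight = 1, sigma = sigma_lateral)
      }
    }
    if (!length(keep)) stop("no spots generated for beam ", ga)
    beams[[bi]] <- beam(ga, do.call(rbind, keep), repaint_factor)
  }
  proton_plan(beams, prescription_dose, n_fractions, ...)
}

set_plan_weights <- function(plan, weights) {
  i <- 0L
  for (bi in seq_along(plan$beams)) {
    n <- nrow(plan$beams[[bi]]$spots)
    plan$beams[[bi]]$spots$weight <- weights[(i + 1L):(i + n)]
    i <- i + n
  }
  plan
}

plan_weights <- function(plan) {
  unlist(lapply(plan$beams, function(b) b$spots$weight), use.names = FALSE)
}

scale_plan_weights <- function(plan, factor) {
  set_plan_weights(plan, plan_weights(plan) * factor)
}
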