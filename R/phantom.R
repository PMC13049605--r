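#' Configuration for the synthetic 4D thorax phantom
#'
#' Describes a thorax-like phantom with a mediastinal target wrapping the
#' anterior/superior aspect of the heart, two low-density lungs, left/right
#' breasts, thyroid and esophagus, all defined as analytic shapes so that
#' every respiratory phase and weekly variant has ground-truth deformation
#' fields.  Breathing is a single smooth spatial envelope (largest in the
#' caudal mediastinum, decaying cranially) times a sinusoidal phase factor
#' sampled at 10 phases; phase 5 (0-based, end-of-exhale) is the reference.
#'
#' @param grid_dim integer length-3 grid dimensions (default 48^3).
#' @param spacing voxel spacing in mm (default 3 mm isotropic).
#' @param amplitude_mm peak target motion: the realized point-max displacement
#'   of any target voxel at end-of-inhale (mm).
#' @param motion_dir dominant motion direction (unnormalized; default mainly
#'   superior-inferior with a smaller anterior-posterior component).
#' @param z_apex,lambda_z center (mm) and length scale (mm) of the Gaussian
#'   cranio-caudal motion envelope.
#' @param weekly_mm peak magnitude of the random smooth weekly anatomical
#'   displacement (mm).
#' @param weekly_density_drift relative weekly density drift amplitude
#'   (uniform in +/- this value; default 0).
#' @param ctv_center,ctv_semi center and semi-axes (mm) of the CTV ellipsoid.
#' @param heart_center,heart_semi center and semi-axes (mm) of the heart.
#' @param n_phases number of respiratory phases (fixed at 10).
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_dim = c(48, 48, 48), spacing = c(3, 3, 3),
                           amplitude_mm = 10, motion_dir = c(0, 0.35, 1),
                           z_apex = -50, lambda_z = 40,
                           weekly_mm = 3, weekly_density_drift = 0,
                           ctv_center = c(0, -10, 6),
                           ctv_semi = c(18, 14, 26),
                           heart_center = c(8, 10, -26),
                           heart_semi = c(22, 20, 22),
                           n_phases = 10) {
  if (any(grid_dim <= 0) || any(spacing <= 0)) {
    stop("grid dimensions and spacing must be positive")
  }
  if (amplitude_mm < 0 || weekly_mm < 0) stop("amplitudes must be >= 0")
  if (n_phases != 10) stop("the phantom uses a 10-phase breathing cycle")
  structure(list(
    grid_dim = as.integer(grid_dim), spacing = as.numeric(spacing),
    amplitude_mm = amplitude_mm,
    motion_dir = motion_dir / sqrt(sum(motion_dir^2)),
    z_apex = z_apex, lambda_z = lambda_z,
    weekly_mm = weekly_mm, weekly_density_drift = weekly_density_drift,
    ctv_center = ctv_center, ctv_semi = ctv_semi,
    heart_center = heart_center, heart_semi = heart_semi,
    n_phases = 10L, reference_phase = 5L
  ), class = "phantom_config")
}

in_ellipsoid <- function(pts, center, semi) {
  ((pts[, 1] - center[1]) / semi[1])^2 +
    ((pts[, 2] - center[2]) / semi[2])^2 +
    ((pts[, 3] - center[3]) / semi[3])^2 <= 1
}

# Analytic shape indicators at arbitrary world points (n x 3 mm matrix).
phantom_shapes <- function(cfg, pts) {
  body <- (pts[, 1] / 66)^2 + (pts[, 2] / 56)^2 <= 1
  lung_l <- in_ellipsoid(pts, c(36, 2, -6), c(24, 34, 54))
  lung_r <- in_ellipsoid(pts, c(-36, 2, -6), c(24, 34, 54))
  heart <- in_ellipsoid(pts, cfg$heart_center, cfg$heart_semi)
  ctv <- in_ellipsoid(pts, cfg$ctv_center, cfg$ctv_semi) & !heart
  breast_l <- in_ellipsoid(pts, c(40, -44, -18), c(18, 14, 18)) & body
  breast_r <- in_ellipsoid(pts, c(-40, -44, -18), c(18, 14, 18)) & body
  thyroid <- in_ellipsoid(pts, c(0, -14, 40), c(10, 7, 9)) & body
  esophagus <- ((pts[, 1] + 5)^2 + (pts[, 2] - 14)^2 <= 36) & body
  lungs <- (lung_l | lung_r) & body & !heart & !ctv & !esophagus
  list(body = body, lungs = lungs, heart = heart & body, ctv = ctv & body,
       breast_l = breast_l, breast_r = breast_r, thyroid = thyroid,
       esophagus = esophagus)
}

phantom_density_at <- function(cfg, pts) {
  sh <- phantom_shapes(cfg, pts)
  d <- numeric(nrow(pts))
  d[sh$body] <- 1
  d[sh$lungs] <- 0.3
  d
}

# Forward breathing displacement (mm) at world points for one phase factor.
breathing_disp <- function(cfg, pts, phase_factor, amp_norm) {
  env <- exp(-((pts[, 3] - cfg$z_apex) / cfg$lambda_z)^2)
  mag <- amp_norm * phase_factor * env
  cbind(mag * cfg$motion_dir[1], mag * cfg$motion_dir[2],
        mag * cfg$motion_dir[3])
}

# Smooth random weekly drift field: two Gaussian blobs with seeded centers
# and direction vectors, normalized to the configured peak magnitude.
weekly_params <- function(cfg, week, seed) {
  rs <- .lcg_seed(seed, week)
  set.seed(rs)
  ext <- (cfg$grid_dim - 1) * cfg$spacing / 2
  centers <- cbind(runif(2, -ext[1] / 2, ext[1] / 2),
                   runif(2, -ext[2] / 2, ext[2] / 2),
                   runif(2, -ext[3] / 2, ext[3] / 2))
  dirs <- matrix(rnorm(6), 2, 3)
  drift <- if (cfg$weekly_density_drift > 0) {
    runif(1, -cfg$weekly_density_drift, cfg$weekly_density_drift)
  } else 0
  list(centers = centers, dirs = dirs, sigma = 45, drift = drift)
}

# Evaluate the weekly drift field at arbitrary points.  `scale` is the
# fixed normalization (peak magnitude over the phantom grid mapped to the
# configured weekly magnitude), precomputed once per week so the field is a
# well-defined function of position.
weekly_disp <- function(wp, pts, scale) {
  if (scale == 0) return(matrix(0, nrow(pts), 3))
  n <- nrow(pts)
  dx <- numeric(n); dy <- numeric(n); dz <- numeric(n)
  inv2s2 <- 1 / (2 * wp$sigma^2)
  for (b in 1:2) {
    g <- exp(-((pts[, 1] - wp$centers[b, 1])^2 +
                 (pts[, 2] - wp$centers[b, 2])^2 +
                 (pts[, 3] - wp$centers[b, 3])^2) * inv2s2)
    dx <- dx + g * wp$dirs[b, 1]
    dy <- dy + g * wp$dirs[b, 2]
    dz <- dz + g * wp$dirs[b, 3]
  }
  cbind(dx, dy, dz) * scale
}

# Fixed normalization factor for one week's drift field.
weekly_disp_scale <- function(wp, coords, weekly_mm) {
  if (weekly_mm == 0) return(0)
  raw <- weekly_disp(wp, coords, 1)
  peak <- max(sqrt(rowSums(raw^2)))
  if (peak > 0) weekly_mm / peak else 0
}

# deterministic small-integer seed derivation, kept below 2^31
.lcg_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729 + 12345) %%
               2147483647)
}

# Invert x -> x + disp(x) by fixed-point iteration (fields are smooth with
# Jacobian perturbation well below 1, so convergence is geometric).
invert_forward <- function(disp_fun, pts, iters = 8) {
  x <- pts
  for (it in seq_len(iters)) x <- pts - disp_fun(x)
  x
}

make_anatomy_phase <- function(cfg, coords, disp_fun, density_fun,
                               density_factor = 1, light = FALSE) {
  xinv <- invert_forward(disp_fun, coords)
  g <- disp_fun(coords)
  density <- array(density_fun(xinv) * density_factor, dim = cfg$grid_dim)
  masks <- NULL
  if (!light) {
    sh <- phantom_shapes(cfg, xinv)
    masks <- lapply(sh, function(v) array(v, dim = cfg$grid_dim))
  }
  structure(list(
    density = density, masks = masks,
    dvf = list(dx = array(g[, 1], cfg$grid_dim),
               dy = array(g[, 2], cfg$grid_dim),
               dz = array(g[, 3], cfg$grid_dim)),
    spacing = cfg$spacing,
    origin = -(cfg$grid_dim - 1) / 2 * cfg$spacing
  ), class = "anatomy_phase")
}

#' Generate a synthetic 4D breathing thorax phantom
#'
#' Builds 10 respiratory phases on a shared grid.  Each phase stores density
#' (a relative stopping-power surrogate), binary structure masks, and the
#' ground-truth displacement field to the end-of-exhale reference phase
#' (stored on the reference grid; pulling a phase dose back through this
#' field maps it onto the reference anatomy).  Anatomy per phase is evaluated
#' analytically at inverted positions, so masks are exact indicator samples
#' with no resampling error.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @return A `phantom4d` object with fields `phases` (list of 10
#'   `anatomy_phase`), `reference_phase_index` (0-based, = 5),
#'   `weekly_variants` (filled lazily by [sample_weekly_anatomy()]),
#'   `voxel_spacing`, and `rng_seed`.
#' @export
generate_phantom <- function(config, seed = 1L) {
  cfg <- config
  if (!inherits(cfg, "phantom_config")) stop("config must be a phantom_config")
  coords <- grid_coords(cfg$grid_dim, cfg$spacing,
                        -(cfg$grid_dim - 1) / 2 * cfg$spacing)
  # normalize the envelope so the realized point-max target motion equals
  # amplitude_mm at end-of-inhale
  sh_ref <- phantom_shapes(cfg, coords)
  if (!any(sh_ref$ctv)) stop("configuration produced an empty CTV")
  env_ctv <- exp(-((coords[sh_ref$ctv, 3] - cfg$z_apex) / cfg$lambda_z)^2)
  amp_norm <- if (cfg$amplitude_mm > 0) cfg$amplitude_mm / max(env_ctv) else 0
  pref <- cfg$reference_phase
  phase_factor <- (1 - cos(2 * pi * ((0:9) - pref) / 10)) / 2
  phases <- vector("list", 10)
  for (p in 1:10) {
    pf <- phase_factor[p]
    dfun <- function(x) breathing_disp(cfg, x, pf, amp_norm)
    phases[[p]] <- make_anatomy_phase(cfg, coords, dfun,
                                      function(x) phantom_density_at(cfg, x))
  }
  structure(list(
    phases = phases, reference_phase_index = pref,
    weekly_variants = list(), voxel_spacing = cfg$spacing,
    rng_seed = as.integer(seed), config = cfg, amp_norm = amp_norm
  ), class = "phantom4d")
}

#' @exportS3Method base::print
print.phantom4d <- function(x, ...) {
  cat(sprintf("<phantom4d %s voxels, %d phases, reference phase %d>\n",
              paste(x$config$grid_dim, collapse = "x"), length(x$phases),
              x$reference_phase_index), ...)
  invisible(x)
}

reference_phase <- function(phantom) {
  phantom$phases[[phantom$reference_phase_index + 1L]]
}

#' Target motion statistics
#'
#' For every target voxel on the reference phase, the peak-to-reference
#' displacement magnitude across all phases is taken from the ground-truth
#' fields; the mean and the maximum of that quantity over the target are the
#' mean motion and point-max motion.
#'
#' @param phantom a `phantom4d`.
#' @return list with `mean_motion_mm` and `point_max_motion_mm`.
#' @export
compute_motion_stats <- function(phantom) {
  if (length(phantom$phases) < 2) stop("phantom must have >= 2 phases")
  ctv <- reference_phase(phantom)$masks$ctv
  if (is.null(ctv) || !any(ctv)) stop("empty target mask")
  sel <- which(ctv)
  peak <- numeric(length(sel))
  for (ph in phantom$phases) {
    mag <- sqrt(ph$dvf$dx[sel]^2 + ph$dvf$dy[sel]^2 + ph$dvf$dz[sel]^2)
    peak <- pmax(peak, mag)
  }
  list(mean_motion_mm = mean(peak), point_max_motion_mm = max(peak))
}

#' Map a binary mask through a displacement field
#'
#' Trilinear interpolation of the mask indicator at the displaced positions,
#' thresholded at 0.5 with the tie broken toward inclusion (conservative
#' for target coverage).
#'
#' @param mask logical 3D array.
#' @param dvf list with `dx`, `dy`, `dz` displacement arrays (mm).
#' @param spacing voxel spacing in mm.
#' @return logical 3D array.
#' @export
warp_mask <- function(mask, dvf, spacing = c(3, 3, 3)) {
  dims <- dim(mask)
  out <- cpp_pullback(mask + 0, dims, spacing, dvf$dx, dvf$dy, dvf$dz)
  array(out >= 0.5, dims)
}

#' Internal target volume (ITV)
#'
#' Envelope of the target across the breathing cycle: the union over phases
#' of each phase's CTV mask on the shared grid together with its image
#' mapped through the phase's displacement field onto the reference tissue
#' (the mapping uses the conservative inclusion threshold of
#' [warp_mask()], so voxelization never erodes the envelope).  A superset
#' of the reference CTV and equal to it for zero motion.
#'
#' @param phantom a `phantom4d`.
#' @return logical 3D array.
#' @export
build_itv <- function(phantom) {
  itv <- NULL
  for (ph in phantom$phases) {
    if (is.null(ph$masks$ctv)) stop("phase without CTV mask")
    m <- ph$masks$ctv | warp_mask(ph$masks$ctv, ph$dvf, ph$spacing)
    itv <- if (is.null(itv)) m else (itv | m)
  }
  itv
}

#' Average CT over the breathing cycle
#'
#' Warps each phase density to the end-of-exhale reference through its
#' ground-truth field and takes the per-voxel arithmetic mean with equal
#' phase weights.  Masks are taken from the reference phase, with the ITV
#' added.
#'
#' @param phantom a `phantom4d`.
#' @return An `anatomy_phase` whose masks include `itv`.
#' @export
make_average_ct <- function(phantom) {
  ref <- reference_phase(phantom)
  dims <- dim(ref$density)
  acc <- array(0, dims)
  for (ph in phantom$phases) {
    w <- cpp_pullback(ph$density, dims, ph$spacing,
                      ph$dvf$dx, ph$dvf$dy, ph$dvf$dz)
    acc <- acc + array(w, dims)
  }
  avg <- ref
  avg$density <- acc / length(phantom$phases)
  avg$masks$itv <- build_itv(phantom)
  avg$dvf <- list(dx = array(0, dims), dy = array(0, dims),
                  dz = array(0, dims))
  avg
}

#' Weekly anatomy snapshot
#'
#' Deterministically perturbs the planning phantom with a small smooth
#' random displacement (and optional density drift) representing week-scale
#' anatomical change, then rebuilds all 10 breathing phases on the perturbed
#' anatomy.  Displacement fields of the returned phases map onto the
#' *planning* reference phase, so accumulated weekly doses land on a common
#' frame in one warp.
#'
#' @param phantom a `phantom4d` from [generate_phantom()].
#' @param week integer in 1..8.
#' @param seed integer seed.
#' @return A `phantom4d` snapshot (phases carry density, CTV/body masks and
#'   composed displacement fields to the planning reference).
#' @export
sample_weekly_anatomy <- function(phantom, week, seed = phantom$rng_seed) {
  if (!(week %in% 1:8)) stop("week must be in 1..8")
  cfg <- phantom$config
  coords <- grid_coords(cfg$grid_dim, cfg$spacing,
                        -(cfg$grid_dim - 1) / 2 * cfg$spacing)
  wp <- weekly_params(cfg, week, seed)
  wscale <- weekly_disp_scale(wp, coords, cfg$weekly_mm)
  pref <- cfg$reference_phase
  phase_factor <- (1 - cos(2 * pi * ((0:9) - pref) / 10)) / 2
  amp_norm <- phantom$amp_norm
  phases <- vector("list", 10)
  for (p in 1:10) {
    pf <- phase_factor[p]
    # composed forward displacement from planning reference:
    # drift first, then breathing evaluated on the drifted anatomy
    dfun <- function(x) {
      dw <- weekly_disp(wp, x, wscale)
      dw + breathing_disp(cfg, x + dw, pf, amp_norm)
    }
    phases[[p]] <- make_anatomy_phase(cfg, coords, dfun,
                                      function(x) phantom_density_at(cfg, x),
                                      density_factor = 1 + wp$drift,
                                      light = TRUE)
  }
  structure(list(
    phases = phases, reference_phase_index = pref,
    weekly_variants = list(), voxel_spacing = cfg$spacing,
    rng_seed = as.integer(seed), config = cfg, amp_norm = amp_norm,
    week = as.integer(week)
  ), class = "phantom4d")
}
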