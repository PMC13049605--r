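#' Voxel-wise minimum / mean over scenario doses
#'
#' Per-voxel aggregation across a list of scenario dose grids with identical
#' geometry.  The voxel-wise minimum is, by construction, less favorable
#' than any single scenario, which is why coverage gates applied to it are
#' conservative.
#'
#' @param doses non-empty list of [dose_grid()]s with identical geometry.
#' @return A [dose_grid()].
#' @export
voxelwise_min <- function(doses) {
  stopifnot(length(doses) >= 1)
  assert_same_geometry(doses)
  out <- doses[[1]]$data
  for (d in doses[-1]) out <- pmin(out, d$data)
  dose_grid(out, doses[[1]]$spacing, doses[[1]]$origin)
}

#' @rdname voxelwise_min
#' @export
voxelwise_mean <- function(doses) {
  stopifnot(length(doses) >= 1)
  assert_same_geometry(doses)
  out <- doses[[1]]$data
  for (d in doses[-1]) out <- out + d$data
  dose_grid(out / length(doses), doses[[1]]$spacing, doses[[1]]$origin)
}

#' Exact voxel-sample DVH
#'
#' Stores every voxel dose of a structure, sorted descending (no binning),
#' plus the voxel volume, from which dose-at-volume and volume-at-dose
#' metrics are exact order statistics.
#'
#' @param dose a [dose_grid()].
#' @param mask logical array on the same grid.
#' @param structure_name optional label.
#' @return A `dvh` object.
#' @export
dvh <- function(dose, mask, structure_name = "structure") {
  stopifnot(inherits(dose, "dose_grid"), identical(dim(dose$data), dim(mask)))
  sel <- which(mask)
  if (!length(sel)) stop("empty structure mask")
  structure(list(structure_name = structure_name,
                 samples = sort(dose$data[sel], decreasing = TRUE),
                 voxel_volume = voxel_volume_cm3(dose)),
            class = "dvh")
}

#' Dose at volume (D-metrics)
#'
#' Minimum dose received by the hottest `volume_pct` of the structure,
#' using the conservative no-interpolation convention: the
#' `ceiling(n * volume_pct / 100)`-th largest voxel sample.  `D98 =
#' dose_at_volume(dvh, 98)`.
#'
#' @param x a [dvh()].
#' @param volume_pct volume percentage in (0, 100].
#' @return dose in Gy(RBE).
#' @export
dose_at_volume <- function(x, volume_pct) {
  if (volume_pct <= 0 || volume_pct > 100) stop("volume_pct out of (0, 100]")
  n <- length(x$samples)
  k <- max(1L, ceiling(n * volume_pct / 100))
  x$samples[k]
}

#' Volume at dose (V-metrics)
#'
#' Fraction of the structure receiving at least `dose_threshold`, in percent
#' of the structure volume and in cm^3.  `V95 = volume_at_dose(dvh,
#' 0.95 * prescription)`.
#'
#' @param x a [dvh()].
#' @param dose_threshold threshold in Gy(RBE), >= 0.
#' @return list with `pct` and `cm3`.
#' @export
volume_at_dose <- function(x, dose_threshold) {
  if (dose_threshold < 0) stop("threshold must be >= 0")
  cnt <- sum(x$samples >= dose_threshold)
  list(pct = 100 * cnt / length(x$samples), cm3 = cnt * x$voxel_volume)
}

#' Target coverage verdict
#'
#' Clinical gate on a (typically voxel-wise minimum) dose distribution:
#' D98 must exceed 95 % of the prescription and V95 must exceed 98 % of the
#' structure volume, both strict inequalities.
#'
#' @param dose a [dose_grid()].
#' @param target_mask logical array.
#' @param prescription prescription dose in Gy(RBE).
#' @return list with `d98_pct_of_rx`, `v95_pct`, `pass`.
#' @export
coverage_verdict <- function(dose, target_mask, prescription) {
  h <- dvh(dose, target_mask, "target")
  d98 <- 100 * dose_at_volume(h, 98) / prescription
  v95 <- volume_at_dose(h, 0.95 * prescription)$pct
  list(d98_pct_of_rx = d98, v95_pct = v95, pass = (d98 > 95) && (v95 > 98))
}

#' Organ-of-interest dose metrics
#'
#' Mean doses for heart (MHD), lungs (MLD), left/right breast, thyroid and
#' esophagus, plus lung V5 % and breast V4 % (thresholds as percent of the
#' prescription dose), each reported in percent of structure volume and in
#' cm^3.
#'
#' @param dose a [dose_grid()] (e.g. the nominal or the 4D voxel-wise mean).
#' @param masks named list of logical arrays; recognised names: `heart`,
#'   `lungs`, `breast_l`, `breast_r`, `thyroid`, `esophagus`.
#' @param prescription prescription dose in Gy(RBE).
#' @return one-row data.frame of metrics.
#' @export
ooi_metrics <- function(dose, masks, prescription) {
  m <- function(name) {
    if (is.null(masks[[name]]) || !any(masks[[name]])) return(NA_real_)
    mean(dose$data[masks[[name]]])
  }
  v <- function(name, frac) {
    if (is.null(masks[[name]]) || !any(masks[[name]])) {
      return(list(pct = NA_real_, cm3 = NA_real_))
    }
    volume_at_dose(dvh(dose, masks[[name]]), frac * prescription)
  }
  v5l <- v("lungs", 0.05)
  v4bl <- v("breast_l", 0.04)
  v4br <- v("breast_r", 0.04)
  data.frame(
    mhd = m("heart"), mld = m("lungs"), mbld = m("breast_l"),
    mbrd = m("breast_r"), mtd = m("thyroid"), med = m("esophagus"),
    lung_v5_pct = v5l$pct, lung_v5_cm3 = v5l$cm3,
    breast_l_v4_pct = v4bl$pct, breast_l_v4_cm3 = v4bl$cm3,
    breast_r_v4_pct = v4br$pct, breast_r_v4_cm3 = v4br$cm3)
}

#' 3D robustness evaluation (voxel-wise minimum over 28 scenarios)
#'
#' Computes all evaluation-scenario doses of a plan on the planning (average)
#' anatomy, aggregates the voxel-wise minimum, applies the coverage gate on
#' the target (the ITV for 3D evaluation), and extracts organ-of-interest
#' metrics from the nominal dose.  With `su_mm = 0` the scenario set
#' degenerates to the nominal scenario only.
#'
#' @param plan a [proton_plan()].
#' @param anatomy planning anatomy (`anatomy_phase`).
#' @param su_mm setup uncertainty in mm (same value used for optimization).
#' @param ru_pct range uncertainty in percent.
#' @param target_mask logical array (ITV).
#' @return list with `vwmin` ([dose_grid()]), `nominal` ([dose_grid()]),
#'   `verdict` (from [coverage_verdict()]), `ooi` (nominal-dose metrics),
#'   and `per_scenario` (data.frame of per-scenario D98/V95).
#' @export
run_3drem <- function(plan, anatomy, su_mm, ru_pct, target_mask) {
  cache <- new.env(parent = emptyenv())
  nominal <- compute_plan_dose(plan, anatomy, scenario_spec(),
                               wepl_cache = cache)
  scen <- if (su_mm > 0) {
    evaluation_scenarios(su_mm, ru_pct)$scenarios
  } else {
    list(scenario_spec())
  }
  doses <- vector("list", length(scen))
  per <- vector("list", length(scen))
  rx <- plan$prescription_dose
  for (i in seq_along(scen)) {
    doses[[i]] <- compute_plan_dose(plan, anatomy, scen[[i]],
                                    wepl_cache = cache)
    h <- dvh(doses[[i]], target_mask)
    per[[i]] <- data.frame(
      scenario = i,
      dx = scen[[i]]$isocenter_shift[1], dy = scen[[i]]$isocenter_shift[2],
      dz = scen[[i]]$isocenter_shift[3], scale = scen[[i]]$density_scale,
      d98_pct_of_rx = 100 * dose_at_volume(h, 98) / rx,
      v95_pct = volume_at_dose(h, 0.95 * rx)$pct)
  }
  vwmin <- voxelwise_min(doses)
  list(vwmin = vwmin, nominal = nominal,
       verdict = coverage_verdict(vwmin, target_mask, rx),
       ooi = ooi_metrics(nominal, anatomy$masks, rx),
       per_scenario = do.call(rbind, per))
}
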