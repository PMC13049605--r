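#' Read / write volumetric grids as NIfTI
#'
#' Grids (dose, density, masks, displacement-field components) round-trip
#' through NIfTI with voxel spacing preserved; dose is stored as 32-bit
#' float, masks as 8-bit integers.  The world origin is kept in a JSON
#' sidecar (`<file>.json`) because the package uses a voxel-center,
#' isocenter-relative frame.
#'
#' @param grid a [dose_grid()] (or logical array via `mask = TRUE`).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param mask write as an integer label volume.
#' @return `write_grid_nifti`: the path, invisibly.
#' @export
write_grid_nifti <- function(grid, path, mask = FALSE) {
  dat <- if (mask) {
    storage.mode(grid$data) <- "integer"
    grid$data
  } else grid$data
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path, datatype = if (mask) "uint8" else "float")
  jsonlite::write_json(list(origin = grid$origin, spacing = grid$spacing),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_grid_nifti
#' @return `read_grid_nifti`: a [dose_grid()].
#' @export
read_grid_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    dose_grid(array(as.numeric(img), dim = dim(img)),
              spacing = meta$spacing, origin = meta$origin)
  } else {
    dose_grid(array(as.numeric(img), dim = dim(img)),
              spacing = RNifti::pixdim(img))
  }
}

#' Write / read a plan as YAML
#'
#' Serializes beams, energy layers, spots (position, range, weight, sigma),
#' repainting factor, prescription, fractionation and engine parameters;
#' numeric fields round-trip losslessly at full double precision.
#'
#' @param plan a [proton_plan()].
#' @param path file path.
#' @export
write_plan_yaml <- function(plan, path) {
  obj <- list(
    prescription_dose = plan$prescription_dose,
    n_fractions = plan$n_fractions,
    rbe_factor = plan$rbe_factor,
    bragg_pars = as.numeric(plan$bragg_pars),
    beams = lapply(plan$beams, function(b) {
      list(gantry_angle = b$gantry_angle,
           repaint_factor = b$repaint_factor,
           spots = lapply(seq_len(nrow(b$spots)), function(i) {
             as.list(b$spots[i, c("u", "v", "range", "weight", "sigma")])
           }))
    }))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_plan_yaml
#' @return `read_plan_yaml`: a [proton_plan()].
#' @export
read_plan_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  beams <- lapply(obj$beams, function(b) {
    spots <- do.call(rbind, lapply(b$spots, as.data.frame))
    beam(b$gantry_angle, spots, b$repaint_factor)
  })
  proton_plan(beams, obj$prescription_dose, obj$n_fractions, obj$rbe_factor,
              sigma_falloff = obj$bragg_pars[3],
              peak_ratio = obj$bragg_pars[1],
              buildup_power = obj$bragg_pars[2],
              lateral_cut_sd = obj$bragg_pars[4])
}
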