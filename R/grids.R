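#' Dose / scalar grid on a regular lattice
#'
#' A `dose_grid` is a 3D numeric array with voxel spacing and world origin
#' metadata (mm, voxel-center convention, 0-based world indexing:
#' world = origin + (index - 1) * spacing for R's 1-based indices).
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, voxel spacing in mm.
#' @param origin numeric length-3, world position of voxel `[1,1,1]` in mm.
#' @return A `dose_grid` object.
#' @export
dose_grid <- function(data, spacing = c(3, 3, 3), origin = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * spacing
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "dose_grid")
}

#' @exportS3Method base::print
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid %s, spacing %s mm, range [%.3g, %.3g]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.dose_grid <- function(x) dim(x$data)

grid_compatible <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

assert_same_geometry <- function(grids) {
  g1 <- grids[[1]]
  for (g in grids[-1]) {
    if (!grid_compatible(g1, g)) stop("dose grids have mismatching geometry")
  }
  invisible(TRUE)
}

#' Voxel volume of a grid in cm^3
#' @param x a `dose_grid` or a spacing triplet in mm.
#' @return scalar volume of one voxel in cm^3.
#' @export
voxel_volume_cm3 <- function(x) {
  sp <- if (inherits(x, "dose_grid")) x$spacing else as.numeric(x)
  prod(sp) / 1000
}

# World coordinates of every voxel center (n x 3 matrix), in grid order.
grid_coords <- function(dim, spacing, origin) {
  xs <- origin[1] + (seq_len(dim[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dim[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dim[3]) - 1) * spacing[3]
  cbind(rep(xs, times = dim[2] * dim[3]),
        rep(rep(ys, each = dim[1]), times = dim[3]),
        rep(zs, each = dim[1] * dim[2]))
}
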