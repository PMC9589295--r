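#' 3D scalar volume on a physical grid
#'
#' A `volume_grid` holds a 3D numeric array together with its physical
#' geometry (voxel spacing and origin in mm, axes ordered x, y, z with z the
#' superior--inferior axis) and a unit tag. Voxel centers sit at
#' `origin + (index - 1) * spacing`. All voxel-wise operations in the package
#' require geometry compatibility (equal shape, spacing and origin within
#' 1e-6 mm).
#'
#' @param values 3D numeric array.
#' @param spacing Numeric length-3, voxel spacing in mm (strictly positive).
#' @param origin Numeric length-3, position of the first voxel center in mm.
#' @param unit One of `"HU"`, `"Gy"`, `"unitless"`, `"probability"`.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        unit = "unitless") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  unit <- match.arg(unit, c("HU", "Gy", "unitless", "probability"))
  if (unit == "probability") {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop("probability-tagged values must lie in [0, 1]", call. = FALSE)
  }
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = spacing, origin = origin,
                 unit = unit),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d [%s], spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3], x$unit,
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ",")))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

geometry_of <- function(vol) {
  list(dim = dim(vol$values), spacing = vol$spacing, origin = vol$origin)
}

#' Test whether two volumes share one grid geometry
#'
#' @param a,b `volume_grid` objects (or bare geometry lists with `dim`,
#'   `spacing`, `origin`).
#' @param tol Absolute tolerance in mm for spacing/origin comparison.
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  ga <- if (inherits(a, "volume_grid")) geometry_of(a) else a
  gb <- if (inherits(b, "volume_grid")) geometry_of(b) else b
  identical(as.integer(ga$dim), as.integer(gb$dim)) &&
    all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol)
}

stop_if_incompatible <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b))
    stop(sprintf("%s are not geometry-compatible", what), call. = FALSE)
  invisible(TRUE)
}

stop_if_unit_mismatch <- function(a, b) {
  if (!identical(a$unit, b$unit))
    stop(sprintf("unit mismatch: %s vs %s", a$unit, b$unit), call. = FALSE)
  invisible(TRUE)
}

#' Replace the values of a volume, keeping its geometry
#'
#' @param vol `volume_grid` supplying geometry.
#' @param values New 3D array (same shape).
#' @param unit Optional new unit tag (default: keep).
#' @return A `volume_grid`.
#' @export
with_values <- function(vol, values, unit = vol$unit) {
  if (!all(dim(values) == dim(vol$values)))
    stop("replacement values have a different shape", call. = FALSE)
  volume_grid(values, vol$spacing, vol$origin, unit)
}

#' Resample a volume onto the geometry of a reference
#'
#' Trilinear (`"linear"`) or nearest-neighbour (`"nearest"`) resampling onto
#' the reference grid; voxels that fall outside the source grid get
#' `background`. Binary masks must use `mode = "nearest"` so the output stays
#' binary.
#'
#' @param vol `volume_grid` to resample.
#' @param reference `volume_grid` (or geometry list) defining the output grid.
#' @param mode `"linear"` or `"nearest"`.
#' @param background Fill value outside the source grid.
#' @return A `volume_grid` on the reference geometry.
#' @export
resample_like <- function(vol, reference, mode = c("linear", "nearest"),
                          background = 0) {
  mode <- match.arg(mode)
  g <- if (inherits(reference, "volume_grid")) geometry_of(reference) else reference
  if (any(g$spacing <= 0) || any(g$dim < 1))
    stop("degenerate reference geometry", call. = FALSE)
  if (same_geometry(vol, g)) return(vol)
  out <- cpp_resample(as.double(vol$values), dim(vol$values),
                      vol$spacing, vol$origin,
                      as.integer(g$dim), as.numeric(g$spacing),
                      as.numeric(g$origin),
                      as.integer(mode == "nearest"), background)
  dim(out) <- as.integer(g$dim)
  volume_grid(out, g$spacing, g$origin, vol$unit)
}

as_mask <- function(x) {
  if (inherits(x, "volume_grid")) x <- x$values
  if (is.logical(x)) return(x)
  x > 0.5
}
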