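#' Named binary masks sharing one grid geometry
#'
#' A `structure_set` collects organ masks (body, bones, bladder, rectum,
#' prostate, CTVs, optional cortical/spongy bone) defined on a common
#' reference geometry. Organ masks must be contained in the body mask, and
#' cortical + spongy masks, when present, must partition the bones mask.
#'
#' @param geometry A `volume_grid` (or geometry list) defining the grid.
#' @param masks Named list of logical 3D arrays (or `volume_grid`s).
#' @param check Validate containment/partition invariants (default `TRUE`).
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(geometry, masks, check = TRUE) {
  g <- if (inherits(geometry, "volume_grid")) geometry_of(geometry) else geometry
  masks <- lapply(masks, function(m) {
    if (inherits(m, "volume_grid")) {
      if (!same_geometry(m, g)) stop("mask not geometry-compatible", call. = FALSE)
      m <- m$values
    }
    if (!all(dim(m) == g$dim)) stop("mask shape mismatch", call. = FALSE)
    m <- as_mask(m)
    m
  })
  ss <- structure(list(geometry = g, masks = masks), class = "structure_set")
  if (check) validate_structure_set(ss)
  ss
}

validate_structure_set <- function(ss) {
  m <- ss$masks
  if (!is.null(m$body)) {
    for (org in intersect(c("bladder", "rectum", "prostate", "bones"), names(m)))
      if (any(m[[org]] & !m$body))
        stop(sprintf("organ mask '%s' not contained in body", org), call. = FALSE)
  }
  if (!is.null(m$cortical) && !is.null(m$spongy) && !is.null(m$bones)) {
    if (any(m$cortical & m$spongy))
      stop("cortical and spongy masks overlap", call. = FALSE)
    if (!identical(m$cortical | m$spongy, m$bones))
      stop("cortical and spongy masks do not partition bones", call. = FALSE)
  }
  invisible(ss)
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %s on %s grid\n",
              paste(names(x$masks), collapse = ", "),
              paste(x$geometry$dim, collapse = "x")))
  invisible(x)
}

get_mask <- function(ss, name) {
  m <- ss$masks[[name]]
  if (is.null(m)) stop(sprintf("structure '%s' missing", name), call. = FALSE)
  m
}

mask_volume_cm3 <- function(mask, spacing) {
  sum(mask) * prod(spacing) / 1000
}

#' Per-voxel 3D displacement field in mm
#'
#' Backward-warping convention: a field `f` on grid coordinates `x` maps a
#' volume `v` to `v(x + f(x))`. The zero field is the identity.
#'
#' @param dx,dy,dz 3D arrays of displacement components in mm.
#' @param spacing,origin Grid geometry (mm).
#' @return An object of class `vector_field`.
#' @export
vector_field <- function(dx, dy, dz, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!all(dim(dx) == dim(dy)) || !all(dim(dx) == dim(dz)))
    stop("displacement components differ in shape", call. = FALSE)
  structure(list(dx = dx, dy = dy, dz = dz,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "vector_field")
}

#' Zero (identity) displacement field on a reference geometry
#' @param reference `volume_grid` or geometry list.
#' @return A `vector_field` of zeros.
#' @export
zero_field <- function(reference) {
  g <- if (inherits(reference, "volume_grid")) geometry_of(reference) else reference
  z <- array(0, g$dim)
  vector_field(z, z, z, g$spacing, g$origin)
}

#' @export
print.vector_field <- function(x, ...) {
  mag <- sqrt(x$dx^2 + x$dy^2 + x$dz^2)
  cat(sprintf("<vector_field> %s, |f| max %.3f mm, mean %.3f mm\n",
              paste(dim(x$dx), collapse = "x"), max(mag), mean(mag)))
  invisible(x)
}

field_geometry <- function(f) list(dim = dim(f$dx), spacing = f$spacing, origin = f$origin)

#' Bundle one patient's volumes and structures
#'
#' @param id Patient identifier.
#' @param mri,ct `volume_grid`s (MRI-like intensity; CT in HU).
#' @param structures A `structure_set`.
#' @param scts Named list of sCT `volume_grid`s (HU).
#' @param doses Named list of dose `volume_grid`s (Gy).
#' @param truth Optional list of generator ground truth (phantom only).
#' @return An object of class `patient_case`.
#' @export
patient_case <- function(id, mri, ct, structures, scts = list(),
                         doses = list(), truth = list()) {
  stop_if_incompatible(mri, ct, "mri/ct")
  if (!same_geometry(mri, structures$geometry))
    stop("structures not geometry-compatible with images", call. = FALSE)
  for (s in scts) stop_if_incompatible(mri, s, "mri/sct")
  for (d in doses) stop_if_incompatible(mri, d, "mri/dose")
  structure(list(id = id, mri = mri, ct = ct, structures = structures,
                 scts = scts, doses = doses, truth = truth),
            class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case> %s: %s grid, sCTs [%s], doses [%s]\n",
              x$id, paste(dim(x$ct$values), collapse = "x"),
              paste(names(x$scts), collapse = ", "),
              paste(names(x$doses), collapse = ", ")))
  invisible(x)
}
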