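#' Bulk-density HU assignment
#'
#' Tissue-class HU values for the bulk-density sCT: water-equivalent soft
#' tissue (0 HU), bone (350 HU) and rectal air (-450 HU), plus the MRI
#' threshold used to segment air inside the rectum, expressed as a fraction
#' of the median MRI intensity inside the body.
#'
#' @param soft_hu,bone_hu,air_hu Assigned HU values (must satisfy
#'   `air_hu < soft_hu < bone_hu`).
#' @param air_threshold Fraction of the body-median MRI intensity below which
#'   a rectal voxel is classified as air.
#' @param background_hu HU assigned outside the body contour.
#' @return An object of class `bulk_assignment`.
#' @export
bulk_assignment <- function(soft_hu = 0, bone_hu = 350, air_hu = -450,
                            air_threshold = 0.3, background_hu = -1000) {
  if (!(air_hu < soft_hu && soft_hu < bone_hu))
    stop("require air_hu < soft_hu < bone_hu", call. = FALSE)
  structure(list(soft_hu = soft_hu, bone_hu = bone_hu, air_hu = air_hu,
                 air_threshold = air_threshold, background_hu = background_hu),
            class = "bulk_assignment")
}

#' Segment rectal air from the MRI
#'
#' Air appears dark on MRI: voxels inside the rectum whose intensity falls
#' below `air_threshold` times the median body MRI intensity are labelled
#' air. The returned mask is always contained in the rectum mask.
#'
#' @param mri MRI `volume_grid`.
#' @param rectum Logical rectum mask (or `volume_grid`).
#' @param body Logical body mask used for the median.
#' @param assignment A `bulk_assignment`.
#' @return Logical 3D mask.
#' @export
segment_rectal_air <- function(mri, rectum, body, assignment = bulk_assignment()) {
  rectum <- as_mask(rectum); body <- as_mask(body)
  if (!any(rectum)) stop("empty rectum mask", call. = FALSE)
  thr <- assignment$air_threshold * stats::median(mri$values[body])
  rectum & (mri$values < thr)
}

#' Generate a bulk-density synthetic CT
#'
#' Piecewise-constant sCT: `bone_hu` on bones, `air_hu` on the segmented air,
#' `soft_hu` on the remainder of the body, `background_hu` outside. On
#' overlap the precedence is air > bone > soft (a warning is logged when air
#' and bone masks intersect).
#'
#' @param structures A `structure_set` with `body` and `bones` masks.
#' @param air Logical air mask (e.g. from [segment_rectal_air()]).
#' @param assignment A `bulk_assignment`.
#' @return A `volume_grid` (HU).
#' @export
generate_bulk_sct <- function(structures, air = NULL,
                              assignment = bulk_assignment()) {
  body <- get_mask(structures, "body")
  bones <- get_mask(structures, "bones")
  if (is.null(air)) air <- array(FALSE, dim(body))
  air <- as_mask(air)
  if (any(air & bones))
    warning("air and bone masks overlap; air takes precedence")
  vals <- array(assignment$background_hu, dim(body))
  vals[body] <- assignment$soft_hu
  vals[bones & body] <- assignment$bone_hu
  vals[air & body] <- assignment$air_hu
  g <- structures$geometry
  volume_grid(vals, g$spacing, g$origin, "HU")
}

#' Cohort-mean HU inside a mask (optional bulk-value helper)
#'
#' Computes the mean CT number over a named structure across a cohort, the
#' quantity from which bulk assignments can be re-derived. Not part of the
#' default bulk path.
#'
#' @param cases List of `patient_case`s.
#' @param structure Structure name (e.g. `"bones"`).
#' @return Mean HU (scalar).
#' @export
cohort_mask_mean_hu <- function(cases, structure) {
  vals <- unlist(lapply(cases, function(cs)
    cs$ct$values[get_mask(cs$structures, structure)]))
  mean(vals)
}
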