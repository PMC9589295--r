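#' Crop the body mask to the dosimetric pelvis
#'
#' Restricts the body mask to the superior--inferior (z) range spanned by
#' the rectum extended by 2 cm above and below, focusing the dose analysis
#' on the region of the dose distribution.
#'
#' @param body,rectum Logical masks (or `volume_grid`s) on the same grid.
#' @param spacing Voxel spacing in mm.
#' @param origin Grid origin in mm.
#' @param margin_mm Extension beyond the rectum extent (default 20 mm).
#' @return Logical mask.
#' @export
crop_pelvis <- function(body, rectum, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), margin_mm = 20) {
  if (inherits(body, "volume_grid")) {
    spacing <- body$spacing; origin <- body$origin
  }
  body <- as_mask(body); rectum <- as_mask(rectum)
  if (!any(rectum)) stop("empty rectum mask", call. = FALSE)
  kz <- which(apply(rectum, 3, any))
  zmm <- origin[3] + (seq_len(dim(body)[3]) - 1) * spacing[3]
  zlo <- zmm[min(kz)] - margin_mm
  zhi <- zmm[max(kz)] + margin_mm
  keep <- zmm >= zlo & zmm <= zhi
  out <- body
  out[, , !keep] <- FALSE
  out
}

#' Mean-absolute-dose-error volume histogram (MADE-VH)
#'
#' Cumulative histogram built like a DVH but from the voxel-wise mean
#' absolute dose error map: for each threshold t, the percentage of the ROI
#' volume with vMAE >= t. `V(0.5)` and `V(1)` are the conventional summary
#' criteria.
#'
#' @param vmae_dose `volume_grid` (Gy) of voxel-wise mean absolute dose
#'   error.
#' @param roi Logical ROI mask.
#' @param bin_width Threshold step in Gy.
#' @param roi_name Label stored with the histogram.
#' @return An object of class `made_vh`: `thresholds` (Gy), `percent`
#'   (non-increasing, 100 at t = 0), `roi`.
#' @export
made_vh <- function(vmae_dose, roi, bin_width = 0.05, roi_name = "roi") {
  roi <- as_mask(roi)
  if (!any(roi)) stop("empty ROI mask", call. = FALSE)
  vals <- vmae_dose$values[roi]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("ROI contains no defined vMAE values", call. = FALSE)
  tmax <- max(vals, 0)
  thresholds <- seq(0, tmax + bin_width, by = bin_width)
  percent <- vapply(thresholds, function(t) 100 * mean(vals >= t), 0.0)
  structure(list(thresholds = thresholds, percent = percent, roi = roi_name,
                 n = length(vals)),
            class = "made_vh")
}

#' Volume fraction with error at least a threshold
#'
#' Reads `V(t)` off a [made_vh()] curve at an arbitrary threshold (exact
#' re-count, not interpolation of the binned curve).
#'
#' @param x A `made_vh`.
#' @param threshold_gy Threshold in Gy.
#' @return Percent of ROI volume (0-100).
#' @export
made_vh_at <- function(x, threshold_gy) {
  i <- which(abs(x$thresholds - threshold_gy) < 1e-9)
  if (length(i)) return(x$percent[i[1]])
  stats::approx(x$thresholds, x$percent, xout = threshold_gy, rule = 2)$y
}

#' @export
print.made_vh <- function(x, ...) {
  cat(sprintf("<made_vh> %s: V0.5Gy %.2f%%, V1Gy %.2f%% (%d voxels)\n",
              x$roi, made_vh_at(x, 0.5), made_vh_at(x, 1), x$n))
  invisible(x)
}

#' DVH criteria of a dose in an ROI
#'
#' Dmean and Dx% for x in 2, 50, 95, where Dx% is the minimum dose received
#' by the hottest x% of the ROI volume, i.e. the (100-x)th percentile of the
#' in-ROI dose, computed by linear interpolation of the sorted dose values.
#'
#' @param dose `volume_grid` (Gy).
#' @param roi Logical ROI mask.
#' @return Named list: `dmean`, `d2`, `d50`, `d95` (Gy).
#' @export
dvh_criteria <- function(dose, roi) {
  roi <- as_mask(roi)
  if (!any(roi)) stop("empty ROI mask", call. = FALSE)
  v <- dose$values[roi]
  q <- stats::quantile(v, probs = 1 - c(2, 50, 95) / 100, names = FALSE,
                       type = 7)
  list(dmean = mean(v), d2 = q[1], d50 = q[2], d95 = q[3])
}

#' Absolute DVH-criteria differences between two doses
#'
#' @param ref,pred Dose `volume_grid`s (Gy) on the same grid.
#' @param rois Named list of logical ROI masks.
#' @return data.frame with columns `roi`, `metric`, `ref`, `pred`,
#'   `abs_diff`.
#' @export
criteria_diff <- function(ref, pred, rois) {
  stop_if_incompatible(ref, pred)
  rows <- lapply(names(rois), function(rn) {
    a <- dvh_criteria(ref, rois[[rn]])
    b <- dvh_criteria(pred, rois[[rn]])
    data.frame(roi = rn, metric = c("dmean", "d2", "d50", "d95"),
               ref = unlist(a), pred = unlist(b),
               abs_diff = abs(unlist(a) - unlist(b)),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' 3D gamma analysis
#'
#' Pointwise gamma index combining relative dose difference and
#' distance-to-agreement: for each evaluable reference voxel (reference dose
#' at or above `threshold_pct`% of the maximum reference dose),
#' gamma = min over the search neighbourhood of
#' sqrt((dose diff / delta)^2 + (distance / dta)^2), with delta equal to
#' `dose_pct`% of the local reference dose (`"local"`) or of the maximum
#' reference dose (`"global"`). The search is truncated at 3x dta (gamma
#' values are capped beyond), with subvoxel refinement by trilinear
#' interpolation of the evaluated dose on a search lattice at least 3x
#' finer than the voxel grid and 10x finer than the DTA criterion (the
#' gamma optimum is quadratic around its argmin, so the lattice spacing
#' must be well below the DTA scale). Pass criterion: gamma <= 1.
#'
#' @param ref_dose,eval_dose Geometry-compatible dose `volume_grid`s (Gy).
#' @param dose_pct Dose-difference criterion in percent (default 1).
#' @param dta_mm Distance-to-agreement criterion in mm (default 1).
#' @param normalization `"local"` or `"global"`.
#' @param threshold_pct Low-dose threshold in percent of the maximum
#'   reference dose (default 10).
#' @return An object of class `gamma_result`: `gamma` (`volume_grid`, NA
#'   below threshold), `pass_rate` (percent), `mean_gamma`, `n_evaluated`,
#'   `criteria`.
#' @export
gamma_3d <- function(ref_dose, eval_dose, dose_pct = 1, dta_mm = 1,
                     normalization = c("local", "global"),
                     threshold_pct = 10) {
  normalization <- match.arg(normalization)
  stop_if_incompatible(ref_dose, eval_dose)
  d <- dim(ref_dose$values)
  sample_step <- min(min(ref_dose$spacing) / 3, dta_mm / 10)
  g <- cpp_gamma(as.double(ref_dose$values), as.double(eval_dose$values),
                 d, ref_dose$spacing, dose_pct, dta_mm,
                 as.integer(normalization == "local"), threshold_pct,
                 3 * dta_mm, sample_step)
  dim(g) <- d
  ev <- !is.na(g)
  if (!any(ev)) stop("no voxel above the dose threshold", call. = FALSE)
  structure(list(gamma = volume_grid(g, ref_dose$spacing, ref_dose$origin,
                                     "unitless"),
                 pass_rate = 100 * mean(g[ev] <= 1),
                 mean_gamma = mean(g[ev]),
                 n_evaluated = sum(ev),
                 criteria = list(dose_pct = dose_pct, dta_mm = dta_mm,
                                 normalization = normalization,
                                 threshold_pct = threshold_pct)),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cr <- x$criteria
  cat(sprintf("<gamma_result> %s %g%%/%gmm (thr %g%%): pass %.2f%%, mean %.3f (%d voxels)\n",
              cr$normalization, cr$dose_pct, cr$dta_mm, cr$threshold_pct,
              x$pass_rate, x$mean_gamma, x$n_evaluated))
  invisible(x)
}
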