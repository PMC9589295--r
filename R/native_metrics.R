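#' Per-voxel error maps between a reference and a prediction
#'
#' Computes the signed error `e = ref - pred` (positive where the prediction
#' underestimates the reference), the absolute error `ae = |e|`, and the
#' absolute percent error `ape = |e / ref|`. APE is undefined where the
#' reference magnitude falls below a unit-dependent epsilon (1 HU, 0.01 Gy);
#' those voxels are excluded via the validity mask.
#'
#' @param ref,pred Geometry- and unit-compatible `volume_grid`s.
#' @return An object of class `error_volume` with fields `e`, `ae`, `ape`
#'   (all `volume_grid`s), `valid` (logical mask) and `unit`.
#' @export
voxel_errors <- function(ref, pred) {
  stop_if_incompatible(ref, pred)
  stop_if_unit_mismatch(ref, pred)
  eps <- ape_eps(ref$unit)
  e <- ref$values - pred$values
  ae <- abs(e)
  valid <- abs(ref$values) >= eps
  ape <- array(NA_real_, dim(e))
  ape[valid] <- ae[valid] / abs(ref$values[valid])
  structure(list(e = with_values(ref, e),
                 ae = with_values(ref, ae),
                 ape = with_values(ref, ape, unit = "unitless"),
                 valid = valid, unit = ref$unit),
            class = "error_volume")
}

ape_eps <- function(unit) switch(unit, HU = 1, Gy = 0.01, 1e-8)

#' @export
print.error_volume <- function(x, ...) {
  cat(sprintf("<error_volume> [%s] mae %.4g, me %.4g over full grid\n",
              x$unit, mean(x$ae$values), mean(x$e$values)))
  invisible(x)
}

#' Regional mean errors (MAE, ME, MAPE)
#'
#' Averages the voxel error maps over a region of interest. MAPE is averaged
#' over the intersection of the mask with the APE validity mask.
#'
#' @param errs An `error_volume`.
#' @param mask Logical ROI mask (or `volume_grid`).
#' @return Named list: `mae`, `me`, `mape`, plus the voxel counts `n` and
#'   `n_mape` actually used.
#' @export
regional_summary <- function(errs, mask) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  vmask <- mask & errs$valid
  list(mae = mean(errs$ae$values[mask]),
       me = mean(errs$e$values[mask]),
       mape = if (any(vmask)) mean(errs$ape$values[vmask]) else NA_real_,
       n = sum(mask), n_mape = sum(vmask))
}

#' Per-organ error table
#'
#' Convenience wrapper producing a long-format data frame of regional MAE,
#' ME and MAPE for a set of named structures.
#'
#' @param errs An `error_volume`.
#' @param structures A `structure_set`.
#' @param regions Character vector of structure names.
#' @return data.frame with columns `region`, `metric`, `value`, `n`.
#' @export
regional_table <- function(errs, structures,
                           regions = intersect(c("body", "bones", "bladder",
                                                 "rectum", "prostate"),
                                               names(structures$masks))) {
  rows <- lapply(regions, function(r) {
    s <- regional_summary(errs, get_mask(structures, r))
    data.frame(region = r,
               metric = c("mae", "me", "mape"),
               value = c(s$mae, s$me, s$mape),
               n = c(s$n, s$n, s$n_mape))
  })
  do.call(rbind, rows)
}
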