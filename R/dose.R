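#' Beam configuration for the analytic dose surrogate
#'
#' Deterministic ray-cast dose engine standing in for a treatment planning
#' system: coplanar beams at equally spaced gantry angles deposit dose along
#' parallel rays aimed at the target centroid, attenuated exponentially by
#' the cumulative relative electron density integrated along each ray, with
#' a sigmoid lateral field edge (Gaussian-like penumbra). The sequential
#' prescription is 50 Gy to CTV1 plus a 28 Gy boost to CTV2 (78 Gy total).
#'
#' @param n_beams Number of coplanar beams (default 7).
#' @param prescription_ctv1 Plan-1 dose to CTV1 in Gy.
#' @param boost_ctv2 Plan-2 boost to CTV2 in Gy.
#' @param mu Linear attenuation per mm per unit relative electron density.
#' @param density_points HU -> relative electron density calibration nodes
#'   (piecewise linear, extrapolated with the last slope, clamped at 0).
#' @param penumbra_mm Lateral sigmoid width in mm.
#' @param field_margin_mm Field radius margin beyond the target in mm.
#' @param step_mm Ray-marching step (default half the smallest voxel).
#' @return An object of class `beam_config`.
#' @export
beam_config <- function(n_beams = 7L, prescription_ctv1 = 50, boost_ctv2 = 28,
                        mu = 0.005,
                        density_points = cbind(hu = c(-1000, 0, 1000),
                                               rho = c(0, 1, 1.6)),
                        penumbra_mm = 3, field_margin_mm = 5, step_mm = NULL) {
  if (mu < 0) stop("attenuation must be >= 0", call. = FALSE)
  structure(list(n_beams = as.integer(n_beams),
                 prescription_ctv1 = prescription_ctv1,
                 boost_ctv2 = boost_ctv2,
                 total = prescription_ctv1 + boost_ctv2,
                 mu = mu, density_points = density_points,
                 penumbra_mm = penumbra_mm, field_margin_mm = field_margin_mm,
                 step_mm = step_mm),
            class = "beam_config")
}

#' HU to relative electron density
#'
#' Piecewise-linear interpolation through the configured calibration nodes,
#' extrapolated with the boundary slopes and clamped at zero.
#'
#' @param hu Numeric HU values (vector or array).
#' @param config A `beam_config`.
#' @return Relative electron densities, same shape as `hu`.
#' @export
hu_to_density <- function(hu, config = beam_config()) {
  pts <- config$density_points
  out <- stats::approx(pts[, 1], pts[, 2], xout = as.numeric(hu), rule = 1)$y
  n <- nrow(pts)
  lo_slope <- (pts[2, 2] - pts[1, 2]) / (pts[2, 1] - pts[1, 1])
  hi_slope <- (pts[n, 2] - pts[n - 1, 2]) / (pts[n, 1] - pts[n - 1, 1])
  below <- as.numeric(hu) < pts[1, 1]
  above <- as.numeric(hu) > pts[n, 1]
  out[below] <- pts[1, 2] + (as.numeric(hu)[below] - pts[1, 1]) * lo_slope
  out[above] <- pts[n, 2] + (as.numeric(hu)[above] - pts[n, 1]) * hi_slope
  out <- pmax(out, 0)
  if (is.array(hu)) dim(out) <- dim(hu)
  out
}

beam_directions <- function(n_beams) {
  theta <- 2 * pi * (seq_len(n_beams) - 1) / n_beams
  cbind(x = sin(theta), y = cos(theta), z = 0)
}

mask_centroid_mm <- function(mask, spacing, origin = c(0, 0, 0)) {
  idx <- which(mask, arr.ind = TRUE)
  (colMeans(idx) - 1) * spacing + origin
}

#' Unit-weight dose of a single beam
#'
#' Exposes the raw ray-cast kernel: exponential depth attenuation of the
#' relative electron density with a sigmoid lateral field edge. Used by
#' [compute_dose()] and directly useful for checking the engine against the
#' closed-form attenuation profile.
#'
#' @param image `volume_grid` in HU.
#' @param direction Unit propagation direction (length-3).
#' @param axis_point Point on the beam axis in mm.
#' @param field_radius Field radius in mm.
#' @param config A `beam_config`.
#' @return A `volume_grid` (unitless).
#' @export
beam_unit_dose <- function(image, direction, axis_point, field_radius,
                           config = beam_config()) {
  rho <- hu_to_density(image$values, config)
  step <- config$step_mm %||% (min(image$spacing) / 2)
  out <- cpp_ray_dose(as.double(rho), dim(rho), image$spacing,
                      as.numeric(direction), as.numeric(axis_point),
                      config$mu, field_radius, config$penumbra_mm, step, 1e-4)
  dim(out) <- dim(rho)
  volume_grid(out, image$spacing, image$origin, "unitless")
}

plan_raw_dose <- function(image, target_mask, config) {
  dirs <- beam_directions(config$n_beams)
  axis_point <- mask_centroid_mm(target_mask, image$spacing, image$origin)
  # field radius: max perpendicular extent of the target over all beams + margin
  idx <- which(target_mask, arr.ind = TRUE)
  pts <- sweep((idx - 1) %*% diag(image$spacing), 2,
               -image$origin, FUN = "+")
  radius <- 0
  for (b in seq_len(config$n_beams)) {
    d <- dirs[b, ]
    rel <- sweep(pts, 2, axis_point)
    proj <- as.numeric(rel %*% d)
    perp <- rel - outer(proj, d)
    radius <- max(radius, sqrt(max(rowSums(perp^2))))
  }
  radius <- radius + config$field_margin_mm
  total <- array(0, dim(image$values))
  for (b in seq_len(config$n_beams)) {
    total <- total + beam_unit_dose(image, dirs[b, ], axis_point,
                                    radius, config)$values
  }
  list(dose = total, axis_point = axis_point, radius = radius)
}

#' Calibrate beam weights on the reference CT
#'
#' Scales the two plans once on the reference image so that the median CTV1
#' dose from plan 1 equals the CTV1 prescription and the median total CTV2
#' dose equals the full prescription. The returned weights are reused
#' verbatim for any sCT input, mirroring clinical practice of recomputing a
#' fixed plan on the synthetic image.
#'
#' @param image Reference CT `volume_grid` (HU).
#' @param structures `structure_set` with `ctv1` and `ctv2`.
#' @param config A `beam_config`.
#' @return An object of class `beam_weights` (`s1`, `s2`, beam geometry).
#' @export
calibrate_beams <- function(image, structures, config = beam_config()) {
  ctv1 <- get_mask(structures, "ctv1")
  ctv2 <- get_mask(structures, "ctv2")
  if (!any(ctv1) || !any(ctv2)) stop("empty CTV mask", call. = FALSE)
  p1 <- plan_raw_dose(image, ctv1, config)
  p2 <- plan_raw_dose(image, ctv2, config)
  s1 <- config$prescription_ctv1 / stats::median(p1$dose[ctv1])
  f <- function(s2) stats::median(s1 * p1$dose[ctv2] + s2 * p2$dose[ctv2]) -
    config$total
  hi <- config$total / stats::median(p2$dose[ctv2]) * 2 + 1
  s2 <- stats::uniroot(f, c(0, hi), tol = 1e-12)$root
  structure(list(s1 = s1, s2 = s2,
                 plan1 = list(axis_point = p1$axis_point, radius = p1$radius),
                 plan2 = list(axis_point = p2$axis_point, radius = p2$radius),
                 config = config),
            class = "beam_weights")
}

#' Compute the surrogate dose on an image
#'
#' With `weights = NULL` the beams are calibrated on this image first
#' (reference-CT usage); passing a `beam_weights` object reuses a previous
#' calibration unchanged (sCT usage), so HU errors in the image propagate
#' into dose errors.
#'
#' @param image `volume_grid` (HU).
#' @param structures `structure_set` with `ctv1`, `ctv2` (used for geometry
#'   when calibrating).
#' @param config A `beam_config`.
#' @param weights Optional `beam_weights` from [calibrate_beams()].
#' @return A `volume_grid` (Gy) with the `beam_weights` attached as
#'   attribute `"weights"`.
#' @export
compute_dose <- function(image, structures, config = beam_config(),
                         weights = NULL) {
  if (is.null(weights)) weights <- calibrate_beams(image, structures, config)
  cfg <- weights$config
  dirs <- beam_directions(cfg$n_beams)
  total <- array(0, dim(image$values))
  for (plan in c("plan1", "plan2")) {
    s <- if (plan == "plan1") weights$s1 else weights$s2
    geo <- weights[[plan]]
    for (b in seq_len(cfg$n_beams)) {
      total <- total + s * beam_unit_dose(image, dirs[b, ], geo$axis_point,
                                          geo$radius, cfg)$values
    }
  }
  out <- volume_grid(total, image$spacing, image$origin, "Gy")
  attr(out, "weights") <- weights
  out
}
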