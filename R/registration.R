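#' Signed Euclidean distance map of a mask
#'
#' Voxel-center distances in mm: positive outside the mask (distance to the
#' nearest mask voxel center), negative inside (distance to the nearest
#' background voxel center). Anisotropic spacing is respected exactly.
#'
#' @param mask Logical 3D array or `volume_grid`.
#' @param spacing Voxel spacing in mm (ignored when `mask` is a
#'   `volume_grid`).
#' @param origin Grid origin (mm).
#' @return A `volume_grid` (mm, tagged unitless).
#' @export
distance_map <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (inherits(mask, "volume_grid")) {
    spacing <- mask$spacing; origin <- mask$origin; mask <- as_mask(mask)
  }
  if (!any(mask)) stop("empty mask", call. = FALSE)
  d_out <- sqrt(cpp_edt_sq(mask, dim(mask), spacing))
  d_in <- sqrt(cpp_edt_sq(!mask, dim(mask), spacing))
  vals <- d_out - d_in
  dim(vals) <- dim(mask)
  volume_grid(vals, spacing, origin, "unitless")
}

mask_surface <- function(mask) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by > 0) { idx_dst[[ax]] <- seq(1 + by, d[ax]); idx_src[[ax]] <- seq(1, d[ax] - by) }
    else { idx_dst[[ax]] <- seq(1, d[ax] + by); idx_src[[ax]] <- seq(1 - by, d[ax]) }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  interior <- mask
  for (ax in 1:3) interior <- interior & shift(mask, ax, 1) & shift(mask, ax, -1)
  # voxels at the volume edge count as surface
  edge <- array(FALSE, d)
  edge[c(1, d[1]), , ] <- TRUE; edge[, c(1, d[2]), ] <- TRUE; edge[, , c(1, d[3])] <- TRUE
  mask & (!interior | edge)
}

mask_connected <- function(mask) {
  # flood fill by 26-connectivity: iterate 3x3x3 box dilation within the mask
  d <- dim(mask)
  dilate1 <- function(m, ax) {
    out <- m
    idx <- lapply(d, seq_len)
    up <- idx; up[[ax]] <- pmin(idx[[ax]] + 1L, d[ax])
    dn <- idx; dn[[ax]] <- pmax(idx[[ax]] - 1L, 1L)
    out | m[up[[1]], up[[2]], up[[3]]] | m[dn[[1]], dn[[2]], dn[[3]]]
  }
  reach <- array(FALSE, d)
  reach[which(mask)[1]] <- TRUE
  repeat {
    grown <- reach
    for (ax in 1:3) grown <- dilate1(grown, ax)
    grown <- grown & mask
    if (identical(grown, reach)) break
    reach <- grown
  }
  all(reach[mask])
}

laplace_solve_masked <- function(mask, sink, spacing, tol = 1e-5,
                                 max_iter = 5000L) {
  lab <- array(0L, dim(mask))
  lab[mask] <- 1L
  lab[mask_surface(mask)] <- 2L
  lab[sink] <- 3L
  out <- cpp_laplace(lab, dim(mask), spacing, tol, max_iter)
  dim(out) <- dim(mask)
  out
}

#' Laplace field of a tubular structure
#'
#' Solves the discrete Laplace equation inside the mask with Dirichlet
#' boundary conditions: 1 on the mask surface and 0 on the central path
#' extracted as the chain of slice-wise in-plane centroids along the tube
#' (z) axis. The result is a normalized distance-like field in [0, 1] from
#' the central path to the wall.
#'
#' @param mask Logical 3D array or `volume_grid` (connected tubular region).
#' @param spacing Voxel spacing in mm.
#' @param origin Grid origin.
#' @param tol Gauss-Seidel stopping tolerance (max update).
#' @return A `volume_grid`; `NA` outside the mask.
#' @export
laplace_field_tubular <- function(mask, spacing = c(1, 1, 1),
                                  origin = c(0, 0, 0), tol = 1e-5) {
  if (inherits(mask, "volume_grid")) {
    spacing <- mask$spacing; origin <- mask$origin; mask <- as_mask(mask)
  }
  if (!any(mask)) stop("empty mask", call. = FALSE)
  if (!mask_connected(mask)) stop("mask is disconnected", call. = FALSE)
  d <- dim(mask)
  sink <- array(FALSE, d)
  snapped <- FALSE
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    ij <- which(sl, arr.ind = TRUE)
    ci <- round(mean(ij[, 1])); cj <- round(mean(ij[, 2]))
    if (!sl[ci, cj]) {
      snapped <- TRUE
      d2 <- (ij[, 1] - ci)^2 + (ij[, 2] - cj)^2
      best <- which.min(d2)
      ci <- ij[best, 1]; cj <- ij[best, 2]
    }
    sink[ci, cj, k] <- TRUE
  }
  if (snapped) warning("central-path centroid snapped to nearest in-mask voxel")
  vals <- laplace_solve_masked(mask, sink, spacing, tol)
  volume_grid(vals, spacing, origin, "unitless")
}

#' Laplace field of a blob-like structure
#'
#' As [laplace_field_tubular()] but with the sink at the structure's
#' barycenter voxel (snapped to the nearest in-mask voxel when the barycenter
#' falls outside a non-convex mask).
#'
#' @inheritParams laplace_field_tubular
#' @return A `volume_grid`; `NA` outside the mask.
#' @export
laplace_field_radial <- function(mask, spacing = c(1, 1, 1),
                                 origin = c(0, 0, 0), tol = 1e-5) {
  if (inherits(mask, "volume_grid")) {
    spacing <- mask$spacing; origin <- mask$origin; mask <- as_mask(mask)
  }
  if (!any(mask)) stop("empty mask", call. = FALSE)
  if (!mask_connected(mask)) stop("mask is disconnected", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  c0 <- round(colMeans(idx))
  if (!mask[c0[1], c0[2], c0[3]]) {
    warning("barycenter outside mask; snapped to nearest in-mask voxel")
    d2 <- colSums((t(idx) - c0)^2)
    c0 <- idx[which.min(d2), ]
  }
  sink <- array(FALSE, dim(mask))
  sink[c0[1], c0[2], c0[3]] <- TRUE
  vals <- laplace_solve_masked(mask, sink, spacing, tol)
  volume_grid(vals, spacing, origin, "unitless")
}

# interior profile of an organ in [0, 1]: 0 at the surface, rising to 1
# deep inside; Laplace-based when a field is given (rectum: distance to the
# central path; prostate: distance to the barycenter), depth-ramp otherwise
organ_profile <- function(mask, spacing, depth_mm = 8, laplace = NULL) {
  mask <- as_mask(mask)
  g <- array(0, dim(mask))
  if (!is.null(laplace)) {
    lv <- laplace$values
    g[mask] <- 1 - lv[mask]
    g[mask & is.na(lv)] <- 0
  } else {
    sd_map <- distance_map(mask, spacing)$values
    g[mask] <- pmin(-sd_map[mask] / depth_mm, 1)
  }
  g
}

# backwards-compatible ramp descriptor (used by the bone refinement):
# 1 deep inside, 0.5 at the surface, fading to 0 delta mm outside
organ_descriptor <- function(mask, spacing, delta_mm = 10, laplace = NULL) {
  sd_map <- distance_map(mask, spacing)$values
  g <- pmin(pmax(0.5 - sd_map / (2 * delta_mm), 0), 1)
  if (!is.null(laplace)) {
    lv <- laplace$values
    inside <- as_mask(mask)
    g[inside] <- 0.5 + 0.5 * (1 - lv[inside])
    g[inside & is.na(lv)] <- 1
  }
  g
}

#' Build the structural description of a patient
#'
#' Each organ gets an interior scalar profile (the Laplace field relative
#' to the central path for the rectum and to the barycenter for the
#' prostate; a signed-distance depth ramp for body, bones and bladder),
#' affinely rescaled into a disjoint intensity band and summed. Because the
#' organ masks are disjoint, the bands do not overlap spatially and every
#' organ surface carries its own sharp, unambiguous contrast step: all
#' registration stages optimize one consistent image. The merged volume
#' alpha-blends this banded description with the intensity-normalized MRI
#' and drives the whole-pelvis stage; the banded sum alone (`organs`
#' channel) drives the organ stages; the per-organ profiles localize them.
#'
#' @param mri MRI `volume_grid`.
#' @param structures `structure_set` with body, bones, bladder, rectum,
#'   prostate.
#' @param w_sd Blend weight of the structural description against the MRI
#'   (0 = MRI only, 1 = structures only).
#' @param bands Named list of `c(lo, hi)` intensity bands per organ.
#' @param depth_mm Interior depth over which the ramp profiles saturate.
#' @return An object of class `structural_description` with `merged`
#'   (`volume_grid`) and `channels` (named list of `volume_grid`s: one
#'   profile per organ plus `organs` and `pelvis`).
#' @export
build_sd <- function(mri, structures, w_sd = 0.5,
                     bands = list(body = c(0.05, 0.15), bones = c(0.2, 0.35),
                                  rectum = c(0.4, 0.55),
                                  prostate = c(0.6, 0.75),
                                  bladder = c(0.8, 0.95)),
                     depth_mm = 8) {
  for (org in c("body", "bones", "bladder", "rectum", "prostate"))
    get_mask(structures, org)
  sp <- structures$geometry$spacing
  g_fields <- list(
    body = organ_profile(get_mask(structures, "body"), sp, 30),
    bones = organ_profile(get_mask(structures, "bones"), sp, depth_mm),
    bladder = organ_profile(get_mask(structures, "bladder"), sp, depth_mm),
    rectum = organ_profile(get_mask(structures, "rectum"), sp, depth_mm,
                           laplace = laplace_field_tubular(
                             get_mask(structures, "rectum"), sp)),
    prostate = organ_profile(get_mask(structures, "prostate"), sp, depth_mm,
                             laplace = laplace_field_radial(
                               get_mask(structures, "prostate"), sp)))
  sd_sum <- array(0, dim(g_fields$body))
  contribs <- list()
  for (org in names(bands)) {
    b <- bands[[org]]
    mask <- get_mask(structures, org)
    contrib <- array(0, dim(mask))
    contrib[mask] <- b[1] + g_fields[[org]][mask] * (b[2] - b[1])
    contribs[[org]] <- contrib
    sd_sum <- sd_sum + contrib
  }
  body <- get_mask(structures, "body")
  q <- stats::quantile(mri$values[body], c(0.01, 0.99), names = FALSE)
  mri_norm <- pmin(pmax((mri$values - q[1]) / max(q[2] - q[1], 1e-9), 0), 1)
  merged <- (1 - w_sd) * mri_norm + w_sd * sd_sum
  mk <- function(v) volume_grid(v, sp, structures$geometry$origin, "unitless")
  channels <- list(bladder = mk(g_fields$bladder), pelvis = mk(merged),
                   prostate = mk(g_fields$prostate),
                   rectum = mk(g_fields$rectum), bones = mk(g_fields$bones),
                   organs = mk(sd_sum))
  structure(list(merged = mk(merged), channels = channels,
                 contributions = lapply(contribs, mk), bands = bands,
                 w_sd = w_sd),
            class = "structural_description")
}

#' Select the cohort template by median organ volumes
#'
#' Scores each patient by the summed relative deviation of its bladder,
#' rectum and prostate volumes from the cohort medians and returns the
#' argmin; ties break to the lowest patient id.
#'
#' @param cases List of `patient_case`s (>= 3).
#' @return Patient id (character scalar).
#' @export
select_template <- function(cases) {
  if (length(cases) < 3) stop("need at least 3 patients", call. = FALSE)
  organs <- c("bladder", "rectum", "prostate")
  vols <- sapply(organs, function(org)
    vapply(cases, function(cs)
      mask_volume_cm3(get_mask(cs$structures, org), cs$ct$spacing), 0.0))
  med <- apply(vols, 2, stats::median)
  score <- rowSums(abs(sweep(vols, 2, med)) %*% diag(1 / med))
  ids <- vapply(cases, `[[`, "", "id")
  names(score) <- ids
  cand <- ids[score <= min(score) + 1e-12]
  unname(sort(cand)[1])
}

#' Translation-only rigid prealignment
#'
#' Matches body-mask centers of mass, then refines the translation by a
#' local mean-squared-difference search (+/- `search_mm` in 1 mm steps) on
#' 4x-downsampled merged structural descriptions.
#'
#' @param moving,fixed Merged SD `volume_grid`s.
#' @param moving_body,fixed_body Logical body masks.
#' @param search_mm Half-width of the local refinement search.
#' @return A constant `vector_field` (case -> template).
#' @export
rigid_translate <- function(moving, fixed, moving_body, fixed_body,
                            search_mm = 5) {
  moving_body <- as_mask(moving_body); fixed_body <- as_mask(fixed_body)
  if (!any(moving_body) || !any(fixed_body))
    stop("empty body mask", call. = FALSE)
  stop_if_incompatible(moving, fixed)
  t0 <- mask_centroid_mm(moving_body, moving$spacing) -
    mask_centroid_mm(fixed_body, fixed$spacing)
  # refine on a coarse grid
  f <- 4L
  g <- list(dim = pmax(dim(fixed$values) %/% f, 2L),
            spacing = fixed$spacing * dim(fixed$values) /
              pmax(dim(fixed$values) %/% f, 2L),
            origin = fixed$origin)
  fx <- resample_like(smooth_volume(fixed, fixed$spacing * f / 2), g)
  mv <- resample_like(smooth_volume(moving, moving$spacing * f / 2), g)
  dmv <- dim(mv$values)
  best <- c(0, 0, 0); best_val <- Inf
  steps <- seq(-search_mm, search_mm, by = 1)
  for (dx in steps) for (dy in steps) for (dz in steps) {
    tr <- t0 + c(dx, dy, dz)
    w <- cpp_warp(as.double(mv$values), dmv, mv$spacing,
                  rep(tr[1], prod(dmv)), rep(tr[2], prod(dmv)),
                  rep(tr[3], prod(dmv)), 0L, 0, 1L)
    val <- mean((w - as.double(fx$values))^2)
    if (val < best_val) { best_val <- val; best <- c(dx, dy, dz) }
  }
  tr <- t0 + best
  d <- dim(fixed$values)
  vector_field(array(tr[1], d), array(tr[2], d), array(tr[3], d),
               fixed$spacing, fixed$origin)
}

#' Default staged Demons schedule
#'
#' Registration stages in order (bladder, whole pelvis, prostate, rectum,
#' bones) with per-stage iteration counts at four resolution levels
#' (downsample factors 8, 4, 2, 1) and the Gaussian regularization sigma of
#' 1 voxel. A zero iteration count skips that level.
#'
#' @param iters Named list of length-4 integer vectors per stage.
#' @param sigma Gaussian smoothing sigma of the Demons update field (voxels).
#' @param factors Downsample factors of the four levels (coarse to fine).
#' @return An object of class `stage_schedule`.
#' @export
stage_schedule <- function(iters = list(bladder = c(300, 300, 200, 20),
                                        pelvis = c(200, 200, 100, 0),
                                        prostate = c(200, 200, 150, 5),
                                        rectum = c(100, 100, 100, 5),
                                        bones = c(100, 100, 150, 50)),
                           sigma = 1, factors = c(4, 2, 1, 1)) {
  for (st in names(iters)) {
    if (length(iters[[st]]) != 4L)
      stop("each stage needs exactly 4 resolution levels", call. = FALSE)
    if (any(iters[[st]] < 0))
      stop("iteration counts must be non-negative", call. = FALSE)
  }
  structure(list(stages = names(iters), iters = iters, sigma = sigma,
                 factors = as.integer(factors)),
            class = "stage_schedule")
}

#' One multi-resolution diffeomorphic Demons stage
#'
#' Symmetric-forces Demons with Gaussian smoothing of the update field
#' (sigma in voxels) and compositive field accumulation, run over four
#' resolution levels (downsample factors 8, 4, 2, 1 by default). A level
#' with 0 iterations is skipped. The returned field is the total
#' displacement in mm, initialized from `init`.
#'
#' @param fixed,moving Geometry-compatible `volume_grid`s.
#' @param iterations Integer vector of length 4 (coarse to fine).
#' @param sigma Update-field smoothing sigma in voxels.
#' @param init Optional initial `vector_field` (default zero).
#' @param factors Downsample factors per level.
#' @param max_step_vox Per-iteration displacement cap in voxels.
#' @param total_sigma Additional smoothing sigma (voxels) applied to the
#'   stage's accumulated delta field each iteration (diffusion-like
#'   regularization); one value per resolution level (recycled), annealed
#'   from strong at coarse levels (robust capture) to weak at the finest
#'   (sub-voxel surface precision).
#' @param weight Optional 3D array in [0, 1] attenuating the stage's delta
#'   before composition; organ-driven stages use it to keep their
#'   adjustment local to the organ.
#' @param localize When `TRUE`, additionally restrict the delta to the
#'   neighbourhood (10 mm falloff) of the driving channel's support in
#'   either image, so an organ stage cannot disturb distant structures.
#' @return A `vector_field`.
#' @export
demons_stage <- function(fixed, moving, iterations, sigma = 1, init = NULL,
                         factors = c(8, 4, 2, 1), max_step_vox = 1,
                         total_sigma = c(0.75, 0.5, 0.25, 0.25), weight = NULL,
                         localize = FALSE) {
  stop_if_incompatible(fixed, moving)
  if (any(!is.finite(fixed$values)) || any(!is.finite(moving$values)))
    stop("non-finite values in registration inputs", call. = FALSE)
  if (all(iterations == 0)) return(if (is.null(init)) zero_field(fixed) else init)
  d <- dim(fixed$values)
  # estimate a fresh delta on the init-warped moving image, then compose:
  # pushing the accumulated field itself through the coarse pyramid would
  # erase the fine-scale detail gained by earlier stages
  moving_arr <- moving$values
  if (!is.null(init)) {
    moving_arr <- cpp_warp(as.double(moving$values), d, fixed$spacing,
                           as.double(init$dx), as.double(init$dy),
                           as.double(init$dz), 0L, 0, 1L)
    dim(moving_arr) <- d
  }
  z <- double(prod(d))
  res <- cpp_demons(as.double(fixed$values), as.double(moving_arr), d,
                    fixed$spacing, as.integer(iterations), as.integer(factors),
                    sigma, as.numeric(total_sigma), z, z, z, max_step_vox)
  mk <- function(v) { dim(v) <- d; v }
  delta <- vector_field(mk(res$x), mk(res$y), mk(res$z), fixed$spacing,
                        fixed$origin)
  if (localize) {
    w_loc <- stage_weight(pmax(fixed$values, moving_arr), fixed$spacing)
    weight <- if (is.null(weight)) w_loc else weight * w_loc
  }
  if (!is.null(weight)) {
    # masking a smooth delta can fold space at sharp weight boundaries;
    # one light smoothing pass of the masked delta restores regularity
    sm <- function(v) {
      out <- cpp_gauss(as.double(v * weight), d, rep(0.5, 3))
      dim(out) <- d
      out
    }
    delta$dx <- sm(delta$dx)
    delta$dy <- sm(delta$dy)
    delta$dz <- sm(delta$dz)
  }
  if (is.null(init)) delta else compose_fields(init, delta)
}

#' Full staged registration of one case to the template
#'
#' Pipeline: translation-only rigid alignment (body centers of mass plus
#' local refinement), a coarse free-form prealignment on the bladder
#' descriptor (control-point spacing 16 voxels, mean-squared metric), then
#' staged multi-resolution Demons in the order bladder, whole pelvis,
#' prostate, rectum, bones. Organ stages are driven by that organ's
#' descriptor channel; the whole-pelvis stage by the merged structural
#' description. All stages accumulate into a single composed displacement
#' field (case -> template).
#'
#' @param case,template `patient_case`s.
#' @param schedule A `stage_schedule`.
#' @param case_sd,template_sd Optional precomputed
#'   `structural_description`s.
#' @param w_sd Blend weight passed to [build_sd()] when SDs are built here.
#' @return A `vector_field` mapping template-space coordinates into the
#'   case's native space (backward warping).
#' @export
staged_registration <- function(case, template, schedule = stage_schedule(),
                                case_sd = NULL, template_sd = NULL,
                                w_sd = 0.5) {
  if (is.null(case_sd)) case_sd <- build_sd(case$mri, case$structures, w_sd)
  if (is.null(template_sd))
    template_sd <- build_sd(template$mri, template$structures, w_sd)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("registration stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  f <- run_stage("rigid", rigid_translate(
    case_sd$merged, template_sd$merged,
    get_mask(case$structures, "body"), get_mask(template$structures, "body")))
  f <- run_stage("ffd_prealign", {
    d <- dim(template_sd$channels$bladder$values)
    res <- cpp_ffd_prealign(as.double(template_sd$channels$bladder$values),
                            as.double(case_sd$channels$bladder$values),
                            d, template_sd$channels$bladder$spacing,
                            16L, 40L, 1.0,
                            as.double(f$dx), as.double(f$dy), as.double(f$dz))
    mk <- function(v) { dim(v) <- d; v }
    vector_field(mk(res$x), mk(res$y), mk(res$z), f$spacing, f$origin)
  })
  organ_stages <- c("bladder", "prostate", "rectum", "bones")
  f <- run_stage("landmark_prealign",
                 organ_landmark_field(case, template, f))
  organ_stages <- c("bladder", "prostate", "rectum", "bones")
  aligned <- character(0)
  sp <- template_sd$merged$spacing
  band_sum <- function(sd, which_orgs) {
    v <- sd$contributions$body$values
    for (org in which_orgs) v <- v + sd$contributions[[org]]$values
    with_values(sd$merged, v)
  }
  for (st in schedule$stages) {
    # Organ stages are driven by their own intensity band, the body
    # background, and the bands of organs aligned by earlier stages: an
    # aligned organ sits in force equilibrium and keeps its position, and
    # organs not yet aligned are left out of the drive so they cannot
    # attract this stage's organ into a wrong basin. Each organ stage is
    # initialized by a local centroid snap (per tube section for the
    # rectum, per component for the bones) and restricted to its organ's
    # neighbourhood. The whole-pelvis stage aligns the body outline and
    # soft tissue globally on the body band (plus aligned organs).
    if (st %in% organ_stages) {
      frz <- if (st == "bones")
        freeze_zone(case, template, f, c("bladder", "prostate", "rectum"))
      f <- run_stage(paste0(st, "_snap"),
                     organ_snap(case, template, f, st, freeze = frz))
      drive_f <- band_sum(template_sd, union(st, aligned))
      drive_m <- band_sum(case_sd, union(st, aligned))
      own <- pmax(get_mask(template$structures, st) + 0,
                  warp_volume(get_mask(case$structures, st), f,
                              mode = "nearest") + 0)
      w <- stage_weight(own, sp)
      if (!is.null(frz)) w <- w * frz
    } else {
      drive_f <- band_sum(template_sd, aligned)
      drive_m <- band_sum(case_sd, aligned)
      w <- NULL
    }
    f <- run_stage(st, demons_stage(drive_f, drive_m,
                                    schedule$iters[[st]], schedule$sigma,
                                    init = f, factors = schedule$factors,
                                    weight = w))
    if (st %in% organ_stages) aligned <- union(aligned, st)
  }
  f
}

# smooth [0,1] weight: 1 on/near the channel support, fading to 0 over
# falloff_mm; keeps an organ stage's delta local so it cannot disturb
# previously aligned structures elsewhere
stage_weight <- function(channel_values, spacing, falloff_mm = 10) {
  support <- channel_values > 0.5
  if (!any(support)) return(array(1, dim(channel_values)))
  dist <- sqrt(cpp_edt_sq(support, dim(channel_values), spacing))
  dim(dist) <- dim(channel_values)
  pmin(pmax(1 - dist / falloff_mm, 0), 1)
}

# weighted local translation moving the warped case mask's centroid onto
# the template mask's; the weight fades over falloff_mm so the snap stays
# local to the organ
snap_translation <- function(f, tpl_m, case_m, sp, falloff_mm = 10,
                             freeze = NULL) {
  if (!any(tpl_m) || !any(case_m)) return(f)
  tr <- mask_centroid_mm(case_m, sp) - mask_centroid_mm(tpl_m, sp)
  tr_mag <- sqrt(sum(tr^2))
  if (tr_mag < 0.5) return(f)
  # the weight gradient is |tr|/falloff: keep it below 2/3 so the local
  # translation cannot fold space
  falloff_mm <- max(falloff_mm, 1.5 * tr_mag)
  w0 <- stage_weight(pmax(tpl_m + 0, case_m + 0), sp, falloff_mm)
  if (!is.null(freeze)) w0 <- w0 * freeze
  compose_fields(f, vector_field(tr[1] * w0, tr[2] * w0, tr[3] * w0, sp,
                                 f$origin))
}

# per-stage initialization snap: tube sections for the rectum, connected
# components for the bones, whole-organ centroid otherwise
organ_snap <- function(case, template, f, st, freeze = NULL) {
  sp <- f$spacing
  tpl_m <- get_mask(template$structures, st)
  case_m <- warp_volume(get_mask(case$structures, st), f, mode = "nearest")
  if (!any(case_m)) return(f)
  if (st == "bones") {
    case_comps <- mask_components(case_m)
    cc <- t(vapply(case_comps, mask_centroid_mm, numeric(3), sp))
    for (comp in mask_components(tpl_m)) {
      ct <- mask_centroid_mm(comp, sp)
      j <- which.min(colSums((t(cc) - ct)^2))
      f <- snap_translation(f, comp, case_comps[[j]], sp, freeze = freeze)
      case_m <- warp_volume(get_mask(case$structures, st), f, mode = "nearest")
    }
  } else if (st == "rectum") {
    kz_t <- which(apply(tpl_m, 3, any))
    kz_c <- which(apply(case_m, 3, any))
    n_sect <- 3L
    br_t <- unique(round(seq(min(kz_t) - 1, max(kz_t), length.out = n_sect + 1)))
    br_c <- unique(round(seq(min(kz_c) - 1, max(kz_c), length.out = n_sect + 1)))
    n <- min(length(br_t), length(br_c)) - 1
    for (s in seq_len(n)) {
      sect_t <- array(FALSE, dim(tpl_m))
      kk <- (br_t[s] + 1):br_t[s + 1]
      sect_t[, , kk] <- tpl_m[, , kk]
      sect_c <- array(FALSE, dim(case_m))
      kk <- (br_c[s] + 1):br_c[s + 1]
      sect_c[, , kk] <- case_m[, , kk]
      f <- snap_translation(f, sect_t, sect_c, sp, falloff_mm = 12)
      case_m <- warp_volume(get_mask(case$structures, st), f, mode = "nearest")
    }
  } else {
    f <- snap_translation(f, tpl_m, case_m, sp)
  }
  f
}

# product of short-falloff freeze factors over the given organs (template
# side and case side as currently warped): a stage with this weight cannot
# displace those structures
freeze_zone <- function(case, template, f, organs, falloff_mm = 4,
                        margin_mm = 3) {
  d <- dim(f$dx)
  w <- array(1, d)
  for (org in organs) {
    inside <- get_mask(template$structures, org) |
      warp_volume(get_mask(case$structures, org), f, mode = "nearest")
    if (!any(inside)) next
    dist <- sqrt(cpp_edt_sq(inside, d, f$spacing))
    dim(dist) <- d
    # fully frozen out to margin_mm beyond the organ surface, then ramp
    w <- w * pmin(pmax((dist - margin_mm) / falloff_mm, 0), 1)
  }
  w
}

# smooth Gaussian-RBF field interpolating the residual centroid offsets of
# the soft organs (bladder, prostate, rectum) after prealignment, anchored
# by zero-displacement landmarks on the bones and the body periphery: one
# smooth warp brings every organ within the capture range of the Demons
# stages without distorting the rest of the pelvis
organ_landmark_field <- function(case, template, f, sigma_mm = 30,
                                 organs = c("bladder", "prostate",
                                            "rectum")) {
  sp <- f$spacing
  d <- dim(f$dx)
  centers <- NULL; offsets <- NULL
  section_centroids <- function(m, n_sections) {
    kz <- which(apply(m, 3, any))
    breaks <- unique(round(seq(min(kz) - 1, max(kz), length.out = n_sections + 1)))
    out <- NULL
    for (s in seq_len(length(breaks) - 1)) {
      sect <- array(FALSE, dim(m))
      kk <- (breaks[s] + 1):breaks[s + 1]
      sect[, , kk] <- m[, , kk]
      if (any(sect)) out <- rbind(out, mask_centroid_mm(sect, sp))
    }
    out
  }
  for (org in organs) {
    tpl_m <- get_mask(template$structures, org)
    case_m <- warp_volume(get_mask(case$structures, org), f, mode = "nearest")
    if (!any(tpl_m) || !any(case_m)) next
    if (org == "rectum") {
      # the tube gets one landmark per z-section of its central path, so a
      # curvature difference is captured, not just the bulk offset
      ct <- section_centroids(tpl_m, 4)
      cc <- section_centroids(case_m, 4)
      n <- min(nrow(ct), nrow(cc))
      centers <- rbind(centers, ct[seq_len(n), , drop = FALSE])
      offsets <- rbind(offsets, cc[seq_len(n), , drop = FALSE] -
                         ct[seq_len(n), , drop = FALSE])
    } else {
      centers <- rbind(centers, mask_centroid_mm(tpl_m, sp))
      offsets <- rbind(offsets, mask_centroid_mm(case_m, sp) -
                         mask_centroid_mm(tpl_m, sp))
    }
  }
  # bone components are moving landmarks too: each template component is
  # paired with the nearest component of the warped case bones
  tpl_comps <- mask_components(get_mask(template$structures, "bones"))
  case_comps <- mask_components(
    warp_volume(get_mask(case$structures, "bones"), f, mode = "nearest"))
  if (length(tpl_comps) && length(case_comps)) {
    case_cents <- t(vapply(case_comps, mask_centroid_mm, numeric(3), sp))
    for (comp in tpl_comps) {
      ct <- mask_centroid_mm(comp, sp)
      j <- which.min(colSums((t(case_cents) - ct)^2))
      centers <- rbind(centers, ct)
      offsets <- rbind(offsets, case_cents[j, ] - ct)
    }
  }
  if (is.null(centers) || max(abs(offsets)) < 0.25) return(f)
  body_idx <- which(get_mask(template$structures, "body"), arr.ind = TRUE)
  for (ax in 1:3) for (side in c(which.min, which.max)) {
    pt <- (body_idx[side(body_idx[, ax]), ] - 1) * sp
    centers <- rbind(centers, pt)
    offsets <- rbind(offsets, c(0, 0, 0))
  }
  K <- exp(-as.matrix(stats::dist(centers))^2 / (2 * sigma_mm^2))
  A <- solve(K + diag(1e-8, nrow(K)), offsets)   # RBF weights per axis
  co <- voxel_coords(d, sp, f$origin)
  X <- array(co$x, d)
  Y <- aperm(array(co$y, d[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(co$z, d[c(3, 1, 2)]), c(2, 3, 1))
  lx <- array(0, d); ly <- array(0, d); lz <- array(0, d)
  for (k in seq_len(nrow(centers))) {
    phi <- exp(-((X - centers[k, 1])^2 + (Y - centers[k, 2])^2 +
                   (Z - centers[k, 3])^2) / (2 * sigma_mm^2))
    lx <- lx + A[k, 1] * phi
    ly <- ly + A[k, 2] * phi
    lz <- lz + A[k, 3] * phi
  }
  compose_fields(f, vector_field(lx, ly, lz, sp, f$origin))
}

# list of connected components (26-connectivity) of a mask, largest first
mask_components <- function(mask, max_components = 8L) {
  comps <- list()
  left <- mask
  while (any(left) && length(comps) < max_components) {
    d <- dim(left)
    reach <- array(FALSE, d)
    reach[which(left)[1]] <- TRUE
    repeat {
      grown <- reach
      idx <- lapply(d, seq_len)
      for (ax in 1:3) {
        up <- idx; up[[ax]] <- pmin(idx[[ax]] + 1L, d[ax])
        dn <- idx; dn[[ax]] <- pmax(idx[[ax]] - 1L, 1L)
        grown <- grown | grown[up[[1]], up[[2]], up[[3]]] |
          grown[dn[[1]], dn[[2]], dn[[3]]]
      }
      grown <- grown & left
      if (identical(grown, reach)) break
      reach <- grown
    }
    comps[[length(comps) + 1]] <- reach
    left <- left & !reach
  }
  comps[order(vapply(comps, sum, 0), decreasing = TRUE)]
}

#' Compose two displacement fields
#'
#' `compose_fields(f_outer, f_inner)(x) = f_inner(x) + f_outer(x + f_inner(x))`
#' with linear interpolation of the outer field, so that warping with the
#' composed field equals warping with `f_outer` first and `f_inner` second
#' (backward-warp convention).
#'
#' @param f_outer,f_inner Geometry-compatible `vector_field`s.
#' @return A `vector_field`.
#' @export
compose_fields <- function(f_outer, f_inner) {
  if (!all(dim(f_outer$dx) == dim(f_inner$dx)))
    stop("fields are not geometry-compatible", call. = FALSE)
  d <- dim(f_outer$dx)
  res <- cpp_compose(as.double(f_outer$dx), as.double(f_outer$dy),
                     as.double(f_outer$dz), as.double(f_inner$dx),
                     as.double(f_inner$dy), as.double(f_inner$dz),
                     d, f_outer$spacing)
  mk <- function(v) { dim(v) <- d; v }
  vector_field(mk(res$x), mk(res$y), mk(res$z), f_outer$spacing, f_outer$origin)
}

#' Warp a volume or mask with a displacement field
#'
#' Backward warping: `out(x) = vol(x + f(x))`. Scalars use linear
#' interpolation, masks nearest-neighbour (so they stay binary).
#' Out-of-field voxels are filled with a unit-appropriate background
#' (-1000 HU, 0 Gy, 0 otherwise).
#'
#' @param vol `volume_grid`, or a logical/0-1 array for masks.
#' @param field A `vector_field` on the same geometry.
#' @param mode `"linear"` or `"nearest"`.
#' @param background Override for the out-of-field fill value.
#' @return Same type as `vol`.
#' @export
warp_volume <- function(vol, field, mode = c("linear", "nearest"),
                        background = NULL) {
  mode <- match.arg(mode)
  is_grid <- inherits(vol, "volume_grid")
  arr <- if (is_grid) vol$values else (as_mask(vol) + 0)
  if (!is_grid && mode == "linear") mode <- "nearest"
  if (is.null(background))
    background <- if (is_grid) switch(vol$unit, HU = -1000, Gy = 0, 0) else 0
  d <- dim(arr)
  if (!all(d == dim(field$dx)))
    stop("field not geometry-compatible with volume", call. = FALSE)
  out <- cpp_warp(as.double(arr), d, field$spacing,
                  as.double(field$dx), as.double(field$dy), as.double(field$dz),
                  as.integer(mode == "nearest"), background, 0L)
  dim(out) <- d
  if (is_grid) with_values(vol, out) else out > 0.5
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks are defined to agree perfectly
#' (Dice 1).
#'
#' @param a,b Logical masks (or `volume_grid`s) of equal shape.
#' @return Numeric scalar in [0, 1].
#' @export
dice <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (!all(dim(a) == dim(b))) stop("masks differ in shape", call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1.0)
  2 * sum(a & b) / (na + nb)
}

#' Registration quality gate
#'
#' A case passes only when every organ Dice is strictly greater than the
#' threshold (0.85 by default); a case failing the gate is excluded from the
#' population analysis.
#'
#' @param dices Named numeric of Dice scores; must contain body, bones,
#'   bladder, rectum, prostate.
#' @param threshold Strict lower bound.
#' @return List with `pass` (logical) and `failures` (character).
#' @export
qa_gate <- function(dices, threshold = 0.85) {
  needed <- c("body", "bones", "bladder", "rectum", "prostate")
  missing <- setdiff(needed, names(dices))
  if (length(missing))
    stop(sprintf("missing organ dice: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  fails <- names(dices)[!(dices > threshold)]
  list(pass = length(fails) == 0L, failures = fails, dices = dices,
       threshold = threshold)
}

otsu_threshold <- function(x, n_bins = 128L) {
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  counts <- h$counts; mids <- h$mids
  w <- cumsum(counts); total <- w[length(w)]
  sumx <- cumsum(counts * mids); sum_total <- sumx[length(sumx)]
  wb <- w[-length(w)]; wf <- total - wb
  valid <- wb > 0 & wf > 0
  mb <- sumx[-length(sumx)] / wb
  mf <- (sum_total - sumx[-length(sumx)]) / wf
  between <- wb * wf * (mb - mf)^2
  between[!valid] <- -Inf
  mids[which.max(between)] + (mids[2] - mids[1]) / 2
}

#' Spongy/cortical bone refinement of a composed field
#'
#' After propagation to the common coordinate system, the bones of the
#' warped case CT and of the template CT are each split into cortical and
#' spongy compartments by Otsu thresholding of the CT values inside the
#' bones mask, and one additional Demons stage per compartment (driven by
#' distance-ramp descriptors of the compartment masks) is composed onto the
#' input field. The refined field is kept only if it does not degrade the
#' bone Dice; if the Otsu split is degenerate (one compartment under 5% of
#' the bone volume) refinement is skipped with a warning.
#'
#' @param case,template `patient_case`s.
#' @param field Composed `vector_field` from [staged_registration()].
#' @param iterations Demons iterations for the refinement stages.
#' @param sigma Update-field smoothing sigma (voxels).
#' @return List: `field` (possibly refined), `refined` (logical), and the
#'   cortical/spongy masks of case (in CCS) and template.
#' @export
bone_refinement <- function(case, template, field,
                            iterations = c(0, 20, 20, 10), sigma = 1) {
  tpl_ct <- template$ct
  tpl_bones <- get_mask(template$structures, "bones")
  case_ct_ccs <- warp_volume(case$ct, field)
  case_bones_ccs <- warp_volume(get_mask(case$structures, "bones"), field,
                                mode = "nearest")
  split_bones <- function(ct_vals, bones) {
    thr <- otsu_threshold(ct_vals[bones])
    cort <- bones & (ct_vals >= thr)
    list(cortical = cort, spongy = bones & !cort, threshold = thr)
  }
  tpl_split <- split_bones(tpl_ct$values, tpl_bones)
  case_split <- split_bones(case_ct_ccs$values, case_bones_ccs)
  frac <- function(s) min(sum(s$cortical), sum(s$spongy)) /
    max(sum(s$cortical) + sum(s$spongy), 1)
  if (frac(tpl_split) < 0.05 || frac(case_split) < 0.05) {
    warning("degenerate cortical/spongy split; bone refinement skipped")
    return(list(field = field, refined = FALSE,
                case_cortical = case_split$cortical,
                case_spongy = case_split$spongy,
                template_cortical = tpl_split$cortical,
                template_spongy = tpl_split$spongy))
  }
  sp <- tpl_ct$spacing
  mkv <- function(v) volume_grid(v, sp, tpl_ct$origin, "unitless")
  organ_dice <- function(f) {
    vapply(c("bones", "bladder", "rectum", "prostate"), function(org)
      dice(warp_volume(get_mask(case$structures, org), f, mode = "nearest"),
           get_mask(template$structures, org)), 0.0)
  }
  dice_before <- organ_dice(field)
  delta <- zero_field(tpl_ct)
  two_band <- function(split) {
    v <- array(0, dim(split$cortical))
    v[split$spongy] <- 0.5
    v[split$cortical] <- 0.9
    mkv(v)
  }
  drive_f <- two_band(tpl_split)
  drive_m <- two_band(case_split)
  # the refinement must not displace the soft organs adjacent to the bones
  frz <- freeze_zone(case, template, field,
                     c("bladder", "prostate", "rectum"))
  for (part in c("cortical", "spongy")) {
    w <- stage_weight(pmax(tpl_split[[part]] + 0, case_split[[part]] + 0),
                      sp, falloff_mm = 8) * frz
    delta <- demons_stage(drive_f, drive_m, iterations, sigma, init = delta,
                          weight = w)
  }
  refined <- compose_fields(field, delta)
  dice_after <- organ_dice(refined)
  accepted <- all(dice_after >= dice_before - 1e-12) ||
    (dice_after["bones"] > dice_before["bones"] &&
       all(dice_after >= dice_before - 0.005))
  if (!accepted) {
    warning("bone refinement degraded organ overlap; keeping unrefined field")
    refined <- field
  }
  list(field = refined, refined = accepted,
       case_cortical = case_split$cortical, case_spongy = case_split$spongy,
       template_cortical = tpl_split$cortical,
       template_spongy = tpl_split$spongy)
}

#' Fraction of positive Jacobian determinants of (id + field)
#'
#' Central-difference Jacobian of the deformation `x + f(x)`; the fraction
#' of voxels (within `mask`, if given) where the determinant is positive
#' indicates how close the field is to a diffeomorphism.
#'
#' @param field A `vector_field`.
#' @param mask Optional logical mask restricting the evaluation.
#' @return Fraction in [0, 1].
#' @export
jacobian_positive_fraction <- function(field, mask = NULL) {
  d <- dim(field$dx)
  grad <- function(arr, ax) {
    sp <- field$spacing[ax]
    idx <- lapply(d, seq_len)
    hi <- idx; lo <- idx
    hi[[ax]] <- pmin(idx[[ax]] + 1L, d[ax])
    lo[[ax]] <- pmax(idx[[ax]] - 1L, 1L)
    span_1d <- (hi[[ax]] - lo[[ax]]) * sp   # 1 voxel at edges, 2 inside
    span <- if (ax == 1) array(span_1d, d)
    else if (ax == 2) aperm(array(span_1d, c(d[2], d[1], d[3])), c(2, 1, 3))
    else aperm(array(span_1d, c(d[3], d[1], d[2])), c(2, 3, 1))
    (arr[hi[[1]], hi[[2]], hi[[3]]] - arr[lo[[1]], lo[[2]], lo[[3]]]) / span
  }
  J11 <- 1 + grad(field$dx, 1); J12 <- grad(field$dx, 2); J13 <- grad(field$dx, 3)
  J21 <- grad(field$dy, 1); J22 <- 1 + grad(field$dy, 2); J23 <- grad(field$dy, 3)
  J31 <- grad(field$dz, 1); J32 <- grad(field$dz, 2); J33 <- 1 + grad(field$dz, 3)
  det <- J11 * (J22 * J33 - J23 * J32) - J12 * (J21 * J33 - J23 * J31) +
    J13 * (J21 * J32 - J22 * J31)
  if (!is.null(mask)) det <- det[as_mask(mask)]
  mean(det > 0)
}
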