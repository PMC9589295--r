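#' Parameters of the synthetic pelvic phantom cohort
#'
#' The phantom emulates a cohort of male-pelvis radiotherapy patients:
#' an elliptical body, two femoral heads and a sacrum (each with a dense
#' cortical shell around a less dense spongy interior), bladder, prostate,
#' two seminal-vesicle blobs fused to the prostate (CTV1), and a gently
#' curved rectal tube containing an air pocket. CT values are drawn per
#' tissue from configured means/SDs (soft tissue near 0 HU, heterogeneous
#' bone, negative rectal air); the MRI-like image uses a different monotone
#' intensity map (bone dark, bladder bright) modulated by a smooth
#' multiplicative bias field. Inter-patient variability combines global
#' anisotropic scaling, per-organ scale and position jitter, and a smooth
#' random warp of the whole anatomy whose analytic displacement field is
#' retained as registration ground truth.
#'
#' All lengths are in mm; organ geometry is expressed relative to the grid
#' center. Setting every variation coefficient to zero yields identical
#' patients.
#'
#' @param shape Grid dimensions (x, y, z).
#' @param spacing Voxel spacing in mm.
#' @param organs Named list of organ primitives (see defaults).
#' @param hu Named list of per-tissue `c(mean, sd)` in HU.
#' @param mri Named list: per-tissue intensities, `bias_amp`, `bias_corr_mm`,
#'   `noise_sd`.
#' @param variation Named list: `axis_scale_sd`, `organ_scale_sd`,
#'   `jitter_sd_mm`, `warp_amp_mm`, `warp_corr_mm`.
#' @param sct_error Learned-like sCT error model: per-tissue `amplitude`
#'   (HU) and `corr_mm` correlation length.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(96L, 96L, 48L),
                           spacing = c(2, 2, 2),
                           organs = list(),
                           hu = list(),
                           mri = list(),
                           variation = list(),
                           sct_error = list()) {
  def_organs <- list(
    body_semi     = c(82, 70),
    bladder       = list(center = c(0, -20, 14), semi = c(21, 17, 18)),
    prostate      = list(center = c(0, 2, -8),   semi = c(14, 12, 12)),
    vesicle       = list(center = c(11, -5, 6),  semi = c(8, 5, 6)),
    rectum        = list(center = c(0, 22, 0), radius = 8, half_length = 34,
                         curve_amp = 3),
    air_semi      = c(4.5, 4.5, 9),
    femoral       = list(center = c(52, 2, 4), radius = 17, shell = 3.5),
    sacrum        = list(center = c(0, 45, 0), semi = c(24, 9, 30), shell = 3))
  def_hu <- list(background = c(-1000, 0), soft = c(30, 20), bladder = c(5, 15),
                 prostate = c(30, 15), vesicle = c(30, 15),
                 rectum_wall = c(25, 20), air = c(-700, 50),
                 cortical = c(650, 120), spongy = c(100, 80))
  def_mri <- list(background = 20, soft = 400, bladder = 850, prostate = 430,
                  vesicle = 430, rectum_wall = 420, air = 30, cortical = 80,
                  spongy = 220, bias_amp = 0.08, bias_corr_mm = 40,
                  noise_sd = 15)
  def_var <- list(axis_scale_sd = 0.06, organ_scale_sd = 0.05,
                  jitter_sd_mm = 3, warp_amp_mm = 2.5, warp_corr_mm = 25)
  def_err <- list(amplitude = c(soft = 25, bone = 90, air = 60), corr_mm = 12)
  p <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
            organs = utils::modifyList(def_organs, organs),
            hu = utils::modifyList(def_hu, hu),
            mri = utils::modifyList(def_mri, mri),
            variation = utils::modifyList(def_var, variation),
            sct_error = utils::modifyList(def_err, sct_error))
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  o <- p$organs
  radii <- c(o$body_semi, o$bladder$semi, o$prostate$semi, o$vesicle$semi,
             o$rectum$radius, o$femoral$radius, o$sacrum$semi, o$air_semi)
  if (any(radii <= 0)) stop("all radii must be positive", call. = FALSE)
  v <- p$variation
  if (any(unlist(v) < 0)) stop("variation coefficients must be >= 0", call. = FALSE)
  # organs must fit inside the body at maximal plausible displacement
  margin <- 3 * v$jitter_sd_mm + v$warp_amp_mm
  reach_x <- max(abs(o$bladder$center[1]) + o$bladder$semi[1],
                 abs(o$femoral$center[1]) + o$femoral$radius,
                 abs(o$vesicle$center[1]) + o$vesicle$semi[1])
  reach_y <- max(abs(o$bladder$center[2]) + o$bladder$semi[2],
                 abs(o$sacrum$center[2]) + o$sacrum$semi[2],
                 abs(o$rectum$center[2]) + o$rectum$radius + o$rectum$curve_amp)
  if (reach_x + margin > o$body_semi[1] || reach_y + margin > o$body_semi[2])
    stop("organs do not fit inside the body at maximum jitter", call. = FALSE)
  invisible(p)
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Gaussian-smooth a volume
#'
#' Separable Gaussian filter with reflective boundaries; the kernel is
#' normalized to unit sum (so smoothing white noise shrinks its variance).
#'
#' @param vol `volume_grid` or 3D array.
#' @param sigma_mm Standard deviation in mm (scalar or per-axis).
#' @return Same type as the input.
#' @export
smooth_volume <- function(vol, sigma_mm) {
  arr <- if (inherits(vol, "volume_grid")) vol$values else vol
  sp <- if (inherits(vol, "volume_grid")) vol$spacing else c(1, 1, 1)
  sig <- rep(sigma_mm, length.out = 3) / sp
  out <- cpp_gauss(as.double(arr), dim(arr), sig)
  dim(out) <- dim(arr)
  if (inherits(vol, "volume_grid")) with_values(vol, out) else out
}

# smooth unit-SD noise field (array), correlation length in mm
smooth_noise <- function(shape, spacing, corr_mm) {
  w <- array(stats::rnorm(prod(shape)), shape)
  if (corr_mm <= 0) return(w)
  s <- cpp_gauss(as.double(w), shape, corr_mm / spacing)
  dim(s) <- shape
  s / stats::sd(s)
}

voxel_coords <- function(shape, spacing, origin = c(0, 0, 0)) {
  list(x = origin[1] + (seq_len(shape[1]) - 1) * spacing[1],
       y = origin[2] + (seq_len(shape[2]) - 1) * spacing[2],
       z = origin[3] + (seq_len(shape[3]) - 1) * spacing[3])
}

#' Generate one synthetic patient
#'
#' Draws per-patient anatomical variation, rasterizes the organ primitives,
#' and synthesizes CT and MRI-like volumes. Ground truth (tissue labels,
#' rectal air mask, cortical/spongy bone labels, and the smooth anatomical
#' warp field) is kept in `$truth`.
#'
#' @param params A `phantom_params`.
#' @param patient_seed Integer seed for this patient's draws.
#' @param id Patient identifier string.
#' @return A `patient_case`.
#' @export
generate_patient <- function(params, patient_seed, id = sprintf("P%05d", patient_seed)) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(patient_seed, {
    for (attempt in seq_len(10L)) {
      case <- try(rasterize_patient(params, id), silent = TRUE)
      if (!inherits(case, "try-error")) return(case)
      if (!grepl("outside the body", case)) stop(attr(case, "condition"))
    }
    stop("organs collide with the body boundary after 10 jitter redraws",
         call. = FALSE)
  })
}

rasterize_patient <- function(params, id) {
  shp <- params$shape; sp <- params$spacing
  o <- params$organs; v <- params$variation
  cm <- (shp - 1) * sp / 2
  g <- pmin(pmax(1 + stats::rnorm(3) * v$axis_scale_sd, 0.75), 1.3)
  jit <- function() stats::rnorm(3) * v$jitter_sd_mm
  osc <- function() pmin(pmax(1 + stats::rnorm(1) * v$organ_scale_sd, 0.7), 1.4)
  draws <- list(bladder = list(j = jit(), s = osc()),
                prostate = list(j = jit(), s = osc()),
                vesicle = list(j = jit(), s = osc()),
                rectum = list(j = jit(), s = osc()),
                femoral_l = list(j = jit(), s = osc()),
                femoral_r = list(j = jit(), s = osc()),
                sacrum = list(j = jit(), s = osc()))
  # smooth anatomical warp (ground truth for registration tests)
  if (v$warp_amp_mm > 0) {
    Wx <- v$warp_amp_mm * smooth_noise(shp, sp, v$warp_corr_mm)
    Wy <- v$warp_amp_mm * smooth_noise(shp, sp, v$warp_corr_mm)
    Wz <- v$warp_amp_mm * smooth_noise(shp, sp, v$warp_corr_mm)
  } else {
    Wx <- Wy <- Wz <- array(0, shp)
  }
  co <- voxel_coords(shp, sp)
  X <- array(co$x, shp)
  Y <- aperm(array(co$y, shp[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(co$z, shp[c(3, 1, 2)]), c(2, 3, 1))
  # anatomical coordinates: warp, then center and undo the global scaling
  U1 <- (X + Wx - cm[1]) / g[1]
  U2 <- (Y + Wy - cm[2]) / g[2]
  U3 <- (Z + Wz - cm[3]) / g[3]
  ell <- function(center, semi) {
    ((U1 - center[1]) / semi[1])^2 + ((U2 - center[2]) / semi[2])^2 +
      ((U3 - center[3]) / semi[3])^2 <= 1
  }
  body <- (U1 / o$body_semi[1])^2 + (U2 / o$body_semi[2])^2 <= 1
  d <- draws$bladder
  bladder <- ell(o$bladder$center + d$j, o$bladder$semi * d$s)
  d <- draws$prostate
  prostate <- ell(o$prostate$center + d$j, o$prostate$semi * d$s)
  d <- draws$vesicle
  ves_c <- o$vesicle$center + d$j
  vesicle <- ell(ves_c, o$vesicle$semi * d$s) |
    ell(c(-ves_c[1], ves_c[2], ves_c[3]), o$vesicle$semi * d$s)
  d <- draws$rectum
  rc <- o$rectum$center + d$j
  R <- o$rectum$radius * d$s
  hl <- o$rectum$half_length * d$s
  ypath <- rc[2] + o$rectum$curve_amp * sin(pi * (U3 - rc[3]) / (2 * hl))
  in_z <- abs(U3 - rc[3]) <= hl
  rectum <- in_z & ((U1 - rc[1])^2 + (U2 - ypath)^2 <= R^2)
  air <- ((U1 - rc[1]) / o$air_semi[1])^2 +
    ((U2 - ypath) / o$air_semi[2])^2 +
    ((U3 - rc[3]) / o$air_semi[3])^2 <= 1
  air <- air & rectum
  d <- draws$femoral_l
  fc <- o$femoral$center + d$j
  r2l <- (U1 - fc[1])^2 + (U2 - fc[2])^2 + (U3 - fc[3])^2
  fem_l <- r2l <= (o$femoral$radius * d$s)^2
  fem_l_sp <- r2l <= (pmax(o$femoral$radius * d$s - o$femoral$shell, 1))^2
  d <- draws$femoral_r
  fc <- o$femoral$center * c(-1, 1, 1) + d$j
  r2r <- (U1 - fc[1])^2 + (U2 - fc[2])^2 + (U3 - fc[3])^2
  fem_r <- r2r <= (o$femoral$radius * d$s)^2
  fem_r_sp <- r2r <= (pmax(o$femoral$radius * d$s - o$femoral$shell, 1))^2
  d <- draws$sacrum
  sc <- o$sacrum$center + d$j
  sac <- ell(sc, o$sacrum$semi * d$s)
  sac_sp <- ell(sc, pmax(o$sacrum$semi * d$s - o$sacrum$shell, 1))
  bones <- fem_l | fem_r | sac
  spongy <- (fem_l_sp | fem_r_sp | sac_sp) & bones
  cortical <- bones & !spongy
  # precedence: bones > bladder > prostate > rectum; vesicles yield to organs
  bladder <- bladder & !bones
  prostate <- prostate & !bones & !bladder
  rectum <- rectum & !bones & !bladder & !prostate
  air <- air & rectum
  vesicle <- vesicle & !bones & !bladder & !rectum
  organs_all <- bones | bladder | prostate | rectum
  if (any(organs_all & !body))
    stop("organs collide outside the body", call. = FALSE)
  # a rectum bitten apart (or emptied) by bone precedence counts as a
  # collision too: redraw the jitter rather than emit an unusable case
  if (!any(rectum) || !any(prostate) || !any(bladder) ||
      !mask_connected(rectum))
    stop("organs collide: rectum disrupted outside the body plan", call. = FALSE)
  # tissue labels
  lab <- array(0L, shp)           # 0 background
  lab[body] <- 1L                 # soft
  lab[vesicle & body] <- 8L
  lab[bladder] <- 2L
  lab[prostate] <- 3L
  lab[rectum] <- 4L
  lab[air] <- 5L
  lab[cortical] <- 6L
  lab[spongy] <- 7L
  hu <- params$hu
  hu_mean <- c(hu$background[1], hu$soft[1], hu$bladder[1], hu$prostate[1],
               hu$rectum_wall[1], hu$air[1], hu$cortical[1], hu$spongy[1],
               hu$vesicle[1])
  hu_sd <- c(hu$background[2], hu$soft[2], hu$bladder[2], hu$prostate[2],
             hu$rectum_wall[2], hu$air[2], hu$cortical[2], hu$spongy[2],
             hu$vesicle[2])
  ct_vals <- hu_mean[lab + 1L] + stats::rnorm(prod(shp)) * hu_sd[lab + 1L]
  dim(ct_vals) <- shp
  mp <- params$mri
  mri_int <- c(mp$background, mp$soft, mp$bladder, mp$prostate, mp$rectum_wall,
               mp$air, mp$cortical, mp$spongy, mp$vesicle)
  bias <- 1 + mp$bias_amp * smooth_noise(shp, sp, mp$bias_corr_mm)
  mri_vals <- mri_int[lab + 1L]
  dim(mri_vals) <- shp
  # magnitude images are non-negative
  mri_vals <- pmax(mri_vals * bias + stats::rnorm(prod(shp)) * mp$noise_sd, 0)
  ctv2 <- prostate
  ctv1 <- prostate | (vesicle & body)
  ss <- structure_set(list(dim = shp, spacing = sp, origin = c(0, 0, 0)),
                      list(body = body, bones = bones, bladder = bladder,
                           rectum = rectum, prostate = prostate,
                           ctv1 = ctv1, ctv2 = ctv2,
                           cortical = cortical, spongy = spongy))
  ct <- volume_grid(ct_vals, sp, c(0, 0, 0), "HU")
  mri <- volume_grid(mri_vals, sp, c(0, 0, 0), "unitless")
  truth <- list(labels = lab, air = air,
                cortical = cortical, spongy = spongy,
                warp = vector_field(Wx, Wy, Wz, sp, c(0, 0, 0)),
                draws = draws, axis_scale = g)
  patient_case(id, mri, ct, ss, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Per-patient seeds are drawn deterministically from the master seed, so the
#' same `(params, n_patients, seed)` always reproduces the identical cohort.
#'
#' @param params A `phantom_params`.
#' @param n_patients Number of patients (>= 2).
#' @param seed Master seed.
#' @return List of `patient_case` objects named by patient id.
#' @export
generate_cohort <- function(params, n_patients, seed) {
  if (n_patients < 2) stop("n_patients must be >= 2", call. = FALSE)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_patients))
  cases <- lapply(seq_len(n_patients), function(i)
    generate_patient(params, seeds[i], id = sprintf("P%02d", i)))
  names(cases) <- vapply(cases, `[[`, "", "id")
  cases
}

#' Learned-like synthetic CT surrogate
#'
#' Adds a smooth, spatially correlated error field to the reference CT with a
#' per-tissue amplitude (soft tissue, bone, rectal air), emulating the
#' heterogeneous residual errors of a trained image-translation model. Zero
#' amplitude returns the CT unchanged. The white-noise field is smoothed with
#' a unit-sum Gaussian kernel, so the realized error SD is the amplitude
#' times the kernel's variance-shrink factor.
#'
#' @param case A `patient_case`.
#' @param amplitude Named numeric: per-tissue error amplitude in HU
#'   (`soft`, `bone`, `air`).
#' @param corr_mm Correlation length (Gaussian sigma, mm) of the error field.
#' @param seed Integer seed.
#' @return A `volume_grid` (HU).
#' @export
make_learned_like_sct <- function(case, amplitude = c(soft = 25, bone = 90, air = 60),
                                  corr_mm = 12, seed = 1L) {
  if (any(amplitude < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (corr_mm < 0) stop("correlation length must be >= 0", call. = FALSE)
  ct <- case$ct
  shp <- dim(ct$values)
  bones <- get_mask(case$structures, "bones")
  body <- get_mask(case$structures, "body")
  air <- if (!is.null(case$truth$air)) case$truth$air else
    (get_mask(case$structures, "rectum") & ct$values < -300)
  soft <- body & !bones & !air
  amp_map <- array(0, shp)
  amp_map[soft] <- amplitude[["soft"]]
  amp_map[bones] <- amplitude[["bone"]]
  amp_map[air] <- amplitude[["air"]]
  err <- with_seed(seed, {
    w <- array(stats::rnorm(prod(shp)), shp)
    if (corr_mm > 0) {
      w <- cpp_gauss(as.double(w), shp, corr_mm / ct$spacing)
      dim(w) <- shp
    }
    w
  })
  with_values(ct, ct$values + amp_map * err, unit = "HU")
}
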