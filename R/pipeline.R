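#' Register a whole cohort to its template
#'
#' Builds structural descriptions for every case, selects (or accepts) the
#' template, runs [staged_registration()] for each remaining case, applies
#' the spongy/cortical bone refinement, and evaluates per-organ Dice, the
#' DSC > threshold quality gate and the positive-Jacobian fraction. The
#' template itself carries the identity field.
#'
#' @param cases Named list of `patient_case`s.
#' @param schedule A `stage_schedule`.
#' @param template_id Template patient id; `NULL` selects by median organ
#'   volumes.
#' @param w_sd Structural-description blend weight.
#' @param refine_bones Apply [bone_refinement()] after the staged pipeline.
#' @param gate_threshold Strict Dice threshold of the quality gate.
#' @param verbose Log progress to stderr.
#' @return An object of class `cohort_registration`: `template_id`,
#'   `fields` (named list of `vector_field`s), `dice` (data.frame), `gates`,
#'   `jacobian_positive` (named numeric).
#' @export
register_cohort <- function(cases, schedule = stage_schedule(),
                            template_id = NULL, w_sd = 0.5,
                            refine_bones = TRUE, gate_threshold = 0.85,
                            verbose = TRUE) {
  organs <- c("body", "bones", "bladder", "rectum", "prostate")
  if (is.null(template_id)) template_id <- select_template(cases)
  template <- cases[[template_id]]
  if (verbose) log_msg("template: %s", template_id)
  template_sd <- build_sd(template$mri, template$structures, w_sd)
  fields <- list(); dice_rows <- list(); gates <- list(); jac <- c()
  tpl_body <- get_mask(template$structures, "body")
  for (id in names(cases)) {
    case <- cases[[id]]
    if (id == template_id) {
      f <- zero_field(template$ct)
    } else {
      case_sd <- build_sd(case$mri, case$structures, w_sd)
      f <- staged_registration(case, template, schedule,
                               case_sd = case_sd, template_sd = template_sd)
      if (refine_bones) f <- bone_refinement(case, template, f)$field
    }
    fields[[id]] <- f
    dices <- vapply(organs, function(org)
      dice(warp_volume(get_mask(case$structures, org), f, mode = "nearest"),
           get_mask(template$structures, org)), 0.0)
    dice_rows[[id]] <- data.frame(id = id, organ = organs, dice = dices,
                                  row.names = NULL)
    gates[[id]] <- qa_gate(dices, gate_threshold)
    jac[id] <- jacobian_positive_fraction(f, tpl_body)
    if (verbose)
      log_msg("%s: dice [%s], gate %s", id,
              paste(sprintf("%s %.3f", organs, dices), collapse = ", "),
              if (gates[[id]]$pass) "pass" else "FAIL")
  }
  structure(list(template_id = template_id, fields = fields,
                 dice = do.call(rbind, dice_rows), gates = gates,
                 jacobian_positive = jac, gate_threshold = gate_threshold),
            class = "cohort_registration")
}

#' Attach synthetic CTs to every case
#'
#' Adds the bulk-density sCT (rectal air segmented from the MRI) and the
#' learned-like surrogate sCT to each case.
#'
#' @param cases Named list of `patient_case`s.
#' @param assignment A `bulk_assignment`.
#' @param learned_amplitude,learned_corr_mm Learned-like error model.
#' @param seed Base seed; patient i uses `seed + i`.
#' @return The cases with `$scts$bulk` and `$scts$learned` set.
#' @export
add_scts <- function(cases, assignment = bulk_assignment(),
                     learned_amplitude = c(soft = 25, bone = 90, air = 60),
                     learned_corr_mm = 12, seed = 1L) {
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    air <- segment_rectal_air(cs$mri, get_mask(cs$structures, "rectum"),
                              get_mask(cs$structures, "body"), assignment)
    cs$scts$bulk <- generate_bulk_sct(cs$structures, air, assignment)
    cs$scts$learned <- make_learned_like_sct(cs, learned_amplitude,
                                             learned_corr_mm, seed + i)
    cases[[i]] <- cs
  }
  cases
}

#' Compute reference and sCT doses for every case
#'
#' Calibrates the beam weights once per patient on the reference CT, then
#' recomputes the dose with the identical weights on each sCT, so image
#' errors propagate into dose errors.
#'
#' @param cases Named list of `patient_case`s (with sCTs attached).
#' @param config A `beam_config`.
#' @param verbose Log progress.
#' @return The cases with `$doses$ct` and one dose per sCT method.
#' @export
add_doses <- function(cases, config = beam_config(), verbose = TRUE) {
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    w <- calibrate_beams(cs$ct, cs$structures, config)
    cs$doses$ct <- compute_dose(cs$ct, cs$structures, config, weights = w)
    for (m in names(cs$scts))
      cs$doses[[m]] <- compute_dose(cs$scts[[m]], cs$structures, config,
                                    weights = w)
    cases[[i]] <- cs
    if (verbose) log_msg("%s: doses computed (median CTV2 %.2f Gy)",
                         cs$id, stats::median(cs$doses$ct$values[
                           get_mask(cs$structures, "ctv2")]))
  }
  cases
}

#' Propagate a per-patient volume selection to the CCS
#'
#' @param cases Named list of `patient_case`s.
#' @param registration A `cohort_registration`.
#' @param what `"ct"`, `"mri"`, `"sct:<method>"` or `"dose:<source>"`.
#' @param ids Which patients (default: all that passed the gate).
#' @return Named list of warped `volume_grid`s.
#' @export
propagate_to_ccs <- function(cases, registration, what, ids = NULL) {
  if (is.null(ids)) ids <- gate_passing_ids(registration)
  lapply(stats::setNames(ids, ids), function(id) {
    cs <- cases[[id]]
    vol <- if (what == "ct") cs$ct
    else if (what == "mri") cs$mri
    else if (startsWith(what, "sct:")) cs$scts[[sub("^sct:", "", what)]]
    else if (startsWith(what, "dose:")) cs$doses[[sub("^dose:", "", what)]]
    else stop(sprintf("unknown selection '%s'", what), call. = FALSE)
    if (is.null(vol)) stop(sprintf("%s missing for %s", what, id), call. = FALSE)
    warp_volume(vol, registration$fields[[id]])
  })
}

#' @rdname propagate_to_ccs
#' @export
gate_passing_ids <- function(registration) {
  ids <- names(registration$gates)
  ids[vapply(registration$gates, `[[`, TRUE, "pass")]
}

#' Run the full voxel-wise population QA workflow
#'
#' End-to-end convenience wrapper: attach sCTs and doses, register the
#' cohort to its template, propagate CT/sCT/dose volumes to the common
#' coordinate system, compute voxel-wise population maps and permutation
#' tests (HU and Gy) per method, and derive the dose-QA summaries
#' (MADE-VH with V0.5Gy/V1Gy, DVH-criteria differences, 3D gamma on the
#' mean doses).
#'
#' @param cases Named list of `patient_case`s.
#' @param methods sCT method names to evaluate.
#' @param schedule A `stage_schedule`.
#' @param beam A `beam_config`.
#' @param n_perm,alpha Permutation-test settings.
#' @param seed Seed driving sCT noise and the permutation flips.
#' @param refine_bones Apply bone refinement during registration.
#' @param gamma_criteria List with `dose_pct`, `dta_mm`, `normalization`,
#'   `threshold_pct`.
#' @param verbose Log progress.
#' @return A list with the intermediate and final products (cases,
#'   registration, CCS stacks, voxel maps, p-value volumes, ESR masks,
#'   MADE-VH curves, DVH differences, gamma results).
#' @export
run_qa_pipeline <- function(cases, methods = c("bulk", "learned"),
                            schedule = stage_schedule(),
                            beam = beam_config(), n_perm = 1000L,
                            alpha = 0.05, seed = 1L, refine_bones = TRUE,
                            gamma_criteria = list(dose_pct = 1, dta_mm = 1,
                                                  normalization = "local",
                                                  threshold_pct = 10),
                            verbose = TRUE) {
  cases <- add_scts(cases, seed = seed)
  cases <- add_doses(cases, beam, verbose = verbose)
  reg <- register_cohort(cases, schedule, refine_bones = refine_bones,
                         verbose = verbose)
  ids <- gate_passing_ids(reg)
  if (length(ids) < 2) stop("fewer than 2 cases passed the registration gate",
                            call. = FALSE)
  template <- cases[[reg$template_id]]
  body <- get_mask(template$structures, "body")
  ct_ccs <- propagate_to_ccs(cases, reg, "ct", ids)
  ref_hu <- cohort_stack(ct_ccs, ids, body)
  dose_ct_ccs <- propagate_to_ccs(cases, reg, "dose:ct", ids)
  ref_gy <- cohort_stack(dose_ct_ccs, ids, body)
  pelvis <- crop_pelvis(body, get_mask(template$structures, "rectum"),
                        template$ct$spacing, template$ct$origin)
  rois <- list(pelvis = pelvis,
               bladder = get_mask(template$structures, "bladder"),
               rectum = get_mask(template$structures, "rectum"),
               prostate = get_mask(template$structures, "prostate"))
  mean_vol <- function(stack) {
    m <- matrix(stack$data, ncol = dim(stack$data)[4])
    volume_grid(array(rowMeans(m), dim(stack$data)[1:3]), stack$spacing,
                stack$origin, stack$unit)
  }
  mean_dose_ct <- mean_vol(ref_gy)
  out <- list(cases = cases, registration = reg, ids = ids,
              template_id = reg$template_id, analysis_mask = body,
              rois = rois, ref_hu = ref_hu, ref_gy = ref_gy,
              mean_dose_ct = mean_dose_ct, methods = list())
  for (m in methods) {
    if (verbose) log_msg("population statistics for method '%s'", m)
    sct_ccs <- propagate_to_ccs(cases, reg, paste0("sct:", m), ids)
    dose_ccs <- propagate_to_ccs(cases, reg, paste0("dose:", m), ids)
    pred_hu <- cohort_stack(sct_ccs, ids, body)
    pred_gy <- cohort_stack(dose_ccs, ids, body)
    hu_maps <- voxelwise_maps(ref_hu, pred_hu)
    gy_maps <- voxelwise_maps(ref_gy, pred_gy)
    hu_test <- paired_permutation_test(ref_hu, pred_hu, n_perm, alpha,
                                       seed = seed + 101L)
    gy_test <- paired_permutation_test(ref_gy, pred_gy, n_perm, alpha,
                                       seed = seed + 202L)
    made <- lapply(names(rois), function(rn)
      made_vh(gy_maps$vmae, rois[[rn]], roi_name = rn))
    names(made) <- names(rois)
    mean_dose <- mean_vol(pred_gy)
    gam <- gamma_3d(mean_dose_ct, mean_dose, gamma_criteria$dose_pct,
                    gamma_criteria$dta_mm, gamma_criteria$normalization,
                    gamma_criteria$threshold_pct)
    dvh <- criteria_diff(mean_dose_ct, mean_dose,
                         rois[c("bladder", "rectum", "prostate")])
    out$methods[[m]] <- list(hu_maps = hu_maps, gy_maps = gy_maps,
                             hu_test = hu_test, gy_test = gy_test,
                             hu_esr = esr_mask(hu_test),
                             gy_esr = esr_mask(gy_test),
                             made_vh = made, mean_dose = mean_dose,
                             gamma = gam, dvh_diff = dvh)
  }
  out
}

#' Write a phantom cohort to disk
#'
#' Per-patient NIfTI volumes (CT, MRI) and masks plus a cohort manifest
#' JSON recording the generation parameters and seeds.
#'
#' @param cases Named list of `patient_case`s.
#' @param dir Output directory (created if needed).
#' @param params The `phantom_params` used (stored in the manifest).
#' @param seed Master seed (stored in the manifest).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cases, dir, params = NULL, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g0 <- NULL
  for (cs in cases) {
    pd <- file.path(dir, cs$id)
    dir.create(pd, showWarnings = FALSE)
    write_volume(cs$ct, file.path(pd, "ct.nii.gz"))
    write_volume(cs$mri, file.path(pd, "mri.nii.gz"))
    for (mn in names(cs$structures$masks)) {
      mv <- volume_grid(cs$structures$masks[[mn]] + 0,
                        cs$ct$spacing, cs$ct$origin, "unitless")
      write_volume(mv, file.path(pd, sprintf("mask_%s.nii.gz", mn)))
    }
    if (!is.null(cs$truth$air)) {
      write_volume(volume_grid(cs$truth$air + 0, cs$ct$spacing, cs$ct$origin,
                               "unitless"),
                   file.path(pd, "mask_truth_air.nii.gz"))
    }
    g0 <- geometry_of(cs$ct)
  }
  manifest <- list(ids = names(cases), n = length(cases), seed = seed,
                   shape = g0$dim, spacing = g0$spacing,
                   params = if (!is.null(params)) unclass(params))
  write_manifest(manifest, file.path(dir, "cohort_manifest.json"))
}

#' Load a phantom cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return Named list of `patient_case`s (generator ground truth restricted
#'   to what was serialized).
#' @export
load_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "cohort_manifest.json"),
                                  simplifyVector = TRUE)
  cases <- lapply(manifest$ids, function(id) {
    pd <- file.path(dir, id)
    ct <- read_volume(file.path(pd, "ct.nii.gz"), unit = "HU")
    mri <- read_volume(file.path(pd, "mri.nii.gz"), unit = "unitless")
    mask_files <- list.files(pd, pattern = "^mask_", full.names = TRUE)
    masks <- list()
    truth <- list()
    for (f in mask_files) {
      nm <- sub("^mask_(.*)\\.nii\\.gz$", "\\1", basename(f))
      m <- as_mask(read_volume(f))
      if (nm == "truth_air") truth$air <- m else masks[[nm]] <- m
    }
    ss <- structure_set(geometry_of(ct), masks)
    patient_case(id, mri, ct, ss, truth = truth)
  })
  names(cases) <- manifest$ids
  cases
}
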