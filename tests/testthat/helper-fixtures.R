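# Shared fixtures. The phantom study grid is 64x64x32 at 2.5 mm: large
# enough to hold the default pelvic anatomy, small enough for the suite.
# Expensive artifacts (the registered cohort and the end-to-end QA run) are
# built once per session and memoized.

.fixture_env <- new.env(parent = emptyenv())

test_params <- function(...) {
  phantom_params(shape = c(64L, 64L, 32L), spacing = c(2.5, 2.5, 2.5), ...)
}

# fine grid for tests that need a well-resolved rectal air pocket
test_params_fine <- function(...) {
  phantom_params(shape = c(96L, 96L, 48L), spacing = c(2, 2, 2), ...)
}

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

get_test_case <- function() {
  memo("case", function() generate_patient(test_params(), 42, id = "T42"))
}

get_test_cohort <- function() {
  memo("cohort", function() generate_cohort(test_params(), 10, seed = 7))
}

get_registered_cohort <- function() {
  memo("registered", function() {
    cases <- get_test_cohort()
    register_cohort(cases, verbose = FALSE)
  })
}

# full end-to-end pipeline on the registered cohort (bulk + learned sCTs,
# doses, CCS stacks, population statistics, dose QA)
get_pipeline_result <- function() {
  memo("pipeline", function() {
    cases <- get_test_cohort()
    reg <- get_registered_cohort()
    res <- run_qa_pipeline_prereg(cases, reg)
    res
  })
}

# run_qa_pipeline but reusing an existing registration (the expensive part)
run_qa_pipeline_prereg <- function(cases, reg, n_perm = 800L, seed = 11L) {
  cases <- add_scts(cases, seed = seed)
  cases <- add_doses(cases, beam_config(), verbose = FALSE)
  ids <- gate_passing_ids(reg)
  template <- cases[[reg$template_id]]
  body <- template$structures$masks$body
  ct_ccs <- propagate_to_ccs(cases, reg, "ct", ids)
  ref_hu <- cohort_stack(ct_ccs, ids, body)
  dose_ct <- propagate_to_ccs(cases, reg, "dose:ct", ids)
  ref_gy <- cohort_stack(dose_ct, ids, body)
  pelvis <- crop_pelvis(body, template$structures$masks$rectum,
                        template$ct$spacing, template$ct$origin)
  rois <- list(pelvis = pelvis,
               bladder = template$structures$masks$bladder,
               rectum = template$structures$masks$rectum,
               prostate = template$structures$masks$prostate)
  mean_vol <- function(stack) {
    m <- matrix(stack$data, ncol = dim(stack$data)[4])
    volume_grid(array(rowMeans(m), dim(stack$data)[1:3]), stack$spacing,
                stack$origin, stack$unit)
  }
  out <- list(cases = cases, registration = reg, ids = ids,
              template_id = reg$template_id, analysis_mask = body,
              rois = rois, ref_hu = ref_hu, ref_gy = ref_gy,
              mean_dose_ct = mean_vol(ref_gy), methods = list())
  for (m in c("bulk", "learned")) {
    pred_hu <- cohort_stack(propagate_to_ccs(cases, reg, paste0("sct:", m), ids),
                            ids, body)
    pred_gy <- cohort_stack(propagate_to_ccs(cases, reg, paste0("dose:", m), ids),
                            ids, body)
    hu_test <- paired_permutation_test(ref_hu, pred_hu, n_perm, 0.05,
                                       seed = seed + 101L)
    gy_test <- paired_permutation_test(ref_gy, pred_gy, n_perm, 0.05,
                                       seed = seed + 202L)
    gy_maps <- voxelwise_maps(ref_gy, pred_gy)
    hu_maps <- voxelwise_maps(ref_hu, pred_hu)
    made <- lapply(names(rois), function(rn)
      made_vh(gy_maps$vmae, rois[[rn]], roi_name = rn))
    names(made) <- names(rois)
    mean_dose <- mean_vol(pred_gy)
    out$methods[[m]] <- list(
      hu_maps = hu_maps, gy_maps = gy_maps,
      hu_test = hu_test, gy_test = gy_test,
      hu_esr = esr_mask(hu_test), gy_esr = esr_mask(gy_test),
      made_vh = made, mean_dose = mean_dose,
      gamma = gamma_3d(out$mean_dose_ct, mean_dose),
      dvh_diff = criteria_diff(out$mean_dose_ct, mean_dose,
                               rois[c("bladder", "rectum", "prostate")]))
  }
  out
}
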