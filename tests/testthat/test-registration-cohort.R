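# Cohort-level registration behavior. The registered 10-patient cohort is
# expensive and shared (memoized) with the acceptance tests.

test_that("self-registration is the identity within tolerance", {
  case <- get_test_case()
  f <- staged_registration(case, case)
  mag <- sqrt(f$dx^2 + f$dy^2 + f$dz^2) / min(case$ct$spacing)
  expect_lt(max(mag), 0.1)
  for (org in c("body", "bones", "bladder", "rectum", "prostate")) {
    warped <- warp_volume(case$structures$masks[[org]], f, mode = "nearest")
    expect_identical(warped, case$structures$masks[[org]])
  }
})

test_that("cohort registration passes the Dice gate for nearly all patients", {
  reg <- get_registered_cohort()
  n_pass <- length(gate_passing_ids(reg))
  expect_gte(n_pass, 9)
  # every bone/bladder Dice clears the gate comfortably
  expect_true(all(reg$dice$dice[reg$dice$organ == "bones"] > 0.9))
  expect_true(all(reg$dice$dice[reg$dice$organ == "body"] > 0.85))
})

test_that("deformations are diffeomorphic in intent: positive Jacobians nearly everywhere", {
  reg <- get_registered_cohort()
  expect_true(all(reg$jacobian_positive >= 0.99))
})

test_that("registered organ volumes collapse toward the template volume", {
  cases <- get_test_cohort()
  reg <- get_registered_cohort()
  ids <- gate_passing_ids(reg)
  for (org in c("bladder", "rectum", "prostate", "bones")) {
    native <- vapply(cases[ids], function(cs)
      sum(cs$structures$masks[[org]]), 0L)
    registered <- vapply(ids, function(id)
      sum(warp_volume(cases[[id]]$structures$masks[[org]], reg$fields[[id]],
                      mode = "nearest")), 0L)
    expect_lt(sd(registered), 0.2 * sd(native) + 1e-9)
  }
})

test_that("the gate flags unregistered cohorts with extreme anatomical variation", {
  # strongest variation the generator's containment bound allows on this grid
  p_ext <- test_params(variation = list(axis_scale_sd = 0.12,
                                        organ_scale_sd = 0.12,
                                        jitter_sd_mm = 3, warp_amp_mm = 4,
                                        warp_corr_mm = 30))
  ext <- generate_cohort(p_ext, 3, seed = 77)
  organs <- c("body", "bones", "bladder", "rectum", "prostate")
  native_dices <- vapply(organs, function(o)
    dice(ext[[1]]$structures$masks[[o]], ext[[2]]$structures$masks[[o]]), 0.0)
  expect_false(qa_gate(native_dices)$pass)
  # while a registered moderate-variation case passes
  reg <- get_registered_cohort()
  pass_ids <- gate_passing_ids(reg)
  expect_gt(length(pass_ids), 0)
})

test_that("bone refinement recovers the cortical/spongy partition and never degrades bones", {
  cases <- get_test_cohort()
  reg <- get_registered_cohort()
  template <- cases[[reg$template_id]]
  id <- setdiff(gate_passing_ids(reg), reg$template_id)[1]
  case <- cases[[id]]
  # rebuild the pre-refinement field to compare before/after
  f0 <- staged_registration(case, template)
  bones_before <- dice(warp_volume(case$structures$masks$bones, f0,
                                   mode = "nearest"),
                       template$structures$masks$bones)
  br <- bone_refinement(case, template, f0)
  bones_after <- dice(warp_volume(case$structures$masks$bones, br$field,
                                  mode = "nearest"),
                      template$structures$masks$bones)
  expect_gte(bones_after, bones_before)
  # Otsu split vs generator ground truth (template side, in its own space)
  expect_gte(dice(br$template_cortical, template$truth$cortical), 0.8)
  expect_gte(dice(br$template_spongy, template$truth$spongy), 0.8)
})

test_that("uniform-HU bones skip the refinement with a warning", {
  cases <- get_test_cohort()
  reg <- get_registered_cohort()
  template <- cases[[reg$template_id]]
  id <- setdiff(names(cases), reg$template_id)[1]
  case <- cases[[id]]
  flat <- function(cs) {
    bones <- cs$structures$masks$bones
    cs$ct$values[bones] <- 300
    cs
  }
  case_f <- flat(case); template_f <- flat(template)
  expect_warning(
    br <- bone_refinement(case_f, template_f, reg$fields[[id]]),
    "degenerate")
  expect_false(br$refined)
  expect_identical(br$field$dx, reg$fields[[id]]$dx)
})
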