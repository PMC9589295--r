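test_that("cohort generation is deterministic and zero variation collapses to one anatomy", {
  p <- test_params()
  c1 <- generate_cohort(p, 3, seed = 5)
  c2 <- generate_cohort(p, 3, seed = 5)
  expect_identical(c1$P01$ct$values, c2$P01$ct$values)
  expect_identical(c1$P03$structures$masks$bladder, c2$P03$structures$masks$bladder)
  p0 <- test_params(variation = list(axis_scale_sd = 0, organ_scale_sd = 0,
                                     jitter_sd_mm = 0, warp_amp_mm = 0))
  a <- generate_patient(p0, 1); b <- generate_patient(p0, 2)
  expect_identical(a$structures$masks$prostate, b$structures$masks$prostate)
  expect_identical(a$structures$masks$rectum, b$structures$masks$rectum)
  expect_error(generate_cohort(p, 1, seed = 1), ">= 2")
})

test_that("target volumes follow the sequential prescription construction", {
  case <- get_test_case()
  m <- case$structures$masks
  expect_identical(m$ctv2, m$prostate)
  expect_true(all(m$ctv1[m$prostate]))              # prostate subset of ctv1
  expect_gt(sum(m$ctv1), sum(m$ctv2))               # vesicles enlarge ctv1
})

test_that("organ masks are disjoint, inside the body, and bones partition into compartments", {
  cases <- generate_cohort(test_params(), 4, seed = 3)
  for (cs in cases) {
    m <- cs$structures$masks
    organs <- list(m$bladder, m$rectum, m$prostate, m$bones)
    for (i in 1:3) for (j in (i + 1):4)
      expect_false(any(organs[[i]] & organs[[j]]))
    expect_true(all(m$body[m$bladder | m$rectum | m$prostate | m$bones]))
    expect_false(any(m$cortical & m$spongy))
    expect_identical(m$cortical | m$spongy, m$bones)
    expect_true(all(vapply(m, sum, 0L) > 0))
    # rectal air is inside the rectum and negative in CT
    expect_true(all(m$rectum[cs$truth$air]))
    expect_lt(mean(cs$ct$values[cs$truth$air]), -300)
  }
})

test_that("tissue CT statistics match the configured distributions (Monte-Carlo oracle)", {
  p <- test_params()
  cases <- generate_cohort(p, 20, seed = 9)
  cort_vals <- unlist(lapply(cases, function(cs)
    cs$ct$values[cs$structures$masks$cortical]))
  # brute-force resampling oracle for the SEM of the mean
  oracle_means <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    mean(rnorm(length(cort_vals), p$hu$cortical[1], p$hu$cortical[2]))
  }, 0.0)
  sem <- sd(oracle_means)
  expect_lt(abs(mean(cort_vals) - p$hu$cortical[1]), 3 * sem + 1e-9)
  spongy_vals <- unlist(lapply(cases, function(cs)
    cs$ct$values[cs$structures$masks$spongy]))
  expect_lt(abs(mean(spongy_vals) - p$hu$spongy[1]),
            3 * p$hu$spongy[2] / sqrt(length(spongy_vals)) + 1e-9)
  # cortical shell is denser than the spongy interior
  expect_gt(mean(cort_vals), mean(spongy_vals) + 200)
})

test_that("cohort organ-volume variability matches the configured coefficients", {
  pv <- test_params(variation = list(axis_scale_sd = 0.05, organ_scale_sd = 0.04,
                                     jitter_sd_mm = 2, warp_amp_mm = 0))
  cases <- generate_cohort(pv, 20, seed = 21)
  vols <- vapply(cases, function(cs) sum(cs$structures$masks$bladder), 0L)
  cv_obs <- sd(vols) / mean(vols)
  # sample-statistics oracle: volume multiplier = prod(axis scales) * s^3
  oracle_cv <- vapply(1:400, function(i) {
    set.seed(2000 + i)
    mult <- vapply(1:20, function(j)
      prod(pmin(pmax(1 + rnorm(3) * 0.05, 0.75), 1.3)) *
        pmin(pmax(1 + rnorm(1) * 0.04, 0.7), 1.4)^3, 0.0)
    sd(mult) / mean(mult)
  }, 0.0)
  expect_gt(cv_obs, quantile(oracle_cv, 0.005))
  expect_lt(cv_obs, quantile(oracle_cv, 0.995))
})

test_that("MRI uses a different contrast than CT with a smooth bias field", {
  case <- get_test_case()
  m <- case$structures$masks
  mri <- case$mri$values
  # T2-like ordering: bladder bright, soft intermediate, cortical bone dark
  expect_gt(mean(mri[m$bladder]), mean(mri[m$body & !m$bones & !m$bladder]))
  expect_gt(mean(mri[m$body & !m$bones & !m$bladder]), mean(mri[m$cortical]))
  # CT ordering is reversed for bone: monotone maps differ
  expect_gt(mean(case$ct$values[m$cortical]),
            mean(case$ct$values[m$body & !m$bones]))
})

test_that("learned-like sCT error field obeys the per-tissue amplitude model", {
  case <- get_test_case()
  # zero amplitude: identical to CT
  s0 <- make_learned_like_sct(case, c(soft = 0, bone = 0, air = 0), 12, seed = 3)
  expect_identical(s0$values, case$ct$values)
  # bone-only amplitude: untouched outside bones
  sb <- make_learned_like_sct(case, c(soft = 0, bone = 50, air = 0), 12, seed = 3)
  bones <- case$structures$masks$bones
  expect_identical(sb$values[!bones], case$ct$values[!bones])
  expect_gt(sd(sb$values[bones] - case$ct$values[bones]), 0)
  expect_error(make_learned_like_sct(case, c(soft = -1, bone = 0, air = 0)),
               ">= 0")
  expect_error(make_learned_like_sct(case, corr_mm = -2), ">= 0")
})

test_that("realized error SD matches amplitude after smoothing-variance correction", {
  # fine grid and a short correlation length so the bone region holds many
  # independent patches of the error field
  case <- memo("case_fine", function()
    generate_patient(test_params_fine(), 1234, id = "F1"))
  amp <- 120; corr <- 3
  sct <- make_learned_like_sct(case, c(soft = 0, bone = amp, air = 0), corr,
                               seed = 17)
  bones <- case$structures$masks$bones
  # brute-force variance oracle on the separable smoothing kernel: the
  # unit-sum Gaussian kernel shrinks white-noise SD by sqrt(sum(k^2))^3
  sigma_vox <- corr / case$ct$spacing[1]
  r <- max(1, ceiling(3 * sigma_vox))
  k <- exp(-0.5 * (-r:r)^2 / sigma_vox^2)
  k <- k / sum(k)
  shrink <- sqrt(sum(k^2))^3
  emp_sd <- sd((sct$values - case$ct$values)[bones])
  expect_lt(abs(emp_sd - amp * shrink) / (amp * shrink), 0.15)
})
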