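stack_of <- function(mat, unit = "HU", mask = NULL) {
  # mat: voxels x patients; volumes are Vx1x1 grids
  vols <- lapply(seq_len(ncol(mat)), function(j)
    volume_grid(array(mat[, j], c(nrow(mat), 1, 1)), unit = unit))
  names(vols) <- sprintf("P%02d", seq_len(ncol(mat)))
  cohort_stack(vols, mask = mask)
}

test_that("voxelwise maps reproduce hand-computed and degenerate cases", {
  ref <- stack_of(cbind(c(100), c(100)))
  pred <- stack_of(cbind(c(90), c(110)))
  m <- voxelwise_maps(ref, pred)
  expect_equal(as.vector(m$vmae$values), 10)
  expect_equal(as.vector(m$vme$values), 0)
  expect_equal(as.vector(m$rsd_ae$values), 0)
  # identical stacks: zero maps, dispersion undefined (0/0)
  m0 <- voxelwise_maps(ref, ref)
  expect_true(all(m0$vmae$values == 0))
  expect_true(all(m0$vme$values == 0))
  expect_true(all(is.na(m0$rsd_ae$values)))
})

test_that("voxelwise maps equal a naive per-voxel loop oracle to 1e-12", {
  set.seed(6)
  p <- 5; d <- c(16, 16, 16); n <- prod(d)
  refm <- matrix(rnorm(n * p, 40, 60), n, p)
  predm <- matrix(rnorm(n * p, 40, 60), n, p)
  vols_r <- lapply(1:p, function(j) volume_grid(array(refm[, j], d), unit = "HU"))
  vols_p <- lapply(1:p, function(j) volume_grid(array(predm[, j], d), unit = "HU"))
  names(vols_r) <- names(vols_p) <- sprintf("P%02d", 1:p)
  maps <- voxelwise_maps(cohort_stack(vols_r), cohort_stack(vols_p))
  for (i in sample.int(n, 50)) {
    r <- refm[i, ]; q <- predm[i, ]
    ae <- abs(r - q)
    vmae <- mean(ae)
    expect_equal(as.vector(maps$vmae$values)[i], vmae, tolerance = 1e-12)
    expect_equal(as.vector(maps$vme$values)[i], mean(r - q), tolerance = 1e-12)
    valid <- abs(r) >= 1
    want_mape <- if (any(valid)) mean(ae[valid] / abs(r[valid])) else NA_real_
    expect_equal(as.vector(maps$vmape$values)[i], want_mape, tolerance = 1e-12)
    want_rsd <- if (vmae >= 1) sqrt(mean((ae - vmae)^2)) / vmae else NA_real_
    expect_equal(as.vector(maps$rsd_ae$values)[i], want_rsd, tolerance = 1e-12)
  }
  # vmae dominates |vme| voxel-wise
  ok <- !is.na(maps$vmae$values)
  expect_true(all(maps$vmae$values[ok] >= abs(maps$vme$values[ok]) - 1e-12))
})

test_that("sign-flip invariance: negating all differences flips vME only", {
  set.seed(7)
  p <- 6; d <- c(6, 6, 3); n <- prod(d)
  refm <- matrix(rnorm(n * p, 0, 50), n, p)
  predm <- matrix(rnorm(n * p, 0, 50), n, p)
  mk <- function(m) {
    vols <- lapply(1:p, function(j) volume_grid(array(m[, j], d), unit = "HU"))
    names(vols) <- sprintf("P%02d", 1:p)
    cohort_stack(vols)
  }
  a <- voxelwise_maps(mk(refm), mk(predm))
  b <- voxelwise_maps(mk(predm), mk(refm))   # negates every D_j
  expect_equal(a$vmae$values, b$vmae$values)
  expect_equal(a$vme$values, -b$vme$values)
  expect_equal(a$rsd_ae$values, b$rsd_ae$values)
  pa <- paired_permutation_test(mk(refm), mk(predm), 500, seed = 5)
  pb <- paired_permutation_test(mk(predm), mk(refm), 500, seed = 5)
  expect_identical(pa$p$values, pb$p$values)
})

test_that("permutation test handles degenerate voxels per the documented conventions", {
  p <- 8
  d <- c(3, 1, 1)
  refm <- matrix(0, 3, p); predm <- matrix(0, 3, p)
  # voxel 1: all zero differences -> p = 1
  # voxel 2: constant nonzero difference -> |T| = Inf, only all-same-sign ties
  refm[2, ] <- 5
  # voxel 3: strong signal
  refm[3, ] <- 100 + rnorm(p, sd = 0.1)
  mk <- function(m) {
    vols <- lapply(1:p, function(j) volume_grid(array(m[, j], d), unit = "HU"))
    names(vols) <- sprintf("P%02d", 1:p)
    cohort_stack(vols)
  }
  set.seed(1)
  res <- paired_permutation_test(mk(refm), mk(predm), n_perm = 2000, seed = 3)
  pv <- as.vector(res$p$values)
  expect_identical(pv[1], 1)
  # expected tie rate for constant differences: 2^(1-p) of random flips
  expect_lt(pv[2], 0.05)
  expect_gt(pv[2], 1 / 2001)
  expect_lt(pv[3], 0.01)
  # p-values bounded below by the add-one estimator
  expect_true(all(pv >= 1 / 2001))
  # determinism under a fixed seed
  res2 <- paired_permutation_test(mk(refm), mk(predm), n_perm = 2000, seed = 3)
  expect_identical(res$p$values, res2$p$values)
  expect_error(paired_permutation_test(mk(refm), mk(predm), n_perm = 50),
               "unstable")
})

test_that("ESR mask uses a strict threshold inside the analysis mask", {
  d <- c(4, 1, 1)
  pv <- volume_grid(array(c(0.01, 0.05, 0.2, 1), d))
  obj <- structure(list(p = pv, n_perm = 100L, alpha = 0.05, seed = 1L,
                        mask = array(c(TRUE, TRUE, TRUE, FALSE), d)),
                   class = "pvalue_volume")
  esr <- esr_mask(obj)
  expect_identical(as.vector(esr), c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(sum(esr), 1L)  # counting oracle
  # all p = 1: empty
  obj$p <- volume_grid(array(1, d))
  expect_false(any(esr_mask(obj)))
})

test_that("p-values are super-uniform under an exchangeable null", {
  set.seed(8)
  p <- 12; d <- c(12, 12, 4); n <- prod(d)
  mk <- function(m) {
    vols <- lapply(1:p, function(j) volume_grid(array(m[, j], d), unit = "Gy"))
    names(vols) <- sprintf("P%02d", 1:p)
    cohort_stack(vols)
  }
  refm <- matrix(rnorm(n * p), n, p)
  predm <- matrix(rnorm(n * p), n, p)
  res <- paired_permutation_test(mk(refm), mk(predm), n_perm = 600, seed = 2)
  pv <- as.vector(res$p$values)
  for (t in c(0.01, 0.05, 0.1, 0.2)) {
    se <- sqrt(t * (1 - t) / n)
    expect_lte(mean(pv <= t), t + 3 * se)
  }
})
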