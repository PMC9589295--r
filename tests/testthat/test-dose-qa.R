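test_that("pelvis crop extends 2 cm beyond the rectum along z", {
  d <- c(10, 10, 45); sp <- c(2, 2, 2)
  body <- array(TRUE, d)
  rectum <- array(FALSE, d)
  rectum[5, 5, 21:31] <- TRUE       # z in [40, 60] mm (0-based centers)
  crop <- crop_pelvis(body, rectum, sp, c(0, 0, 0))
  kz <- which(apply(crop, 3, any))
  zmm <- (kz - 1) * 2
  expect_equal(range(zmm), c(20, 80))            # [40-20, 60+20]
  # slice-counting oracle for the cardinality
  keep <- ((1:45) - 1) * 2 >= 20 & ((1:45) - 1) * 2 <= 80
  expect_identical(sum(crop), sum(body[, , keep]))
  # rectum spanning the whole z-extent: crop == body
  rect_all <- array(FALSE, d); rect_all[5, 5, ] <- TRUE
  expect_identical(crop_pelvis(body, rect_all, sp), body)
  expect_error(crop_pelvis(body, array(FALSE, d), sp), "empty rectum")
})

test_that("MADE-VH curves follow the counting definition", {
  d <- c(10, 10, 1)
  roi <- array(TRUE, d)
  flat <- volume_grid(array(0.7, d), unit = "Gy")
  h <- made_vh(flat, roi)
  expect_equal(made_vh_at(h, 0.5), 100)
  expect_equal(made_vh_at(h, 1), 0)
  expect_equal(h$percent[1], 100)                 # V(0) is always 100%
  expect_true(all(diff(h$percent) <= 1e-9))       # non-increasing
  zero <- volume_grid(array(0, d), unit = "Gy")
  hz <- made_vh(zero, roi)
  expect_equal(made_vh_at(hz, 0.05), 0)           # drops at first positive bin
  # linear ramp 0..2 Gy: V0.5 = 75%, V1 = 50% within one bin
  n <- 100
  ramp <- volume_grid(array(seq(0, 2, length.out = n), c(n, 1, 1)),
                      unit = "Gy")
  hr <- made_vh(ramp, array(TRUE, c(n, 1, 1)))
  vals <- seq(0, 2, length.out = n)
  expect_equal(made_vh_at(hr, 0.5), 100 * mean(vals >= 0.5))  # counting oracle
  expect_equal(made_vh_at(hr, 1.0), 100 * mean(vals >= 1.0))
  expect_lt(abs(made_vh_at(hr, 0.5) - 75), 2)
  expect_lt(abs(made_vh_at(hr, 1.0) - 50), 2)
  expect_error(made_vh(flat, array(FALSE, d)), "empty ROI")
})

test_that("DVH criteria use linear-interpolated percentiles of the sorted dose", {
  d <- c(10, 10, 1)
  uni <- volume_grid(array(78, d), unit = "Gy")
  roi <- array(TRUE, d)
  crit <- dvh_criteria(uni, roi)
  expect_equal(unlist(crit), c(dmean = 78, d2 = 78, d50 = 78, d95 = 78))
  # 100-voxel ramp 0..99: D50 = 49.5 by the interpolation rule
  ramp <- volume_grid(array(0:99, c(100, 1, 1)), unit = "Gy")
  cr <- dvh_criteria(ramp, array(TRUE, c(100, 1, 1)))
  expect_equal(cr$d50, 49.5)
  # sort-and-index oracle via quantile type 7
  expect_equal(cr$d2, unname(quantile(0:99, 0.98)))
  expect_equal(cr$d95, unname(quantile(0:99, 0.05)))
  expect_gte(cr$d2, cr$d50); expect_gte(cr$d50, cr$d95)
  # identical doses give identically zero differences
  diffs <- criteria_diff(ramp, ramp, list(all = array(TRUE, c(100, 1, 1))))
  expect_true(all(diffs$abs_diff == 0))
})

test_that("gamma of identical doses is zero and a uniform 0.5% offset gives gamma 0.5", {
  d <- c(12, 12, 6)
  ref <- volume_grid(array(50, d), c(2, 2, 2), unit = "Gy")
  g0 <- gamma_3d(ref, ref)
  expect_true(all(g0$gamma$values[!is.na(g0$gamma$values)] < 1e-9))
  expect_equal(g0$pass_rate, 100)
  # uniform field, +0.5% dose: no DTA benefit anywhere, gamma = 0.5
  ev <- with_values(ref, ref$values * 1.005)
  gh <- gamma_3d(ref, ev, dose_pct = 1, dta_mm = 1)
  gv <- gh$gamma$values[!is.na(gh$gamma$values)]
  expect_lt(max(abs(gv - 0.5)), 1e-6)
  expect_equal(gh$pass_rate, 100)
})

test_that("gamma matches an exhaustive brute-force search within 0.02", {
  set.seed(13)
  d <- c(24, 24, 24); sp <- c(2, 2, 2)
  # gently varying fields (about 1%/mm gradients) so the subvoxel search
  # is numerically well posed for both implementations
  base <- smooth_volume(array(rnorm(prod(d)), d), 12)
  ref_arr <- 50 + 10 * base / sd(base)
  pert <- smooth_volume(array(rnorm(prod(d)), d), 12)
  ev_arr <- ref_arr * (1 + 0.003 * pert / sd(pert)) + 0.12
  ref <- volume_grid(ref_arr, sp, unit = "Gy")
  ev <- volume_grid(ev_arr, sp, unit = "Gy")
  res <- gamma_3d(ref, ev, dose_pct = 1, dta_mm = 1, threshold_pct = 10)
  # exhaustive oracle: full scan of a dense offset lattice, no shortcuts
  dmax <- max(ref_arr)
  step <- 0.1
  offs <- expand.grid(ox = seq(-3, 3, step), oy = seq(-3, 3, step),
                      oz = seq(-3, 3, step))  # dense full-lattice scan
  offs <- offs[offs$ox^2 + offs$oy^2 + offs$oz^2 <= 9 + 1e-9, ]
  r2 <- offs$ox^2 + offs$oy^2 + offs$oz^2
  interp1 <- function(arr, x, y, z) {
    # trilinear sample at voxel coords (vectorized over points)
    x0 <- pmin(pmax(floor(x), 0), d[1] - 2); fx <- x - x0
    y0 <- pmin(pmax(floor(y), 0), d[2] - 2); fy <- y - y0
    z0 <- pmin(pmax(floor(z), 0), d[3] - 2); fz <- z - z0
    # fractional parts computed after clamping, so boundary samples stay exact
    id <- function(a, b, cc) a + d[1] * (b + d[2] * cc) + 1
    c000 <- arr[id(x0, y0, z0)]; c100 <- arr[id(x0 + 1, y0, z0)]
    c010 <- arr[id(x0, y0 + 1, z0)]; c110 <- arr[id(x0 + 1, y0 + 1, z0)]
    c001 <- arr[id(x0, y0, z0 + 1)]; c101 <- arr[id(x0 + 1, y0, z0 + 1)]
    c011 <- arr[id(x0, y0 + 1, z0 + 1)]; c111 <- arr[id(x0 + 1, y0 + 1, z0 + 1)]
    c00 <- c000 + (c100 - c000) * fx; c10 <- c010 + (c110 - c010) * fx
    c01 <- c001 + (c101 - c001) * fx; c11 <- c011 + (c111 - c011) * fx
    c0 <- c00 + (c10 - c00) * fy; c1 <- c01 + (c11 - c01) * fy
    c0 + (c1 - c0) * fz
  }
  evaluable <- which(ref_arr >= 0.1 * dmax)
  set.seed(14)
  sample_idx <- sample(evaluable, 150)
  arr_ind <- arrayInd(sample_idx, d)
  for (q in seq_along(sample_idx)) {
    i <- arr_ind[q, 1]; j <- arr_ind[q, 2]; k <- arr_ind[q, 3]
    rd <- ref_arr[i, j, k]
    delta <- 0.01 * rd
    X <- (i - 1) + offs$ox / sp[1]
    Y <- (j - 1) + offs$oy / sp[2]
    Z <- (k - 1) + offs$oz / sp[3]
    inb <- X >= 0 & X <= d[1] - 1 & Y >= 0 & Y <= d[2] - 1 &
      Z >= 0 & Z <= d[3] - 1
    ed <- interp1(ev_arr, X[inb], Y[inb], Z[inb])
    g2 <- ((ed - rd) / delta)^2 + r2[inb] / 1^2
    want <- sqrt(min(g2))
    expect_lt(abs(res$gamma$values[i, j, k] - want), 0.02)
  }
  expect_true(all(res$gamma$values[!is.na(res$gamma$values)] >= 0))
})

test_that("loosening gamma criteria never increases any gamma value", {
  set.seed(15)
  d <- c(16, 16, 8); sp <- c(2.5, 2.5, 2.5)
  base <- smooth_volume(array(rnorm(prod(d)), d), 8)
  ref <- volume_grid(40 + 10 * base / sd(base), sp, unit = "Gy")
  ev <- with_values(ref, ref$values * 1.006 + 0.1)
  tight <- gamma_3d(ref, ev, dose_pct = 1, dta_mm = 1)
  loose_d <- gamma_3d(ref, ev, dose_pct = 2, dta_mm = 1)
  loose_r <- gamma_3d(ref, ev, dose_pct = 1, dta_mm = 2)
  ok <- !is.na(tight$gamma$values)
  expect_true(all(loose_d$gamma$values[ok] <= tight$gamma$values[ok] + 1e-9))
  expect_true(all(loose_r$gamma$values[ok] <= tight$gamma$values[ok] + 1e-9))
  expect_error(gamma_3d(ref, ev, threshold_pct = 101), "threshold|voxel")
})
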