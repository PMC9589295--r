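test_that("signed distance maps match geometry and a brute-force oracle", {
  d <- c(9, 9, 9)
  single <- array(FALSE, d); single[5, 5, 5] <- TRUE
  dm <- distance_map(single, spacing = c(2, 2, 2))
  expect_equal(dm$values[6, 5, 5], 2)          # neighbor center distance
  expect_equal(dm$values[5, 5, 7], 4)
  expect_lt(dm$values[5, 5, 5], 0)             # negative inside
  # sphere: |value at center| close to the radius
  d2 <- c(21, 21, 21)
  co <- (0:20) * 2
  X <- array(co, d2); Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))
  R <- 12
  sphere <- (X - 20)^2 + (Y - 20)^2 + (Z - 20)^2 <= R^2
  dms <- distance_map(sphere, spacing = c(2, 2, 2))
  expect_lt(abs(abs(dms$values[11, 11, 11]) - R), sqrt(3 * 4) + 1e-9)
  # random blob on a 20^3 grid vs exhaustive nearest-voxel search
  set.seed(9)
  d3 <- c(20, 20, 20); sp <- c(1, 1.5, 2)
  blob <- array(FALSE, d3)
  blob[sample(prod(d3), 40)] <- TRUE
  got <- distance_map(blob, spacing = sp)$values
  idx_in <- which(blob, arr.ind = TRUE)
  idx_out <- which(!blob, arr.ind = TRUE)
  scale <- function(m) sweep(m - 1, 2, sp, `*`)
  pin <- scale(idx_in); pout <- scale(idx_out)
  for (q in sample(nrow(idx_out), 25)) {
    want <- sqrt(min(colSums((t(pin) - pout[q, ])^2)))
    expect_equal(got[idx_out[q, 1], idx_out[q, 2], idx_out[q, 3]], want,
                 tolerance = 1e-9)
  }
  for (q in sample(nrow(idx_in), 10)) {
    want <- -sqrt(min(colSums((t(pout) - pin[q, ])^2)))
    expect_equal(got[idx_in[q, 1], idx_in[q, 2], idx_in[q, 3]], want,
                 tolerance = 1e-9)
  }
  expect_error(distance_map(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("tubular Laplace field is radially monotone and discretely harmonic", {
  d <- c(17, 17, 13)
  co <- 0:16
  X <- array(co, d); Y <- aperm(array(co, d[c(2, 1, 3)]), c(2, 1, 3))
  cyl <- (X - 8)^2 + (Y - 8)^2 <= 25
  field <- laplace_field_tubular(cyl, spacing = c(1, 1, 1))
  v <- field$values
  # zero on the axis, one at the wall (voxels with a 6-neighbour outside the
  # mask, or at the volume z-faces), monotone in radius
  expect_equal(v[9, 9, 7], 0)
  nb6_out <- function(m, i, j, k) {
    dd <- dim(m)
    !(i > 1 && m[i - 1, j, k]) || !(i < dd[1] && m[i + 1, j, k]) ||
      !(j > 1 && m[i, j - 1, k]) || !(j < dd[2] && m[i, j + 1, k]) ||
      !(k > 1 && m[i, j, k - 1]) || !(k < dd[3] && m[i, j, k + 1])
  }
  wall <- array(FALSE, d)
  for (ii0 in which(cyl)) {
    ai <- arrayInd(ii0, d)
    wall[ii0] <- nb6_out(cyl, ai[1], ai[2], ai[3])
  }
  wall[9, 9, ] <- FALSE   # the central-path sink takes precedence over wall
  expect_true(all(v[wall] == 1))
  mids <- v[11, 9, 7]  # radius 2
  expect_gt(mids, 0); expect_lt(mids, 1)
  expect_lt(v[10, 9, 7], v[11, 9, 7])
  # 2D finite-difference oracle at the same unit discretization: single-cell
  # sink at the center, wall on cells with a 4-neighbour outside the disc
  solve_2d <- function(n = 17) {
    xs <- 0:(n - 1)
    disc <- outer((xs - 8)^2, (xs - 8)^2, `+`) <= 25
    wall2 <- disc & !(rbind(FALSE, disc[-n, ]) & rbind(disc[-1, ], FALSE) &
                        cbind(FALSE, disc[, -n]) & cbind(disc[, -1], FALSE))
    u <- matrix(0.5, n, n)
    u[!disc] <- 1
    u[wall2] <- 1
    u[9, 9] <- 0
    for (it in 1:4000) {
      un <- 0.25 * (rbind(u[-1, ], u[n, ]) + rbind(u[1, ], u[-n, ]) +
                      cbind(u[, -1], u[, n]) + cbind(u[, 1], u[, -n]))
      un[wall2] <- 1; un[9, 9] <- 0; un[!disc] <- 1
      delta <- max(abs(un - u))
      u <- un
      if (delta < 1e-8) break
    }
    u
  }
  u2 <- solve_2d()
  # mid-plane of the 3D tube vs the 2D solution: the z-faces (value 1) are
  # 6 slices away, their influence decays to a few percent by the middle
  expect_lt(abs(mids - u2[11, 9]), 0.08)
  # interior voxels satisfy the discrete mean-value property
  interior <- cyl & !wall
  interior[9, 9, ] <- FALSE                      # exclude the sink line
  ii <- which(interior, arr.ind = TRUE)
  for (q in sample(nrow(ii), 20)) {
    i <- ii[q, 1]; j <- ii[q, 2]; k <- ii[q, 3]
    nb <- c(v[i - 1, j, k], v[i + 1, j, k], v[i, j - 1, k], v[i, j + 1, k],
            v[i, j, k - 1], v[i, j, k + 1])
    expect_lt(abs(v[i, j, k] - mean(nb)), 1e-3)
  }
})

test_that("one-voxel-thick tube is all boundary", {
  d <- c(7, 7, 9)
  thin <- array(FALSE, d)
  thin[4, 4, 2:8] <- TRUE
  f <- laplace_field_tubular(thin, spacing = c(1, 1, 1))
  # every mask voxel is on the central path (sink) or surface; off-path
  # voxels do not exist, so the field is 0 on the path
  expect_true(all(f$values[thin] %in% c(0, 1)))
})

test_that("radial Laplace field is spherically symmetric with the maximum at the surface", {
  d <- c(17, 17, 17)
  co <- 0:16
  X <- array(co, d); Y <- aperm(array(co, d[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(co, d[c(3, 1, 2)]), c(2, 3, 1))
  r2 <- (X - 8)^2 + (Y - 8)^2 + (Z - 8)^2
  sphere <- r2 <= 36
  f <- laplace_field_radial(sphere, spacing = c(1, 1, 1))
  v <- f$values
  expect_equal(v[9, 9, 9], 0)                    # barycenter sink
  inside <- sphere & !is.na(v)
  expect_true(all(v[inside] >= 0 & v[inside] <= 1))
  expect_equal(max(v[inside]), 1)                # maximum principle: surface
  # symmetry oracle: matched-radius shells have near-equal values
  for (rr in c(4, 9, 16)) {
    shell <- sphere & abs(r2 - rr) < 0.5
    if (sum(shell) > 3) expect_lt(diff(range(v[shell])), 0.08)
  }
  # monotone in radius along an axis
  prof <- v[9:14, 9, 9]
  expect_true(all(diff(prof) > -1e-9))
  expect_error(laplace_field_radial(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("template selection minimizes summed relative deviation from median volumes", {
  cases <- get_test_cohort()
  got <- select_template(cases)
  # brute-force scoring oracle
  organs <- c("bladder", "rectum", "prostate")
  vols <- sapply(organs, function(o)
    vapply(cases, function(cs) sum(cs$structures$masks[[o]]), 0L))
  med <- apply(vols, 2, median)
  score <- rowSums(abs(sweep(vols, 2, med)) %*% diag(1 / med))
  expect_identical(got, names(cases)[which.min(score)])
  # tie rule: identical patients resolve to the lowest id
  p0 <- test_params(variation = list(axis_scale_sd = 0, organ_scale_sd = 0,
                                     jitter_sd_mm = 0, warp_amp_mm = 0))
  same <- generate_cohort(p0, 3, seed = 1)
  expect_identical(select_template(same), "P01")
  expect_error(select_template(same[1:2]), "at least 3")
})

test_that("field composition has the zero field as identity and sums translations", {
  d <- c(10, 10, 6)
  g <- volume_grid(array(0, d), c(2, 2, 2))
  z <- zero_field(g)
  cst <- function(v) vector_field(array(v[1], d), array(v[2], d),
                                  array(v[3], d), c(2, 2, 2))
  f <- cst(c(3, -2, 1))
  expect_equal(compose_fields(z, f)$dx, f$dx)
  expect_equal(compose_fields(f, z)$dx, f$dx)
  both <- compose_fields(cst(c(1, 2, 0)), cst(c(3, 0, -1)))
  expect_true(all(abs(both$dx - 4) < 1e-12))
  expect_true(all(abs(both$dy - 2) < 1e-12))
  expect_true(all(abs(both$dz - (-1)) < 1e-12))
})

test_that("warping with a composed field matches sequential warps on smooth volumes", {
  set.seed(10)
  d <- c(24, 24, 12); sp <- c(2, 2, 2)
  base <- array(rnorm(prod(d)), d)
  vol <- volume_grid(smooth_volume(base, 6), sp)
  smooth_field <- function(seed) {
    set.seed(seed)
    mk <- function() 3 * smooth_volume(array(rnorm(prod(d)), d), 10) /
      sd(smooth_volume(array(rnorm(prod(d)), d), 10))
    vector_field(mk(), mk(), mk(), sp)
  }
  f1 <- smooth_field(21); f2 <- smooth_field(22)
  comp <- compose_fields(f1, f2)
  oneshot <- warp_volume(vol, comp)
  twostep <- warp_volume(warp_volume(vol, f1), f2)
  core <- array(FALSE, d); core[5:20, 5:20, 3:10] <- TRUE
  expect_lt(mean(abs(oneshot$values - twostep$values)[core]), 0.05)
})

test_that("warp_volume identities, shifts and mask behavior", {
  set.seed(11)
  d <- c(12, 10, 8); sp <- c(2, 2, 2)
  vol <- volume_grid(array(rnorm(prod(d)), d), sp, unit = "HU")
  z <- zero_field(vol)
  expect_equal(warp_volume(vol, z)$values, vol$values)
  # constant one-voxel shift along x: interior is an exact shift
  shift <- vector_field(array(2, d), array(0, d), array(0, d), sp)
  w <- warp_volume(vol, shift)
  expect_equal(w$values[1:11, , ], vol$values[2:12, , ])
  expect_true(all(w$values[12, , ] == -1000))    # HU background
  mask <- array(runif(prod(d)) > 0.5, d)
  wm <- warp_volume(mask, shift)
  expect_type(wm, "logical")
})

test_that("dice handles the documented edge cases", {
  a <- array(FALSE, c(4, 4, 4)); b <- a
  expect_identical(dice(a, b), 1.0)              # both empty
  a[1:2, , ] <- TRUE
  expect_identical(dice(a, a), 1.0)
  b[3:4, , ] <- TRUE
  expect_identical(dice(a, b), 0.0)
  # 10^3 cubes offset by half: analytic 0.5
  big <- c(20, 10, 10)
  x <- array(FALSE, big); y <- array(FALSE, big)
  x[1:10, , ] <- TRUE; y[6:15, , ] <- TRUE
  expect_equal(dice(x, y), 0.5)
})

test_that("qa gate requires every organ strictly above threshold", {
  all9 <- c(body = 0.9, bones = 0.9, bladder = 0.9, rectum = 0.9,
            prostate = 0.9)
  expect_true(qa_gate(all9)$pass)
  exact <- all9; exact["rectum"] <- 0.85
  g <- qa_gate(exact)
  expect_false(g$pass)
  expect_identical(g$failures, "rectum")
  expect_true(qa_gate(all9 * 0 + 1)$pass)
  expect_error(qa_gate(c(body = 1)), "missing organ")
})

test_that("rigid translation recovers a known shift and is a fixed point at identity", {
  case <- get_test_case()
  sd_obj <- build_sd(case$mri, case$structures)
  body <- case$structures$masks$body
  # identity
  f0 <- rigid_translate(sd_obj$merged, sd_obj$merged, body, body)
  expect_lt(max(abs(c(f0$dx[1], f0$dy[1], f0$dz[1]))), 1.01)
  # known shift: move the merged SD by 6 mm along x via a constant warp
  d <- dim(sd_obj$merged$values)
  shift6 <- vector_field(array(6, d), array(0, d), array(0, d),
                         sd_obj$merged$spacing)
  # warp with +6 mm samples at x+6: the anatomy moves 6 mm toward -x, so
  # the recovered translation back onto the template is -6 mm
  moved <- warp_volume(sd_obj$merged, shift6, background = 0)
  moved_body <- warp_volume(body, shift6)
  fr <- rigid_translate(moved, sd_obj$merged, moved_body, body)
  expect_lt(abs(fr$dx[1] + 6), 2.6)              # within one voxel
  expect_lt(abs(fr$dy[1]), 2.6)
  expect_error(rigid_translate(sd_obj$merged, sd_obj$merged,
                               array(FALSE, d), body), "empty body")
})

test_that("demons is the identity on equal images and skips empty schedules", {
  case <- get_test_case()
  ch <- build_sd(case$mri, case$structures)$channels$organs
  f <- demons_stage(ch, ch, c(20, 20, 10, 0), sigma = 1)
  mag <- sqrt(f$dx^2 + f$dy^2 + f$dz^2) / min(ch$spacing)
  expect_lt(max(mag), 0.1)
  init <- vector_field(array(1, dim(ch$values)), array(0, dim(ch$values)),
                       array(0, dim(ch$values)), ch$spacing)
  f0 <- demons_stage(ch, ch, c(0, 0, 0, 0), init = init)
  expect_identical(f0$dx, init$dx)
  bad <- with_values(ch, ch$values + c(NaN, rep(0, length(ch$values) - 1)))
  expect_error(demons_stage(ch, bad, c(1, 0, 0, 0)), "non-finite")
})

test_that("demons recovers a known smooth synthetic warp within a voxel", {
  # a feature-rich volume (texture everywhere) so the displacement is
  # identifiable at every voxel; a featureless interior would make full
  # in-body recovery impossible for any intensity-driven method
  d <- c(64L, 64L, 32L); sp <- c(2.5, 2.5, 2.5)
  set.seed(12)
  tex <- smooth_volume(array(rnorm(prod(d)), d), 6)
  img <- volume_grid(100 * tex / sd(tex), sp)
  mkc <- function() {
    w <- smooth_volume(array(rnorm(prod(d)), d), 20)
    4 * w / sd(w)
  }
  truth <- vector_field(mkc(), mkc(), mkc(), sp)
  warped <- warp_volume(img, truth, background = 0)
  rec <- demons_stage(warped, img, c(100, 100, 50, 20), sigma = 1,
                      factors = c(4, 2, 1, 1))
  err <- sqrt((rec$dx - truth$dx)^2 + (rec$dy - truth$dy)^2 +
                (rec$dz - truth$dz)^2)
  core <- array(FALSE, d); core[9:56, 9:56, 5:28] <- TRUE
  expect_lt(mean(err[core]), min(sp))
})

test_that("jacobian of a small smooth field stays positive, a folding field does not", {
  d <- c(16, 16, 8); sp <- c(2, 2, 2)
  mild <- vector_field(array(1, d), array(0.5, d), array(0, d), sp)
  expect_identical(jacobian_positive_fraction(mild), 1)
  # a steep sign-flipping displacement folds space
  ramp <- array(rep(c(6, -6), length.out = d[1]), d)
  folding <- vector_field(ramp, array(0, d), array(0, d), sp)
  expect_lt(jacobian_positive_fraction(folding), 1)
})
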