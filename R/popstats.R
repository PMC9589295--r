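#' Per-voxel aligned cohort of volumes in the common coordinate system
#'
#' Stacks p geometry-compatible patient volumes (already propagated to the
#' CCS) into one 4D array, together with the analysis mask (the template
#' body contour): all population statistics are computed inside that mask
#' only.
#'
#' @param volumes List of `volume_grid`s (one per patient, same geometry and
#'   unit).
#' @param ids Patient identifiers aligned with `volumes`.
#' @param mask Logical analysis mask (template body contour).
#' @return An object of class `cohort_stack`.
#' @export
cohort_stack <- function(volumes, ids = names(volumes), mask = NULL) {
  p <- length(volumes)
  if (p < 2) stop("a cohort stack needs at least 2 patients", call. = FALSE)
  ref <- volumes[[1]]
  for (v in volumes[-1]) {
    stop_if_incompatible(ref, v)
    stop_if_unit_mismatch(ref, v)
  }
  if (is.null(ids)) ids <- sprintf("P%02d", seq_len(p))
  d <- dim(ref$values)
  data <- array(0, c(d, p))
  for (j in seq_len(p)) data[, , , j] <- volumes[[j]]$values
  if (is.null(mask)) mask <- array(TRUE, d)
  mask <- as_mask(mask)
  structure(list(data = data, ids = as.character(ids), mask = mask,
                 spacing = ref$spacing, origin = ref$origin, unit = ref$unit),
            class = "cohort_stack")
}

#' @export
print.cohort_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cohort_stack> %d patients on %s grid [%s], %d voxels in mask\n",
              d[4], paste(d[1:3], collapse = "x"), x$unit, sum(x$mask)))
  invisible(x)
}

check_paired <- function(ref_stack, pred_stack) {
  if (!identical(dim(ref_stack$data), dim(pred_stack$data)))
    stop("stacks differ in shape", call. = FALSE)
  if (!identical(ref_stack$ids, pred_stack$ids))
    stop("patient ids are not aligned between stacks", call. = FALSE)
  invisible(TRUE)
}

#' Voxel-wise population error maps
#'
#' For each voxel i with patient values ref(i,j), pred(i,j), j = 1..p:
#' vMAE(i) = mean_j |ref - pred|, vME(i) = mean_j (ref - pred),
#' vMAPE(i) = mean over valid j of |(ref - pred)/ref| (valid: |ref| above
#' the unit epsilon), and RSD_AE(i) = sqrt(mean_j (AE - vMAE)^2) / vMAE, the
#' coefficient of variation of the absolute error (undefined where vMAE is
#' below epsilon). Values outside the analysis mask are NA.
#'
#' @param ref_stack,pred_stack Paired `cohort_stack`s.
#' @return List of `volume_grid`s `vmae`, `vme`, `vmape`, `rsd_ae`, plus
#'   `vmape_n` (per-voxel count of valid patients).
#' @export
voxelwise_maps <- function(ref_stack, pred_stack) {
  check_paired(ref_stack, pred_stack)
  d4 <- dim(ref_stack$data)
  d3 <- d4[1:3]
  p <- d4[4]
  eps <- ape_eps(ref_stack$unit)
  Dm <- matrix(ref_stack$data - pred_stack$data, ncol = p)
  Am <- abs(Dm)
  Rm <- matrix(ref_stack$data, ncol = p)
  vmae <- rowMeans(Am)
  vme <- rowMeans(Dm)
  validm <- abs(Rm) >= eps
  apem <- Am / abs(Rm)
  apem[!validm] <- 0
  nvalid <- rowSums(validm)
  vmape <- ifelse(nvalid > 0, rowSums(apem) / nvalid, NA_real_)
  rsd <- sqrt(rowMeans((Am - vmae)^2))
  rsd <- ifelse(vmae >= eps, rsd / vmae, NA_real_)
  dim(vmae) <- d3; dim(vme) <- d3; dim(vmape) <- d3; dim(rsd) <- d3
  dim(nvalid) <- d3
  msk <- ref_stack$mask
  mkv <- function(v, unit) {
    v[!msk] <- NA_real_
    volume_grid(v, ref_stack$spacing, ref_stack$origin, unit)
  }
  list(vmae = mkv(vmae, ref_stack$unit), vme = mkv(vme, ref_stack$unit),
       vmape = mkv(vmape, "unitless"), rsd_ae = mkv(rsd, "unitless"),
       vmape_n = nvalid)
}

#' Studentized sign-flip paired permutation test, voxel-wise
#'
#' At each voxel the paired differences D_j = ref_j - pred_j give the
#' observed statistic T = mean(D) / (sd(D)/sqrt(p)) (sample sd, p-1
#' denominator). The null distribution is generated by `n_perm` independent
#' uniform sign-flip vectors (swapping a pair is equivalent to negating its
#' difference); the same flip sequence, drawn from `seed`, is reused across
#' voxels. Two-sided p-values use the add-one estimator
#' p = (1 + #\{|T*| >= |T|\}) / (n_perm + 1), so p is never exactly 0.
#' Voxels with all D_j = 0 carry no evidence and get p = 1; voxels with a
#' constant non-zero difference have |T| = Inf and only all-same-sign flips
#' tie.
#'
#' @param ref_stack,pred_stack Paired `cohort_stack`s.
#' @param n_perm Number of sign-flip permutations (>= 100).
#' @param alpha Significance level recorded in the result.
#' @param seed Integer seed for the flip matrix.
#' @param block_voxels Voxels processed per block (memory control).
#' @return An object of class `pvalue_volume`: `p` (`volume_grid` of
#'   p-values, NA outside the mask), `n_perm`, `alpha`, `seed`.
#' @export
paired_permutation_test <- function(ref_stack, pred_stack, n_perm = 10000L,
                                    alpha = 0.05, seed = 1L,
                                    block_voxels = 20000L) {
  check_paired(ref_stack, pred_stack)
  if (n_perm < 100) stop("n_perm below 100 gives unstable p-values", call. = FALSE)
  d4 <- dim(ref_stack$data)
  p <- d4[4]
  msk <- ref_stack$mask
  nvox <- sum(msk)
  D <- matrix(ref_stack$data - pred_stack$data, ncol = p)[which(msk), , drop = FALSE]
  S <- with_seed(seed,
                 matrix(sample(c(-1, 1), p * n_perm, replace = TRUE), nrow = p))
  pvals <- numeric(nvox)
  for (start in seq(1, nvox, by = block_voxels)) {
    idx <- start:min(start + block_voxels - 1, nvox)
    Db <- D[idx, , drop = FALSE]
    ss <- rowSums(Db^2)
    m_obs <- rowMeans(Db)
    var_obs <- pmax((ss - p * m_obs^2) / (p - 1), 0)
    t_obs <- abs(m_obs) / sqrt(var_obs / p)   # Inf when var = 0, m != 0
    M <- (Db %*% S) / p
    Vr <- pmax((ss - p * M^2) / (p - 1), 0)
    Tp <- abs(M) / sqrt(Vr / p)
    cnt <- rowSums(Tp >= t_obs)
    pv <- (1 + cnt) / (n_perm + 1)
    allzero <- ss == 0
    pv[allzero] <- 1
    pvals[idx] <- pv
  }
  out <- array(NA_real_, d4[1:3])
  out[which(msk)] <- pvals
  structure(list(p = volume_grid(out, ref_stack$spacing, ref_stack$origin,
                                 "unitless"),
                 n_perm = as.integer(n_perm), alpha = alpha, seed = seed,
                 mask = msk),
            class = "pvalue_volume")
}

#' @export
print.pvalue_volume <- function(x, ...) {
  pv <- x$p$values[x$mask]
  cat(sprintf("<pvalue_volume> %d voxels, %d permutations, %.1f%% below alpha=%g\n",
              length(pv), x$n_perm, 100 * mean(pv < x$alpha), x$alpha))
  invisible(x)
}

#' Error subregion (ESR) mask
#'
#' Voxels where the permutation test rejects equality of reference and
#' prediction: strictly `p < alpha`, intersected with the analysis mask.
#'
#' @param pvals A `pvalue_volume`.
#' @param alpha Significance level (default the one stored in `pvals`).
#' @return Logical 3D mask.
#' @export
esr_mask <- function(pvals, alpha = pvals$alpha) {
  pv <- pvals$p$values
  out <- !is.na(pv) & pv < alpha & pvals$mask
  dim(out) <- dim(pv)
  out
}
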