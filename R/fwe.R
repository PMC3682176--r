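# Family-wise-error control for the Step-1 search.
#
# The whole-brain correction is a sign-flipping permutation test on the
# subject difference images: under the null of no covariate effect the
# subject-wise relation between density change (time effect removed by the
# model intercept) and the encoded IQ-change covariate is symmetric, so
# each permutation randomly negates each subject's covariates and records
# the maximal voxel t (height) and the maximal supra-threshold cluster
# size (extent). The 95th percentiles of these max distributions are the
# corrected thresholds. A Bonferroni height threshold is available as a
# cheap, more conservative alternative.

# Joint null distribution for both IQ covariates. D: subjects x voxels
# difference matrix; dmat: subjects x 2 (d_viq, d_piq). The identity
# permutation is included as the first sample.
sign_flip_null <- function(D, dmat, n_perm, seed, forming_t, dim,
                           connectivity = 26L) {
  n <- nrow(D)
  df <- n - 3
  stopifnot(df > 0, length(forming_t) == 2)
  set.seed(derive_seed(seed, "signflip"))
  Dss <- colSums(D^2)
  max_t <- matrix(NA_real_, n_perm, 2)
  max_k <- matrix(NA_integer_, n_perm, 2)
  for (r in seq_len(n_perm)) {
    s <- if (r == 1) rep(1, n) else sample(c(-1, 1), n, replace = TRUE)
    X <- cbind(1, s * dmat[, 1], s * dmat[, 2])
    XtX_inv <- solve(crossprod(X))
    XtY <- crossprod(X, D)
    B <- XtX_inv %*% XtY
    sigma2 <- pmax(Dss - colSums(B * XtY), 0) / df
    for (j in 1:2) {
      tj <- B[j + 1, ] / sqrt(sigma2 * XtX_inv[j + 1, j + 1])
      tj[!is.finite(tj)] <- 0 # zero-residual, zero-effect voxels
      max_t[r, j] <- max(tj)
      max_k[r, j] <- max_cluster_size(which(tj >= forming_t[j]), dim,
                                      connectivity)
    }
  }
  list(max_t = max_t, max_k = max_k, df = df)
}

#' Permutation FWE thresholds for one IQ-change contrast
#'
#' Computes the corrected height (peak t) and extent (cluster size)
#' thresholds at the 5% family-wise level by sign-flipping permutation on
#' the subject difference images (see the module notes above).
#'
#' @param volumes a `cohort_volumes` object.
#' @param design design matrix from [build_design()] for the same cohort.
#' @param contrast `c(0, 1, 0)` (VIQ change) or `c(0, 0, 1)` (PIQ change);
#'   corrected thresholds are defined for the single-covariate contrasts.
#' @param n_perm number of permutations, at least 100 (the 95th percentile
#'   is not estimable below that).
#' @param seed integer seed for the sign flips.
#' @param cluster_forming_p one-sided uncorrected p defining the
#'   supra-threshold clusters whose extent is tested.
#' @param fwe_p family-wise level (default 0.05).
#' @param connectivity cluster connectivity (6, 18 or 26).
#' @return a list: `height_t_crit`, `extent_k_crit`, `forming_t`, `df`.
#' @export
fwe_thresholds <- function(volumes, design, contrast, n_perm = 500, seed = 1,
                           cluster_forming_p = 0.001, fwe_p = 0.05,
                           connectivity = 26L) {
  if (n_perm < 100)
    abort("n_perm must be at least 100 for a stable 95th percentile")
  stopifnot(length(contrast) == 3)
  j <- if (identical(as.numeric(contrast), c(0, 1, 0))) 1L
  else if (identical(as.numeric(contrast), c(0, 0, 1))) 2L
  else abort("FWE thresholds are defined for contrasts (0,1,0) and (0,0,1)")
  dmat <- cbind(attr(design, "d_viq"), attr(design, "d_piq"))
  df <- nrow(dmat) - 3
  forming_t <- rep(qt(1 - cluster_forming_p, df), 2)
  null <- sign_flip_null(density_change_matrix(volumes), dmat, n_perm, seed,
                         forming_t, volumes$dim, connectivity)
  list(
    height_t_crit = perm_critical(null$max_t[, j], 1 - fwe_p),
    extent_k_crit = perm_critical(null$max_k[, j], 1 - fwe_p),
    forming_t = forming_t[j], df = df
  )
}

#' Bonferroni height threshold
#'
#' Height-only corrected threshold `qt(1 - fwe_p / V, df)`; the matching
#' extent threshold is infinite (no extent rule). More conservative than
#' the permutation thresholds when voxels are spatially correlated, but
#' free of any permutation cost.
#'
#' @param n_voxels number of voxels searched.
#' @param df error degrees of freedom.
#' @param fwe_p family-wise level.
#' @return a list shaped like the [fwe_thresholds()] value.
#' @export
bonferroni_threshold <- function(n_voxels, df, fwe_p = 0.05) {
  list(height_t_crit = qt(1 - fwe_p / n_voxels, df),
       extent_k_crit = Inf, forming_t = NA_real_, df = df)
}
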