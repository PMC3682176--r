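# Internal numeric helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in a run (cohort simulation, permutations, split
#' assignment) flows from one master seed through purpose-specific
#' sub-seeds, so that e.g. adding permutations does not perturb the split
#' sequence. Result is always a positive integer below 2^31.
#'
#' @param master integer master seed.
#' @param purpose character tag naming the consumer of the sub-seed.
#' @param index integer index (fold, repeat, permutation block).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, purpose, index = 0L) {
  h <- (abs(as.double(master)) %% 2147483647) * 48271 +
    sum(utf8ToInt(purpose)) * 9973 +
    as.double(index) * 7919
  as.integer(h %% 2147483629) + 1L
}

# One-sided t -> z map used for all reported z-scores. Works in log-p space
# so very large t does not underflow; |z| capped at 38 (the sentinel for a
# perfect, zero-residual fit).
t_to_z <- function(t, df, cap = 38) {
  z <- ifelse(
    is.infinite(t), sign(t) * cap,
    qnorm(pt(t, df, lower.tail = FALSE, log.p = TRUE),
          lower.tail = FALSE, log.p = TRUE)
  )
  pmin(pmax(z, -cap), cap)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Dense 1-D smoothing operator: truncated discrete Gaussian, each row
# renormalised so the operator preserves a constant field (no edge dimming).
smoothing_operator <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma_vox))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) {
    d <- abs(i - j)
    ifelse(d <= r, exp(-d^2 / (2 * sigma_vox^2)), 0)
  })
  K / rowSums(K)
}

#' Smooth a 3-D array with a separable Gaussian kernel
#'
#' FWHM is given in mm and converted per axis through the voxel size.
#' The kernel is truncated at 3 sigma and renormalised at the edges.
#'
#' @param x 3-D numeric array.
#' @param fwhm full width at half maximum, mm (scalar).
#' @param voxel_size length-3 numeric, mm per voxel along each axis.
#' @return smoothed array of the same dimension.
#' @export
gaussian_smooth <- function(x, fwhm, voxel_size) {
  stopifnot(length(dim(x)) == 3, length(voxel_size) == 3, fwhm >= 0)
  if (fwhm == 0) return(x)
  d <- dim(x)
  for (ax in 1:3) {
    K <- smoothing_operator(d[ax], fwhm_to_sigma(fwhm) / voxel_size[ax])
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(x, perm), nrow = d[ax])
    m <- K %*% m
    x <- aperm(array(m, d[perm]), order(perm))
  }
  x
}

# linear index <-> voxel coordinate helpers (R-internal 1-based; user-facing
# tables report 0-based coordinates, see coord columns in cluster tables)
lin_to_coord <- function(idx, dim) arrayInd(idx, dim)
coord_to_lin <- function(xyz, dim) {
  (xyz[, 3] - 1L) * dim[1] * dim[2] + (xyz[, 2] - 1L) * dim[1] + xyz[, 1]
}

# empirical permutation critical value: k-th order statistic with
# k = ceiling(level * n); exceeding it has probability <= 1 - level under
# exchangeability when the observed statistic is included in the null set
perm_critical <- function(x, level = 0.95) {
  sort(x)[ceiling(level * length(x))]
}
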