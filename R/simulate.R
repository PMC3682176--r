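# Synthetic cohort generator: behavioural tables and paired grey-matter
# density volumes with planted, disjoint regional couplings to VIQ and PIQ
# change. The generator emulates already-preprocessed (segmented,
# normalised, smoothed) longitudinal data, which is what the analysis
# pipeline consumes.

#' Ground truth for a synthetic cohort
#'
#' Defines the grid geometry and the planted structure behind a simulated
#' cohort: two disjoint effect regions (one coupled to VIQ change, one to
#' PIQ change), a shared age/time slope, subject-specific smooth baseline
#' maps and smoothed Gaussian noise.
#'
#' Density follows, per subject `i`, scan `t` and voxel `v`,
#' \deqn{GMD(i,t,v) = baseline_i(v) + a(v)\tau_t + b_V(v) e_V(i,t) +
#'   b_P(v) e_P(i,t) + \epsilon(i,t,v)}
#' with \eqn{\tau_t \in \{-1,+1\}} and the IQ-change covariates encoded as
#' minus the change at Time 1 and plus the change at Time 2 — the same
#' encoding the analysis design uses, so slope units (density per
#' encoded-IQ-point) are directly interpretable.
#'
#' @param shape length-3 integer grid dimensions (voxels). Default 32^3.
#' @param voxel_size length-3 numeric, mm per voxel. Default 4 mm isotropic
#'   so that the default 8 mm FWHM smoothing spans two voxels.
#' @param center_v,center_p 1-based voxel coordinates of the planted VIQ /
#'   PIQ region centres. Defaults: left- and right-of-centre boxes.
#' @param region_halfwidth half-width (voxels) of the cubic planted
#'   regions; default 1 (3x3x3 = 27 voxels).
#' @param region_v,region_p optional explicit logical masks overriding the
#'   cubic defaults; must be disjoint and inside the grid.
#' @param slope_v,slope_p planted effect slopes, density units per
#'   encoded-IQ-point (the `b` coefficients).
#' @param age_slope shared age/time slope `a`, density units per encoded
#'   time unit; scalar or an array of grid shape.
#' @param noise_sd SD of the voxel-wise Gaussian noise before smoothing,
#'   density units.
#' @param smooth_fwhm isotropic Gaussian FWHM (mm) applied to the noise,
#'   mirroring the 8 mm smoothing of a standard VBM pipeline.
#' @param baseline_mean,baseline_sd mean level and spatial SD of the
#'   subject-specific smooth baseline maps, density units.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(shape = c(32L, 32L, 32L),
                         voxel_size = c(4, 4, 4),
                         center_v = NULL, center_p = NULL,
                         region_halfwidth = 1L,
                         region_v = NULL, region_p = NULL,
                         slope_v = 5e-4, slope_p = 5e-4,
                         age_slope = -0.005,
                         noise_sd = 0.02,
                         smooth_fwhm = 8,
                         baseline_mean = 0.5, baseline_sd = 0.05) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 4), length(voxel_size) == 3,
            all(voxel_size > 0), is.finite(slope_v), is.finite(slope_p),
            smooth_fwhm >= 0)
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (is.null(center_v)) center_v <- pmax(1L, round(shape * c(0.3, 0.5, 0.5)))
  if (is.null(center_p)) center_p <- pmax(1L, round(shape * c(0.7, 0.5, 0.5)))
  box_mask <- function(center) {
    lo <- center - region_halfwidth
    hi <- center + region_halfwidth
    if (any(lo < 1) || any(hi > shape)) abort("planted region outside the grid")
    m <- array(FALSE, shape)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    m
  }
  if (is.null(region_v)) region_v <- box_mask(center_v)
  if (is.null(region_p)) region_p <- box_mask(center_p)
  stopifnot(identical(dim(region_v), shape), identical(dim(region_p), shape))
  if (any(region_v & region_p)) abort("planted regions must be disjoint")
  structure(list(
    shape = shape, voxel_size = as.numeric(voxel_size),
    center_v = as.integer(center_v), center_p = as.integer(center_p),
    region_v = region_v, region_p = region_p,
    slope_v = slope_v, slope_p = slope_p,
    age_slope = age_slope, noise_sd = noise_sd,
    smooth_fwhm = smooth_fwhm,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", paste(x$shape, collapse = "x"), "grid,",
      paste(x$voxel_size, collapse = "x"), "mm voxels\n")
  cat("  VIQ region:", sum(x$region_v), "voxels at (",
      paste(x$center_v - 1L, collapse = ", "), "), slope", x$slope_v, "\n")
  cat("  PIQ region:", sum(x$region_p), "voxels at (",
      paste(x$center_p - 1L, collapse = ", "), "), slope", x$slope_p, "\n")
  cat("  noise sd", x$noise_sd, ", smoothing FWHM", x$smooth_fwhm, "mm\n")
  invisible(x)
}

#' Simulate a behavioural IQ table
#'
#' Draws, per measure, (Time 1, Time 2) scores from a bivariate normal
#' with the stated Time 1 mean and SD, test-retest correlation, and mean
#' and SD of the change score; the implied Time 2 SD is
#' `r * sd_t1 + sqrt(change_sd^2 - sd_t1^2 (1 - r^2))`. Scores are rounded
#' to whole IQ points, matching the granularity of standardised scores.
#' Defaults reproduce the reference cohort's marginals (Time 1 mean 113 /
#' 108, SD 15.1 / 12.3, retest r 0.81 / 0.59, change mean 3.1 / -0.9, SD
#' 10.6 / 10.2 for VIQ / PIQ), under which the implied Time 2 SDs come out
#' at the observed 18.0 and 9.6.
#'
#' @param n number of subjects (>= 3).
#' @param seed integer seed; identical seeds give identical tables.
#' @param mean_t1,sd_t1 named length-2 vectors (`viq`, `piq`), IQ points.
#' @param retest_r test-retest correlations, in `[-1, 1]`.
#' @param mean_change,change_sd mean and SD of the t2 - t1 change.
#' @return an IQ tibble as from [read_iq_table()].
#' @export
simulate_iq <- function(n, seed,
                        mean_t1 = c(viq = 113, piq = 108),
                        sd_t1 = c(viq = 15.1, piq = 12.3),
                        retest_r = c(viq = 0.81, piq = 0.59),
                        mean_change = c(viq = 3.1, piq = -0.9),
                        change_sd = c(viq = 10.6, piq = 10.2)) {
  if (n < 3) abort("n must be at least 3")
  if (any(abs(retest_r) > 1)) abort("retest_r must lie in [-1, 1]")
  if (any(sd_t1 < 0) || any(change_sd < 0)) abort("SDs must be non-negative")
  set.seed(derive_seed(seed, "iq"))
  draw <- function(m) {
    s1 <- sd_t1[[m]]; r <- retest_r[[m]]; sdd <- change_sd[[m]]
    disc <- sdd^2 - s1^2 * (1 - r^2)
    if (disc < 0)
      abort(paste0("change_sd for ", m, " incompatible with sd_t1 and retest_r"))
    s2 <- r * s1 + sqrt(disc)
    z1 <- rnorm(n); z2 <- rnorm(n)
    t1 <- round(mean_t1[[m]] + s1 * z1)
    t2 <- round(mean_t1[[m]] + mean_change[[m]] +
                  s2 * (r * z1 + sqrt(1 - r^2) * z2))
    list(t1 = pmax(t1, 40), t2 = pmax(t2, 40))
  }
  v <- draw("viq"); p <- draw("piq")
  tibble::tibble(
    subject_id = seq_len(n),
    viq_t1 = v$t1, piq_t1 = p$t1, viq_t2 = v$t2, piq_t2 = p$t2,
    d_viq = v$t2 - v$t1, d_piq = p$t2 - p$t1
  )
}

new_cohort_volumes <- function(t1, t2, subject_ids, voxel_size) {
  structure(list(
    t1 = t1, t2 = t2,
    subject_ids = as.integer(subject_ids),
    dim = dim(t1)[1:3], voxel_size = as.numeric(voxel_size),
    affine = diag(c(voxel_size, 1))
  ), class = "cohort_volumes")
}

#' @export
print.cohort_volumes <- function(x, ...) {
  cat("Cohort volumes:", length(x$subject_ids), "subjects x 2 time points,",
      paste(x$dim, collapse = "x"), "grid,",
      paste(x$voxel_size, collapse = "x"), "mm voxels\n")
  invisible(x)
}

#' Simulate paired grey-matter-density volumes for a cohort
#'
#' Generates, for each subject, a Time 1 and a Time 2 volume following the
#' ground-truth model (see [ground_truth()]): a subject-specific smooth
#' baseline identical at both time points, a shared age/time effect, the
#' planted regional couplings to the subject's VIQ and PIQ change, and
#' Gaussian noise smoothed to the configured FWHM. Bit-identical for a
#' fixed (table, truth, seed) triple.
#'
#' @param table an IQ table (provides the change scores driving the
#'   planted effects).
#' @param truth a [ground_truth()] object.
#' @param seed integer seed.
#' @return a `cohort_volumes` object: 4-D arrays `t1` and `t2`
#'   (x, y, z, subject), subject ids, grid geometry.
#' @export
simulate_volumes <- function(table, truth, seed) {
  validate_iq_table(table)
  stopifnot(inherits(truth, "ground_truth"))
  n <- nrow(table)
  shp <- truth$shape
  v <- prod(shp)
  set.seed(derive_seed(seed, "volumes"))
  bV <- ifelse(truth$region_v, truth$slope_v, 0)
  bP <- ifelse(truth$region_p, truth$slope_p, 0)
  a <- if (length(truth$age_slope) == 1) {
    array(truth$age_slope, shp)
  } else {
    stopifnot(identical(dim(truth$age_slope), shp))
    truth$age_slope
  }
  t1 <- array(0, c(shp, n)); t2 <- array(0, c(shp, n))
  for (i in seq_len(n)) {
    # low-order random field baseline: white noise smoothed at twice the
    # analysis FWHM, standardised to (baseline_mean, baseline_sd)
    base <- gaussian_smooth(array(rnorm(v), shp),
                            fwhm = max(2 * truth$smooth_fwhm, 1),
                            voxel_size = truth$voxel_size)
    base <- truth$baseline_mean +
      truth$baseline_sd * (base - mean(base)) / sd(base)
    eps1 <- eps2 <- 0
    if (truth$noise_sd > 0) {
      eps1 <- gaussian_smooth(array(rnorm(v, sd = truth$noise_sd), shp),
                              truth$smooth_fwhm, truth$voxel_size)
      eps2 <- gaussian_smooth(array(rnorm(v, sd = truth$noise_sd), shp),
                              truth$smooth_fwhm, truth$voxel_size)
    }
    dv <- table$d_viq[i]; dp <- table$d_piq[i]
    t1[, , , i] <- base - a - bV * dv - bP * dp + eps1
    t2[, , , i] <- base + a + bV * dv + bP * dp + eps2
  }
  new_cohort_volumes(t1, t2, table$subject_id, truth$voxel_size)
}

#' Post-smoothing effective noise SD
#'
#' Smoothing reduces the voxel-wise SD of white noise; this estimates the
#' effective SD empirically from a noise-only simulation: `n_rep`
#' independent noise fields are generated and smoothed exactly as
#' [simulate_volumes()] does, and the SD across replicates is taken at the
#' planted VIQ region centre.
#'
#' @param truth a [ground_truth()] object.
#' @param n_rep number of noise-only replicate fields.
#' @param seed integer seed for the noise-only simulation.
#' @return scalar effective SD (density units).
#' @export
noise_sd_effective <- function(truth, n_rep = 200, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (truth$noise_sd == 0) return(0)
  set.seed(derive_seed(seed, "noise_eff"))
  ctr <- matrix(truth$center_v, nrow = 1)
  lin <- coord_to_lin(ctr, truth$shape)
  vals <- vapply(seq_len(n_rep), function(r) {
    f <- gaussian_smooth(array(rnorm(prod(truth$shape), sd = truth$noise_sd),
                               truth$shape),
                         truth$smooth_fwhm, truth$voxel_size)
    f[lin]
  }, numeric(1))
  sd(vals)
}

#' Theoretical peak R-squared of the planted coupling
#'
#' Returns the proportion of variance in density change explained by the
#' IQ-change regressor at the planted peak:
#' `Var(2 b d) / (Var(2 b d) + 2 sigma_eff^2)`, where `sigma_eff` is the
#' post-smoothing effective noise SD (difference of two scans doubles the
#' noise variance) and `d` are the table's change scores.
#'
#' @param truth a [ground_truth()] object.
#' @param table an IQ table providing the change scores.
#' @param measure `"viq"` or `"piq"`.
#' @param n_rep,seed passed to [noise_sd_effective()].
#' @return scalar in `[0, 1]`.
#' @export
theoretical_r2 <- function(truth, table, measure = c("viq", "piq"),
                           n_rep = 200, seed = 1) {
  measure <- match.arg(measure)
  validate_iq_table(table)
  b <- if (measure == "viq") truth$slope_v else truth$slope_p
  d <- table[[paste0("d_", measure)]]
  vs <- var(2 * b * d)
  sig <- noise_sd_effective(truth, n_rep = n_rep, seed = seed)
  tot <- vs + 2 * sig^2
  if (tot == 0) abort("total variance at the peak is zero")
  vs / tot
}

#' Slope giving a target theoretical peak R-squared
#'
#' Inverts [theoretical_r2()]: given the cohort's change scores and the
#' truth's noise/smoothing configuration, returns the planted slope for
#' which the peak coupling explains `target_r2` of the density-change
#' variance.
#'
#' @param truth a [ground_truth()] object (its slopes are ignored).
#' @param d numeric vector of IQ change scores the cohort will carry.
#' @param target_r2 desired proportion in `[0, 1)`.
#' @param n_rep,seed passed to [noise_sd_effective()].
#' @return scalar slope (density units per encoded-IQ-point).
#' @export
slope_for_r2 <- function(truth, d, target_r2, n_rep = 200, seed = 1) {
  stopifnot(target_r2 >= 0, target_r2 < 1)
  sig <- noise_sd_effective(truth, n_rep = n_rep, seed = seed)
  sqrt(target_r2 / (1 - target_r2) * 2 * sig^2 / var(2 * d))
}

#' Subset a cohort's volumes by subject
#'
#' @param volumes a `cohort_volumes` object.
#' @param idx integer positions or subject ids to keep (positions when all
#'   values index into the subject vector).
#' @return a `cohort_volumes` object for the selected subjects, in order.
#' @export
subset_volumes <- function(volumes, idx) {
  stopifnot(inherits(volumes, "cohort_volumes"))
  new_cohort_volumes(volumes$t1[, , , idx, drop = FALSE],
                     volumes$t2[, , , idx, drop = FALSE],
                     volumes$subject_ids[idx], volumes$voxel_size)
}

#' Per-subject density-change images
#'
#' @param volumes a `cohort_volumes` object.
#' @return matrix, subjects x voxels, of Time 2 minus Time 1 density.
#' @export
density_change_matrix <- function(volumes) {
  v <- prod(volumes$dim)
  n <- length(volumes$subject_ids)
  t(matrix(volumes$t2, v, n) - matrix(volumes$t1, v, n))
}
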