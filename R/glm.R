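# Step 1 machinery: longitudinal mass-univariate GLM.
#
# The model has one indicator per subject (absorbing the subject's average
# density), a time covariate tau coded -1 / +1, and the two IQ-change
# covariates encoded as minus the change at Time 1 and plus the change at
# Time 2. With 2N scans and N + 3 parameters the error degrees of freedom
# are N - 3. Contrast weights are given over (tau, e_viq, e_piq); subject
# indicators always carry weight zero.

#' Build the longitudinal design matrix
#'
#' Rows are ordered subject-major (subject 1 Time 1, subject 1 Time 2,
#' subject 2 Time 1, ...). Columns: one indicator per subject, the time
#' covariate `tau` (-1 at Time 1, +1 at Time 2), and the encoded IQ-change
#' covariates `e_viq`, `e_piq` (minus the subject's change at Time 1, plus
#' the change at Time 2, so each covariate sums to zero within subject and
#' is orthogonal to every subject indicator).
#'
#' @param table an IQ table with at least 4 subjects (fewer leaves no
#'   error degrees of freedom).
#' @return a numeric matrix with attributes `subject_ids`, `d_viq`,
#'   `d_piq`, `n`, and `degenerate` (names of all-zero covariate columns,
#'   e.g. `e_viq` when every VIQ change is 0).
#' @export
build_design <- function(table) {
  validate_iq_table(table)
  n <- nrow(table)
  if (n <= 3) abort("at least 4 subjects required: the model has N + 3 parameters")
  X <- matrix(0, 2 * n, n + 3)
  colnames(X) <- c(paste0("subj_", table$subject_id), "tau", "e_viq", "e_piq")
  for (i in seq_len(n)) {
    r <- c(2 * i - 1, 2 * i)
    X[r, i] <- 1
    X[r, n + 1] <- c(-1, 1)
    X[r, n + 2] <- c(-table$d_viq[i], table$d_viq[i])
    X[r, n + 3] <- c(-table$d_piq[i], table$d_piq[i])
  }
  degen <- colnames(X)[n + 1 + which(c(
    all(table$d_viq == 0), all(table$d_piq == 0)))]
  structure(X,
            subject_ids = table$subject_id,
            d_viq = table$d_viq, d_piq = table$d_piq,
            n = n, degenerate = degen)
}

# scan-order response matrix (2N x V) matching build_design's row order
scan_matrix <- function(volumes) {
  v <- prod(volumes$dim)
  n <- length(volumes$subject_ids)
  Y <- matrix(0, 2 * n, v)
  Y[seq(1, 2 * n, 2), ] <- t(matrix(volumes$t1, v, n))
  Y[seq(2, 2 * n, 2), ] <- t(matrix(volumes$t2, v, n))
  Y
}

#' Fit the longitudinal GLM at every voxel
#'
#' One ordinary-least-squares fit of density on the design, shared across
#' all voxels (the design is voxel-independent, so the fit is a single
#' matrix solve). Use [contrast_map()] to turn the fit into t/z statistic
#' maps; [fit_contrast()] combines the two steps.
#'
#' @param volumes a `cohort_volumes` object.
#' @param design matrix from [build_design()] for the same subjects in the
#'   same order.
#' @return an internal `vbm_fit` object (coefficients, residual sums of
#'   squares, `(X'X)^{-1}`, degrees of freedom, geometry).
#' @export
fit_glm <- function(volumes, design) {
  stopifnot(inherits(volumes, "cohort_volumes"))
  if (!identical(attr(design, "subject_ids"), volumes$subject_ids))
    abort("design and volumes refer to different subjects or orders")
  keep <- colSums(design != 0) > 0
  X <- design[, keep, drop = FALSE]
  qx <- qr(X)
  if (qx$rank < ncol(X))
    abort(paste0("design is rank deficient; collinear column(s): ",
                 paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]],
                       collapse = ", ")))
  Y <- scan_matrix(volumes)
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  B <- solve(XtX, XtY)
  rss <- pmax(colSums(Y^2) - colSums(B * XtY), 0)
  df <- nrow(X) - ncol(X) # 2N - (N+3) = N - 3 for a non-degenerate design
  structure(list(
    B = B, rss = rss, XtX_inv = solve(XtX), df = df,
    columns = colnames(X), all_columns = colnames(design),
    dropped = colnames(design)[!keep],
    n = attr(design, "n"),
    dim = volumes$dim, voxel_size = volumes$voxel_size
  ), class = "vbm_fit")
}

#' t/z statistic map for a covariate contrast
#'
#' @param fit a `vbm_fit` from [fit_glm()].
#' @param weights length-3 numeric over `(tau, e_viq, e_piq)`, e.g.
#'   `c(0, 1, 0)` for the VIQ-change effect or `c(0, 1, -1)` for the
#'   VIQ-minus-PIQ difference. One-sided in the direction of positive
#'   `c'beta`. Zero-residual (perfect-fit) voxels get an infinite t and a
#'   z capped at 38.
#' @return a `stat_map`: 3-D arrays `t` and `z`, degrees of freedom,
#'   the weights and the grid geometry.
#' @export
contrast_map <- function(fit, weights) {
  stopifnot(inherits(fit, "vbm_fit"), length(weights) == 3)
  if (all(weights == 0)) abort("contrast weights must not all be zero")
  covnames <- c("tau", "e_viq", "e_piq")
  used <- covnames[weights != 0]
  bad <- setdiff(used, fit$columns)
  if (length(bad) > 0)
    abort(paste0("contrast puts weight on degenerate (all-zero) column(s): ",
                 paste(bad, collapse = ", ")))
  cvec <- setNames(numeric(length(fit$columns)), fit$columns)
  cvec[covnames[covnames %in% fit$columns]] <-
    weights[covnames %in% fit$columns]
  cb <- drop(crossprod(cvec, fit$B))
  vc <- drop(crossprod(cvec, fit$XtX_inv %*% cvec))
  se <- sqrt(fit$rss / fit$df * vc)
  t <- ifelse(se > 0, cb / se, sign(cb) * Inf)
  t[se == 0 & cb == 0] <- 0
  structure(list(
    t = array(t, fit$dim), z = array(t_to_z(t, fit$df), fit$dim),
    df = fit$df, weights = weights,
    dim = fit$dim, voxel_size = fit$voxel_size
  ), class = "stat_map")
}

#' Fit a contrast directly from volumes and design
#'
#' Convenience wrapper: [fit_glm()] then [contrast_map()].
#'
#' @inheritParams fit_glm
#' @inheritParams contrast_map
#' @return a `stat_map`.
#' @export
fit_contrast <- function(volumes, design, weights) {
  contrast_map(fit_glm(volumes, design), weights)
}

#' @export
print.stat_map <- function(x, ...) {
  cat("Stat map", paste(x$dim, collapse = "x"), "- contrast (",
      paste(x$weights, collapse = ", "), "), df =", x$df,
      ", max t =", round(max(x$t), 2), "\n")
  invisible(x)
}
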