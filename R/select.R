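# Region selection: corrected thresholds, difference-contrast conjunction,
# and the anatomical search-space fallback.

#' Analysis configuration
#'
#' Collects every tunable of the two-step pipeline with the defaults used
#' throughout: 5% family-wise level, cluster-forming thresholds p < 0.001
#' (VIQ) and p < 0.01 (PIQ), difference-contrast conjunction at p < 0.01
#' uncorrected, 26-neighbour connectivity, peak-voxel density extraction,
#' 25 split repeats.
#'
#' @param correction `"permutation"` (sign-flip maxT / max cluster size)
#'   or `"bonferroni"` (height-only).
#' @param n_perm permutations per training analysis (>= 100).
#' @param fwe_p family-wise error level.
#' @param forming_p named length-2 vector of one-sided cluster-forming
#'   p-values per measure.
#' @param conjunction_p uncorrected one-sided p required of the
#'   VIQ-vs-PIQ difference contrast at the selected peak.
#' @param connectivity 6, 18 or 26.
#' @param extraction `"peak"` (density change at the peak voxel) or
#'   `"cluster_mean"`.
#' @param repeats number of stratified split-half repeats.
#' @param seed master seed; all sub-seeds derive from it.
#' @return a validated list of class `cv_config`.
#' @export
cv_config <- function(correction = c("permutation", "bonferroni"),
                      n_perm = 500, fwe_p = 0.05,
                      forming_p = c(viq = 0.001, piq = 0.01),
                      conjunction_p = 0.01, connectivity = 26L,
                      extraction = c("peak", "cluster_mean"),
                      repeats = 25L, seed = 1L) {
  correction <- match.arg(correction)
  extraction <- match.arg(extraction)
  probs <- c(fwe_p, forming_p, conjunction_p)
  if (any(probs <= 0 | probs >= 1))
    abort("all probability thresholds must lie strictly in (0, 1)")
  if (n_perm < 100) abort("n_perm must be at least 100")
  if (!connectivity %in% c(6L, 18L, 26L)) abort("connectivity must be 6, 18 or 26")
  if (repeats < 1) abort("repeats must be positive")
  stopifnot(all(c("viq", "piq") %in% names(forming_p)))
  structure(list(
    correction = correction, n_perm = as.integer(n_perm), fwe_p = fwe_p,
    forming_p = forming_p[c("viq", "piq")], conjunction_p = conjunction_p,
    connectivity = as.integer(connectivity), extraction = extraction,
    repeats = as.integer(repeats), seed = as.integer(seed)
  ), class = "cv_config")
}

#' Read an analysis configuration from YAML
#'
#' @param file path to a YAML file whose keys are [cv_config()] arguments.
#' @return a `cv_config` object.
#' @export
read_config <- function(file) {
  vals <- yaml::read_yaml(file)
  if ("forming_p" %in% names(vals)) vals$forming_p <- unlist(vals$forming_p)
  do.call(cv_config, vals)
}

#' Select regions for both IQ measures from the four contrast maps
#'
#' A cluster of the VIQ map (formed at its cluster-forming threshold) is
#' selected when it survives whole-brain correction in height (peak t
#' above `height_crit`) or extent (size above `extent_k_crit`), and its
#' peak additionally shows a one-sided VIQ-minus-PIQ difference at
#' `conjunction_p` uncorrected — symmetrically for PIQ with the reversed
#' difference map. When nothing survives correction and a search mask is
#' supplied, the most significant supra-threshold cluster inside the mask
#' is selected instead (basis `search-space-max`, conjunction not applied,
#' `type2` flagged); if no voxel inside the mask passes the forming
#' threshold, the selection degrades to the mask's peak voxel.
#'
#' @param map_v,map_p `stat_map`s for contrasts `(0,1,0)` and `(0,0,1)`.
#' @param map_vmp,map_pmv `stat_map`s for the difference contrasts
#'   `(0,1,-1)` and `(0,-1,1)`.
#' @param thresholds list with per-measure named vectors `forming_t`,
#'   `height_crit`, `extent_crit` (names `viq`, `piq`) and scalar
#'   `conjunction_p`.
#' @param search_mask optional logical array (the anatomical search
#'   space); must be non-empty.
#' @param connectivity cluster connectivity.
#' @return a `region_selection`: a `clusters` tibble (measure, basis,
#'   size, 0-based peak coordinates, peak t/z, difference-contrast t and
#'   p at the peak, voxel list) plus `type2` flags and the thresholds
#'   used.
#' @export
select_regions <- function(map_v, map_p, map_vmp, map_pmv, thresholds,
                           search_mask = NULL, connectivity = 26L) {
  stopifnot(identical(map_v$dim, map_p$dim),
            identical(map_v$dim, map_vmp$dim),
            identical(map_v$dim, map_pmv$dim))
  if (!is.null(search_mask)) {
    stopifnot(identical(dim(search_mask), map_v$dim))
    if (!any(search_mask)) abort("search mask is empty")
  }
  df <- map_v$df
  one <- function(measure) {
    main <- if (measure == "viq") map_v else map_p
    diffm <- if (measure == "viq") map_vmp else map_pmv
    ft <- thresholds$forming_t[[measure]]
    cl <- extract_clusters(main, ft, connectivity)
    surv_h <- cl$peak_t > thresholds$height_crit[[measure]]
    surv_e <- cl$size > thresholds$extent_crit[[measure]]
    type2 <- !any(surv_h | surv_e)
    cl$basis <- as.character(ifelse(surv_h, "height-FWE",
                                    ifelse(surv_e, "extent-FWE",
                                           NA_character_)))
    cl <- cl[surv_h | surv_e, , drop = FALSE]
    if (nrow(cl) > 0) {
      dt <- diffm$t[cl$peak_idx]
      dp <- pt(dt, df, lower.tail = FALSE)
      keep <- dp < thresholds$conjunction_p
      cl$diff_peak_t <- dt
      cl$diff_peak_p <- dp
      cl <- cl[keep, , drop = FALSE]
    } else {
      cl$diff_peak_t <- numeric(0)
      cl$diff_peak_p <- numeric(0)
    }
    if (nrow(cl) == 0 && !is.null(search_mask)) {
      masked <- main$t
      masked[!search_mask] <- -Inf
      cl <- extract_clusters(masked, ft, connectivity, df = df)
      if (nrow(cl) == 0) {
        peak <- which(masked == max(masked))[1]
        xyz <- lin_to_coord(peak, map_v$dim)[1, ]
        cl <- tibble::tibble(
          size = 1L, peak_x = xyz[1] - 1L, peak_y = xyz[2] - 1L,
          peak_z = xyz[3] - 1L, peak_t = main$t[peak],
          peak_z_score = t_to_z(main$t[peak], df),
          peak_idx = as.integer(peak), voxels = list(as.integer(peak))
        )
      }
      cl <- cl[1, , drop = FALSE] # single most significant cluster
      cl$basis <- "search-space-max"
      cl$diff_peak_t <- diffm$t[cl$peak_idx]
      cl$diff_peak_p <- pt(cl$diff_peak_t, df, lower.tail = FALSE)
    }
    cl$measure <- rep(measure, nrow(cl))
    list(clusters = cl, type2 = type2)
  }
  rv <- one("viq"); rp <- one("piq")
  clusters <- dplyr::bind_rows(rv$clusters, rp$clusters)
  clusters <- dplyr::relocate(clusters, "measure", "basis")
  structure(list(
    clusters = clusters,
    type2 = c(viq = rv$type2, piq = rp$type2),
    thresholds = thresholds, df = df,
    connectivity = connectivity, dim = map_v$dim,
    voxel_size = map_v$voxel_size
  ), class = "region_selection")
}

#' @export
print.region_selection <- function(x, ...) {
  cat("Region selection (df =", x$df, "): type2 VIQ =", x$type2[["viq"]],
      ", PIQ =", x$type2[["piq"]], "\n")
  print(dplyr::select(x$clusters, -"voxels", -"peak_idx"))
  invisible(x)
}

#' Run the full Step-1 region selection on a training sample
#'
#' Builds the longitudinal design, fits the four contrasts (VIQ change,
#' PIQ change and both difference directions), computes the corrected
#' thresholds per measure (permutation or Bonferroni, per `config`), and
#' applies [select_regions()].
#'
#' @param table IQ table of the training subjects.
#' @param volumes matching `cohort_volumes`.
#' @param config a [cv_config()].
#' @param search_mask optional logical array enabling the search-space
#'   fallback.
#' @param perm_seed seed for the permutation thresholds (defaults to a
#'   sub-seed of `config$seed`).
#' @return a `region_selection`.
#' @export
step1_select <- function(table, volumes, config, search_mask = NULL,
                         perm_seed = NULL) {
  stopifnot(inherits(config, "cv_config"))
  design <- build_design(table)
  fit <- fit_glm(volumes, design)
  map_v <- contrast_map(fit, c(0, 1, 0))
  map_p <- contrast_map(fit, c(0, 0, 1))
  map_vmp <- contrast_map(fit, c(0, 1, -1))
  map_pmv <- contrast_map(fit, c(0, -1, 1))
  df <- fit$df
  forming_t <- c(viq = qt(1 - config$forming_p[["viq"]], df),
                 piq = qt(1 - config$forming_p[["piq"]], df))
  if (config$correction == "permutation") {
    if (is.null(perm_seed)) perm_seed <- derive_seed(config$seed, "perm")
    dmat <- cbind(attr(design, "d_viq"), attr(design, "d_piq"))
    null <- sign_flip_null(density_change_matrix(volumes), dmat,
                           config$n_perm, perm_seed, forming_t,
                           volumes$dim, config$connectivity)
    height_crit <- c(viq = perm_critical(null$max_t[, 1], 1 - config$fwe_p),
                     piq = perm_critical(null$max_t[, 2], 1 - config$fwe_p))
    extent_crit <- c(viq = perm_critical(null$max_k[, 1], 1 - config$fwe_p),
                     piq = perm_critical(null$max_k[, 2], 1 - config$fwe_p))
  } else {
    b <- bonferroni_threshold(prod(volumes$dim), df, config$fwe_p)
    height_crit <- c(viq = b$height_t_crit, piq = b$height_t_crit)
    extent_crit <- c(viq = Inf, piq = Inf)
  }
  thresholds <- list(forming_t = forming_t, height_crit = height_crit,
                     extent_crit = extent_crit,
                     conjunction_p = config$conjunction_p)
  select_regions(map_v, map_p, map_vmp, map_pmv, thresholds,
                 search_mask = search_mask,
                 connectivity = config$connectivity)
}

#' Rectangular search mask around the planted regions
#'
#' Convenience analogue of an anatomically defined search space: the
#' union of the planted regions dilated by `margin` voxels along each
#' axis.
#'
#' @param truth a [ground_truth()].
#' @param margin dilation in voxels.
#' @return a logical array of the truth's grid shape.
#' @export
search_mask_around <- function(truth, margin = 4L) {
  m <- array(FALSE, truth$shape)
  grow <- function(center) {
    lo <- pmax(center - margin, 1L)
    hi <- pmin(center + margin, truth$shape)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <<- TRUE
  }
  grow(truth$center_v); grow(truth$center_p)
  m
}
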