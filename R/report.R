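# Reporting: fold tables, R-squared histograms, overlap maps and
# scheme-comparison summaries. All reporting is a pure function of the
# stored result tables, so every artefact regenerates identically from
# folds.csv + summary.json.

#' Per-voxel selection overlap map
#'
#' Counts, per voxel, in how many selections the voxel belongs to a
#' selected cluster of the given measure.
#'
#' @param selections list of `region_selection` objects sharing one grid.
#' @param dim grid dimensions.
#' @param measure `"viq"` or `"piq"`.
#' @return an integer array of counts (max bounded by
#'   `length(selections)`).
#' @export
overlap_map <- function(selections, dim, measure = c("viq", "piq")) {
  measure <- match.arg(measure)
  out <- array(0L, dim)
  for (sel in selections) {
    if (!identical(sel$dim, as.integer(dim)) &&
        !identical(as.integer(sel$dim), as.integer(dim)))
      abort("selection grid does not match the requested grid")
    cl <- sel$clusters[sel$clusters$measure == measure, ]
    vox <- unique(unlist(cl$voxels))
    if (length(vox) > 0) out[vox] <- out[vox] + 1L
  }
  out
}

#' Fold-by-fold report table
#'
#' One row per fold (or split analysis) per measure with the selection
#' basis, cluster size, 0-based peak coordinates, peak z and the
#' difference-contrast z at the peak — the layout of a per-fold results
#' table.
#'
#' @param result a `cv_result`.
#' @return a tibble without list columns, ready for CSV round-tripping.
#' @export
fold_table <- function(result) {
  stopifnot(inherits(result, "cv_result"))
  if (nrow(result$folds) == 0) abort("empty cross-validation result")
  keep <- intersect(
    c("fold", "analysis", "held_out", "repeat_index", "orientation",
      "measure", "basis", "type2", "excluded", "size",
      "peak_x", "peak_y", "peak_z", "peak_t", "peak_z_score",
      "diff_peak_t", "diff_peak_p", "diff_peak_z",
      "density_change", "measured_change", "predicted_change",
      "measured_t2", "predicted_t2", "r2_change", "r2_t2_full",
      "r2_t2_after_t1"),
    names(result$folds))
  result$folds[keep]
}

#' Histogram of per-analysis R-squared values
#'
#' Bins the split-half per-analysis R-squared values (in percent) into
#' `bin_width`-point bins over 0-100; the counts across bins sum to the
#' number of analyses.
#'
#' @param result a split-half `cv_result`, or a numeric vector of
#'   R-squared proportions in `[0, 1]`.
#' @param bin_width bin width in percentage points (default 10).
#' @param metric which per-analysis column to bin when `result` is a
#'   `cv_result`.
#' @param measure optional filter (`"viq"` or `"piq"`).
#' @return a tibble `bin_lo`, `bin_hi`, `count` (plus `measure` when
#'   binning a `cv_result`).
#' @export
r2_histogram <- function(result, bin_width = 10,
                         metric = c("r2_change", "r2_t2_full",
                                    "r2_t2_after_t1"),
                         measure = NULL) {
  metric <- match.arg(metric)
  bins <- seq(0, 100, by = bin_width)
  bin_one <- function(r2) {
    pct <- pmin(pmax(100 * r2, 0), 100)
    lo <- bins[-length(bins)]
    hi <- bins[-1]
    count <- vapply(seq_along(lo), function(i) {
      upper_closed <- i == length(lo)
      sum(pct >= lo[i] & (pct < hi[i] | (upper_closed & pct <= hi[i])))
    }, integer(1))
    tibble::tibble(bin_lo = lo, bin_hi = hi, count = count)
  }
  if (is.numeric(result)) return(bin_one(result))
  stopifnot(inherits(result, "cv_result"))
  if (result$scheme != "splithalf")
    abort("per-analysis histograms are defined for split-half results")
  f <- result$folds
  if (!is.null(measure)) f <- f[f$measure == measure, ]
  f |>
    dplyr::group_by(.data$measure) |>
    dplyr::group_modify(~ bin_one(.x[[metric]])) |>
    dplyr::ungroup()
}

#' Compare Leave-One-Out and split-half results
#'
#' Per measure: the LOO out-of-sample R-squared, the split-half mean and
#' across-analysis variance of R-squared, the peak dispersion (maximal
#' pairwise distance in mm between selected peaks across folds or
#' analyses), per-scheme type-II rates, and the number of Step-1 model
#' fits each scheme costs.
#'
#' @param loo a `cv_result` from [loo_run()].
#' @param split a `cv_result` from [split_half_run()].
#' @param voxel_size mm per voxel, for peak dispersion in mm.
#' @return a tibble with one row per measure.
#' @export
scheme_comparison <- function(loo, split, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(loo, "cv_result"), loo$scheme == "loo",
            inherits(split, "cv_result"), split$scheme == "splithalf")
  dispersion <- function(folds, measure, voxel_size) {
    f <- folds[folds$measure == measure & !is.na(folds$peak_x), ]
    if (nrow(f) < 2) return(0)
    xyz <- cbind(f$peak_x, f$peak_y, f$peak_z) *
      rep(voxel_size, each = nrow(f))
    max(stats::dist(xyz))
  }
  vsz <- voxel_size
  purrr::map_dfr(c("viq", "piq"), function(m) {
    ls <- loo$summary[loo$summary$measure == m, ]
    ss <- split$summary[split$summary$measure == m, ]
    sf <- split$folds[split$folds$measure == m, ]
    tibble::tibble(
      measure = m,
      loo_r2_change = ls$r2_change,
      split_mean_r2_change = ss$r2_change,
      split_var_r2_change = var(sf$r2_change, na.rm = TRUE),
      loo_peak_dispersion = dispersion(loo$folds, m, vsz),
      split_peak_dispersion = dispersion(split$folds, m, vsz),
      loo_type2_rate = ls$type2_rate,
      split_type2_rate = ss$type2_rate,
      loo_step1_fits = ls$n_folds,
      split_step1_fits = ss$n_analyses
    )
  })
}

#' @export
tidy.cv_result <- function(x, ...) fold_table(x)

#' @export
glance.cv_result <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "measure",
                       values_from = -dplyr::all_of("measure")) |>
    dplyr::mutate(scheme = x$scheme, .before = 1)
}

#' @export
autoplot.cv_result <- function(object, ...) {
  if (object$scheme == "splithalf") {
    h <- r2_histogram(object)
    ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_lo + diff(c(0, 10))[1] / 2,
                                    y = .data$count)) +
      ggplot2::geom_col(width = 9, fill = "grey40") +
      ggplot2::facet_wrap(~measure) +
      ggplot2::labs(x = expression(R^2 ~ "(% of variance in IQ change)"),
                    y = "number of analyses",
                    title = "Split-half: variability of per-analysis R²")
  } else {
    f <- object$folds[!object$folds$excluded, ]
    ggplot2::ggplot(f, ggplot2::aes(x = .data$predicted_change,
                                    y = .data$measured_change)) +
      ggplot2::geom_point() +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           colour = "grey40") +
      ggplot2::facet_wrap(~measure, scales = "free") +
      ggplot2::labs(x = "predicted IQ change (points)",
                    y = "measured IQ change (points)",
                    title = "Leave-One-Out: predicted vs measured change")
  }
}

#' Plot a slice of an overlap (selection-frequency) map
#'
#' @param map integer array from [overlap_map()].
#' @param slice z index (1-based); default the slice with the largest
#'   total count.
#' @return a ggplot object.
#' @export
plot_overlap_slice <- function(map, slice = NULL) {
  if (is.null(slice)) slice <- which.max(apply(map, 3, sum))
  sl <- map[, , slice]
  df <- tidyr::expand_grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$count <- sl[cbind(df$x, df$y)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste("Selection frequency, slice z =", slice - 1))
}
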