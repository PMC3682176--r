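# Step 2 and orchestration: exhaustive Leave-One-Out and repeated
# stratified split-half cross-validation.

measure_cols <- function(measure) {
  list(d = paste0("d_", measure),
       t1 = paste0(measure, "_t1"),
       t2 = paste0(measure, "_t2"))
}

#' Predict a held-out subject's IQ change from training pairs
#'
#' Ordinary least squares of IQ change on density change over the
#' training pairs; the fitted line is evaluated at the held-out subject's
#' density change.
#'
#' @param pairs data frame with columns `density` (grey-matter density
#'   change) and `change` (IQ change), one row per training subject.
#' @param held_out_density density change of the held-out subject(s).
#' @return predicted IQ change, same length as `held_out_density`.
#' @export
predict_held_out <- function(pairs, held_out_density) {
  stopifnot(all(c("density", "change") %in% names(pairs)))
  if (nrow(pairs) < 3) abort("at least 3 training pairs required")
  if (var(pairs$density) == 0)
    abort("zero variance in training density change")
  fit <- lm(change ~ density, data = pairs)
  unname(predict(fit, tibble::tibble(density = held_out_density)))
}

# density change for given subjects at a cluster (peak voxel or cluster
# mean, per config)
extract_density <- function(volumes, subject_pos, cluster_row, extraction) {
  v <- prod(volumes$dim)
  vox <- if (extraction == "peak") cluster_row$peak_idx else cluster_row$voxels[[1]]
  vapply(subject_pos, function(i) {
    off <- (i - 1) * v
    mean(volumes$t2[vox + off] - volumes$t1[vox + off])
  }, numeric(1))
}

#' Stratified split of a cohort into two halves
#'
#' Subjects are ranked on a full-scale IQ proxy (the mean of the four
#' scores: VIQ and PIQ at both time points), median-split into high and
#' low strata, and each stratum is randomly halved between groups A and B;
#' an odd stratum's extra subject goes to the currently smaller group
#' (coin flip on ties), so group sizes never differ by more than one.
#' Deterministic for a fixed (seed, repeat_index).
#'
#' @param table an IQ table with at least 4 subjects.
#' @param repeat_index index of the split repetition (>= 1).
#' @param seed master seed.
#' @return a list with `repeat_index`, subject-id vectors `group_a` and
#'   `group_b`, and a `strata` tibble (`subject_id`, `fsiq_proxy`,
#'   `stratum`).
#' @export
stratified_split <- function(table, repeat_index, seed) {
  validate_iq_table(table)
  n <- nrow(table)
  if (n < 4) abort("at least 4 subjects required for a split")
  set.seed(derive_seed(seed, "split", repeat_index))
  proxy <- rowMeans(table[IQ_SCORE_COLS])
  ord <- order(-proxy, table$subject_id)
  n_high <- ceiling(n / 2)
  stratum <- character(n)
  stratum[ord[seq_len(n_high)]] <- "high"
  stratum[ord[-seq_len(n_high)]] <- "low"
  group <- character(n)
  size_a <- 0; size_b <- 0
  for (s in c("high", "low")) {
    ids <- which(stratum == s)
    ids <- ids[sample.int(length(ids))]
    half <- length(ids) %/% 2
    extra <- length(ids) - 2 * half
    a_take <- half
    if (extra == 1) {
      to_a <- if (size_a < size_b) TRUE
      else if (size_a > size_b) FALSE
      else sample(c(TRUE, FALSE), 1)
      if (to_a) a_take <- half + 1
    }
    group[ids[seq_len(a_take)]] <- "A"
    group[ids[-seq_len(a_take)]] <- "B"
    size_a <- size_a + a_take
    size_b <- size_b + (length(ids) - a_take)
  }
  list(
    repeat_index = as.integer(repeat_index),
    group_a = table$subject_id[group == "A"],
    group_b = table$subject_id[group == "B"],
    strata = tibble::tibble(subject_id = table$subject_id,
                            fsiq_proxy = proxy, stratum = stratum)
  )
}

#' Hierarchical regression of Time 2 IQ
#'
#' Two nested OLS fits of Time 2 score: on Time 1 alone, then on Time 1
#' plus density change. The increment is the gain in R-squared from the
#' density term, which is non-negative by construction for nested
#' within-sample fits.
#'
#' @param records data frame with columns `t1` and `t2` (IQ points).
#' @param density density change per record.
#' @return a list: `r2_t1_only`, `r2_full`, `increment`.
#' @export
hierarchical_r2 <- function(records, density) {
  stopifnot(all(c("t1", "t2") %in% names(records)))
  if (nrow(records) < 4) abort("at least 4 records required")
  d <- tibble::tibble(t1 = records$t1, t2 = records$t2, density = density)
  f1 <- lm(t2 ~ t1, data = d)
  f2 <- lm(t2 ~ t1 + density, data = d)
  if (anyNA(coef(f2)))
    warn("density change collinear with Time 1 IQ; increment is 0")
  r1 <- summary(f1)$r.squared
  r2 <- summary(f2)$r.squared
  list(r2_t1_only = r1, r2_full = r2, increment = r2 - r1)
}

new_cv_result <- function(scheme, folds, summary, config, extra = list()) {
  structure(c(list(scheme = scheme, folds = folds, summary = summary,
                   config = config), extra),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validation result (", x$scheme, "): ",
      nrow(x$folds) / 2, " analyses\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Exhaustive Leave-One-Out cross-validation
#'
#' For each subject in turn, Step 1 (region selection) runs on the
#' remaining subjects; per measure the selected cluster with the highest
#' peak t is retained, the held-out subject's density change at its peak
#' is extracted, and training-set regressions of (i) IQ change on density
#' change and (ii) Time 2 IQ on Time 1 IQ plus density change are applied
#' to the held-out subject. After all folds the predicted values are
#' regressed against the measured ones across subjects: `r2_change` is
#' the out-of-sample proportion of IQ-change variance accounted for,
#' `r2_t2` the same for Time 2 IQ. Folds whose training analysis selects
#' nothing (no search mask) or has degenerate density variance are
#' flagged and excluded from aggregation with a warning count.
#'
#' @param table IQ table (n >= 5).
#' @param volumes matching `cohort_volumes`.
#' @param config a [cv_config()].
#' @param search_mask optional logical array; when supplied, training
#'   analyses fall back to the most significant cluster inside it.
#' @param progress print a line per fold.
#' @return a `cv_result` with per-fold rows (two per fold, one per
#'   measure) and a per-measure summary.
#' @export
loo_run <- function(table, volumes, config, search_mask = NULL,
                    progress = FALSE) {
  validate_iq_table(table)
  stopifnot(inherits(config, "cv_config"))
  n <- nrow(table)
  if (n < 5) abort("Leave-One-Out requires at least 5 subjects")
  if (!identical(table$subject_id, volumes$subject_ids))
    abort("table and volumes subject order disagree")
  rows <- list()
  for (s in seq_len(n)) {
    tr <- setdiff(seq_len(n), s)
    train_tab <- table[tr, ]
    # independence audit: the held-out subject never enters the training
    # design that produces the fold's peak
    stopifnot(!(table$subject_id[s] %in% train_tab$subject_id))
    sel <- step1_select(train_tab, subset_volumes(volumes, tr), config,
                        search_mask = search_mask,
                        perm_seed = derive_seed(config$seed, "perm", s))
    if (progress)
      cat("fold", s, "/", n, ": ",
          paste(sel$clusters$measure, collapse = ","), "\n")
    for (m in c("viq", "piq")) {
      cols <- measure_cols(m)
      cl <- sel$clusters[sel$clusters$measure == m, ]
      base <- tibble::tibble(
        fold = s, held_out = table$subject_id[s], measure = m,
        type2 = sel$type2[[m]],
        measured_change = table[[cols$d]][s],
        measured_t1 = table[[cols$t1]][s],
        measured_t2 = table[[cols$t2]][s]
      )
      if (nrow(cl) == 0) {
        base$excluded <- TRUE
        rows[[length(rows) + 1]] <- base
        next
      }
      cl <- cl[1, ] # highest peak t among selected clusters
      dens_tr <- extract_density(volumes, tr, cl, config$extraction)
      dens_ho <- extract_density(volumes, s, cl, config$extraction)
      if (var(dens_tr) == 0) {
        base$excluded <- TRUE
        rows[[length(rows) + 1]] <- base
        next
      }
      train <- tibble::tibble(
        density = dens_tr,
        change = train_tab[[cols$d]],
        t1 = train_tab[[cols$t1]], t2 = train_tab[[cols$t2]]
      )
      pred_change <- predict_held_out(train[c("density", "change")], dens_ho)
      fit_t2 <- lm(t2 ~ t1 + density, data = train)
      fit_t1only <- lm(t2 ~ t1, data = train)
      newd <- tibble::tibble(t1 = table[[cols$t1]][s], density = dens_ho)
      out <- dplyr::mutate(
        base,
        basis = cl$basis, size = cl$size,
        peak_x = cl$peak_x, peak_y = cl$peak_y, peak_z = cl$peak_z,
        peak_idx = cl$peak_idx,
        peak_t = cl$peak_t, peak_z_score = cl$peak_z_score,
        diff_peak_t = cl$diff_peak_t, diff_peak_p = cl$diff_peak_p,
        diff_peak_z = t_to_z(cl$diff_peak_t, sel$df),
        density_change = dens_ho,
        predicted_change = pred_change,
        predicted_t2 = unname(predict(fit_t2, newd)),
        predicted_t2_t1only = unname(predict(fit_t1only, newd)),
        excluded = FALSE
      )
      out$voxels <- cl$voxels
      rows[[length(rows) + 1]] <- out
    }
  }
  folds <- dplyr::bind_rows(rows)
  summarise_m <- function(m) {
    f <- folds[folds$measure == m & !folds$excluded, ]
    r2_of <- function(meas, pred) {
      if (nrow(f) < 3 || var(pred) == 0) return(NA_real_)
      summary(lm(meas ~ pred))$r.squared
    }
    r2_change <- r2_of(f$measured_change, f$predicted_change)
    # OLS identity: regressing measured on predicted gives the squared
    # Pearson correlation; asserted each run
    if (!is.na(r2_change))
      stopifnot(abs(r2_change - cor(f$measured_change,
                                    f$predicted_change)^2) < 1e-10)
    r2_t2 <- r2_of(f$measured_t2, f$predicted_t2)
    r2_t1only <- r2_of(f$measured_t2, f$predicted_t2_t1only)
    tibble::tibble(
      measure = m, n_folds = sum(folds$measure == m), n_used = nrow(f),
      r2_change = r2_change, r2_t2 = r2_t2,
      r2_t2_t1_only = r2_t1only,
      r2_t2_after_t1 = r2_t2 - r2_t1only,
      type2_rate = mean(folds$type2[folds$measure == m]),
      n_excluded = sum(folds$measure == m & folds$excluded)
    )
  }
  n_excl <- sum(folds$excluded)
  if (n_excl > 0)
    warn(paste0(n_excl, " fold-measure analyses excluded from aggregation"))
  new_cv_result("loo", folds,
                dplyr::bind_rows(summarise_m("viq"), summarise_m("piq")),
                config)
}

#' Repeated stratified split-half cross-validation
#'
#' For each of `config$repeats` stratified splits, Step 1 runs once per
#' orientation (train on A test on B, then train on B test on A), always
#' with the search-space fallback available. Per measure the top selected
#' cluster's density change is extracted in the *test* group and the
#' Step-2 regressions are fitted within the test sample (region selection
#' is out-of-sample, the regression parameters are not — deliberately
#' mirroring the scheme this package characterises): R-squared of IQ
#' change on density change, and the hierarchical pair for Time 2 IQ
#' (Time 1 first, density change second).
#'
#' @param table IQ table (n >= 8).
#' @param volumes matching `cohort_volumes`.
#' @param config a [cv_config()]; `config$repeats` splits are run.
#' @param search_mask logical array, required (split-half training halves
#'   rarely survive whole-brain correction).
#' @param progress print a line per analysis.
#' @return a `cv_result`: one row per analysis per measure in `folds`,
#'   per-measure means over analyses in `summary`, and per-voxel
#'   selection-frequency arrays in `selection_freq`.
#' @export
split_half_run <- function(table, volumes, config, search_mask,
                           progress = FALSE) {
  validate_iq_table(table)
  stopifnot(inherits(config, "cv_config"))
  if (nrow(table) < 8) abort("split-half requires at least 8 subjects")
  if (is.null(search_mask)) abort("split-half requires a search mask")
  if (!identical(table$subject_id, volumes$subject_ids))
    abort("table and volumes subject order disagree")
  rows <- list()
  freq <- list(viq = array(0L, volumes$dim), piq = array(0L, volumes$dim))
  for (r in seq_len(config$repeats)) {
    split <- stratified_split(table, r, config$seed)
    for (orient in 1:2) {
      train_ids <- if (orient == 1) split$group_a else split$group_b
      test_ids <- if (orient == 1) split$group_b else split$group_a
      analysis <- 2 * (r - 1) + orient
      tr <- match(train_ids, table$subject_id)
      te <- match(test_ids, table$subject_id)
      if (length(te) < 4) abort("test group smaller than 4 subjects")
      sel <- step1_select(table[tr, ], subset_volumes(volumes, tr), config,
                          search_mask = search_mask,
                          perm_seed = derive_seed(config$seed, "perm",
                                                  analysis + 10000L))
      if (progress) cat("analysis", analysis, "/", 2 * config$repeats, "\n")
      for (m in c("viq", "piq")) {
        cols <- measure_cols(m)
        cl <- sel$clusters[sel$clusters$measure == m, ][1, ]
        freq[[m]][cl$voxels[[1]]] <- freq[[m]][cl$voxels[[1]]] + 1L
        dens_te <- extract_density(volumes, te, cl, config$extraction)
        test <- tibble::tibble(
          density = dens_te,
          change = table[[cols$d]][te],
          t1 = table[[cols$t1]][te], t2 = table[[cols$t2]][te]
        )
        r2_change <- if (var(test$density) == 0) NA_real_
        else summary(lm(change ~ density, data = test))$r.squared
        hier <- hierarchical_r2(test, test$density)
        out <- tibble::tibble(
          analysis = analysis, repeat_index = r,
          orientation = c("A>B", "B>A")[orient], measure = m,
          n_train = length(tr), n_test = length(te),
          type2 = sel$type2[[m]],
          basis = cl$basis, size = cl$size,
          peak_x = cl$peak_x, peak_y = cl$peak_y, peak_z = cl$peak_z,
          peak_idx = cl$peak_idx,
          peak_t = cl$peak_t, peak_z_score = cl$peak_z_score,
          diff_peak_t = cl$diff_peak_t, diff_peak_p = cl$diff_peak_p,
          r2_change = r2_change,
          r2_t2_t1_only = hier$r2_t1_only,
          r2_t2_full = hier$r2_full,
          r2_t2_after_t1 = hier$increment
        )
        out$voxels <- cl$voxels
        rows[[length(rows) + 1]] <- out
      }
    }
  }
  folds <- dplyr::bind_rows(rows)
  summary <- folds |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(
      n_analyses = dplyr::n(),
      r2_change = mean(.data$r2_change, na.rm = TRUE),
      r2_t2_full = mean(.data$r2_t2_full),
      r2_t2_after_t1 = mean(.data$r2_t2_after_t1),
      type2_rate = mean(.data$type2),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$measure))
  new_cv_result("splithalf", folds, summary, config,
                extra = list(selection_freq = freq))
}
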