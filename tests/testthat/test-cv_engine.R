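test_that("held-out prediction is the training regression line", {
  pairs <- tibble::tibble(density = c(0, 1, 2), change = c(0, 2, 4))
  expect_equal(predict_held_out(pairs, 3), 6)
  # constant training changes: slope 0, prediction is the constant
  flat <- tibble::tibble(density = c(0, 1, 2, 5), change = rep(7, 4))
  expect_equal(predict_held_out(flat, 100), 7)
  # OLS passes through the means
  set.seed(1)
  p <- tibble::tibble(density = rnorm(10), change = rnorm(10))
  expect_equal(predict_held_out(p, mean(p$density)), mean(p$change))
  expect_error(predict_held_out(pairs[1:2, ], 1), "at least 3")
  expect_error(predict_held_out(tibble::tibble(density = c(1, 1, 1),
                                               change = 1:3), 1),
               "zero variance")
})

test_that("stratified splits balance size and strata and are reproducible", {
  tab <- iq_reference_table()
  s <- stratified_split(tab, repeat_index = 1, seed = 9)
  expect_setequal(c(s$group_a, s$group_b), tab$subject_id)
  expect_equal(sort(c(length(s$group_a), length(s$group_b))), c(16, 17))
  # each group's high-stratum share within one subject of a half
  high <- s$strata$subject_id[s$strata$stratum == "high"]
  expect_lte(abs(sum(s$group_a %in% high) - length(high) / 2), 1)
  expect_lte(abs(sum(s$group_b %in% high) - length(high) / 2), 1)
  expect_identical(s, stratified_split(tab, repeat_index = 1, seed = 9))
  expect_false(identical(s$group_a,
                         stratified_split(tab, 2, seed = 9)$group_a))
  # different repeats under one master seed give different partitions
  parts <- vapply(1:10, function(r)
    paste(sort(stratified_split(tab, r, seed = 9)$group_a), collapse = ","),
    character(1))
  expect_gt(length(unique(parts)), 1)
})

test_that("hierarchical regression matches a hand-computed nested fit", {
  rec <- tibble::tibble(t1 = c(100, 110, 120, 130, 140),
                        t2 = c(102, 115, 118, 135, 150))
  dens <- c(0.1, -0.2, 0.3, 0.0, 0.2)
  h <- hierarchical_r2(rec, dens)
  # frozen values from an explicit normal-equations solve
  expect_equal(h$r2_t1_only, 0.9625178827, tolerance = 1e-9)
  expect_equal(h$r2_full, 0.9770928166, tolerance = 1e-9)
  expect_equal(h$increment, 0.0145749339, tolerance = 1e-8)
  expect_gte(h$increment, 0)

  # exact linear dependence gives r2_full = 1
  rec2 <- tibble::tibble(t1 = c(1, 2, 3, 4, 5) * 10)
  rec2$t2 <- 2 * rec2$t1 + 3 * dens
  expect_equal(suppressWarnings(hierarchical_r2(rec2, dens)$r2_full), 1)

  # collinear density is flagged
  expect_warning(hierarchical_r2(rec, rec$t1 * 2), "collinear")
  expect_error(hierarchical_r2(rec[1:3, ], dens[1:3]), "at least 4")
})

test_that("leave-one-out is exhaustive, independent and self-consistent", {
  co <- strong_cohort()
  res <- strong_loo()
  expect_equal(res$scheme, "loo")
  expect_equal(nrow(res$folds), 2 * 33)
  expect_setequal(unique(res$folds$held_out), co$tab$subject_id)
  # each subject held out exactly once per measure
  expect_true(all(table(res$folds$held_out) == 2))
  # out-of-sample R2 equals the squared correlation of predicted and
  # measured change (OLS identity)
  for (m in c("viq", "piq")) {
    f <- res$folds[res$folds$measure == m & !res$folds$excluded, ]
    expect_equal(res$summary$r2_change[res$summary$measure == m],
                 cor(f$predicted_change, f$measured_change)^2)
  }
  expect_true(all(res$summary$r2_change >= 0 & res$summary$r2_change <= 1))
})

test_that("leave-one-out flags folds without a surviving selection", {
  nc <- null_cohort(n = 8, shape = c(8, 8, 8), seed = 500)
  cfg <- cv_config(correction = "bonferroni", seed = 501)
  expect_warning(res <- loo_run(nc$tab, nc$vols, cfg), "excluded")
  expect_true(all(res$folds$excluded))
  expect_true(all(is.na(res$summary$r2_change)))
  expect_equal(res$summary$type2_rate, c(1, 1))
})

test_that("split-half runs 2 x repeats analyses with non-negative increments", {
  co <- strong_cohort()
  cfg <- cv_config(correction = "bonferroni", repeats = 3, seed = 71)
  res <- split_half_run(co$tab, co$vols, cfg, search_mask = co$mask)
  expect_equal(res$scheme, "splithalf")
  expect_equal(nrow(res$folds), 2 * 2 * 3) # analyses x measures
  expect_equal(res$summary$n_analyses, c(6, 6))
  # nested within-sample fits: the density increment can never be negative
  expect_true(all(res$folds$r2_t2_after_t1 >= -1e-12))
  # every subject appears in a validation set every repeat
  expect_error(split_half_run(co$tab, co$vols, cfg, search_mask = NULL),
               "search mask")
  # selection-frequency maps count one cluster per analysis
  expect_equal(max(res$selection_freq$viq), 6)
})

test_that("increasing noise degrades out-of-sample prediction for both schemes", {
  tab <- simulate_iq(14, seed = 81)
  mk <- function(noise) {
    truth <- ground_truth(shape = c(10, 10, 10), noise_sd = noise)
    truth$slope_v <- truth$slope_p <- 8e-4
    simulate_volumes(tab, truth, seed = 82)
  }
  truth0 <- ground_truth(shape = c(10, 10, 10))
  mask <- search_mask_around(truth0, margin = 2L)
  cfg <- cv_config(correction = "bonferroni", repeats = 3, seed = 83)
  lo_low <- loo_run(tab, mk(0.01), cfg, search_mask = mask)
  lo_high <- loo_run(tab, mk(0.06), cfg, search_mask = mask)
  expect_gt(mean(lo_low$summary$r2_change), mean(lo_high$summary$r2_change))
  sp_low <- split_half_run(tab, mk(0.01), cfg, search_mask = mask)
  sp_high <- split_half_run(tab, mk(0.06), cfg, search_mask = mask)
  expect_gt(mean(sp_low$summary$r2_change, na.rm = TRUE),
            mean(sp_high$summary$r2_change, na.rm = TRUE))
})
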