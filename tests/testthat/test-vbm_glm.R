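test_that("design matrix encodes the within-subject covariates as specified", {
  tab <- toy_iq_table(d_viq = c(2, -1, 0, 3), d_piq = c(1, 1, -2, 0))
  X <- build_design(tab)
  expect_equal(dim(X), c(8, 7))
  expect_equal(unname(X[, "e_viq"]), c(-2, 2, 1, -1, 0, 0, -3, 3))
  expect_equal(unname(X[, "e_piq"]), c(-1, 1, -1, 1, 2, -2, 0, 0))
  expect_equal(sum(X[, "tau"]), 0)
  # covariates are orthogonal to every subject indicator
  for (j in 1:4) {
    expect_equal(sum(X[, j] * X[, "tau"]), 0)
    expect_equal(sum(X[, j] * X[, "e_viq"]), 0)
    expect_equal(sum(X[, j] * X[, "e_piq"]), 0)
  }
  expect_error(build_design(toy_iq_table(d_viq = c(1, 2, 3))), "at least 4")
})

test_that("all-zero changes flag a degenerate covariate and block its contrast", {
  tab <- toy_iq_table(d_viq = c(0, 0, 0, 0, 0), d_piq = c(1, -1, 2, 0, 3))
  X <- build_design(tab)
  expect_equal(attr(X, "degenerate"), "e_viq")
  truth <- ground_truth(shape = c(8, 8, 8), noise_sd = 0.02)
  vols <- simulate_volumes(tab, truth, seed = 1)
  expect_error(fit_contrast(vols, X, c(0, 1, 0)), "e_viq")
  # the PIQ contrast is still estimable
  expect_s3_class(fit_contrast(vols, X, c(0, 0, 1)), "stat_map")
})

test_that("full-model t equals the difference-model t at every voxel", {
  tab <- simulate_iq(8, seed = 51)
  truth <- ground_truth(shape = c(4, 4, 4), center_v = c(2, 2, 2),
                        center_p = c(4, 4, 4), region_halfwidth = 0L,
                        noise_sd = 0.02)
  vols <- simulate_volumes(tab, truth, seed = 52)
  des <- build_design(tab)
  fit <- fit_glm(vols, des)
  D <- density_change_matrix(vols)
  for (w in list(c(0, 1, 0), c(0, 0, 1), c(0, 1, -1))) {
    map <- contrast_map(fit, w)
    for (vox in seq_len(64)) {
      # difference-model oracle: Delta ~ 1 + d_viq + d_piq across subjects
      sfit <- summary(lm(D[, vox] ~ tab$d_viq + tab$d_piq))$coefficients
      oracle_t <- if (identical(w, c(0, 1, -1))) {
        ct <- c(0, 1, -1)
        b <- lm(D[, vox] ~ tab$d_viq + tab$d_piq)
        V <- vcov(b)
        sum(ct * coef(b)) / sqrt(drop(t(ct) %*% V %*% ct))
      } else if (w[2] == 1) sfit[2, 3] else sfit[3, 3]
      expect_equal(map$t[vox], oracle_t, tolerance = 1e-8)
    }
    expect_equal(map$df, 5) # N - 3
  }
})

test_that("null cohorts produce nominal uncorrected false-positive rates", {
  rates <- vapply(1:20, function(r) {
    nc <- null_cohort(n = 12, shape = c(8, 8, 8), seed = 100 + r)
    map <- fit_contrast(nc$vols, build_design(nc$tab), c(0, 1, 0))
    mean(map$t > qt(0.95, map$df))
  }, numeric(1))
  mc_se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.05), 3 * mc_se + 0.005)
})

test_that("a perfect noise-free fit reports the infinite-t sentinel and capped z", {
  tab <- toy_iq_table(d_viq = c(2, -1, 0, 3, 1), d_piq = c(1, 1, -2, 0, -1))
  truth <- ground_truth(shape = c(8, 8, 8), noise_sd = 0, slope_v = 1e-3)
  vols <- simulate_volumes(tab, truth, seed = 1)
  map <- fit_contrast(vols, build_design(tab), c(0, 1, 0))
  ctr <- truth$center_v
  expect_true(is.infinite(map$t[ctr[1], ctr[2], ctr[3]]))
  expect_equal(map$z[ctr[1], ctr[2], ctr[3]], 38)
})

test_that("cluster extraction finds planted blobs, honours ties and order", {
  tarr <- array(0, c(8, 8, 8))
  tarr[2:2, 2:3, 2] <- 5; tarr[2, 2:4, 3] <- 5        # blob of 5 voxels
  tarr[6:7, 6, 6] <- c(7, 7); tarr[6:7, 7, 6] <- 6; tarr[6, 6, 7] <- 6 # 5 voxels
  cl <- extract_clusters(tarr, 4, connectivity = 26, df = 10)
  expect_equal(nrow(cl), 2)
  expect_equal(sort(cl$size), c(5L, 5L))
  # first cluster has the highest peak; tie at 7 broken by smaller linear index
  expect_equal(cl$peak_t[1], 7)
  expect_equal(c(cl$peak_x[1], cl$peak_y[1], cl$peak_z[1]), c(5, 5, 5))
  # uniform sub-threshold map yields no clusters
  expect_equal(nrow(extract_clusters(array(1, c(4, 4, 4)), 4, df = 10)), 0)
  # connectivity matters: two diagonal voxels join under 26 but not 6
  diag2 <- array(0, c(4, 4, 4)); diag2[1, 1, 1] <- 5; diag2[2, 2, 2] <- 5
  expect_equal(nrow(extract_clusters(diag2, 4, connectivity = 26, df = 10)), 1)
  expect_equal(nrow(extract_clusters(diag2, 4, connectivity = 6, df = 10)), 2)
})

test_that("permutation thresholds are sane and tighten with rougher noise", {
  nc <- null_cohort(n = 14, shape = c(8, 8, 8), seed = 300)
  des <- build_design(nc$tab)
  expect_error(fwe_thresholds(nc$vols, des, c(0, 1, 0), n_perm = 50),
               "at least 100")
  expect_error(fwe_thresholds(nc$vols, des, c(1, 0, 0), n_perm = 100),
               "contrasts")

  # constant-zero volumes: observed map is identically zero, so nothing
  # can exceed any non-negative height threshold
  zero <- nc$vols
  zero$t1[] <- 0; zero$t2[] <- 0
  thr0 <- fwe_thresholds(zero, des, c(0, 1, 0), n_perm = 100, seed = 1,
                         cluster_forming_p = 0.01)
  map0 <- fit_contrast(zero, des, c(0, 1, 0))
  expect_true(all(map0$t < pmax(thr0$height_t_crit, 1e-9)))

  # smoother noise -> fewer effective tests -> lower corrected height
  smooth_truth <- ground_truth(shape = c(10, 10, 10), slope_v = 0, slope_p = 0,
                               smooth_fwhm = 12)
  rough_truth <- ground_truth(shape = c(10, 10, 10), slope_v = 0, slope_p = 0,
                              smooth_fwhm = 0)
  tab <- simulate_iq(14, seed = 301)
  vs <- simulate_volumes(tab, smooth_truth, seed = 302)
  vr <- simulate_volumes(tab, rough_truth, seed = 302)
  d2 <- build_design(tab)
  ts <- fwe_thresholds(vs, d2, c(0, 1, 0), n_perm = 200, seed = 303,
                       cluster_forming_p = 0.01)
  tr <- fwe_thresholds(vr, d2, c(0, 1, 0), n_perm = 200, seed = 303,
                       cluster_forming_p = 0.01)
  expect_lt(ts$height_t_crit, tr$height_t_crit)
})

test_that("region selection applies correction, conjunction and fallback", {
  co <- strong_cohort()
  cfg <- cv_config(n_perm = 100, seed = 61)
  sel <- step1_select(co$tab, co$vols, cfg)
  vi <- sel$clusters[sel$clusters$measure == "viq", ]
  pi_ <- sel$clusters[sel$clusters$measure == "piq", ]
  ctr_lin_v <- longicv:::coord_to_lin(matrix(co$truth$center_v, 1), co$truth$shape)
  ctr_lin_p <- longicv:::coord_to_lin(matrix(co$truth$center_p, 1), co$truth$shape)
  expect_true(any(vapply(vi$voxels, function(v) ctr_lin_v %in% v, logical(1))))
  expect_true(any(vapply(pi_$voxels, function(v) ctr_lin_p %in% v, logical(1))))
  expect_false(any(sel$type2))

  # equal effects for both measures at the same voxels: the difference
  # conjunction removes the region from both selections
  df <- 20
  shared <- array(0, c(8, 8, 8)); shared[4:6, 4:6, 4] <- 8
  flat <- array(0, c(8, 8, 8))
  thr <- list(forming_t = c(viq = 3, piq = 3),
              height_crit = c(viq = 5, piq = 5),
              extent_crit = c(viq = Inf, piq = Inf),
              conjunction_p = 0.01)
  sel2 <- select_regions(make_stat_map(shared, df), make_stat_map(shared, df),
                         make_stat_map(flat, df), make_stat_map(flat, df),
                         thr)
  expect_equal(nrow(sel2$clusters), 0)
  expect_false(any(sel2$type2)) # correction was survived; conjunction removed

  # null cohort with a search mask: fallback selection, flagged type 2
  nc <- null_cohort(n = 12, shape = c(10, 10, 10), seed = 305)
  mask <- search_mask_around(nc$truth, margin = 2L)
  sel3 <- step1_select(nc$tab, nc$vols, cv_config(n_perm = 100, seed = 62),
                       search_mask = mask)
  expect_equal(nrow(sel3$clusters), 2)
  expect_true(all(sel3$clusters$basis == "search-space-max"))
  expect_true(all(sel3$type2))
  expect_error(step1_select(nc$tab, nc$vols, cv_config(n_perm = 100),
                            search_mask = array(FALSE, c(10, 10, 10))),
               "empty")
})
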