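# Shared fixtures. Heavy synthetic cohorts are built once per test session
# and cached, so the unit suites and the acceptance suite reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# hand-built IQ table from explicit change scores
toy_iq_table <- function(d_viq, d_piq = rev(d_viq), t1_base = 100) {
  n <- length(d_viq)
  tibble::tibble(
    subject_id = seq_len(n),
    viq_t1 = t1_base + seq_len(n), piq_t1 = t1_base - seq_len(n),
    viq_t2 = t1_base + seq_len(n) + d_viq,
    piq_t2 = t1_base - seq_len(n) + d_piq,
    d_viq = d_viq, d_piq = d_piq
  )
}

# 33-subject cohort on a 16^3 grid with strong planted effects
# (theoretical peak R^2 = 0.8); used by recovery and count checks
strong_cohort <- function() {
  cache_get("strong16", function() {
    tab <- simulate_iq(33, seed = 401)
    truth <- ground_truth(shape = c(16, 16, 16))
    truth$slope_v <- slope_for_r2(truth, tab$d_viq, 0.8, n_rep = 150, seed = 402)
    truth$slope_p <- slope_for_r2(truth, tab$d_piq, 0.8, n_rep = 150, seed = 402)
    vols <- simulate_volumes(tab, truth, seed = 403)
    list(tab = tab, truth = truth, vols = vols,
         mask = search_mask_around(truth, margin = 3L))
  })
}

# full LOO on the strong cohort with permutation correction (shared by the
# structural-count and parameter-recovery checks)
strong_loo <- function() {
  cache_get("strong16_loo", function() {
    co <- strong_cohort()
    loo_run(co$tab, co$vols, cv_config(n_perm = 100, seed = 404))
  })
}

# 25-repeat split-half on the same cohort with the search-mask fallback
strong_split <- function() {
  cache_get("strong16_split", function() {
    co <- strong_cohort()
    split_half_run(co$tab, co$vols,
                   cv_config(n_perm = 100, repeats = 25, seed = 405),
                   search_mask = co$mask)
  })
}

# small noise-only cohort (no planted effects) for null checks
null_cohort <- function(n = 12, shape = c(10, 10, 10), seed = 1) {
  truth <- ground_truth(shape = shape, slope_v = 0, slope_p = 0)
  tab <- simulate_iq(n, seed = derive_seed(seed, "nulltab"))
  vols <- simulate_volumes(tab, truth, seed = derive_seed(seed, "nullvol"))
  list(tab = tab, truth = truth, vols = vols)
}

make_stat_map <- function(tarr, df, voxel_size = c(1, 1, 1)) {
  structure(list(t = tarr, z = array(longicv:::t_to_z(tarr, df), dim(tarr)),
                 df = df, weights = c(0, 1, 0),
                 dim = dim(tarr), voxel_size = voxel_size),
            class = "stat_map")
}
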