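test_that("jackknife errors vanish for empty experiments and match symmetry", {
  g <- tiny_grid()
  mask <- full_mask(g)
  f1 <- voxel_to_mm(g, c(8, 5, 4))
  fl <- list(
    A = list(experiment_id = "A", foci = f1, n_subjects = 15),
    B = list(experiment_id = "B", foci = f1, n_subjects = 15),  # duplicate of A
    C = list(experiment_id = "C", foci = matrix(numeric(0), ncol = 3),
             n_subjects = 15)
  )
  jk <- jackknife_errors(fl, g, mask)
  e <- jk$errors
  expect_equal(e$E_k[e$experiment_id == "C"], 0)
  expect_equal(e$E_k[e$experiment_id == "A"], e$E_k[e$experiment_id == "B"])
  expect_true(all(e$E_k >= 0))
  expect_equal(e$E_k_x100, e$E_k * 100)

  # permutation invariance over experiment order
  jk2 <- jackknife_errors(fl[c(3, 1, 2)], g, mask)
  m1 <- stats::setNames(e$E_k, e$experiment_id)
  m2 <- stats::setNames(jk2$errors$E_k, jk2$errors$experiment_id)
  expect_equal(m2[names(m1)], m1)
})

test_that("the singleton jackknife equals the squared total map", {
  g <- tiny_grid()
  mask <- full_mask(g)
  fl <- list(A = list(experiment_id = "A",
                      foci = voxel_to_mm(g, c(9, 6, 5)), n_subjects = 20))
  cfg <- phac_config()
  jk <- jackknife_errors(fl, g, mask, cfg)
  ma <- apply_midline_compensation(
    build_ma_map(fl$A$foci, g, mask, fwhm = cfg$fwhm),
    cfg$midline_radius_mm, cfg$midline_kernel)
  S0 <- ma$volume$data   # union of one map is the map itself
  expect_equal(jk$errors$E_k, sum(S0^2), tolerance = 1e-12)
})

test_that("jackknife errors shrink as an experiment's foci disappear", {
  g <- tiny_grid()
  mask <- full_mask(g)
  base <- list(experiment_id = "A", foci = voxel_to_mm(g, c(8, 5, 4)),
               n_subjects = 15)
  # continuity: E_k for an experiment with fewer foci is smaller
  strong <- list(A = base,
                 B = list(experiment_id = "B",
                          foci = voxel_to_mm(g, rbind(c(4, 5, 4), c(4, 8, 6))),
                          n_subjects = 15))
  weak <- strong
  weak$B$foci <- weak$B$foci[1, , drop = FALSE]
  none <- strong
  none$B$foci <- matrix(numeric(0), ncol = 3)
  eB <- vapply(list(strong, weak, none), function(fl)
    jackknife_errors(fl, g, mask)$errors$E_k[2], numeric(1))
  expect_true(eB[1] > eB[2] && eB[2] > eB[3] && eB[3] == 0)
})

test_that("bootstrap frequencies are degenerate for identical experiments", {
  w <- small_world(n_experiments = 30, n_pairs = 4, seed = 15)
  cfg <- fast_config(n_samples = 400)
  res <- run_phac(w$foci_list, w$atlas, w$mask, fast_config(n_samples = 400, seed = 1))
  # N copies of the same row: every resample is identical to the full data
  m1 <- w$oracle[rep(1, 30), , drop = FALSE]
  full <- edge_statistics(m1, w$atlas, cfg)
  bt <- bootstrap_reliability(m1, w$atlas, B = 20, cfg, seed = 5)
  expect_true(all(bt$table$freq_significant %in% c(0, 1)))
  expect_equal(bt$table$freq_significant, as.numeric(full$significant))

  # general properties and determinism
  bt2 <- bootstrap_reliability(res$matrix, w$atlas, B = 25, cfg, seed = 9)
  bt3 <- bootstrap_reliability(res$matrix, w$atlas, B = 25, cfg, seed = 9)
  expect_identical(bt2$table, bt3$table)
  expect_true(all(bt2$table$freq_significant >= 0 &
                  bt2$table$freq_significant <= 1))
  expect_true(is.na(bt2$r_kappa) || abs(bt2$r_kappa) <= 1)
  expect_error(bootstrap_reliability(res$matrix, w$atlas, B = 0), "B")
})

test_that("strongly planted pairs are selected in most bootstrap resamples", {
  w <- small_world(n_experiments = 200, n_pairs = 4, seed = 16)
  cfg <- fast_config(n_samples = 500)
  res <- run_phac(w$foci_list, w$atlas, w$mask, fast_config(n_samples = 500, seed = 2))
  planted <- which(res$edges$kappa > 0.5 & res$edges$significant)
  expect_gte(length(planted), 1)
  bt <- bootstrap_reliability(res$matrix, w$atlas, B = 200, cfg, seed = 3)
  expect_true(all(bt$table$freq_significant[planted] >= 0.9))
  expect_gt(bt$r_kappa, 0.9)
})

test_that("bootstrap Monte Carlo error does not grow with more resamples", {
  w <- small_world(n_experiments = 80, n_pairs = 6, seed = 17)
  cfg <- fast_config(n_samples = 300)
  mat <- w$oracle   # oracle matrix: same joint structure, no MA recompute
  sd_at <- function(B, seeds) {
    freqs <- sapply(seeds, function(s)
      bootstrap_reliability(mat, w$atlas, B = B, cfg, seed = s)$table$freq_significant)
    mean(apply(freqs, 1, stats::sd))
  }
  s50 <- sd_at(50, 101:104)
  s200 <- sd_at(200, 201:204)
  expect_lte(s200, s50 + 0.02)
})
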