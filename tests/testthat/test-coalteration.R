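test_that("the 20% VOI rule is boundary-inclusive", {
  atlas <- handmade_atlas(n_voxels = 10)
  lab <- atlas$labels$data
  node1 <- arrayInd(which(lab == 1L), dim(lab))

  two <- binary_at(atlas$labels, node1[1:2, ])
  one <- binary_at(atlas$labels, node1[1, , drop = FALSE])
  zero <- binary_at(atlas$labels, node1[0, , drop = FALSE])
  m <- build_alteration_matrix(list(e1 = two, e2 = one, e3 = zero), atlas)
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(m[, "1"], c(e1 = 1L, e2 = 0L, e3 = 0L))  # 2/10 in, 1/10 out
  expect_identical(m["e3", ], c("1" = 0L, "2" = 0L))
})

test_that("joint counts partition the experiments", {
  m <- cbind("1" = c(1, 1, 0, 0), "2" = c(1, 0, 1, 0))
  jc <- joint_counts(m, 1, 2)
  expect_identical(jc$z, c(1L, 1L, 1L, 1L))
  expect_equal(jc$theta, rep(0.25, 4))

  m0 <- cbind("1" = rep(0, 6), "2" = rep(0, 6))
  expect_identical(joint_counts(m0, 1, 2)$z, c(0L, 0L, 0L, 6L))
  expect_error(joint_counts(m0[0, , drop = FALSE], 1, 2))

  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    mr <- cbind("1" = rbinom(n, 1, 0.4), "2" = rbinom(n, 1, 0.4))
    expect_equal(sum(joint_counts(mr, 1, 2)$z), n)
  }
})

test_that("Patel's kappa matches hand-evaluated cases and is bounded", {
  expect_equal(patel_kappa(c(0.5, 0, 0, 0.5)), 1)
  expect_equal(patel_kappa(c(0.25, 0.25, 0.25, 0.25)), 0)
  expect_equal(patel_kappa(c(0, 0.5, 0.5, 0)), -1)
  # degenerate marginals: not-a-value with a recorded reason
  k <- patel_kappa(c(0, 0, 0.5, 0.5))  # left member never altered
  expect_true(is.na(k))
  expect_match(attr(k, "degenerate"), "marginal")
  expect_true(is.na(patel_kappa(c(0.5, 0.5, 0, 0))))
  expect_error(patel_kappa(c(0.5, 0.5, 0.5, 0.5)))
  expect_error(patel_kappa(c(-0.1, 0.6, 0.25, 0.25)))
})

test_that("kappa is zero at independence and increases in theta1", {
  set.seed(21)
  for (i in 1:50) {
    pa <- runif(1, 0.05, 0.95); pb <- runif(1, 0.05, 0.95)
    th <- c(pa * pb, (1 - pa) * pb, pa * (1 - pb), (1 - pa) * (1 - pb))
    expect_equal(patel_kappa(th), 0, tolerance = 1e-12)
  }
  # strictly increasing in theta1 with both marginals held fixed
  pa <- 0.6; pb <- 0.45
  t1 <- seq(max(0, pa + pb - 1) + 0.01, min(pa, pb) - 0.01, length.out = 60)
  th <- cbind(t1, pb - t1, pa - t1, 1 - pa - pb + t1)
  expect_true(all(diff(patel_kappa(th)) > 0))
})

test_that("Patel's tau follows the two-branch marginal ratio", {
  expect_equal(patel_tau(c(0.2, 0.4, 0.1, 0.3)), 0.5)
  expect_equal(patel_tau(c(0.2, 0.1, 0.4, 0.3)), -0.5)
  expect_equal(patel_tau(c(0.3, 0.2, 0.2, 0.3)), 0)  # equal off-diagonals
  expect_equal(patel_tau(c(0, 0.5, 0, 0.5)), 1)
  expect_equal(patel_tau(c(0, 0, 0.5, 0.5)), -1)
  expect_true(is.na(patel_tau(c(0, 0, 0, 1))))       # never-altered pair
})

test_that("kappa is symmetric and tau antisymmetric under member swap", {
  set.seed(31)
  th <- matrix(rgamma(4e4, 1), ncol = 4)
  th <- th / rowSums(th)
  sw <- th[, c(1, 3, 2, 4)]
  expect_equal(patel_kappa(th), patel_kappa(sw), tolerance = 1e-9)
  expect_equal(patel_tau(th), -patel_tau(sw), tolerance = 1e-9)
  expect_true(all(abs(patel_kappa(th)) <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(abs(patel_tau(th)) <= 1 + 1e-12, na.rm = TRUE))
  # sign(tau) tracks the marginal difference P(b) - P(a) = theta2 - theta3
  expect_equal(sign(patel_tau(th)), sign(th[, 2] - th[, 3]))
})

test_that("Monte Carlo significance separates strong edges from noise", {
  strong <- kappa_significance(c(60, 2, 2, 36), seed = 0)
  expect_true(strong$significant)
  expect_gt(strong$prop_exceed, 0.99)

  flat <- kappa_significance(c(25, 25, 25, 25), seed = 0)
  expect_false(flat$significant)
  expect_lt(flat$prop_exceed, 0.95)

  # reproducible under the same seed
  again <- kappa_significance(c(60, 2, 2, 36), seed = 0)
  expect_identical(strong$prop_exceed, again$prop_exceed)

  # the mode-centred prior guards empty cells and never crashes
  lit <- kappa_significance(c(40, 0, 0, 60), prior_mode = "paper", seed = 2)
  expect_true(is.finite(lit$prop_exceed))
  expect_identical(lit$prior_mode, "paper")

  expect_error(kappa_significance(c(10, 5, 5, 10), n_samples = 0))
  expect_error(kappa_significance(c(-1, 5, 5, 10)))
})

test_that("edge statistics cover every pair and gate tau on significance", {
  w <- small_world(n_experiments = 60, n_pairs = 8, seed = 9)
  m <- build_alteration_matrix(lapply(names(w$foci_list), function(id) {
    ma <- build_ma_map(w$foci_list[[id]]$foci, w$atlas$labels, w$mask$data,
                       fwhm = 10)
    threshold_ma(ma, w$mask$data, method = "absolute", cutoff = 0.005)
  }), w$atlas)
  e <- edge_statistics(m, w$atlas, fast_config(seed = 7))
  expect_equal(nrow(e), nrow(w$atlas$pairs))
  expect_true(all(is.na(e$tau[!e$significant])))
  expect_true(all(!is.na(e$tau[e$significant])))
  expect_true(all(abs(e$kappa) <= 1, na.rm = TRUE))
  conv <- attr(e, "convention")
  expect_match(conv$a, "right")

  # a never-altered pair keeps its row with NA kappa
  m2 <- m
  m2[, c("1", as.character(nrow(w$atlas$pairs) + 1))] <- 0L
  e2 <- edge_statistics(m2, w$atlas, fast_config(seed = 7))
  expect_equal(nrow(e2), nrow(w$atlas$pairs))
  expect_true(is.na(e2$kappa[1]))
  expect_false(e2$significant[1])
})
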