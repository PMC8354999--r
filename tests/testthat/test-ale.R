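test_that("sigma follows the FWHM relation", {
  expect_equal(sigma_from_fwhm(sqrt(8 * log(2))), 1.0)
  expect_equal(sigma_from_fwhm(10), 4.24661, tolerance = 1e-5)
  expect_error(sigma_from_fwhm(0))
  expect_error(sigma_from_fwhm(-3))
  # strictly increasing in FWHM
  f <- seq(1, 20, by = 0.5)
  expect_true(all(diff(sigma_from_fwhm(f)) > 0))
})

test_that("the Gaussian focus density matches its closed form", {
  expect_equal(gaussian_focus_density(0, 1), (2 * pi)^(-1.5), tolerance = 1e-9)
  expect_equal(gaussian_focus_density(0, 1), 0.063494, tolerance = 1e-5)
  expect_equal(gaussian_focus_density(1, 1), 0.063494 * exp(-0.5),
               tolerance = 1e-5)
  expect_error(gaussian_focus_density(1, 0))
  # monotone decreasing in distance
  d <- seq(0, 20, by = 0.25)
  for (s in c(1, 3, 4.24661)) {
    expect_true(all(diff(gaussian_focus_density(d, s)) < 0))
  }
})

test_that("MA maps have the analytic peak and obey the max rule", {
  g <- tiny_grid()
  mask <- full_mask(g)
  focus <- voxel_to_mm(g, c(8, 5, 4))
  ma <- build_ma_map(focus, g, mask, fwhm = 10)
  sig <- sigma_from_fwhm(10)
  peak_expected <- 8 * gaussian_focus_density(0, sig)
  expect_equal(ma$volume$data[8, 5, 4], peak_expected, tolerance = 1e-9)
  expect_equal(peak_expected, 6.633e-3, tolerance = 1e-4)
  expect_equal(max(ma$volume$data), ma$volume$data[8, 5, 4])
  expect_true(all(ma$volume$data >= 0 & ma$volume$data <= 1))

  # duplicated focus: identical map (max-rule idempotence)
  ma2 <- build_ma_map(rbind(focus, focus), g, mask, fwhm = 10)
  expect_equal(ma2$volume$data, ma$volume$data)

  # adding a focus never decreases any voxel value
  ma3 <- build_ma_map(rbind(focus, voxel_to_mm(g, c(3, 3, 3))), g, mask,
                      fwhm = 10)
  expect_true(all(ma3$volume$data >= ma$volume$data - 1e-15))

  # no foci: all-zero map
  ma0 <- build_ma_map(NULL, g, mask, fwhm = 10)
  expect_true(all(ma0$volume$data == 0))

  # peak strictly decreasing in sigma
  peaks <- vapply(seq(6, 16, by = 2), function(f)
    max(build_ma_map(focus, g, mask, fwhm = f)$volume$data), numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("foci outside the mask are dropped with a warning", {
  g <- tiny_grid()
  mask <- full_mask(g)
  mask[1:2, , ] <- FALSE
  inside <- voxel_to_mm(g, c(8, 5, 4))
  outside <- voxel_to_mm(g, c(1, 5, 4))
  expect_warning(ma <- build_ma_map(rbind(inside, outside), g, mask, fwhm = 10),
                 "dropped 1")
  expect_equal(ma$n_dropped_foci, 1L)
  ref <- build_ma_map(inside, g, mask, fwhm = 10)
  expect_equal(ma$volume$data, ref$volume$data)
})

test_that("midline compensation re-weights only within the radius", {
  # 13-wide grid: x coordinate of column i is (i - 7) * 2 mm
  g <- volume_grid(array(0.4, c(13, 4, 4)))
  ma <- structure(list(volume = g, sigma_mm = 4, experiment_id = "m"),
                  class = "ma_map")

  att <- apply_midline_compensation(ma, kernel = "attenuate")
  expect_equal(att$volume$data[1, 1, 1], 0.4)    # |x| = 12: boundary, unchanged
  expect_equal(att$volume$data[13, 1, 1], 0.4)
  expect_equal(att$volume$data[4, 1, 1], 0.2)    # |x| = 6: w = 6/12
  expect_equal(att$volume$data[7, 1, 1], 0)      # midline: w = 0

  inv <- apply_midline_compensation(ma, kernel = "inverse")
  expect_equal(inv$volume$data[1, 1, 1], 0.4)    # unchanged at the boundary
  expect_equal(inv$volume$data[4, 1, 1], 0.8)    # w = 12/6 = 2
  expect_equal(inv$volume$data[7, 1, 1], 1)      # clipped: 0.4 * 12/2 = 2.4 -> 1
  expect_identical(inv$midline_kernel, "inverse")

  expect_error(apply_midline_compensation(ma, kernel = "bogus"))
})

test_that("absolute thresholding keeps exactly the analytic iso-distance ball", {
  g <- tiny_grid(c(21, 21, 21))
  mask <- full_mask(g)
  ctr <- c(11, 11, 11)
  ma <- build_ma_map(voxel_to_mm(g, ctr), g, mask, fwhm = 10)
  cutoff <- 0.005
  bin <- threshold_ma(ma, mask, method = "absolute", cutoff = cutoff)
  sig <- sigma_from_fwhm(10)
  v0 <- 8 * gaussian_focus_density(0, sig)
  d_star <- sqrt(2 * sig^2 * log(v0 / cutoff))   # invert the kernel at cutoff
  ijk <- arrayInd(seq_len(prod(dim(g$data))), dim(g$data))
  d <- sqrt(rowSums(sweep(voxel_to_mm(g, ijk), 2,
                          drop(voxel_to_mm(g, ctr)), "-")^2))
  expect_identical(as.vector(bin$data) == 1, d <= d_star)
})

test_that("null-quantile thresholding is deterministic and rejects empty masks", {
  g <- tiny_grid()
  mask <- full_mask(g)
  ma <- build_ma_map(voxel_to_mm(g, c(8, 5, 4)), g, mask, fwhm = 10)
  b1 <- threshold_ma(ma, mask, method = "null_quantile", n_null = 200, seed = 42)
  b2 <- threshold_ma(ma, mask, method = "null_quantile", n_null = 200, seed = 42)
  expect_identical(attr(b1, "threshold"), attr(b2, "threshold"))
  expect_identical(b1$data, b2$data)
  expect_error(threshold_ma(ma, array(FALSE, dim(g$data))), "empty")

  # all-zero MA map stays all-zero whatever the threshold
  ma0 <- build_ma_map(NULL, g, mask, fwhm = 10)
  b0 <- threshold_ma(ma0, mask, method = "null_quantile", n_null = 100, seed = 1)
  expect_true(all(b0$data == 0))
})

test_that("ALE union has the product form and its algebraic properties", {
  g <- tiny_grid(c(5, 4, 3))
  mk <- function(v) volume_grid(array(v, dim(g$data)))
  expect_equal(ale_union(list(mk(0.3)))$data, mk(0.3)$data)
  expect_equal(ale_union(list(mk(0.5), mk(0.5)))$data[1, 1, 1], 0.75)
  expect_error(ale_union(list()))
  expect_error(ale_union(list(mk(0.5), volume_grid(array(0, c(7, 4, 3))))))

  set.seed(3)
  maps <- lapply(1:4, function(i) mk(array(runif(60), dim(g$data))))
  u <- ale_union(maps)
  expect_true(all(u$data >= 0 & u$data <= 1))
  expect_true(all(u$data >= Reduce(pmax, lapply(maps, `[[`, "data")) - 1e-15))
  # permutation invariance and associativity over groupings
  expect_equal(ale_union(maps[c(3, 1, 4, 2)])$data, u$data)
  expect_equal(ale_union(list(ale_union(maps[1:2]), ale_union(maps[3:4])))$data,
               u$data, tolerance = 1e-12)
})
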