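test_that("fiber generator handles the empty case and rejects bad specs", {
  img <- sim_fiber_image(32, n_fibers = 0, background_noise_sd = 0, seed = 1)
  expect_true(all(img == 0))
  expect_equal(ground_truth(img)$mask_fraction, 0)
  expect_error(sim_fiber_image(0, 5), "image_size")
  expect_error(sim_fiber_image(32, -1), "n_fibers")
  expect_error(sim_fiber_image(32, 5, fiber_width = 0), "fiber_width")
})

test_that("a single horizontal fiber produces a band whose mask fraction matches a direct pixel count", {
  # concentration high enough that the orientation is essentially the mean
  img <- sim_fiber_image(64, n_fibers = 1, fiber_width = 2,
                         orientation_concentration = 1e8,
                         mean_orientation = 0, background_noise_sd = 0,
                         seed = 7)
  gt <- ground_truth(img)
  # direct, independent count on the noiseless intensity
  direct <- sum(gt$clean > gt$intensity / 2) / length(img)
  expect_equal(gt$mask_fraction, direct)
  # the mask is a horizontal band: every column has the same mask profile
  rows_marked <- which(apply(gt$mask, 1, any))
  expect_true(all(gt$mask[rows_marked, ]))
})

test_that("generators are pure functions of their spec and seed", {
  a <- sim_fiber_image(48, 6, background_noise_sd = 3, seed = 42)
  b <- sim_fiber_image(48, 6, background_noise_sd = 3, seed = 42)
  expect_identical(as.vector(a), as.vector(b))
  expect_identical(ground_truth(a)$mask, ground_truth(b)$mask)

  f1 <- sim_correlated_field(64, 5, seed = 42)
  f2 <- sim_correlated_field(64, 5, seed = 42)
  expect_identical(as.vector(f1), as.vector(f2))

  n1 <- sim_nuclei_image(8, c(3, 5), 96, seed = 42)
  n2 <- sim_nuclei_image(8, c(3, 5), 96, seed = 42)
  expect_identical(as.vector(n1), as.vector(n2))

  c1 <- sim_indentation_curve(800, load_noise_sd = 0.05, seed = 42)
  c2 <- sim_indentation_curve(800, load_noise_sd = 0.05, seed = 42)
  expect_identical(c1$load_uN, c2$load_uN)

  d1 <- sim_deg_tables(c(a_up = 5, unchanged = 10), seed = 42)
  d2 <- sim_deg_tables(c(a_up = 5, unchanged = 10), seed = 42)
  expect_identical(d1$table_a, d2$table_a)

  m1 <- sim_count_matrix(30, 4, seed = 42)
  m2 <- sim_count_matrix(30, 4, seed = 42)
  expect_identical(m1$counts, m2$counts)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(sim_fiber_image(32, 3, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("correlated fields have the requested exponential autocovariance", {
  lam <- 20
  fld <- sim_correlated_field(512, corr_length = lam, seed = 11)
  ac <- fft_axis_autocorr(as.matrix(fld), lags = c(lam, 5))
  # at lag = corr_length the autocorrelation is ~exp(-1)
  expect_equal(mean(c(ac$h[1], ac$v[1])), exp(-1), tolerance = 0.15)

  # near-white-noise limit: tiny correlation length kills lag-5 correlation
  wn <- sim_correlated_field(256, corr_length = 0.25, seed = 12)
  ac_wn <- fft_axis_autocorr(as.matrix(wn), lags = 5)
  expect_lt(abs(ac_wn$h[1]), 0.05)
  expect_lt(abs(ac_wn$v[1]), 0.05)
})

test_that("correlated field warns when the correlation length is unresolvable", {
  expect_warning(sim_correlated_field(64, corr_length = 40, seed = 1),
                 "not resolvable")
})

test_that("nuclei generator places exactly n disjoint disks or fails loudly", {
  img <- sim_nuclei_image(0, c(4, 6), 64, seed = 1)
  expect_true(all(img == 0))
  expect_identical(ground_truth(img)$count, 0L)

  img <- sim_nuclei_image(25, c(5, 8), 512, seed = 3)
  gt <- ground_truth(img)
  expect_identical(gt$count, 25L)
  # disks are pairwise disjoint by construction: check centre distances
  d <- as.matrix(dist(gt$centers))
  rsum <- outer(gt$radii, gt$radii, "+")
  diag(d) <- Inf
  expect_true(all(d >= rsum))
  # an impossible packing raises a capacity error, not a short count
  expect_error(sim_nuclei_image(50, c(10, 12), 64, seed = 1),
               class = "stromaquant_capacity_error")
})

test_that("noiseless indentation curves satisfy the Hertz relation exactly", {
  E0 <- 1000
  crv <- sim_indentation_curve(E0, poisson_ratio = 0.5, tip_radius_um = 53.5,
                               max_depth_um = 10, load_noise_sd = 0,
                               contact_offset_um = 2, seed = 1)
  gt <- attr(crv, "ground_truth")
  h_m <- gt$h_um * 1e-6
  post <- tail(crv$load_uN, length(h_m)) * 1e-6
  expect_equal(post, hertz_oracle(h_m, E0, 0.5, 53.5e-6), tolerance = 1e-12)
  # full-depth load agrees with the closed form evaluated by hand
  expect_equal(max(post), (4 / 3) * (1000 / 0.75) * sqrt(53.5e-6) * (1e-5)^1.5,
               tolerance = 1e-12)
  # piezo travel = offset + depth + cantilever deflection
  z_expected <- 2 + gt$h_um + (post / 4.53) * 1e6
  expect_equal(tail(crv$z_um, length(h_m)), z_expected, tolerance = 1e-12)

  expect_error(sim_indentation_curve(0), "true_modulus_Pa")
  expect_error(sim_indentation_curve(100, max_depth_um = -1), "max_depth_um")
})

test_that("DEG fixtures honour their category structure", {
  fx <- sim_deg_tables(c(unchanged = 100), seed = 1)
  expect_equal(sum(fx$table_a$FDR < 0.05), 0)
  expect_equal(sum(fx$table_b$FDR < 0.05), 0)

  fx <- sim_deg_tables(c(a_up = 4, a_down = 3, b_up = 2, common_down = 5,
                         discordant = 2, unchanged = 10), seed = 2)
  expect_false(anyDuplicated(fx$table_a$gene) > 0)
  expect_identical(fx$table_a$gene, fx$table_b$gene)
  # logFC signs consistent with category
  truth <- fx$truth
  up_a <- truth$gene[truth$category %in% c("a_up", "common_up", "discordant")]
  expect_true(all(fx$table_a$logFC[fx$table_a$gene %in% up_a] > 0))

  # an FDR range crossing the significance threshold is ambiguous
  expect_error(sim_deg_tables(c(a_up = 2), fdr_significant_range = c(0.01, 0.1)),
               "ambiguous")
})

test_that("count matrices respect their spec", {
  cm0 <- sim_count_matrix(20, 4, mean_range = c(0, 0), seed = 1)
  expect_true(all(cm0$counts == 0))

  cm <- sim_count_matrix(100, 6, mean_range = c(1, 200), seed = 2)
  expect_true(all(colSums(cm$counts) > 0))
  expect_length(cm$perc_mm, 100)
  expect_error(sim_count_matrix(10, 0), "n_samples")
})

test_that("calibrated images round-trip through 16-bit TIFF with sidecar", {
  img <- sim_fiber_image(48, 4, background_noise_sd = 2, seed = 5,
                         pixel_size = 0.31)
  path <- file.path(withr::local_tempdir(), "img.tif")
  write_calibrated_tiff(img, path)
  back <- read_calibrated_tiff(path)
  expect_equal(pixel_size(back), 0.31)
  # 16-bit quantization: relative error bounded by the intensity range / 2^16
  expect_lt(max(abs(back - as.matrix(img))), diff(range(img)) / 65535)
})
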