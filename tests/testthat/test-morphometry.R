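test_that("collagen fraction reproduces saturation, symmetry and generator truth", {
  # all pixels above a fixed threshold -> 100%
  bright <- calibrated_image(matrix(10, 16, 16))
  expect_equal(collagen_fraction(bright, threshold = 5)$collagen_fraction_pct,
               100)

  # exact checkerboard with the threshold between the two levels -> 50%
  board <- calibrated_image(outer(1:32, 1:32, function(r, c) (r + c) %% 2) * 10)
  res <- collagen_fraction(board, threshold = 5)
  expect_identical(res$collagen_fraction_pct, 50)
  expect_identical(res$n_bright + res$n_dark, res$n_roi)

  # synthetic fibers at the construction threshold match the mask fraction
  img <- sim_fiber_image(256, 20, fiber_width = 3, background_noise_sd = 0,
                         seed = 4)
  gt <- ground_truth(img)
  res <- collagen_fraction(img, threshold = gt$intensity / 2)
  expect_equal(res$collagen_fraction_pct, 100 * gt$mask_fraction,
               tolerance = 0.01) # within 1 percentage point on the percentage scale
})

test_that("collagen fraction honours ROI and exclusion masks and fails on empty ROI", {
  m <- matrix(0, 10, 10)
  m[1:5, ] <- 10
  img <- calibrated_image(m)
  roi <- matrix(FALSE, 10, 10)
  roi[1:5, ] <- TRUE # only the bright half
  expect_equal(collagen_fraction(img, roi = roi, threshold = 5)$collagen_fraction_pct,
               100)
  # excluding the bright half from the full image leaves only dark pixels
  expect_equal(collagen_fraction(img, exclude = roi, threshold = 5)$collagen_fraction_pct,
               0)
  expect_error(collagen_fraction(img, roi = matrix(FALSE, 10, 10)), "empty")
  expect_error(collagen_fraction(calibrated_image(matrix(1, 4, 4))),
               class = "stromaquant_degenerate_threshold")
})

test_that("collagen fraction is monotone in the threshold and conserves pixels", {
  img <- sim_fiber_image(96, 10, background_noise_sd = 5, seed = 8)
  thr <- seq(min(img), max(img), length.out = 15)
  cf <- vapply(thr, function(t) {
    collagen_fraction(img, threshold = t)$collagen_fraction_pct
  }, numeric(1))
  expect_true(all(diff(cf) <= 0))
  expect_true(all(cf >= 0 & cf <= 100))
  # Nc/Nb conservation: fraction >= t plus fraction < t is 100
  t0 <- thr[7]
  below <- 100 * sum(as.matrix(img) < t0) / length(img)
  expect_equal(cf[7] + below, 100)
})

test_that("nuclei counting recovers the generated count and applies its rules", {
  expect_identical(count_nuclei(calibrated_image(matrix(0, 32, 32)))$n_nuclei, 0L)

  img <- sim_nuclei_image(25, c(5, 8), 512, intensity = 100, seed = 6)
  res <- count_nuclei(img, threshold = 50, min_area = 20)
  expect_identical(res$n_nuclei, ground_truth(img)$count)

  # two overlapping disks merge into one 8-connected component
  m <- matrix(0, 32, 32)
  xs <- matrix(rep(1:32, each = 32), 32)
  ys <- matrix(rep(1:32, 32), 32)
  m[(xs - 12)^2 + (ys - 16)^2 <= 25] <- 100
  m[(xs - 18)^2 + (ys - 16)^2 <= 25] <- 100
  expect_identical(count_nuclei(calibrated_image(m), threshold = 50,
                                min_area = 5)$n_nuclei, 1L)

  # intensity rescaling with an equally rescaled threshold changes nothing
  img2 <- calibrated_image(as.matrix(img) * 3 + 7)
  res2 <- count_nuclei(img2, threshold = 50 * 3 + 7, min_area = 20)
  expect_identical(res2$n_nuclei, res$n_nuclei)

  # min_area filters small components
  small <- matrix(0, 16, 16)
  small[8, 8] <- 100 # single-pixel speck
  expect_identical(count_nuclei(calibrated_image(small), threshold = 50,
                                min_area = 2)$n_nuclei, 0L)
})

test_that("component labelling is 8-connective", {
  m <- matrix(0, 4, 4)
  m[1, 1] <- 1
  m[2, 2] <- 1 # diagonal touch: one component under 8-connectivity
  expect_identical(count_nuclei(calibrated_image(m), threshold = 0.5,
                                min_area = 1)$n_nuclei, 1L)
})

test_that("protein area per cell follows calibration arithmetic and generator truth", {
  m <- matrix(0, 20, 20)
  m[1:10, 1:10] <- 10 # 100 bright pixels
  img1 <- calibrated_image(m, pixel_size = 1)
  expect_equal(protein_area_per_cell(img1, 10, threshold = 5)$area_per_cell_um2,
               10)
  img2 <- calibrated_image(m, pixel_size = 0.5)
  expect_equal(protein_area_per_cell(img2, 10, threshold = 5)$area_per_cell_um2,
               2.5)
  expect_error(protein_area_per_cell(img1, 0, threshold = 5), "zero cells")

  # generator round-trip: thresholded protein area over generated nuclei count
  nuc <- sim_nuclei_image(12, c(4, 6), 256, seed = 9)
  prot <- sim_fiber_image(256, 6, fiber_width = 3, background_noise_sd = 0,
                          pixel_size = 0.5, seed = 10)
  gt <- ground_truth(prot)
  got <- protein_area_per_cell(prot, ground_truth(nuc)$count,
                               threshold = gt$intensity / 2)
  expect_equal(got$area_per_cell_um2, sum(gt$mask) * 0.25 / 12)
})

test_that("micro-tissue diameter matches analytic shapes and scales with calibration", {
  disk <- matrix(0, 256, 256)
  xs <- matrix(rep(1:256, each = 256), 256)
  ys <- matrix(rep(1:256, 256), 256)
  disk[(xs - 128)^2 + (ys - 128)^2 <= 100^2] <- 50
  img <- calibrated_image(disk, pixel_size = 1)
  got <- microtissue_diameter(img, threshold = 25)
  expect_equal(got$diameter_um, 200, tolerance = 0.01)

  # square of side s -> equivalent diameter 2 s / sqrt(pi)
  sq <- matrix(0, 64, 64)
  sq[10:29, 10:29] <- 10
  got_sq <- microtissue_diameter(calibrated_image(sq), threshold = 5)
  expect_equal(got_sq$diameter_um, 2 * 20 / sqrt(pi), tolerance = 1e-10)

  # linear scaling with pixel size
  img2 <- calibrated_image(disk, pixel_size = 2.5)
  expect_equal(microtissue_diameter(img2, threshold = 25)$diameter_um,
               got$diameter_um * 2.5)

  # with two objects the largest is measured
  two <- matrix(0, 64, 64)
  two[5:10, 5:10] <- 10   # 36 px
  two[30:49, 30:49] <- 10 # 400 px
  got_two <- microtissue_diameter(calibrated_image(two), threshold = 5)
  expect_equal(got_two$area_um2, 400)

  expect_error(microtissue_diameter(calibrated_image(matrix(0, 8, 8) + 1),
                                    threshold = 5), "no object")

  # Feret diameter of the square: its diagonal (plus pixel extent)
  feret <- microtissue_diameter(calibrated_image(sq), threshold = 5,
                                method = "feret")
  expect_equal(feret$diameter_um, 19 * sqrt(2) + 1, tolerance = 1e-10)
})

test_that("replicate aggregation gives mean and n-1 SD, undefined for n = 1", {
  df <- tibble::tibble(v = c(10, 10, 10))
  expect_equal(summarise_replicates(df, v),
               tibble::tibble(mean = 10, sd = 0, n = 3L))
  df2 <- tibble::tibble(v = c(1, 2, 3))
  got <- summarise_replicates(df2, v)
  expect_equal(got$mean, 2)
  expect_equal(got$sd, 1)
  single <- summarise_replicates(tibble::tibble(v = 5), v)
  expect_true(is.na(single$sd))

  # matches an independent two-pass computation on generated values
  vals <- ground_truth(sim_nuclei_image(10, c(3, 4), 128, seed = 2))$radii
  got <- summarise_replicates(tibble::tibble(v = vals), v)
  oracle <- two_pass_mean_sd(vals)
  expect_equal(c(got$mean, got$sd), unname(oracle), tolerance = 1e-12)
})
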