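#' Simulate an SHG-like collagen fiber image
#'
#' Renders `n_fibers` straight fibers with Gaussian cross-sections on a square
#' image, mimicking a second-harmonic-generation (SHG) collagen channel.
#' Fiber orientations are drawn from a von Mises distribution: concentration
#' `kappa = 0` gives an isotropic ("chaotic") network, large `kappa` an
#' aligned one. Each fiber is an infinite line through a uniformly random
#' anchor point; its intensity profile is
#' `intensity * exp(-d^2 / (2 * fiber_width^2))` with `d` the perpendicular
#' distance to the line. Contributions sum, Gaussian background noise is
#' added, and the ground-truth fiber mask marks pixels whose *noiseless*
#' intensity exceeds half the single-fiber peak intensity.
#'
#' The ground truth carried on the returned image contains the mask, its
#' bright-pixel fraction (a direct pixel count), and the sampled orientations,
#' so threshold-based measurements can be checked against construction.
#'
#' @param image_size Side length in pixels (square image).
#' @param n_fibers Number of fibers (>= 0).
#' @param fiber_width Gaussian cross-section sigma in pixels (> 0).
#' @param orientation_concentration von Mises concentration `kappa >= 0`.
#' @param mean_orientation Mean fiber direction in radians.
#' @param intensity Peak single-fiber intensity (arbitrary units).
#' @param background_noise_sd SD of additive Gaussian background noise.
#' @param pixel_size Calibration in micrometres per pixel.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments including the seed.
#'
#' @return A [calibrated_image()] whose `ground_truth` holds `mask` (logical
#'   matrix), `mask_fraction`, `orientations`, and the generator arguments.
#' @export
#'
#' @examples
#' img <- sim_fiber_image(128, n_fibers = 10, fiber_width = 2, seed = 1)
#' ground_truth(img)$mask_fraction
sim_fiber_image <- function(image_size,
                            n_fibers,
                            fiber_width = 2,
                            orientation_concentration = 0,
                            mean_orientation = 0,
                            intensity = 100,
                            background_noise_sd = 0,
                            pixel_size = 1,
                            seed = 1L) {
  if (!is.numeric(image_size) || length(image_size) != 1L || image_size < 1) {
    abort("`image_size` must be a positive number of pixels.")
  }
  if (n_fibers < 0) abort("`n_fibers` must be >= 0.")
  if (fiber_width <= 0) abort("`fiber_width` must be > 0.")
  if (orientation_concentration < 0) abort("`orientation_concentration` must be >= 0.")
  image_size <- as.integer(image_size)

  withr_seed(seed, {
    clean <- matrix(0, image_size, image_size)
    thetas <- numeric(0)
    if (n_fibers > 0) {
      thetas <- rvonmises_(n_fibers, mean_orientation,
                           orientation_concentration)
      # pixel centres, 0-based coordinates
      xs <- matrix(rep(seq_len(image_size) - 1L, each = image_size),
                   image_size)
      ys <- matrix(rep(seq_len(image_size) - 1L, times = image_size),
                   image_size)
      for (i in seq_len(n_fibers)) {
        x0 <- runif(1, 0, image_size - 1)
        y0 <- runif(1, 0, image_size - 1)
        th <- thetas[i]
        # signed distance to the line through (x0, y0) with direction th
        d <- (xs - x0) * sin(th) - (ys - y0) * cos(th)
        clean <- clean + intensity * exp(-d^2 / (2 * fiber_width^2))
      }
    }
    mask <- clean > intensity / 2
    noisy <- clean
    if (background_noise_sd > 0) {
      noisy <- noisy + matrix(rnorm(image_size^2, 0, background_noise_sd),
                              image_size)
      noisy[noisy < 0] <- 0
    }
    calibrated_image(
      noisy,
      pixel_size = pixel_size,
      ground_truth = list(
        mask = mask,
        mask_fraction = sum(mask) / length(mask),
        clean = clean,
        orientations = thetas,
        n_fibers = n_fibers,
        fiber_width = fiber_width,
        intensity = intensity,
        seed = seed
      )
    )
  })
}

#' Simulate a stationary Gaussian field with exponential covariance
#'
#' Synthesizes, by spectral (FFT) filtering of white noise, a stationary
#' Gaussian random field whose spatial autocovariance decays approximately as
#' `exp(-d / corr_length)`. The filter is the square root of the 2D spectral
#' density of the exponential (Matern nu = 1/2) covariance,
#' `S(k) proportional to (1 + (k * lambda)^2)^(-3/2)`. The field is then
#' standardized and linearly rescaled to the `[0, 1]` intensity range. These
#' fields are the ground-truth inputs for correlation-length recovery: the
#' target length is known by construction.
#'
#' @param image_size Side length in pixels.
#' @param corr_length Target correlation length `lambda0` in pixels (> 0).
#' @param pixel_size Calibration in micrometres per pixel.
#' @param seed Integer seed.
#'
#' @return A [calibrated_image()] in `[0, 1]` whose `ground_truth` records
#'   `corr_length`.
#' @export
#'
#' @examples
#' fld <- sim_correlated_field(256, corr_length = 10, seed = 3)
sim_correlated_field <- function(image_size, corr_length,
                                 pixel_size = 1, seed = 1L) {
  if (!is.numeric(image_size) || length(image_size) != 1L || image_size < 2) {
    abort("`image_size` must be at least 2 pixels.")
  }
  if (corr_length <= 0) abort("`corr_length` must be > 0.")
  image_size <- as.integer(image_size)
  if (corr_length >= image_size / 2) {
    warn(sprintf(
      "corr_length (%.3g px) >= image_size/2 (%.3g px): the correlation length is not resolvable in this field.",
      corr_length, image_size / 2
    ))
  }

  withr_seed(seed, {
    n <- image_size
    freq <- c(seq(0, floor(n / 2)), seq_len(ceiling(n / 2) - 1) - ceiling(n / 2)) / n
    kx <- matrix(rep(2 * pi * freq, each = n), n)
    ky <- matrix(rep(2 * pi * freq, times = n), n)
    k2 <- kx^2 + ky^2
    amp <- (1 + k2 * corr_length^2)^(-3 / 4) # sqrt of spectral density
    white <- matrix(rnorm(n * n), n)
    field <- Re(fft(fft(white) * amp, inverse = TRUE)) / (n * n)
    field <- (field - mean(field)) / sd(field)
    lo <- min(field)
    hi <- max(field)
    field <- (field - lo) / (hi - lo)
    calibrated_image(
      field,
      pixel_size = pixel_size,
      ground_truth = list(corr_length = corr_length, seed = seed)
    )
  })
}

#' Simulate a DAPI-like nuclei image of non-overlapping disks
#'
#' Places `n` bright disks with radii drawn uniformly from `radius_range` on a
#' dark background, by rejection sampling so that no two disks overlap and
#' every disk lies fully inside the image. Disk edges keep at least
#' `min_separation` pixels of clearance so that the rasterized disks are also
#' disjoint as 8-connected pixel components, not merely as geometric circles.
#' If such a configuration cannot be found within `max_tries` placement
#' attempts, the generator stops with a capacity error rather than silently
#' returning fewer nuclei.
#'
#' @param n Number of nuclei (>= 0).
#' @param radius_range Length-2 numeric, disk radius range in pixels.
#' @param image_size Side length in pixels.
#' @param intensity Disk intensity; background is 0.
#' @param pixel_size Calibration in micrometres per pixel.
#' @param max_tries Total placement attempts before giving up.
#' @param min_separation Minimum edge-to-edge clearance between disks in
#'   pixels (default 2, enough for rasterized disks to stay 8-disconnected).
#' @param seed Integer seed.
#'
#' @return A [calibrated_image()] whose `ground_truth` holds `count = n`, the
#'   disk `centers` and `radii`, and the boolean `mask`.
#' @export
#'
#' @examples
#' nuc <- sim_nuclei_image(10, radius_range = c(4, 6), image_size = 128, seed = 2)
#' ground_truth(nuc)$count
sim_nuclei_image <- function(n, radius_range = c(5, 8), image_size = 512,
                             intensity = 100, pixel_size = 1,
                             max_tries = 500 * max(n, 1),
                             min_separation = 2, seed = 1L) {
  if (n < 0) abort("`n` must be >= 0.")
  if (length(radius_range) != 2L || any(radius_range <= 0)) {
    abort("`radius_range` must be two positive radii in pixels.")
  }
  image_size <- as.integer(image_size)
  radius_range <- sort(as.numeric(radius_range))

  withr_seed(seed, {
    centers <- matrix(numeric(0), ncol = 2)
    radii <- numeric(0)
    tries <- 0L
    while (nrow(centers) < n) {
      if (tries >= max_tries) {
        abort(sprintf(
          "could not place %d non-overlapping nuclei of radius %.3g-%.3g in a %d px image after %d attempts.",
          n, radius_range[1], radius_range[2], image_size, max_tries
        ), class = "stromaquant_capacity_error")
      }
      tries <- tries + 1L
      r <- runif(1, radius_range[1], radius_range[2])
      cx <- runif(1, r, image_size - 1 - r)
      cy <- runif(1, r, image_size - 1 - r)
      if (nrow(centers) > 0) {
        dist2 <- (centers[, 1] - cx)^2 + (centers[, 2] - cy)^2
        if (any(dist2 < (radii + r + min_separation)^2)) next
      }
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, r)
    }

    img <- matrix(0, image_size, image_size)
    mask <- matrix(FALSE, image_size, image_size)
    if (n > 0) {
      xs <- matrix(rep(seq_len(image_size) - 1L, each = image_size),
                   image_size)
      ys <- matrix(rep(seq_len(image_size) - 1L, times = image_size),
                   image_size)
      for (i in seq_len(n)) {
        inside <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 <=
          radii[i]^2
        mask <- mask | inside
        img[inside] <- intensity
      }
    }
    calibrated_image(
      img,
      pixel_size = pixel_size,
      ground_truth = list(
        count = as.integer(n),
        centers = centers,
        radii = radii,
        mask = mask,
        intensity = intensity,
        seed = seed
      )
    )
  })
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0 falls
# back to the uniform circle. Returned angles are folded into [0, pi) since
# fiber orientation is axial.
rvonmises_ <- function(n, mu, kappa) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) {
    th <- runif(n, 0, 2 * pi)
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    th <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        u1 <- runif(1)
        z <- cos(pi * u1)
        f <- (1 + r * z) / (r + z)
        c_ <- kappa * (r - f)
        u2 <- runif(1)
        if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
          u3 <- runif(1)
          th[i] <- mu + sign(u3 - 0.5) * acos(f)
          break
        }
      }
    }
  }
  th %% pi
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards, so generators are pure functions of their spec.
withr_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
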