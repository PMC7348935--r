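#' Detect the contact point of an indentation curve
#'
#' Locates where the probe first touches the sample, in two stages. First,
#' the load is smoothed with a short running mean, the leading
#' `baseline_frac` of samples (at least 5) gives the baseline statistics, and
#' a candidate crossing is the first sample where the smoothed load exceeds
#' `baseline mean + noise_multiplier * baseline SD` and stays above it. A
#' curve whose smoothed load never rises above that band carries no contact
#' and is an error. Second, the crossing is back-extrapolated to zero load
#' through the contact mechanics: for a Hertzian loading segment,
#' `(P - baseline)^(2/3)` is linear in the deflection-corrected travel
#' `z - P / k`, so a straight-line fit gives a first contact estimate as its
#' x-intercept, which is then refined by least squares on the load itself
#' (`P = C * max(x - z0, 0)^(3/2)`), where the measurement noise is additive.
#' On a noiseless curve this recovers the contact offset to machine
#' precision, including curves that begin exactly at contact (the
#' extrapolation is then capped at the first sample with a warning).
#'
#' @param curve An [indentation_curve()].
#' @param noise_multiplier Threshold in baseline SDs above the baseline mean
#'   (default 5).
#' @param baseline_frac Fraction of leading samples treated as baseline.
#' @param smooth_k Running-mean window in samples (odd; default 5).
#' @param refine_n Number of post-crossing samples used for the
#'   back-extrapolation fit (default 50).
#'
#' @return A list with `index` (first post-contact sample), `z_contact_um`
#'   (back-extrapolated contact displacement), and `threshold_uN`.
#' @export
detect_contact_point <- function(curve, noise_multiplier = 5,
                                 baseline_frac = 0.1, smooth_k = 5L,
                                 refine_n = 50L) {
  z <- curve$z_um
  P <- curve$load_uN
  k <- attr(curve, "stiffness_N_per_m")
  n <- length(P)
  Ps <- running_mean(P, smooth_k)

  n_base <- max(5L, floor(baseline_frac * n))
  base <- Ps[seq_len(min(n_base, n))]
  base_mean <- mean(base)
  thr <- base_mean + noise_multiplier * sd(base)
  if (!is.finite(thr)) thr <- base_mean

  # sustained crossing: above threshold here and at (almost) all later points
  above <- Ps > thr
  sustained <- which(above & rev(cumsum(rev(above))) >=
                       0.9 * (n - seq_len(n) + 1L))
  sustained <- sustained[sustained <= n - 4L] # need samples to fit beyond it
  if (length(sustained) == 0L) {
    abort("no contact detected: the load never rises above the baseline noise band.",
          class = "stromaquant_no_contact")
  }
  i <- sustained[1]
  # advance to the first raw-load crossing: on a noiseless curve this is the
  # first truly post-contact sample
  raw_above <- which(P > thr)
  raw_above <- raw_above[raw_above >= i]
  if (length(raw_above) > 0L) i <- raw_above[1]

  # Back-extrapolation to zero load through the contact mechanics.
  # Stage 1 (starting values): (P - baseline)^(2/3) is linear in the
  # deflection-corrected travel x = z - P/k on a Hertzian loading segment,
  # so a straight-line fit gives the contact point as its x-intercept.
  x_all <- z - (P * 1e-6) / k * 1e6 # deflection-corrected travel
  j <- seq(i, min(i + as.integer(refine_n) - 1L, n))
  x <- x_all[j]
  y <- pmax(P[j] - base_mean, 0)^(2 / 3)
  fit <- lm(y ~ x)
  slope <- coef(fit)[[2]]
  z0 <- if (is.finite(slope) && slope > 0) {
    -coef(fit)[[1]] / slope
  } else {
    z[max(i - 1L, 1L)]
  }
  # Stage 2: refine by least squares on the load itself, where the noise is
  # additive and unweighted: P = C * max(x - z0, 0)^(3/2) over the loading
  # segment (plus a few samples before the crossing, so z0 is bracketed).
  if (is.finite(slope) && slope > 0) {
    jj <- seq(max(i - 10L, 1L), n)
    dat <- data.frame(P = P[jj], x = x_all[jj])
    nls_fit <- tryCatch(
      minpack.lm::nlsLM(P ~ C * pmax(x - z0, 0)^1.5,
                        start = list(C = max(slope, 1e-12)^1.5, z0 = z0),
                        data = dat,
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL
    )
    if (!is.null(nls_fit)) {
      z0_nls <- coef(nls_fit)[["z0"]]
      if (is.finite(z0_nls) && z0_nls <= z[n]) z0 <- z0_nls
    }
  }
  if (z0 < z[1]) {
    warn("curve appears to begin at or after contact; contact point capped at the first sample.")
    z0 <- z[1]
    i <- 1L
  }
  list(index = as.integer(i), z_contact_um = z0, threshold_uN = thr)
}

#' Cantilever-deflection correction: piezo travel to true depth
#'
#' On a cantilever-based indenter the piezo travel `z` splits into sample
#' indentation and cantilever deflection: the true indentation depth is
#' `h = (z - z_contact) - P / k` with `k` the cantilever stiffness.
#' Pre-contact samples (`h <= 0`) are excluded.
#'
#' @param curve An [indentation_curve()].
#' @param z_contact_um Contact displacement from [detect_contact_point()]
#'   (default: detected automatically).
#' @param ... Passed to [detect_contact_point()] when `z_contact_um` is
#'   `NULL`.
#'
#' @return A tibble with post-contact columns `h_um` (true depth), `load_uN`,
#'   and `z_um`.
#' @export
correct_cantilever <- function(curve, z_contact_um = NULL, ...) {
  k <- attr(curve, "stiffness_N_per_m")
  if (is.null(z_contact_um)) {
    z_contact_um <- detect_contact_point(curve, ...)$z_contact_um
  }
  # deflection P/k in metres -> micrometres; load stored in uN = 1e-6 N
  defl_um <- (curve$load_uN * 1e-6) / k * 1e6
  h_um <- (curve$z_um - z_contact_um) - defl_um
  keep <- h_um > 0
  if (!any(keep)) {
    abort("no post-contact samples with positive depth; check the contact point and cantilever stiffness.")
  }
  tibble(h_um = h_um[keep], load_uN = curve$load_uN[keep],
         z_um = curve$z_um[keep])
}

#' Indentation stress and strain for a spherical probe
#'
#' Transforms load and true depth into indentation stress and strain using
#' the spherical contact radius `a = sqrt(R * h)`:
#' stress `sigma = P / (pi * a^2)` and strain
#' `epsilon = (4 / (3 * pi)) * (h / a) / (1 - nu^2)`. These definitions make
#' the stress/strain ratio reduce exactly to the Hertz relation, so for a
#' linear-elastic sample `sigma / epsilon = E` at every depth. Zero-depth
#' samples are excluded rather than producing divisions by zero.
#'
#' @param load_uN Load samples in micronewtons.
#' @param h_um True indentation depth in micrometres (paired with
#'   `load_uN`).
#' @param tip_radius_um Spherical tip radius in micrometres.
#' @param poisson_ratio Poisson ratio in `[0, 0.5]`.
#'
#' @return A tibble with `h_um`, `contact_radius_um`, `stress_Pa`, `strain`.
#' @export
#'
#' @examples
#' ss <- stress_strain(load_uN = c(0.1, 0.3), h_um = c(2, 4),
#'                     tip_radius_um = 53.5)
stress_strain <- function(load_uN, h_um, tip_radius_um = 53.5,
                          poisson_ratio = 0.5) {
  if (length(load_uN) != length(h_um)) {
    abort("`load_uN` and `h_um` must be paired samples.")
  }
  keep <- h_um > 0
  h_m <- h_um[keep] * 1e-6
  P_N <- load_uN[keep] * 1e-6
  R_m <- tip_radius_um * 1e-6
  a_m <- sqrt(R_m * h_m)
  sigma <- P_N / (pi * a_m^2)
  eps <- (4 / (3 * pi)) * (h_m / a_m) / (1 - poisson_ratio^2)
  tibble(
    h_um = h_um[keep],
    contact_radius_um = a_m * 1e6,
    stress_Pa = sigma,
    strain = eps
  )
}

#' Elastic modulus from an indentation curve
#'
#' Runs the full analysis of one spherical indentation: contact-point
#' detection, cantilever-deflection correction, the stress/strain transform,
#' and the modulus estimate. The default estimate is the slope of a
#' zero-intercept least-squares fit of stress against strain over the depth
#' range (using the whole record makes the estimate robust to load noise);
#' `method = "pointwise"` instead averages the per-sample stress/strain
#' ratio and reports its SD. The reduced modulus `E* = E / (1 - nu^2)` is
#' reported alongside.
#'
#' @param curve An [indentation_curve()].
#' @param depth_range_um Optional length-2 depth window (in micrometres of
#'   true depth) to fit; default uses all post-contact samples. At least 5
#'   samples must remain.
#' @param method `"fit"` (zero-intercept regression, default) or
#'   `"pointwise"`.
#' @param ... Passed to [detect_contact_point()].
#'
#' @return A list of class `modulus_fit` with `E_Pa`, `E_reduced_Pa`,
#'   `E_sd_Pa` (pointwise only), `residual_norm`, `contact`, `n_points`,
#'   `depth_range_um`, `method`, and `converged`.
#' @export
#'
#' @examples
#' crv <- sim_indentation_curve(1000, seed = 1)
#' fit <- elastic_modulus(crv)
#' glance(fit)
elastic_modulus <- function(curve, depth_range_um = NULL,
                            method = c("fit", "pointwise"), ...) {
  method <- arg_match(method)
  R <- attr(curve, "tip_radius_um")
  nu <- attr(curve, "poisson_ratio")
  contact <- detect_contact_point(curve, ...)
  post <- correct_cantilever(curve, z_contact_um = contact$z_contact_um)
  ss <- stress_strain(post$load_uN, post$h_um, tip_radius_um = R,
                      poisson_ratio = nu)
  if (!is.null(depth_range_um)) {
    ss <- filter(ss, .data$h_um >= depth_range_um[1],
                 .data$h_um <= depth_range_um[2])
  }
  if (nrow(ss) < 5L) {
    abort("need at least 5 post-contact samples in the depth range.")
  }

  if (method == "fit") {
    fit <- lm(stress_Pa ~ strain + 0, data = ss)
    E <- unname(coef(fit)[1])
    res <- sqrt(sum(resid(fit)^2))
    E_sd <- NA_real_
  } else {
    ratio <- ss$stress_Pa / ss$strain
    E <- mean(ratio)
    E_sd <- sd(ratio)
    res <- sqrt(sum((ratio - E)^2))
  }
  converged <- is.finite(E) && E > 0

  structure(
    list(
      E_Pa = if (converged) E else NA_real_,
      E_reduced_Pa = if (converged) E / (1 - nu^2) else NA_real_,
      E_sd_Pa = E_sd,
      residual_norm = res,
      contact = contact,
      n_points = nrow(ss),
      depth_range_um = depth_range_um %||% range(ss$h_um),
      method = method,
      poisson_ratio = nu,
      tip_radius_um = R,
      converged = converged,
      stress_strain = ss
    ),
    class = "modulus_fit"
  )
}

#' Aggregate modulus fits over replicate indentation points
#'
#' Each sample is indented at several points; this aggregates the successful
#' fits into mean and SD and reports how many fits failed.
#'
#' @param fits A list of [elastic_modulus()] results.
#' @return A one-row tibble with `E_mean_Pa`, `E_sd_Pa` (NA when only one
#'   success), `n_success`, `n_failed`.
#' @export
sample_modulus <- function(fits) {
  ok <- purrr::keep(fits, ~ isTRUE(.x$converged))
  if (length(ok) == 0L) {
    abort("all modulus fits failed; nothing to aggregate.")
  }
  E <- purrr::map_dbl(ok, "E_Pa")
  tibble(
    E_mean_Pa = mean(E),
    E_sd_Pa = if (length(E) > 1L) sd(E) else NA_real_,
    n_success = length(E),
    n_failed = length(fits) - length(E)
  )
}

#' @export
print.modulus_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf(
      "<modulus_fit> E = %.4g Pa (E* = %.4g Pa), %s over %d points, depth %.3g-%.3g um\n",
      x$E_Pa, x$E_reduced_Pa, x$method, x$n_points,
      x$depth_range_um[1], x$depth_range_um[2]
    ))
  } else {
    cat("<modulus_fit> failed: non-positive or non-finite modulus\n")
  }
  invisible(x)
}

#' @export
tidy.modulus_fit <- function(x, ...) {
  tibble(term = c("E", "E_reduced"),
         estimate = c(x$E_Pa, x$E_reduced_Pa),
         unit = "Pa")
}

#' @export
glance.modulus_fit <- function(x, ...) {
  tibble(E_Pa = x$E_Pa, E_reduced_Pa = x$E_reduced_Pa,
         E_sd_Pa = x$E_sd_Pa, residual_norm = x$residual_norm,
         n_points = x$n_points, method = x$method,
         poisson_ratio = x$poisson_ratio, converged = x$converged)
}

#' Plot the stress-strain record behind a modulus fit
#'
#' @param object A `modulus_fit` from [elastic_modulus()].
#' @param ... Unused.
#' @return A ggplot object showing the stress-strain samples and the fitted
#'   modulus line through the origin.
#' @export
autoplot.modulus_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$stress_strain,
                       ggplot2::aes(.data$strain, .data$stress_Pa)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "indentation strain", y = "indentation stress (Pa)")
  if (isTRUE(object$converged)) {
    p <- p + ggplot2::geom_abline(slope = object$E_Pa, intercept = 0,
                                  linetype = 2)
  }
  p
}

running_mean <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || length(x) < k) return(x)
  sm <- stats::filter(x, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  half <- (k - 1L) %/% 2L
  n <- length(x)
  sm[seq_len(half)] <- sm[half + 1L]
  sm[(n - half + 1L):n] <- sm[n - half]
  sm
}
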