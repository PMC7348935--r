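#' Quantize an image into discrete gray levels
#'
#' Linearly bins the intensity range `[min, max]` of the image into `levels`
#' equal-width bins, returning an integer matrix of levels `0 .. levels - 1`.
#' A constant image maps entirely to level 0. Binning preserves pixel
#' ordering, and an image that already takes exactly `levels` distinct
#' equally-spaced values is reproduced up to relabeling (quantization is
#' idempotent in the level pattern).
#'
#' @param img A [calibrated_image()] or numeric matrix.
#' @param levels Number of gray levels `G >= 2`.
#'
#' @return Integer matrix of the same dimensions with values in
#'   `0 .. levels - 1` and attribute `levels`.
#' @export
quantize_gray <- function(img, levels = 64L) {
  if (levels < 2) abort("`levels` must be >= 2.")
  m <- as_image_matrix(img)
  lo <- min(m)
  hi <- max(m)
  q <- if (hi > lo) {
    pmin(floor((m - lo) / (hi - lo) * levels), levels - 1L)
  } else {
    m * 0L
  }
  storage.mode(q) <- "integer"
  dim(q) <- dim(m)
  attr(q, "levels") <- as.integer(levels)
  q
}

#' Gray-level co-occurrence matrix for one pixel offset
#'
#' Tabulates the joint frequencies of quantized gray-level pairs at the pixel
#' offset `(dx, dy)` (`dx` along columns / x, `dy` along rows / y), over all
#' in-bounds ordered pixel pairs, and normalizes to probabilities. With
#' `symmetric = TRUE` (the default) each pair is also counted in reverse, so
#' the matrix is symmetric and the derived correlation does not depend on the
#' sign of the offset.
#'
#' @param quantized Integer matrix from [quantize_gray()], or any integer
#'   matrix of levels `0 .. levels - 1`.
#' @param dx,dy Pixel offset; `|dx|` must be smaller than the number of
#'   columns and `|dy|` than the number of rows.
#' @param levels Number of gray levels; taken from the `levels` attribute if
#'   absent.
#' @param symmetric Count reversed pairs as well (default `TRUE`).
#'
#' @return A list of class `glcm` with the probability matrix `p`, `counts`,
#'   `dx`, `dy`, `levels`, `symmetric`, and `counts_total`.
#' @export
#'
#' @examples
#' q <- quantize_gray(sim_fiber_image(64, 5, seed = 1), levels = 8)
#' g <- glcm(q, dx = 1, dy = 0)
#' sum(g$p) # 1
glcm <- function(quantized, dx, dy, levels = NULL, symmetric = TRUE) {
  if (is.null(levels)) levels <- attr(quantized, "levels")
  if (is.null(levels)) levels <- max(quantized) + 1L
  levels <- as.integer(levels)
  nr <- nrow(quantized)
  nc <- ncol(quantized)
  if (abs(dx) >= nc || abs(dy) >= nr) {
    abort(sprintf("offset (%d, %d) exceeds the %d x %d image.", dx, dy, nr, nc))
  }
  storage.mode(quantized) <- "integer"
  counts <- .glcm_counts(quantized, as.integer(dx), as.integer(dy),
                         levels, isTRUE(symmetric))
  total <- sum(counts)
  structure(
    list(
      p = counts / total,
      counts = counts,
      dx = as.integer(dx),
      dy = as.integer(dy),
      levels = levels,
      symmetric = isTRUE(symmetric),
      counts_total = total
    ),
    class = "glcm"
  )
}

#' Haralick correlation of a GLCM
#'
#' The correlation feature
#' `sum_ij (i - mu_i) (j - mu_j) p(i, j) / (sigma_i * sigma_j)`,
#' where `mu` and `sigma` are the marginal means and standard deviations of
#' the co-occurrence probabilities. This equals the Pearson correlation of
#' the quantized gray levels over the pixel-pair sample that built the
#' matrix; it lies in `[-1, 1]` and is undefined (an error) when a marginal
#' variance is zero, i.e. on a constant image.
#'
#' @param g A [glcm()].
#' @return A single correlation value in `[-1, 1]`.
#' @export
glcm_correlation <- function(g) {
  p <- g$p
  lev <- seq_len(nrow(p)) - 1
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  mu_i <- sum(lev * pi_)
  mu_j <- sum(lev * pj_)
  var_i <- sum((lev - mu_i)^2 * pi_)
  var_j <- sum((lev - mu_j)^2 * pj_)
  if (var_i <= 0 || var_j <= 0) {
    abort("GLCM correlation is undefined: a marginal variance is zero (constant image).",
          class = "stromaquant_undefined_correlation")
  }
  sum(outer(lev - mu_i, lev - mu_j) * p) / sqrt(var_i * var_j)
}

#' GLCM correlation versus offset distance
#'
#' Computes the GLCM correlation for offsets `(d, 0)` (horizontal) and
#' `(0, d)` (vertical) for `d = 1 .. d_max`, after quantizing the image to
#' `levels` gray levels. With `normalize = TRUE` each direction's curve is
#' divided by its value at `d = 1`, so the curve starts at 1; `C_mean` is the
#' mean of the two (normalized) directional curves. The distance at which the
#' curve falls off is the texture correlation length, extracted by
#' [fit_correlation_length()].
#'
#' @param img A [calibrated_image()] or numeric matrix.
#' @param d_max Largest offset in pixels (default 100); both image dimensions
#'   must exceed `d_max`.
#' @param levels Gray levels for quantization (default 64).
#' @param normalize Divide each directional curve by its `d = 1` value.
#'
#' @return A tibble of class `texture_curve` with columns `d`, `C_h`, `C_v`,
#'   `C_mean` and attributes `levels`, `normalized`, `pixel_size`,
#'   `c1` (the pre-normalization `d = 1` values).
#' @export
#'
#' @examples
#' fld <- sim_correlated_field(256, corr_length = 10, seed = 1)
#' crv <- correlation_curve(fld, d_max = 50)
#' fit_correlation_length(crv)
correlation_curve <- function(img, d_max = 100L, levels = 64L,
                              normalize = TRUE) {
  m <- as_image_matrix(img)
  usable <- min(nrow(m), ncol(m)) - 1L
  if (usable < d_max) {
    abort(sprintf(
      "image is too small for d_max = %d; the largest usable offset is %d px.",
      d_max, usable
    ))
  }
  q <- quantize_gray(m, levels)
  ds <- seq_len(d_max)
  C_h <- vapply(ds, function(d) glcm_correlation(glcm(q, d, 0L, levels)),
                numeric(1))
  C_v <- vapply(ds, function(d) glcm_correlation(glcm(q, 0L, d, levels)),
                numeric(1))
  c1 <- c(h = C_h[1], v = C_v[1])
  if (normalize) {
    C_h <- C_h / c1[["h"]]
    C_v <- C_v / c1[["v"]]
  }
  out <- tibble(d = ds, C_h = C_h, C_v = C_v, C_mean = (C_h + C_v) / 2)
  attr(out, "levels") <- as.integer(levels)
  attr(out, "normalized") <- isTRUE(normalize)
  attr(out, "pixel_size") <- if (is_calibrated_image(img)) pixel_size(img) else NA_real_
  attr(out, "c1") <- c1
  class(out) <- c("texture_curve", class(out))
  out
}

#' Correlation length by exponential-decay fitting
#'
#' Fits `C(d) = A * exp(-d / lambda)` to the direction-averaged normalized
#' correlation curve by nonlinear least squares on the linear scale (the
#' curve can be near zero or slightly negative at large `d`, which rules out
#' a log-scale fit). The amplitude is fitted rather than pinned: a curve
#' normalized to its first distance equals `exp(-(d - 1) / lambda)`, i.e.
#' `A = exp(1 / lambda)` rather than exactly 1, and forcing `A = 1` biases
#' `lambda` upward by roughly `1 / lambda` in relative terms -- material for
#' short correlation lengths. On an exactly normalized exponential the fitted
#' amplitude is recovered accordingly, and on an unnormalized exponential
#' `A = 1`. A fit whose `lambda` runs into the upper bound `10 * max(d)` is
#' flagged non-decaying and reports no length.
#'
#' @param curve A [correlation_curve()] result (normalized).
#' @param fit_range Length-2 numeric range of distances to fit (default: the
#'   full curve). At least 5 points must fall inside.
#' @param direction `"mean"` (default, the direction-averaged curve), `"h"`,
#'   or `"v"`.
#'
#' @return A list of class `correlation_fit` with `lambda_px`, `lambda_um`
#'   (if the curve is calibrated), `amplitude`, `residual_norm`, `converged`,
#'   `fit_range`, and `n_points`.
#' @export
fit_correlation_length <- function(curve, fit_range = NULL,
                                   direction = c("mean", "h", "v")) {
  direction <- arg_match(direction)
  if (!isTRUE(attr(curve, "normalized"))) {
    abort("`curve` must be normalized (C = 1 at its first distance).")
  }
  col <- switch(direction, mean = "C_mean", h = "C_h", v = "C_v")
  d <- curve$d
  C <- curve[[col]]
  if (is.null(fit_range)) fit_range <- range(d)
  keep <- d >= fit_range[1] & d <= fit_range[2] & is.finite(C)
  if (sum(keep) < 5L) abort("need at least 5 points inside `fit_range`.")
  d <- d[keep]
  C <- C[keep]

  lambda_max <- 10 * max(d)
  # start value: first distance where the curve crosses 1/e, else mid-range
  below <- which(C < exp(-1))
  start <- if (length(below) > 0) max(d[below[1]], 1) else max(d) / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(
      C ~ A * exp(-d / lambda),
      start = list(A = 1, lambda = start),
      lower = c(0.01, 0.1), upper = c(10, lambda_max),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    res <- list(lambda_px = NA_real_, lambda_um = NA_real_,
                amplitude = NA_real_,
                residual_norm = NA_real_, converged = FALSE,
                reason = "fit failed")
  } else {
    lambda <- coef(fit)[["lambda"]]
    if (lambda >= lambda_max * (1 - 1e-6)) {
      res <- list(lambda_px = NA_real_, lambda_um = NA_real_,
                  amplitude = coef(fit)[["A"]],
                  residual_norm = sqrt(sum(resid(fit)^2)), converged = FALSE,
                  reason = "non-decaying curve: lambda ran into its upper bound")
    } else {
      ps <- attr(curve, "pixel_size")
      res <- list(
        lambda_px = lambda,
        lambda_um = if (is.na(ps)) NA_real_ else lambda * ps,
        amplitude = coef(fit)[["A"]],
        residual_norm = sqrt(sum(resid(fit)^2)),
        converged = TRUE,
        reason = NULL
      )
    }
  }
  res$fit_range <- fit_range
  res$n_points <- length(d)
  res$direction <- direction
  structure(res, class = "correlation_fit")
}

#' @export
print.correlation_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf("<correlation_fit> lambda = %.4g px%s (residual %.3g, %d points)\n",
                x$lambda_px,
                if (is.na(x$lambda_um)) "" else sprintf(" = %.4g um", x$lambda_um),
                x$residual_norm, x$n_points))
  } else {
    cat(sprintf("<correlation_fit> not converged: %s\n", x$reason))
  }
  invisible(x)
}

#' @export
tidy.correlation_fit <- function(x, ...) {
  tibble(term = "lambda", estimate = x$lambda_px, unit = "px",
         converged = x$converged)
}

#' @export
glance.correlation_fit <- function(x, ...) {
  tibble(lambda_px = x$lambda_px, lambda_um = x$lambda_um,
         amplitude = x$amplitude,
         residual_norm = x$residual_norm, converged = x$converged,
         n_points = x$n_points, direction = x$direction)
}

#' Plot a texture correlation curve
#'
#' @param object A `texture_curve` from [correlation_curve()].
#' @param fit Optional [fit_correlation_length()] result to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.texture_curve <- function(object, fit = NULL, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("C_h", "C_v", "C_mean"),
                              names_to = "direction", values_to = "C")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$d, .data$C,
                                          colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset distance (px)",
                  y = if (isTRUE(attr(object, "normalized")))
                    "normalized GLCM correlation" else "GLCM correlation")
  if (!is.null(fit) && isTRUE(fit$converged)) {
    dd <- tibble(d = object$d, C = exp(-object$d / fit$lambda_px))
    p <- p + ggplot2::geom_line(data = dd,
                                ggplot2::aes(.data$d, .data$C),
                                inherit.aes = FALSE, linetype = 2)
  }
  p
}
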