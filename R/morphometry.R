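#' Collagen fraction of a thresholded region of interest
#'
#' Quantifies the collagen fraction of an SHG image as the percentage of
#' bright ("collagenous") pixels among all pixels of the region of interest:
#' `100 * Nc / (Nb + Nc)`, where `Nc` counts pixels at or above the threshold
#' and `Nb` the remaining ROI pixels. The ROI can exclude pixels (e.g. the
#' micro-scaffold signal) via `exclude`; scaffold exclusion is accepted as an
#' input mask rather than inferred from the image.
#'
#' @param img A [calibrated_image()].
#' @param roi Optional logical matrix selecting the region of interest
#'   (default: whole image).
#' @param exclude Optional logical matrix of pixels to drop from the ROI
#'   (e.g. scaffold).
#' @param threshold Either the string `"otsu"` (default) for Otsu's
#'   histogram threshold, or a fixed numeric intensity. Pixels with intensity
#'   `>= threshold` count as bright.
#'
#' @return A one-row tibble with `collagen_fraction_pct`, the pixel counts
#'   `n_bright` (Nc) and `n_dark` (Nb), `n_roi`, and `threshold_used`.
#' @export
#'
#' @examples
#' img <- sim_fiber_image(128, 8, fiber_width = 2, seed = 1)
#' collagen_fraction(img, threshold = 50)
collagen_fraction <- function(img, roi = NULL, exclude = NULL,
                              threshold = "otsu") {
  m <- as_image_matrix(img)
  sel <- roi_selection(m, roi, exclude)
  vals <- m[sel]
  if (length(vals) == 0L) abort("the region of interest is empty.")
  thr <- resolve_threshold(vals, threshold)
  nc <- sum(vals >= thr)
  nb <- length(vals) - nc
  tibble(
    collagen_fraction_pct = 100 * nc / (nb + nc),
    n_bright = nc,
    n_dark = nb,
    n_roi = length(vals),
    threshold_used = thr
  )
}

#' Count nuclei as thresholded connected components
#'
#' Counts nuclei in a fluorescence (e.g. DAPI) channel as the number of
#' 8-connected components of the thresholded mask with pixel area at least
#' `min_area`. Touching nuclei that merge into one component are counted
#' once: no watershed separation is attempted.
#'
#' @inheritParams collagen_fraction
#' @param min_area Minimum component area in px^2 (>= 1); default 20
#'   suppresses isolated noise specks.
#'
#' @return A one-row tibble with `n_nuclei`, `threshold_used`, and
#'   `min_area`.
#' @export
#'
#' @examples
#' nuc <- sim_nuclei_image(12, c(4, 6), image_size = 128, seed = 5)
#' count_nuclei(nuc, threshold = 50)
count_nuclei <- function(img, threshold = "otsu", min_area = 20) {
  if (min_area < 1) abort("`min_area` must be >= 1 px^2.")
  m <- as_image_matrix(img)
  if (max(m) == min(m)) {
    # blank (constant) image: no objects, regardless of threshold method
    return(tibble(n_nuclei = 0L,
                  threshold_used = NA_real_, min_area = min_area))
  }
  thr <- resolve_threshold(as.vector(m), threshold)
  mask <- m >= thr
  areas <- component_areas(mask)
  tibble(
    n_nuclei = sum(areas >= min_area),
    threshold_used = thr,
    min_area = min_area
  )
}

#' Protein signal area per cell
#'
#' Thresholds a fluorescent protein channel, converts the bright area to
#' square micrometres using the pixel calibration, and divides by the number
#' of cells (nuclei) counted in a paired nuclei channel.
#'
#' @param protein_img A [calibrated_image()] of the protein channel.
#' @param nuclei_count Number of cells (>= 1), e.g. from [count_nuclei()].
#' @param threshold As in [collagen_fraction()].
#'
#' @return A one-row tibble with `area_per_cell_um2`, `protein_area_um2`,
#'   `n_bright_px`, `nuclei_count`, and `threshold_used`.
#' @export
protein_area_per_cell <- function(protein_img, nuclei_count,
                                  threshold = "otsu") {
  if (length(nuclei_count) != 1L || is.na(nuclei_count) ||
      nuclei_count < 1) {
    abort("`nuclei_count` must be a single count >= 1; an area per cell is undefined for zero cells.")
  }
  m <- as_image_matrix(protein_img)
  thr <- resolve_threshold(as.vector(m), threshold)
  n_bright <- sum(m >= thr)
  area_um2 <- n_bright * pixel_size(protein_img)^2
  tibble(
    area_per_cell_um2 = area_um2 / nuclei_count,
    protein_area_um2 = area_um2,
    n_bright_px = n_bright,
    nuclei_count = as.integer(nuclei_count),
    threshold_used = thr
  )
}

#' Micro-tissue diameter from an optical image
#'
#' Measures the diameter of the largest thresholded object, in micrometres.
#' The default definition is the equivalent circular diameter
#' `2 * sqrt(A / pi)` of the largest 8-connected component; `method =
#' "feret"` instead reports the maximum Feret diameter (largest pairwise
#' distance between pixels of the component).
#'
#' @inheritParams collagen_fraction
#' @param method `"equivalent"` (default) or `"feret"`.
#'
#' @return A one-row tibble with `diameter_um`, `area_um2`, `method`, and
#'   `threshold_used`.
#' @export
microtissue_diameter <- function(img, threshold = "otsu",
                                 method = c("equivalent", "feret")) {
  method <- arg_match(method)
  m <- as_image_matrix(img)
  thr <- resolve_threshold(as.vector(m), threshold)
  mask <- m >= thr
  labels <- label_components(mask)
  if (max(labels) == 0L) {
    abort("no object found above the threshold.")
  }
  areas <- tabulate(labels[labels > 0L])
  biggest <- which.max(areas)
  ps <- pixel_size(img)
  area_um2 <- areas[biggest] * ps^2
  diameter <- if (method == "equivalent") {
    2 * sqrt(area_um2 / pi)
  } else {
    pix <- which(labels == biggest, arr.ind = TRUE)
    hull <- pix[grDevices::chull(pix), , drop = FALSE]
    d2 <- as.matrix(stats::dist(hull))
    (max(d2) + 1) * ps # +1 px: pixels are unit squares, not points
  }
  tibble(
    diameter_um = diameter,
    area_um2 = area_um2,
    method = method,
    threshold_used = thr
  )
}

#' Aggregate replicate measurements into mean and SD
#'
#' Summarises per-image measurements (several fields of view per sample) as
#' mean plus sample standard deviation (n - 1 denominator). With a single
#' value the SD is reported as `NA`, not 0.
#'
#' @param data A data frame of per-image values.
#' @param value Column of measurements (tidy-eval).
#' @param ... Optional grouping columns (tidy-eval), e.g. sample id.
#'
#' @return A tibble with one row per group: `mean`, `sd`, `n`.
#' @export
#'
#' @examples
#' df <- tibble::tibble(sample = rep(c("NA", "CF"), each = 3),
#'                      cf = c(10, 12, 11, 20, 22, 21))
#' summarise_replicates(df, cf, sample)
summarise_replicates <- function(data, value, ...) {
  data |>
    group_by(...) |>
    summarise(
      mean = mean({{ value }}),
      sd = if (n() > 1L) sd({{ value }}) else NA_real_,
      n = n(),
      .groups = "drop"
    )
}

# ---- internal helpers -------------------------------------------------------

roi_selection <- function(m, roi, exclude) {
  sel <- if (is.null(roi)) {
    matrix(TRUE, nrow(m), ncol(m))
  } else {
    if (!identical(dim(roi), dim(m))) {
      abort("`roi` must have the same dimensions as the image.")
    }
    roi & TRUE
  }
  if (!is.null(exclude)) {
    if (!identical(dim(exclude), dim(m))) {
      abort("`exclude` must have the same dimensions as the image.")
    }
    sel <- sel & !exclude
  }
  sel
}

# Otsu's threshold maximizing between-class variance on a 256-bin histogram
# of the supplied values; returns an intensity on the original scale placed
# at the lower edge of the first "bright" bin so that `>= thr` reproduces the
# binary split.
otsu_threshold <- function(vals, n_bins = 256L) {
  lo <- min(vals)
  hi <- max(vals)
  if (hi <= lo) {
    abort("Otsu threshold is undefined on a constant image; supply a fixed threshold.",
          class = "stromaquant_degenerate_threshold")
  }
  bins <- pmin(floor((vals - lo) / (hi - lo) * n_bins), n_bins - 1L)
  h <- tabulate(bins + 1L, n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(n_bins) - 1L))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b) # classes: bins <= k-1 vs bins >= k
  lo + k * (hi - lo) / n_bins
}

resolve_threshold <- function(vals, threshold) {
  if (is.character(threshold)) {
    if (!identical(threshold, "otsu")) {
      abort("`threshold` must be \"otsu\" or a numeric intensity.")
    }
    otsu_threshold(vals)
  } else if (is.numeric(threshold) && length(threshold) == 1L &&
             is.finite(threshold)) {
    as.numeric(threshold)
  } else {
    abort("`threshold` must be \"otsu\" or a single finite number.")
  }
}

# Label 8-connected components of a logical mask. Foreground pixels become
# graph vertices, edges join 8-neighbours, and components come from igraph.
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  n_fg <- sum(mask)
  ids <- matrix(0L, nr, nc)
  labels <- matrix(0L, nr, nc)
  if (n_fg == 0L) return(labels)
  ids[mask] <- seq_len(n_fg)

  edge_list <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    a <- ids[r1, c1, drop = FALSE]
    b <- ids[r1 + dr, c1 + dc, drop = FALSE]
    keep <- a > 0L & b > 0L
    if (any(keep)) edge_list[[length(edge_list) + 1L]] <- cbind(a[keep], b[keep])
  }
  if (length(edge_list) == 0L) {
    membership <- seq_len(n_fg)
  } else {
    el <- do.call(rbind, edge_list)
    g <- igraph::make_graph(edges = as.vector(t(el)), n = n_fg,
                            directed = FALSE)
    membership <- igraph::components(g)$membership
  }
  labels[mask] <- as.integer(membership)
  labels
}

component_areas <- function(mask) {
  labels <- label_components(mask)
  if (max(labels) == 0L) return(integer(0))
  tabulate(labels[labels > 0L])
}
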