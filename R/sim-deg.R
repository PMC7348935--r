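#' Simulate a pair of differential-expression tables with known overlap
#'
#' Builds two per-gene DEG tables (gene id, log2 fold change, FDR) for
#' contrasts A and B whose concordance structure is specified exactly:
#' how many genes are significant only in A (up / down), only in B (up /
#' down), significant in both with the same sign (common up / down),
#' significant in both with opposite signs (discordant), and significant in
#' neither (unchanged). Every gene appears in both tables. FDR values are
#' drawn inside `fdr_significant_range` for categories where that table calls
#' the gene significant and inside `fdr_null_range` otherwise; logFC
#' magnitudes are drawn from `logfc_magnitude_range` with the sign dictated
#' by the category. Partitioning the two tables with [compare_degs()] at the
#' significance cutoff separating the two FDR ranges reproduces
#' `category_sizes` exactly.
#'
#' @param category_sizes Named integer vector (any subset of names) with
#'   entries among `a_up`, `a_down`, `b_up`, `b_down`, `common_up`,
#'   `common_down`, `discordant`, `unchanged`; missing names default to 0.
#' @param fdr_significant_range FDR interval for significant calls; must lie
#'   entirely below `fdr_cut`.
#' @param fdr_null_range FDR interval for non-significant calls; must lie
#'   entirely above `fdr_cut`.
#' @param logfc_magnitude_range Range of |logFC| for regulated genes.
#' @param fdr_cut Significance threshold separating the two ranges
#'   (default 0.05).
#' @param seed Integer seed.
#'
#' @return A list with tibbles `table_a`, `table_b` (columns `gene`, `logFC`,
#'   `FDR`), the `truth` tibble mapping each gene to its category, and
#'   `category_sizes` as realized.
#' @export
#'
#' @examples
#' fx <- sim_deg_tables(c(a_up = 5, b_down = 3, common_up = 2, unchanged = 10),
#'                      seed = 1)
#' dplyr::count(fx$truth, category)
sim_deg_tables <- function(category_sizes,
                           fdr_significant_range = c(1e-6, 0.01),
                           fdr_null_range = c(0.2, 1),
                           logfc_magnitude_range = c(1, 6),
                           fdr_cut = 0.05,
                           seed = 1L) {
  all_cats <- c("a_up", "a_down", "b_up", "b_down",
                "common_up", "common_down", "discordant", "unchanged")
  sizes <- stats::setNames(rep(0L, length(all_cats)), all_cats)
  if (is.null(names(category_sizes)) ||
      !all(names(category_sizes) %in% all_cats)) {
    abort(paste0("`category_sizes` must be named with entries among: ",
                 paste(all_cats, collapse = ", ")))
  }
  if (any(category_sizes < 0)) abort("category sizes must be >= 0.")
  sizes[names(category_sizes)] <- as.integer(category_sizes)

  if (max(fdr_significant_range) >= fdr_cut) {
    abort(sprintf(
      "`fdr_significant_range` must lie strictly below the significance cutoff %.3g; the ground truth would otherwise be ambiguous.",
      fdr_cut
    ))
  }
  if (min(fdr_null_range) < fdr_cut) {
    abort(sprintf(
      "`fdr_null_range` must lie at or above the significance cutoff %.3g.",
      fdr_cut
    ))
  }

  withr_seed(seed, {
    n_total <- sum(sizes)
    genes <- sprintf("GENE%06d", seq_len(n_total))
    category <- rep(all_cats, times = sizes)

    r_sig <- function(n) runif(n, fdr_significant_range[1],
                               fdr_significant_range[2])
    r_null <- function(n) runif(n, fdr_null_range[1], fdr_null_range[2])
    r_mag <- function(n) runif(n, logfc_magnitude_range[1],
                               logfc_magnitude_range[2])
    r_small <- function(n) runif(n, -0.5, 0.5) # null logFC, sign-free

    n <- n_total
    sig_a <- category %in% c("a_up", "a_down", "common_up", "common_down",
                             "discordant")
    sig_b <- category %in% c("b_up", "b_down", "common_up", "common_down",
                             "discordant")
    up_a <- category %in% c("a_up", "common_up", "discordant")
    up_b <- category %in% c("b_up", "common_up")

    fdr_a <- ifelse(sig_a, r_sig(n), r_null(n))
    fdr_b <- ifelse(sig_b, r_sig(n), r_null(n))
    lfc_a <- ifelse(sig_a, ifelse(up_a, 1, -1) * r_mag(n), r_small(n))
    lfc_b <- ifelse(sig_b, ifelse(up_b, 1, -1) * r_mag(n), r_small(n))

    list(
      table_a = tibble(gene = genes, logFC = lfc_a, FDR = fdr_a),
      table_b = tibble(gene = genes, logFC = lfc_b, FDR = fdr_b),
      truth = tibble(gene = genes, category = category),
      category_sizes = sizes
    )
  })
}

#' Simulate a raw RNA-seq count matrix with multi-mapping percentages
#'
#' Draws negative-binomial counts for `n_genes` genes across `n_samples`
#' samples, with per-gene means sampled log-uniformly from `mean_range` and a
#' common dispersion, and attaches a per-gene percentage of multi-mapping
#' reads drawn uniformly from `perc_mm_range`. This is the input class for
#' expression filtering: low-expression and high-multi-mapping genes are
#' known by construction.
#'
#' @param n_genes,n_samples Matrix dimensions (`n_samples >= 1`).
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`);
#'   0 gives Poisson counts.
#' @param mean_range Range of per-gene mean counts (log-uniform draw); a gene
#'   mean of 0 yields structural zeros.
#' @param perc_mm_range Range of the multi-mapping percentage, in `[0, 100]`.
#' @param group Optional sample group labels (length `n_samples`).
#' @param seed Integer seed.
#'
#' @return A list of class `count_matrix` with `counts` (genes x samples
#'   integer matrix), `perc_mm` (named per-gene percentages), and `group`.
#' @export
sim_count_matrix <- function(n_genes, n_samples,
                             dispersion = 0.1,
                             mean_range = c(0, 500),
                             perc_mm_range = c(0, 40),
                             group = NULL,
                             seed = 1L) {
  if (n_samples < 1) abort("`n_samples` must be >= 1.")
  if (any(perc_mm_range < 0) || any(perc_mm_range > 100)) {
    abort("`perc_mm_range` must lie in [0, 100].")
  }
  if (is.null(group)) {
    group <- rep(c("A", "B"), length.out = n_samples)
  }
  if (length(group) != n_samples) {
    abort("`group` must have one label per sample.")
  }

  withr_seed(seed, {
    mu <- if (max(mean_range) == 0) {
      rep(0, n_genes)
    } else {
      lo <- max(min(mean_range), 1e-2)
      exp(runif(n_genes, log(lo), log(max(mean_range))))
    }
    draw <- function(m) {
      if (m == 0) return(rep(0, n_samples))
      if (dispersion <= 0) return(as.numeric(stats::rpois(n_samples, m)))
      as.numeric(rnbinom(n_samples, size = 1 / dispersion, mu = m))
    }
    counts <- t(vapply(mu, draw, numeric(n_samples)))
    if (n_samples == 1L) counts <- matrix(counts, ncol = 1L)
    storage.mode(counts) <- "integer"
    rownames(counts) <- sprintf("GENE%06d", seq_len(n_genes))
    colnames(counts) <- sprintf("S%02d", seq_len(n_samples))
    perc_mm <- runif(n_genes, perc_mm_range[1], perc_mm_range[2])
    names(perc_mm) <- rownames(counts)
    structure(
      list(counts = counts, perc_mm = perc_mm, group = group, seed = seed),
      class = "count_matrix"
    )
  })
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples, groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$group), collapse = ", ")))
  invisible(x)
}
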