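#' Counts per million
#'
#' Library-size-normalized expression: each count times 1e6 divided by its
#' sample's library size (column sum of raw counts). Column sums of the
#' result are 1e6 for every sample with nonzero counts.
#'
#' @param counts A [sim_count_matrix()] result or a genes x samples numeric
#'   matrix.
#' @return A genes x samples matrix of CPM values.
#' @export
#'
#' @examples
#' cm <- sim_count_matrix(50, 4, seed = 1)
#' colSums(calc_cpm(cm)) # all 1e6
calc_cpm <- function(counts) {
  m <- counts_matrix_of(counts)
  lib <- colSums(m)
  zero <- lib == 0
  if (any(zero)) {
    abort(sprintf("zero library size in sample(s): %s.",
                  paste(colnames(m)[zero], collapse = ", ")))
  }
  sweep(m, 2, lib, "/") * 1e6
}

#' Expression filter on CPM and multi-mapping percentage
#'
#' Removes genes that are simultaneously weakly expressed and dominated by
#' multi-mapping reads: a gene is removed iff the number of samples in which
#' its CPM reaches `cpm_threshold` is below `n_min` AND its multi-mapping
#' percentage exceeds `perc_mm_threshold` (`logic = "and"`, the default).
#' `logic = "or"` removes a gene when either condition alone holds. Filtering
#' is idempotent: applying the filter to the kept matrix removes nothing
#' further.
#'
#' `n_min` has no universal default and must be supplied; the smallest
#' experimental group size is the usual choice.
#'
#' @param counts A [sim_count_matrix()] result (or a list with elements
#'   `counts` and `perc_mm`).
#' @param n_min Minimum number of samples that must reach `cpm_threshold`
#'   for the expression clause to pass.
#' @param cpm_threshold CPM cutoff (default 1).
#' @param perc_mm_threshold Multi-mapping percentage cutoff (default 20).
#' @param logic `"and"` (default: both clauses required for removal) or
#'   `"or"`.
#'
#' @return A list of class `gene_filter` with `kept` / `removed` gene id
#'   vectors, the filtered `counts` object, and a per-gene `detail` tibble
#'   (`gene`, `n_samples_expressed`, `perc_mm`, `low_expression`, `high_mm`,
#'   `removed`).
#' @export
filter_genes <- function(counts, n_min, cpm_threshold = 1,
                         perc_mm_threshold = 20,
                         logic = c("and", "or")) {
  logic <- arg_match(logic)
  m <- counts_matrix_of(counts)
  perc_mm <- perc_mm_of(counts, nrow(m))
  if (missing(n_min) || is.null(n_min)) {
    abort("`n_min` must be supplied (e.g. the smallest group size); it has no universal default.")
  }
  if (n_min > ncol(m)) abort("`n_min` cannot exceed the number of samples.")

  cpm <- calc_cpm(m)
  n_expressed <- rowSums(cpm >= cpm_threshold)
  low_expr <- n_expressed < n_min
  high_mm <- perc_mm > perc_mm_threshold
  removed <- if (logic == "and") low_expr & high_mm else low_expr | high_mm

  genes <- rownames(m) %||% as.character(seq_len(nrow(m)))
  filtered <- counts
  if (is.list(counts)) {
    filtered$counts <- m[!removed, , drop = FALSE]
    filtered$perc_mm <- perc_mm[!removed]
  } else {
    filtered <- m[!removed, , drop = FALSE]
  }
  structure(
    list(
      kept = genes[!removed],
      removed = genes[removed],
      counts = filtered,
      detail = tibble(
        gene = genes,
        n_samples_expressed = n_expressed,
        perc_mm = unname(perc_mm),
        low_expression = unname(low_expr),
        high_mm = unname(high_mm),
        removed = unname(removed)
      ),
      n_min = n_min,
      cpm_threshold = cpm_threshold,
      perc_mm_threshold = perc_mm_threshold,
      logic = logic
    ),
    class = "gene_filter"
  )
}

#' @export
print.gene_filter <- function(x, ...) {
  cat(sprintf(
    "<gene_filter> kept %d / removed %d genes (cpm >= %g in >= %d samples; perc MM > %g%%; %s logic)\n",
    length(x$kept), length(x$removed), x$cpm_threshold, x$n_min,
    x$perc_mm_threshold, toupper(x$logic)
  ))
  invisible(x)
}

#' Threshold a differential-expression table into up/down gene sets
#'
#' Calls a gene up-regulated when `FDR < fdr_cut` and `logFC > 0` (and
#' `logFC > logfc_cut` when a fold-change cutoff is given), down-regulated
#' symmetrically. Genes significant by FDR but with `logFC` exactly 0 are
#' assigned to neither set and returned as `flagged`.
#'
#' @param table A data frame with columns `gene`, `logFC`, `FDR`.
#' @param fdr_cut FDR significance threshold (default 0.05).
#' @param logfc_cut Optional additional |logFC| cutoff (e.g. 2); `NULL`
#'   (default) applies sign only.
#'
#' @return A list of class `deg_sets` with character vectors `up`, `down`,
#'   `flagged`, and the thresholds used.
#' @export
#'
#' @examples
#' tbl <- tibble::tibble(gene = c("HAS2", "TGFB3"),
#'                       logFC = c(2.062, 1.755), FDR = c(0.01, 0.01))
#' threshold_degs(tbl, logfc_cut = 2)$up # HAS2 only
threshold_degs <- function(table, fdr_cut = 0.05, logfc_cut = NULL) {
  check_deg_table(table)
  sig <- table$FDR < fdr_cut
  up_cut <- if (is.null(logfc_cut)) 0 else logfc_cut
  up <- sig & table$logFC > up_cut
  down <- sig & table$logFC < -up_cut
  flagged <- sig & table$logFC == 0
  structure(
    list(
      up = table$gene[up],
      down = table$gene[down],
      flagged = table$gene[flagged],
      fdr_cut = fdr_cut,
      logfc_cut = logfc_cut
    ),
    class = "deg_sets"
  )
}

#' Concordance partition of two differential-expression contrasts
#'
#' Compares the significant gene sets of two contrasts (e.g. a 2D and a 3D
#' culture condition, each against its own control) and partitions the union
#' into seven disjoint categories: up- or down-regulated only in A, only in
#' B, commonly regulated with concordant sign (up in both / down in both),
#' and discordant (significant in both with opposite signs). Inputs may be
#' raw DEG tables (thresholded internally with `...`) or [threshold_degs()]
#' results. Gene ids are matched exactly after trimming whitespace and
#' upper-casing.
#'
#' @param a,b DEG tables (data frames with `gene`, `logFC`, `FDR`) or
#'   `deg_sets` objects.
#' @param ... Passed to [threshold_degs()] when `a` / `b` are tables.
#'
#' @return A list of class `venn_partition` with the seven gene-id vectors
#'   (`a_up`, `a_down`, `b_up`, `b_down`, `common_up`, `common_down`,
#'   `discordant`), a `membership` tibble (`gene`, `category`), and a
#'   `counts` tibble including the derived totals `a_specific_total`,
#'   `b_specific_total`, `common_total`.
#' @export
#'
#' @examples
#' fx <- sim_deg_tables(c(a_up = 4, b_down = 2, common_up = 3, discordant = 1,
#'                        unchanged = 10), seed = 1)
#' compare_degs(fx$table_a, fx$table_b)$counts
compare_degs <- function(a, b, ...) {
  sets_a <- as_deg_sets(a, ...)
  sets_b <- as_deg_sets(b, ...)

  au <- norm_gene_ids(sets_a$up)
  ad <- norm_gene_ids(sets_a$down)
  bu <- norm_gene_ids(sets_b$up)
  bd <- norm_gene_ids(sets_b$down)
  check_disjoint_within(au, ad, "a")
  check_disjoint_within(bu, bd, "b")

  in_b <- union(bu, bd)
  in_a <- union(au, ad)
  parts <- list(
    a_up = setdiff(au, in_b),
    a_down = setdiff(ad, in_b),
    b_up = setdiff(bu, in_a),
    b_down = setdiff(bd, in_a),
    common_up = intersect(au, bu),
    common_down = intersect(ad, bd),
    discordant = union(intersect(au, bd), intersect(ad, bu))
  )
  membership <- purrr::imap(parts, ~ tibble(gene = .x, category = .y)) |>
    bind_rows() |>
    arrange(.data$gene)

  counts <- tibble(
    category = names(parts),
    n = unname(purrr::map_int(parts, length))
  )
  totals <- tibble(
    a_specific_total = length(parts$a_up) + length(parts$a_down),
    b_specific_total = length(parts$b_up) + length(parts$b_down),
    common_total = length(parts$common_up) + length(parts$common_down) +
      length(parts$discordant)
  )
  structure(
    c(parts, list(membership = membership, counts = counts, totals = totals)),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition>\n")
  cat(sprintf(
    "  A-specific: %d up + %d down = %d\n  B-specific: %d up + %d down = %d\n  common: %d up + %d down + %d discordant = %d\n",
    length(x$a_up), length(x$a_down), x$totals$a_specific_total,
    length(x$b_up), length(x$b_down), x$totals$b_specific_total,
    length(x$common_up), length(x$common_down), length(x$discordant),
    x$totals$common_total
  ))
  invisible(x)
}

#' @export
tidy.venn_partition <- function(x, ...) x$membership

#' @export
glance.venn_partition <- function(x, ...) {
  dplyr::bind_cols(tidyr::pivot_wider(x$counts, names_from = "category",
                                      values_from = "n"), x$totals)
}

#' Plot the category counts of a concordance partition
#'
#' @param object A `venn_partition` from [compare_degs()].
#' @param ... Unused.
#' @return A ggplot bar chart of category sizes.
#' @export
autoplot.venn_partition <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::coord_flip()
}

#' Export the gene lists of a concordance partition
#'
#' Writes one sorted gene-id text file per category plus a `summary.json`
#' with all category counts and derived totals.
#'
#' @param partition A `venn_partition` from [compare_degs()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of files written.
#' @export
export_gene_lists <- function(partition, dir) {
  stopifnot(inherits(partition, "venn_partition"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cats <- c("a_up", "a_down", "b_up", "b_down",
            "common_up", "common_down", "discordant")
  files <- vapply(cats, function(cat) {
    path <- file.path(dir, paste0(cat, ".txt"))
    writeLines(sort(partition[[cat]]), path)
    path
  }, character(1))
  summary <- c(
    as.list(stats::setNames(purrr::map_int(partition[cats], length), cats)),
    as.list(partition$totals)
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(files, summary = file.path(dir, "summary.json")))
}

#' Read back exported gene lists
#'
#' @param dir Directory written by [export_gene_lists()].
#' @return A named list of gene-id vectors, one per category.
#' @export
read_gene_lists <- function(dir) {
  cats <- c("a_up", "a_down", "b_up", "b_down",
            "common_up", "common_down", "discordant")
  out <- lapply(cats, function(cat) {
    path <- file.path(dir, paste0(cat, ".txt"))
    if (!file.exists(path)) character(0) else {
      x <- readLines(path)
      x[nzchar(x)]
    }
  })
  stats::setNames(out, cats)
}

# ---- internal helpers -------------------------------------------------------

counts_matrix_of <- function(counts) {
  m <- if (is.list(counts) && !is.null(counts$counts)) counts$counts else counts
  if (!is.matrix(m) || !is.numeric(m)) {
    abort("`counts` must be a numeric genes x samples matrix or a count_matrix object.")
  }
  if (any(m < 0)) abort("counts must be non-negative.")
  m
}

perc_mm_of <- function(counts, n_genes) {
  pm <- if (is.list(counts) && !is.null(counts$perc_mm)) counts$perc_mm else NULL
  if (is.null(pm)) {
    abort("a per-gene multi-mapping percentage (`perc_mm`) is required for filtering.")
  }
  if (length(pm) != n_genes) {
    abort("`perc_mm` must have one value per gene.")
  }
  pm
}

check_deg_table <- function(table) {
  need <- c("gene", "logFC", "FDR")
  if (!all(need %in% names(table))) {
    abort("a DEG table needs columns `gene`, `logFC`, `FDR`.")
  }
  if (anyDuplicated(norm_gene_ids(table$gene))) {
    abort("duplicate gene ids within a DEG table.")
  }
  if (any(table$FDR < 0 | table$FDR > 1, na.rm = TRUE)) {
    abort("FDR values must lie in [0, 1].")
  }
  invisible(table)
}

as_deg_sets <- function(x, ...) {
  if (inherits(x, "deg_sets")) return(x)
  threshold_degs(x, ...)
}

norm_gene_ids <- function(x) toupper(trimws(as.character(x)))

check_disjoint_within <- function(up, down, label) {
  if (anyDuplicated(up) || anyDuplicated(down)) {
    abort(sprintf("duplicate gene ids within dataset %s.", toupper(label)))
  }
  both <- intersect(up, down)
  if (length(both) > 0) {
    abort(sprintf("gene(s) %s appear as both up and down in dataset %s.",
                  paste(head(both, 3), collapse = ", "), toupper(label)))
  }
}
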