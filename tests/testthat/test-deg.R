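test_that("CPM normalizes to library size and flags empty samples", {
  m <- matrix(c(50, 999950, 0, 1e6), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cpm <- calc_cpm(m)
  expect_equal(cpm["g1", "s1"], 50)
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))

  # a gene holding all reads of a sample has cpm 1e6
  solo <- matrix(c(1234, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(calc_cpm(solo)["g1", 1], 1e6)

  empty <- matrix(c(1, 0, 0, 0), 2, 2,
                  dimnames = list(NULL, c("ok", "empty")))
  expect_error(calc_cpm(empty), "empty")

  # agrees with the reference implementation
  skip_if_not_installed("edgeR")
  cm <- sim_count_matrix(200, 5, seed = 31)
  expect_equal(calc_cpm(cm$counts), edgeR::cpm(cm$counts),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the expression filter matches a hand-enumerated truth table", {
  # six genes covering all combinations of the two removal clauses;
  # 4 samples, n_min = 2, cpm threshold 1, perc MM threshold 20
  counts <- rbind(
    high_lowmm  = c(100, 100, 100, 100), # expressed everywhere, clean
    high_highmm = c(100, 100, 100, 100), # expressed everywhere, multi-mapped
    mid_lowmm   = c(100, 0, 0, 0),       # expressed in 1 sample (< n_min), clean
    mid_highmm  = c(100, 0, 0, 0),       # expressed in 1 sample, multi-mapped
    zero_lowmm  = c(0, 0, 0, 0),         # silent, clean
    zero_highmm = c(0, 0, 0, 0)          # silent, multi-mapped
  )
  colnames(counts) <- paste0("s", 1:4)
  perc_mm <- c(5, 50, 5, 50, 5, 50)
  names(perc_mm) <- rownames(counts)
  obj <- list(counts = counts, perc_mm = perc_mm)

  # AND logic: removal needs BOTH low expression and high multi-mapping
  res <- filter_genes(obj, n_min = 2)
  expect_setequal(res$removed, c("mid_highmm", "zero_highmm"))
  expect_setequal(res$kept,
                  c("high_lowmm", "high_highmm", "mid_lowmm", "zero_lowmm"))
  expect_setequal(c(res$kept, res$removed), rownames(counts))

  # OR logic removes on either clause
  res_or <- filter_genes(obj, n_min = 2, logic = "or")
  expect_setequal(res_or$kept, c("high_lowmm"))

  # idempotence: filtering the kept matrix removes nothing further
  res2 <- filter_genes(res$counts, n_min = 2)
  expect_length(res2$removed, 0)
  expect_setequal(res2$kept, res$kept)

  expect_error(filter_genes(obj), "n_min")
  expect_error(filter_genes(obj, n_min = 10), "cannot exceed")
})

test_that("a gene expressed everywhere survives any multi-mapping percentage", {
  cm <- sim_count_matrix(50, 4, mean_range = c(200, 500),
                         perc_mm_range = c(90, 100), seed = 7)
  res <- filter_genes(cm, n_min = 4)
  expect_length(res$removed, 0)
})

test_that("DEG thresholding applies FDR and fold-change cutoffs with sign rules", {
  # curated fold changes for genes induced in the 3D tissue contrast
  tbl <- tibble::tibble(
    gene = c("TGFB3", "HAS2", "TWIST1", "WNT2", "SFRP2", "RSPO2",
             "TBX4", "ITGA8", "CHI3L1", "HHIP"),
    logFC = c(1.755, 2.062, 2.425, 3.052, 3.695, 4.331,
              4.593, 4.874, 5.027, 5.09),
    FDR = rep(0.001, 10)
  )
  sets <- threshold_degs(tbl, fdr_cut = 0.05, logfc_cut = 2)
  expect_false("TGFB3" %in% sets$up) # 1.755 misses the logFC > 2 cut
  expect_true("HAS2" %in% sets$up)   # 2.062 passes
  expect_length(sets$down, 0)

  # without the fold-change cut, sign alone decides
  expect_setequal(threshold_degs(tbl)$up, tbl$gene)

  # empty and all-null tables give empty sets
  empty <- tibble::tibble(gene = character(), logFC = numeric(),
                          FDR = numeric())
  expect_length(threshold_degs(empty)$up, 0)
  null_tbl <- tibble::tibble(gene = c("a", "b"), logFC = c(3, -3),
                             FDR = c(1, 1))
  expect_length(threshold_degs(null_tbl)$up, 0)
  expect_length(threshold_degs(null_tbl)$down, 0)

  # significant genes with logFC exactly 0 are flagged, not assigned
  zero <- tibble::tibble(gene = "z", logFC = 0, FDR = 0.01)
  sets0 <- threshold_degs(zero)
  expect_length(sets0$up, 0)
  expect_length(sets0$down, 0)
  expect_identical(sets0$flagged, "z")

  expect_error(threshold_degs(tibble::tibble(gene = c("a", "a"),
                                             logFC = c(1, 2),
                                             FDR = c(0.1, 0.1))),
               "duplicate")
})

test_that("thresholding is monotone in its cutoffs", {
  fx <- sim_deg_tables(c(a_up = 30, a_down = 20, unchanged = 50),
                       fdr_significant_range = c(1e-5, 0.04),
                       seed = 17)
  strict <- threshold_degs(fx$table_a, fdr_cut = 0.01, logfc_cut = 3)
  loose <- threshold_degs(fx$table_a, fdr_cut = 0.05, logfc_cut = NULL)
  expect_true(all(strict$up %in% loose$up))
  expect_true(all(strict$down %in% loose$down))
})

test_that("concordance partition handles degenerate overlaps", {
  a <- tibble::tibble(gene = c("g1", "g2"), logFC = c(2, -2),
                      FDR = c(0.01, 0.01))
  b <- tibble::tibble(gene = c("g3", "g4"), logFC = c(2, -2),
                      FDR = c(0.01, 0.01))
  part <- compare_degs(a, b)
  expect_length(part$common_up, 0)
  expect_length(part$common_down, 0)
  expect_length(part$discordant, 0)
  expect_equal(part$totals$common_total, 0)

  # identical tables: everything concordant
  part_same <- compare_degs(a, a)
  expect_setequal(part_same$common_up, "G1")
  expect_setequal(part_same$common_down, "G2")
  expect_equal(part_same$totals$a_specific_total, 0)
  expect_length(part_same$discordant, 0)

  # sign disagreement lands in the discordant set
  flip <- tibble::tibble(gene = c("g1", "g2"), logFC = c(-2, 2),
                         FDR = c(0.01, 0.01))
  expect_setequal(compare_degs(a, flip)$discordant, c("G1", "G2"))
})

test_that("partitions are disjoint, cover the union, and invert the generator", {
  set.seed(99)
  for (i in 1:50) {
    sizes <- random_deg_sizes()
    fx <- sim_deg_tables(sizes, seed = i)
    part <- compare_degs(fx$table_a, fx$table_b)
    cats <- part[c("a_up", "a_down", "b_up", "b_down",
                   "common_up", "common_down", "discordant")]
    all_genes <- unlist(cats)
    expect_identical(anyDuplicated(all_genes), 0L) # pairwise disjoint
    # round-trip: counts equal the generating spec
    got <- purrr::map_int(cats, length)
    want <- sizes[c("a_up", "a_down", "b_up", "b_down",
                    "common_up", "common_down", "discordant")]
    expect_identical(unname(got), unname(as.integer(want)))
    # coverage: union of both thresholded DEG sets
    sa <- threshold_degs(fx$table_a)
    sb <- threshold_degs(fx$table_b)
    expect_setequal(all_genes, toupper(c(sa$up, sa$down, sb$up, sb$down)))
  }
})

test_that("exported gene lists round-trip with a consistent summary", {
  fx <- sim_deg_tables(c(a_up = 6, b_down = 4, common_up = 3, discordant = 2,
                         unchanged = 20), seed = 5)
  part <- compare_degs(fx$table_a, fx$table_b)
  dir <- withr::local_tempdir()
  export_gene_lists(part, dir)
  back <- read_gene_lists(dir)
  for (cat in names(back)) {
    expect_setequal(back[[cat]], part[[cat]])
  }
  summary <- jsonlite::read_json(file.path(dir, "summary.json"),
                                 simplifyVector = TRUE)
  expect_equal(summary$a_up + summary$a_down + summary$b_up + summary$b_down +
                 summary$common_up + summary$common_down + summary$discordant,
               length(unique(part$membership$gene)))
  # empty category: empty file
  expect_length(back$a_down, 0)
})
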