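sparse_counts <- function(m) {
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

test_that("filter_matrix drops cells then genes in a single pass each", {
  m <- matrix(c(
    5, 0, 0, 1, 2,
    3, 4, 0, 1, 0,
    0, 2, 0, 1, 3,
    1, 0, 0, 0, 4,
    0, 0, 1, 0, 0), nrow = 5, byrow = TRUE,
    dimnames = list(paste0("g", 1:5), paste0("c", 1:5)))
  # with (min genes/cell = 2, min cells/gene = 2): cell c3 detects 1 gene ->
  # dropped; then gene g5 (1 remaining cell) is dropped
  out <- filter_matrix(sparse_counts(m), 2, 2)
  expect_identical(rownames(out), paste0("g", 1:4))
  expect_identical(colnames(out), paste0("c", c(1, 2, 4, 5)))
  expect_error(filter_matrix(sparse_counts(m), 100, 1), "no cells")
})

test_that("the detected-genes threshold keeps cells at exactly the minimum", {
  n_genes <- 2000L
  counts <- Matrix::sparseMatrix(
    i = c(seq_len(1799L), seq_len(1800L)),
    j = c(rep(1L, 1799L), rep(2L, 1800L)),
    x = 1, dims = c(n_genes, 2L),
    dimnames = list(sprintf("g%04d", seq_len(n_genes)), c("low", "ok")))
  out <- filter_matrix(counts, min_genes_per_cell = 1800L,
                       min_cells_per_gene = 1L)
  expect_identical(colnames(out), "ok")
})

test_that("normalize_log10 matches its formula and is scale invariant", {
  m <- sparse_counts(matrix(c(0, 10, 10, 0), 2,
                            dimnames = list(c("g1", "g2"), c("c1", "c2"))))
  out <- normalize_log10(m, scale = 1e4)
  expect_equal(out["g1", "c1"], 0)
  # count equals the cell total -> log10(1 + 1e4)
  expect_equal(out["g2", "c1"], log10(10001))
  doubled <- normalize_log10(2 * m, scale = 1e4)
  expect_equal(as.matrix(doubled), as.matrix(out))
  zero <- sparse_counts(matrix(c(1, 0, 0, 0), 2,
                               dimnames = list(c("g1", "g2"),
                                               c("c1", "c2"))))
  expect_warning(nz <- normalize_log10(zero), "zero total")
  expect_identical(ncol(nz), 1L)
})

test_that("marker-based classification labels cells and handles ties", {
  norm <- sparse_counts(matrix(c(
    3, 3, 0, 1,
    0, 0, 3, 1,
    1, 1, 1, 1), nrow = 3, byrow = TRUE,
    dimnames = list(c("mA", "mB", "other"), paste0("c", 1:4))))
  labs <- classify_cells(norm, list(A = "mA", B = "mB"))
  expect_identical(labs[1:3], c(c1 = "A", c2 = "A", c3 = "B"))
  # identical expression across all marker genes -> unassigned
  flat <- sparse_counts(matrix(1, 2, 3, dimnames = list(c("mA", "mB"),
                                                        paste0("c", 1:3))))
  expect_true(all(classify_cells(flat, list(A = "mA", B = "mB")) ==
                    "unassigned"))
  expect_error(classify_cells(norm, list(A = "absent")), "no marker")
})

test_that("classification recovers simulated labels and ignores scaling", {
  # single-cell-scale gene panel (marker signal among hundreds of genes)
  cfg <- sim_config(seed = 6, n_transcripts = 500)
  tx <- simulate_transcriptome(cfg)
  tr <- plant_m6a_sites(tx$models, cfg)
  sc <- simulate_sc_counts(tx$models, tr, cfg)
  norm <- normalize_log10(sc$counts)
  pred <- classify_cells(norm, sc$markers)
  expect_gte(mean(pred == sc$cells$population), 0.9)
  # per-cell rescaling of raw counts does not change labels
  set.seed(2)
  scaled <- sc$counts
  scaled@x <- scaled@x * rep(sample(1:5, ncol(scaled), replace = TRUE),
                             diff(scaled@p))
  pred2 <- classify_cells(normalize_log10(scaled), sc$markers)
  expect_identical(pred, pred2)
})

test_that("gene_z computes the Welch-type statistic with classification", {
  # two genes x 8 cells; the first gene differs between conditions
  vals <- rbind(gA = c(4, 5, 6, 5, 1, 2, 1, 0),
                gB = c(1, 1, 1, 1, 1, 1, 1, 1))
  norm <- sparse_counts(vals)
  colnames(norm) <- paste0("c", 1:8)
  cond <- rep(c("cKO", "Ctrl"), each = 4L)
  pop <- rep("p1", 8L)
  out <- gene_z(norm, cond, pop, "p1", n_min = 2L)
  a <- vals[1, 1:4]; b <- vals[1, 5:8]
  zexp <- (mean(a) - mean(b)) / sqrt(var(a) / 4 + var(b) / 4)
  expect_equal(out$z[out$gene_id == "gA"], zexp)
  expect_equal(out$p[out$gene_id == "gA"], 2 * pnorm(-abs(zexp)))
  expect_identical(out$class[out$gene_id == "gA"], "up")
  # identical groups: z = 0, ns
  expect_equal(out$z[out$gene_id == "gB"], 0)
  expect_identical(out$class[out$gene_id == "gB"], "ns")
  # worked number: means 1 vs 0 with s^2/n terms 0.04 + 0.01
  expect_equal(1 / sqrt(0.05), 4.472136, tolerance = 1e-6)
  # too few cells: skipped with a note
  expect_message(res <- gene_z(norm, cond, pop, "p1", n_min = 10L),
                 "skipped")
  expect_null(res)
})

test_that("scatter table flags blue/red dots with strict thresholds", {
  zr <- data.table::data.table(
    gene_id = sprintf("g%02d", 1:10), population = "p1",
    z = c(-2.5, -1.0, 1.96, 2.5, 0.1, -3.0, 2.2, 0.5, -0.2, 1.0),
    p = 0.5, fdr = 0.5,
    class = c("down", "ns", "ns", "up", "ns", "down", "up", "ns", "ns",
              "ns"))
  scores <- data.table::data.table(
    gene_id = sprintf("g%02d", 1:10),
    density_cds = c(0.9, 0.1, 0.2, 0.8, 0.3, 0.05, 0.15, 0.25, 0.35, 0.4))
  st <- build_scatter(zr, scores, top_frac = 0.2)
  # top 20% of 10 genes = 2 genes: g01 (0.9), g04 (0.8)
  expect_identical(st$gene_id[st$top20_m6a], c("g01", "g04"))
  # blue dot: down and top-20%
  expect_true(st$down[st$gene_id == "g01"])
  expect_true(st$top20_m6a[st$gene_id == "g01"])
  # red dot: up and top-20%
  expect_true(st$up[st$gene_id == "g04"])
  # z = 1.96 exactly is ns (strict inequality)
  expect_false(st$up[st$gene_id == "g03"])
  # brute-force recount of all flags
  expect_identical(sum(st$down), sum(zr$z < -1.96))
  expect_identical(sum(st$up), sum(zr$z > 1.96))
})

test_that("flagged-set enrichment delegates correctly and handles extremes", {
  zr <- data.table::data.table(
    gene_id = sprintf("g%02d", 1:20), population = "p1",
    z = c(rep(3, 4), rep(0, 16)), p = 0.5, fdr = c(rep(0.01, 4),
                                                   rep(0.9, 16)),
    class = c(rep("up", 4), rep("ns", 16)))
  scores <- data.table::data.table(
    gene_id = sprintf("g%02d", 1:20),
    density_cds = seq(1, 0.05, length.out = 20))
  st <- build_scatter(zr, scores, top_frac = 0.2)
  sets <- list(HIT = sprintf("g%02d", 1:4), MISS = sprintf("g%02d", 11:14))
  enr <- flagged_set_enrichment(st, sets, which = "up_top20")
  expect_identical(enr$set_name[1], "HIT")
  expect_lt(enr$p_value[1], 0.05)
  # selection = universe -> p = 1 for every set
  zr_all <- data.table::copy(zr); zr_all$z <- 3; zr_all$class <- "up"
  st_all <- build_scatter(zr_all, scores, top_frac = 1)
  enr_all <- flagged_set_enrichment(st_all, sets, which = "up_top20")
  expect_true(all(enr_all$p_value == 1))
  # empty selection -> empty result with a note
  zr_none <- data.table::copy(zr); zr_none$z <- 0; zr_none$class <- "ns"
  st_none <- build_scatter(zr_none, scores, top_frac = 0.2)
  expect_message(e0 <- flagged_set_enrichment(st_none, sets,
                                              which = "up_top20"),
                 "empty")
  expect_identical(nrow(e0), 0L)
})

test_that("chi-square occupancy matches the Pearson formula", {
  tab <- rbind(c(10, 20), c(20, 10))
  out <- chi_square_occupancy(tab)
  expect_equal(out$chisq, 20 / 3)
  expect_identical(out$df, 1L)
  expect_equal(out$p, pchisq(20 / 3, 1, lower.tail = FALSE))
  prop <- rbind(c(10, 20), c(20, 40))
  out2 <- chi_square_occupancy(prop)
  expect_equal(out2$chisq, 0)
  expect_equal(out2$p, 1)
  expect_error(chi_square_occupancy(rbind(c(0, 0), c(1, 2))),
               "zero marginal")
  # oracle equality on random 2 x 4 tables
  set.seed(12)
  for (i in 1:20) {
    t2 <- matrix(sample(5:50, 8L), nrow = 2L)
    exp_t <- outer(rowSums(t2), colSums(t2)) / sum(t2)
    expect_equal(chi_square_occupancy(t2)$chisq,
                 sum((t2 - exp_t)^2 / exp_t))
  }
})
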