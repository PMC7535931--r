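#' Filter a single-cell count matrix
#'
#' Two single passes in a declared order: first cells expressing fewer than
#' `min_genes_per_cell` genes are dropped, then genes expressed in fewer
#' than `min_cells_per_gene` of the remaining cells are dropped.
#'
#' @param counts Sparse genes x cells matrix of non-negative integers.
#' @param min_genes_per_cell Minimum detected genes per cell (default 1800,
#'   matching "fewer than 1800" removal: a cell with exactly the minimum is
#'   kept).
#' @param min_cells_per_gene Minimum expressing cells per gene (default 10).
#' @return Filtered sparse matrix.
#' @export
filter_matrix <- function(counts, min_genes_per_cell = 1800L,
                          min_cells_per_gene = 10L) {
  detected_genes <- Matrix::colSums(counts > 0)
  counts <- counts[, detected_genes >= min_genes_per_cell, drop = FALSE]
  if (ncol(counts) == 0L) stop("no cells pass the gene-count filter")
  expressing_cells <- Matrix::rowSums(counts > 0)
  counts <- counts[expressing_cells >= min_cells_per_gene, , drop = FALSE]
  if (nrow(counts) == 0L) stop("no genes pass the cell-count filter")
  counts
}

#' Per-cell normalization with log10 transform
#'
#' `value = log10(1 + count * scale / cell_total)`; cells with zero totals
#' are dropped with a warning. Zeros map to zero, so sparsity is preserved,
#' and the transform is invariant to per-cell scaling of the raw counts.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param scale Per-cell scale factor (default 10000).
#' @return Sparse genes x cells matrix of normalized values.
#' @export
normalize_log10 <- function(counts, scale = 1e4) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " cell(s) with zero total dropped")
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  m <- methods::as(counts, "CsparseMatrix")
  percell <- rep(totals, diff(m@p))
  m@x <- log10(1 + m@x * scale / percell)
  m
}

#' Classify cells into populations by marker panels
#'
#' Each marker gene's normalized expression is z-scored across cells; a
#' cell's score for a population is the mean z over that population's
#' markers, and the label is the argmax. Ties, and cells whose best score is
#' not positive, are labelled `"unassigned"`.
#'
#' @param norm Normalized genes x cells matrix ([normalize_log10()]).
#' @param markers Named list: population -> character marker gene ids (each
#'   population must have at least one marker present in the matrix).
#' @return Character vector of population labels, one per cell.
#' @export
classify_cells <- function(norm, markers) {
  scores <- vapply(names(markers), function(p) {
    mk <- intersect(markers[[p]], rownames(norm))
    if (length(mk) == 0L) {
      stop("population ", p, " has no marker genes in the matrix")
    }
    sub <- as.matrix(norm[mk, , drop = FALSE])
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1L, sd)
    sdv[sdv == 0] <- 1
    colMeans((sub - mu) / sdv)
  }, numeric(ncol(norm)))
  apply(scores, 1L, function(s) {
    best <- which(s == max(s))
    if (length(best) > 1L || max(s) <= 0) "unassigned"
    else names(markers)[best]
  })
}

#' Per-population cKO/Ctrl gene Z scores
#'
#' Welch-type standardized difference on normalized expression within one
#' population: `z = (mean_cKO - mean_Ctrl) / sqrt(s2_cKO/n_cKO +
#' s2_Ctrl/n_Ctrl)`, two-sided p from the standard normal,
#' Benjamini-Hochberg FDR across genes, and classification `down` if
#' `z < -1.96`, `up` if `z > 1.96` (strict inequalities), else `ns`. Genes
#' with zero variance in both groups and equal means get `z = 0`.
#'
#' @param norm Normalized genes x cells matrix.
#' @param condition Character vector per cell, values in `{"Ctrl","cKO"}`.
#' @param population Character vector per cell; `which_pop` selects the
#'   population analysed.
#' @param which_pop Population label to analyse.
#' @param n_min Minimum cells per condition (default 20); below it the
#'   population is skipped with a note (returns `NULL`).
#' @param z_cut Classification threshold (default 1.96).
#' @return `data.table` with `gene_id`, `population`, `z`, `p`, `fdr`,
#'   `class`, or `NULL` if the population has too few cells.
#' @export
gene_z <- function(norm, condition, population, which_pop, n_min = 20L,
                   z_cut = 1.96) {
  sel <- population == which_pop
  a <- norm[, sel & condition == "cKO", drop = FALSE]
  b <- norm[, sel & condition == "Ctrl", drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < n_min || nb < n_min) {
    message("population ", which_pop, " has fewer than ", n_min,
            " cells per condition; skipped")
    return(NULL)
  }
  mstats <- function(m) {
    n <- ncol(m)
    mu <- Matrix::rowSums(m) / n
    ex2 <- Matrix::rowSums(m^2) / n
    v <- (ex2 - mu^2) * n / (n - 1)
    v[v < 0] <- 0
    list(mu = mu, v = v)
  }
  sa <- mstats(a); sb <- mstats(b)
  se <- sqrt(sa$v / na + sb$v / nb)
  dmu <- sa$mu - sb$mu
  z <- dmu / se
  z[se == 0 & dmu == 0] <- 0  # degenerate: no variance, no difference
  p <- 2 * pnorm(-abs(z))
  dt <- data.table(gene_id = rownames(norm), population = which_pop,
                   z = as.numeric(z), p = as.numeric(p))
  dt[, fdr := p.adjust(p, method = "BH")]
  dt[, class := ifelse(z < -z_cut, "down", ifelse(z > z_cut, "up", "ns"))]
  dt[]
}

#' Join per-population Z results with CDS m6A density into a scatter table
#'
#' One row per gene per population: the expression-change Z, the
#' coding-sequence SN-uTPM per nt, and flags `down` (`z < -z_cut`), `up`
#' (`z > z_cut`) and `top20_m6a` (CDS density in the top `top_frac` quintile
#' of the joined gene universe).
#'
#' @param z_results `data.table` from [gene_z()] (one or several populations
#'   row-bound).
#' @param scores Transcript score table from [transcript_scores()].
#' @param top_frac Fraction flagged as highly modified (default 0.2).
#' @param z_cut Classification threshold (default 1.96).
#' @return `data.table` scatter table.
#' @export
build_scatter <- function(z_results, scores, top_frac = 0.2, z_cut = 1.96) {
  zr <- as.data.table(z_results)
  sc <- as.data.table(scores)[, list(gene_id, density_cds)]
  sc <- sc[is.finite(density_cds)]
  joined <- merge(zr, sc, by = "gene_id")
  if (length(unique(joined$gene_id)) < 10L) {
    stop("insufficient gene overlap between Z results and m6A scores")
  }
  uni <- unique(joined[, list(gene_id, density_cds)])
  k <- max(1L, as.integer(round(top_frac * nrow(uni))))
  ord <- order(-uni$density_cds, uni$gene_id)
  top_genes <- uni$gene_id[ord][seq_len(k)]
  joined[, top20_m6a := gene_id %in% top_genes]
  joined[, down := z < -z_cut]
  joined[, up := z > z_cut]
  setorder(joined, population, gene_id)
  joined[]
}

#' Enrichment of flagged scatter-table genes against gene sets
#'
#' Selection `"up_top20"` takes the "red dots" (`up & top20_m6a`, optionally
#' also requiring `fdr < fdr_cut`); `"down"` takes the down-classified
#' genes. Delegates to [overlap_enrichment()] with the joined gene universe.
#'
#' @param scatter Table from [build_scatter()] (one population, or pass a
#'   subset).
#' @param gene_sets Named list of gene sets.
#' @param which One of `"up_top20"`, `"down"`.
#' @param fdr_cut Optional FDR filter applied to the selection (`NULL` =
#'   Z-threshold only).
#' @return `data.table` of enrichment results (empty, with a note, when the
#'   selection is empty).
#' @export
flagged_set_enrichment <- function(scatter, gene_sets,
                                   which = c("up_top20", "down"),
                                   fdr_cut = NULL) {
  which <- match.arg(which)
  st <- as.data.table(scatter)
  sel <- if (which == "up_top20") st$up & st$top20_m6a else st$down
  if (!is.null(fdr_cut)) sel <- sel & st$fdr < fdr_cut
  selected <- unique(st$gene_id[sel])
  universe <- unique(st$gene_id)
  if (length(selected) == 0L) {
    message("empty selection; no enrichment computed")
    return(data.table(set_name = character(0), set_size = integer(0),
                      overlap = integer(0), expected = numeric(0),
                      p_value = numeric(0), fdr = numeric(0)))
  }
  overlap_enrichment(selected, universe, gene_sets)
}

#' Pearson chi-square test of condition x population occupancy
#'
#' @param counts 2 x k contingency matrix (conditions in rows).
#' @return List with `chisq`, `df`, `p`.
#' @export
chi_square_occupancy <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal in the contingency table")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected <= 0)) stop("all expected counts must be positive")
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(chisq = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Write a sparse count matrix as MTX with gene/barcode sidecars
#'
#' @param counts Sparse genes x cells matrix with dimnames.
#' @param dir Output directory (created if needed). Writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`.
#' @param cells Optional cell metadata `data.table` (written as
#'   `labels.tsv`).
#' @return Invisibly, `dir`.
#' @export
write_sc_matrix <- function(counts, dir, cells = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  if (!is.null(cells)) {
    fwrite(cells, file.path(dir, "labels.tsv"), sep = "\t")
  }
  invisible(dir)
}

#' Read a sparse count matrix written by [write_sc_matrix()]
#'
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv` (and optionally `labels.tsv`).
#' @return List with `counts` (dgCMatrix) and `cells` (`data.table` or
#'   `NULL`).
#' @export
read_sc_matrix <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  lp <- file.path(dir, "labels.tsv")
  cells <- if (file.exists(lp)) fread(lp) else NULL
  list(counts = m, cells = cells)
}
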