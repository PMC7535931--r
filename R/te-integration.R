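#' Bin genes into quintiles by a metric
#'
#' Genes are sorted descending by metric with ties broken by gene id
#' (stable, lexicographic), then split into five near-equal bins whose sizes
#' differ by at most one. Quintile 5 is the top 20%, quintile 1 the bottom.
#'
#' @param metric Named numeric vector (names = gene ids) with finite values.
#' @return `data.table` with `gene_id`, `metric`, `quintile`.
#' @export
bin_quintiles <- function(metric) {
  metric <- metric[is.finite(metric)]
  n <- length(metric)
  if (n < 5L) stop("need at least 5 genes with finite metric")
  ord <- order(-metric, names(metric))
  q <- 5L - as.integer(floor((seq_len(n) - 1L) * 5 / n))
  data.table(gene_id = names(metric)[ord], metric = unname(metric[ord]),
             quintile = q)
}

#' Empirical cumulative distribution function as a step table
#'
#' @param values Non-empty numeric vector.
#' @return `data.table` with support points `x` and cumulative fractions `F`
#'   (nondecreasing, right-continuous, `F(max) = 1`).
#' @export
ecdf_table <- function(values) {
  if (length(values) == 0L) stop("ecdf of empty sample is undefined")
  x <- sort(unique(values))
  data.table(x = x, F = stats::ecdf(values)(x))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact two-sided p by enumeration of rank assignments when
#' `length(a) + length(b) <= 12` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction. The reported
#' statistic is the Mann-Whitney U for sample `a`.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `U` and two-sided `p`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty group")
  na <- length(a); nb <- length(b); n <- na + nb
  v <- c(a, b)
  rk <- rank(v)
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(v))
  if (n <= 12L && !ties) {
    # enumerate all rank subsets of size na
    combos <- combn(n, na)
    Uperm <- colSums(matrix(rk[combos], nrow = na)) - na * (na + 1) / 2
    centre <- na * nb / 2
    p <- mean(abs(Uperm - centre) >= abs(U - centre) - 1e-12)
  } else {
    mu <- na * nb / 2
    tie_tab <- table(v)
    sig2 <- na * nb / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sig2 <= 0) return(list(U = U, p = 1))
    z <- (abs(U - mu) - 0.5) / sqrt(sig2)
    if (z < 0) z <- 0
    p <- min(1, 2 * pnorm(-z))
  }
  list(U = U, p = p)
}

#' Compare translation efficiency across m6A quintiles
#'
#' Bins genes into quintiles by the chosen region's m6A metric, then
#' contrasts the translation efficiencies of quintile 5 (top 20%) against
#' quintile 1 (bottom 20%) with ECDFs and a Wilcoxon rank-sum test.
#'
#' @param scores Transcript score table from [transcript_scores()].
#' @param te `data.table` with `gene_id`, `te` (positive).
#' @param region One of `"full"`, `"utr5"`, `"cds"`, `"utr3"`.
#' @param metric One of `"density"` (per-nt SN-uTPM, default) or `"snutpm"`
#'   (region sum).
#' @return List with `quintiles`, `ecdf_top`, `ecdf_bottom`, `U`, `p`,
#'   `median_top`, `median_bottom`, `n_top`, `n_bottom`.
#' @export
compare_te_by_m6a <- function(scores, te, region = "cds",
                              metric = c("density", "snutpm")) {
  metric <- match.arg(metric)
  region <- match.arg(region, c("full", "utr5", "cds", "utr3"))
  sc <- as.data.table(scores)
  te <- as.data.table(te)
  if (any(te$te <= 0)) stop("translation efficiencies must be positive")
  col <- paste0(metric, "_", region)
  m <- setNames(sc[[col]], sc$gene_id)
  m <- m[is.finite(m)]
  shared <- intersect(names(m), te$gene_id)
  if (length(shared) < 10L) {
    stop("insufficient gene overlap between m6A scores and TE (",
         length(shared), " < 10)")
  }
  q <- bin_quintiles(m[shared])
  te_of <- setNames(te$te, te$gene_id)
  top <- te_of[q$gene_id[q$quintile == 5L]]
  bottom <- te_of[q$gene_id[q$quintile == 1L]]
  w <- wilcoxon_rank_sum(top, bottom)
  list(quintiles = q, ecdf_top = ecdf_table(top),
       ecdf_bottom = ecdf_table(bottom), U = w$U, p = w$p,
       median_top = stats::median(top), median_bottom = stats::median(bottom),
       n_top = length(top), n_bottom = length(bottom))
}

#' Hypergeometric overlap enrichment of a gene selection against gene sets
#'
#' One-sided hypergeometric p-value per set (sets intersected with the
#' universe; empty intersections skipped with a note), Benjamini-Hochberg
#' FDR across sets. The `p < 0.05 & overlap > 5` style filter used for
#' reporting top pathways is exposed via `min_overlap`/`max_p`.
#'
#' @param selected Character gene selection (subset of `universe`).
#' @param universe Character gene universe.
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param min_overlap,max_p Optional reporting filters (`NULL` = keep all).
#' @return `data.table` with `set_name`, `set_size`, `overlap`, `expected`,
#'   `p_value`, `fdr`, sorted by p.
#' @export
overlap_enrichment <- function(selected, universe, gene_sets,
                               min_overlap = NULL, max_p = NULL) {
  universe <- unique(universe)
  selected <- unique(selected)
  if (!all(selected %in% universe)) {
    stop("selected genes must be a subset of the universe")
  }
  N <- length(universe); n <- length(selected)
  res <- rbindlist(lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    K <- length(set)
    if (K == 0L) {
      message("gene set ", nm, " has no genes in the universe; skipped")
      return(NULL)
    }
    ov <- length(intersect(set, selected))
    p <- phyper(ov - 1L, K, N - K, n, lower.tail = FALSE)
    data.table(set_name = nm, set_size = K, overlap = ov,
               expected = n * K / N, p_value = p)
  }))
  if (nrow(res) == 0L) return(res)
  res[, fdr := p.adjust(p_value, method = "BH")]
  if (!is.null(min_overlap)) res <- res[overlap > min_overlap]
  if (!is.null(max_p)) res <- res[p_value < max_p]
  setorder(res, p_value, set_name)
  res[]
}

#' Preranked GSEA: weighted running-sum enrichment score with permutation p
#'
#' Classical preranked enrichment: genes are ranked by decreasing metric;
#' hits increment the running sum by `|metric|^weight_exponent` (normalized
#' to total 1), misses decrement by `1/(N - N_hits)`; the enrichment score
#' (ES) is the signed maximum deviation. Significance by gene-label
#' permutation: `perm_p = (1 + #{|ES_perm| >= |ES|}) / (n_perm + 1)`.
#'
#' @param ranked_metric Named numeric vector (names = gene ids).
#' @param gene_set Character vector; must hit at least one and not all genes.
#' @param weight_exponent Hit weight exponent (default 1).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return List with `es`, `perm_p`, `n_hits`, `leading_edge`.
#' @export
preranked_gsea <- function(ranked_metric, gene_set, weight_exponent = 1,
                           n_perm = 1000L, seed = 1L) {
  ord <- order(-ranked_metric, names(ranked_metric))
  genes <- names(ranked_metric)[ord]
  stat <- as.numeric(ranked_metric[ord])
  N <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0L) stop("gene set hits no gene in the ranking")
  if (nh == N) stop("gene set covers the whole ranking (degenerate)")
  es_of <- function(hit) {
    w <- abs(stat)^weight_exponent
    hw <- w * hit
    tot <- sum(hw)
    inc <- if (tot > 0) hw / tot else hit / sum(hit)
    dec <- (!hit) / (N - sum(hit))
    rs <- cumsum(inc - dec)
    rs[which.max(abs(rs))]
  }
  es <- es_of(hit)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    es_of(seq_len(N) %in% sample.int(N, nh))
  }, numeric(1))
  perm_p <- (1 + sum(abs(perm) >= abs(es))) / (n_perm + 1)
  peak <- which.max(abs(cumsum({
    w <- abs(stat)^weight_exponent; hw <- w * hit
    hw / sum(hw) - (!hit) / (N - nh)
  })))
  leading <- if (es >= 0) genes[seq_len(peak)][hit[seq_len(peak)]]
             else genes[peak:N][hit[peak:N]]
  list(es = es, perm_p = perm_p, n_hits = nh, leading_edge = leading)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (set name, description, then member genes, tab
#'   separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
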