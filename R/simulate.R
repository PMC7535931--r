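#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. The defaults are
#' the package's declared study conditions: a small transcriptome with
#' stop-codon-biased DRACH-constrained m6A sites, negative-binomial miCLIP and
#' input tag libraries in three replicates, translation efficiencies coupled
#' to true CDS m6A density, and a two-condition (Ctrl/cKO) single-cell
#' experiment over four epithelial populations with planted up/down effects
#' in which the up-regulated set is drawn preferentially from highly
#' CDS-methylated genes.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_transcripts Number of simulated transcripts (one per gene).
#' @param length_range Min/max spliced transcript length (nt).
#' @param utr5_frac,cds_frac Fractions of the transcript allotted to the
#'   5' UTR and CDS (3' UTR takes the remainder; CDS rounded to codons).
#' @param n_exons_range Min/max exon count per transcript.
#' @param intron_length_range Min/max intron length (nt).
#' @param minus_strand_prob Probability a transcript lies on the minus strand.
#' @param site_rate Expected true m6A sites per kb of transcript.
#' @param w_stop Mixture weight of the stop-codon-centred positional
#'   component (remainder uniform along the transcript).
#' @param stop_sd Standard deviation (nt) of the Gaussian kernel centred at
#'   the stop codon.
#' @param meth_range Range of per-site methylation stoichiometry.
#' @param enrichment miCLIP window enrichment factor at a fully methylated
#'   site (declared simulation choice; not reported by typical assays).
#' @param input_mean_cov Mean input unique-tag count per position at unit
#'   expression.
#' @param miclip_bg_cov Mean miCLIP background unique-tag count per position
#'   at unit expression.
#' @param expr_sdlog Log-sd of the log-normal transcript expression levels.
#' @param dispersion Negative-binomial size for tag counts.
#' @param crosslink_mutation_rate Mutation fraction at true crosslink
#'   positions.
#' @param background_mutation_rate Mutation fraction elsewhere.
#' @param crosslink_offset Offset (nt, 3' direction) of the crosslink
#'   mutation from the methylated A.
#' @param n_replicates Number of miCLIP/input replicate pairs.
#' @param depth_miclip,depth_input Per-replicate depth multipliers (recycled
#'   to `n_replicates`).
#' @param te_alpha,te_beta,te_sigma Intercept, effect of standardized true
#'   CDS m6A density, and noise sd of log translation efficiency.
#' @param n_cells Cells per condition.
#' @param pop_props Named proportions of the four populations.
#' @param markers_per_pop,marker_fold Marker genes per population and their
#'   fold elevation in their own population.
#' @param sc_mean_log,sc_mean_sdlog Log-normal parameters of per-gene base
#'   mean UMI counts.
#' @param sc_dispersion Negative-binomial size for UMI counts.
#' @param ko_frac_down,ko_frac_up Fraction of genes in the planted down/up
#'   sets (used when explicit sets are not given).
#' @param ko_down_effect,ko_up_effect Effect sizes d and u: cKO means are
#'   multiplied by (1-d) / (1+u).
#' @param ko_up_top_frac The up set is sampled from genes within this top
#'   fraction of true CDS m6A density (emulating the observed coupling
#'   between heavy CDS methylation and up-regulation after writer loss).
#' @param ko_down_set,ko_up_set Optional explicit gene-id vectors overriding
#'   the sampled sets.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 50L,
                       length_range = c(1200L, 3000L),
                       utr5_frac = 0.2, cds_frac = 0.6,
                       n_exons_range = c(1L, 3L),
                       intron_length_range = c(50L, 300L),
                       minus_strand_prob = 0.5,
                       site_rate = 5,
                       w_stop = 0.8, stop_sd = 50,
                       meth_range = c(0.3, 1),
                       enrichment = 10,
                       input_mean_cov = 15,
                       miclip_bg_cov = 5,
                       expr_sdlog = 0.6,
                       dispersion = 8,
                       crosslink_mutation_rate = 0.2,
                       background_mutation_rate = 0.001,
                       crosslink_offset = 1L,
                       n_replicates = 3L,
                       depth_miclip = c(1, 0.9, 1.1),
                       depth_input = c(1, 1.05, 0.95),
                       te_alpha = 0, te_beta = 1, te_sigma = 0.5,
                       n_cells = 500L,
                       pop_props = c(epi_basal = 0.45, epi_suprabasal = 0.2,
                                     hf_wnt_hi = 0.15, hf_wnt_lo = 0.2),
                       markers_per_pop = 3L, marker_fold = 8,
                       sc_mean_log = 0, sc_mean_sdlog = 1,
                       sc_dispersion = 2,
                       ko_frac_down = 0.05, ko_frac_up = 0.05,
                       ko_down_effect = 0.5, ko_up_effect = 0.5,
                       ko_up_top_frac = 0.3,
                       ko_down_set = NULL, ko_up_set = NULL) {
  cfg <- as.list(environment())
  fr <- c(utr5_frac = utr5_frac, cds_frac = cds_frac, w_stop = w_stop,
          minus_strand_prob = minus_strand_prob,
          crosslink_mutation_rate = crosslink_mutation_rate,
          background_mutation_rate = background_mutation_rate,
          ko_frac_down = ko_frac_down, ko_frac_up = ko_frac_up,
          ko_up_top_frac = ko_up_top_frac)
  if (any(fr < 0 | fr > 1)) {
    stop("config error: fractions must lie in [0,1]: ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "))
  }
  if (utr5_frac + cds_frac >= 1) {
    stop("config error: utr5_frac + cds_frac must leave room for a 3' UTR")
  }
  if (abs(sum(pop_props) - 1) > 1e-8) {
    stop("config error: pop_props must sum to 1")
  }
  pos <- c(n_transcripts = n_transcripts, n_replicates = n_replicates,
           n_cells = n_cells, enrichment = enrichment,
           input_mean_cov = input_mean_cov, dispersion = dispersion,
           sc_dispersion = sc_dispersion)
  if (any(pos <= 0)) {
    stop("config error: sizes must be positive: ",
         paste(names(pos)[pos <= 0], collapse = ", "))
  }
  if (any(c(depth_miclip, depth_input) <= 0)) {
    stop("config error: depth multipliers must be positive")
  }
  if ((1 - ko_down_effect) <= 0 || (1 + ko_up_effect) <= 0) {
    stop("config error: knockout effect multipliers must be in (0, Inf)")
  }
  cfg$depth_miclip <- rep_len(depth_miclip, n_replicates)
  cfg$depth_input <- rep_len(depth_input, n_replicates)
  structure(cfg, class = "sim_config")
}

## ---- transcriptome ---------------------------------------------------------

#' Simulate a transcriptome (genome, annotation and transcript models)
#'
#' Each transcript occupies its own chromosome, with 1-3 exons, a random
#' strand, and a CDS placed according to the configured UTR fractions.
#' Random sequence guarantees abundant DRACH occurrences at the configured
#' transcript lengths. Deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `models` (named list of [transcript_model()] with
#'   sequences attached) and `genome` (named character vector of chromosome
#'   sequences).
#' @export
simulate_transcriptome <- function(cfg) {
  set.seed(cfg$seed)
  bases <- c("A", "C", "G", "T")
  genome <- character(0)
  models <- vector("list", cfg$n_transcripts)
  for (i in seq_len(cfg$n_transcripts)) {
    tid <- sprintf("T%04d", i)
    gid <- sprintf("G%04d", i)
    chrom <- paste0("chr_", tid)
    L <- sample(cfg$length_range[1]:cfg$length_range[2], 1L)
    utr5 <- max(1L, as.integer(round(L * cfg$utr5_frac)))
    cds <- max(3L, 3L * (as.integer(L * cfg$cds_frac) %/% 3L))
    if (utr5 + cds >= L) stop("config error: infeasible length/fractions")
    k <- sample(cfg$n_exons_range[1]:cfg$n_exons_range[2], 1L)
    k <- min(k, L %/% 100L)
    if (k < 1L) k <- 1L
    # split transcript length into k exon widths of at least 50 nt
    cuts <- sort(sample(seq(50L, L - 50L), k - 1L))
    widths <- diff(c(0L, cuts, L))
    introns <- if (k > 1L) {
      sample(cfg$intron_length_range[1]:cfg$intron_length_range[2], k - 1L,
             replace = TRUE)
    } else integer(0)
    starts <- 100L + cumsum(c(0L, widths[-k] + introns))
    exons <- cbind(starts, starts + widths)
    strand <- if (runif(1) < cfg$minus_strand_prob) "-" else "+"
    chrom_len <- max(exons[, 2L]) + 100L
    gseq <- intToUtf8(sample(c(65L, 67L, 71L, 84L), chrom_len,
                             replace = TRUE))
    m <- transcript_model(tid, gid, chrom, strand, exons,
                          cds_start = utr5, cds_end = utr5 + cds)
    m$sequence <- spliced_sequence(m, gseq)
    genome[chrom] <- gseq
    models[[i]] <- m
  }
  names(models) <- vapply(models, `[[`, character(1), "transcript_id")
  list(models = models, genome = genome)
}

#' Extract the spliced transcript sequence from a chromosome sequence
#'
#' Reverse-complements for minus-strand transcripts.
#'
#' @param t A `transcript_model`.
#' @param chrom_seq Character sequence of the transcript's chromosome.
#' @return Character spliced sequence, 5'->3' in transcript orientation.
#' @export
spliced_sequence <- function(t, chrom_seq) {
  ex <- t$exons[order(t$exons[, 1L]), , drop = FALSE]
  parts <- vapply(seq_len(nrow(ex)), function(i) {
    substr(chrom_seq, ex[i, 1L] + 1L, ex[i, 2L])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (t$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

## ---- m6A truth -------------------------------------------------------------

#' Plant true m6A sites on simulated transcripts
#'
#' Sites are placed only at DRACH-centred adenosines. Positions follow a
#' mixture: with weight `w_stop`, a Gaussian kernel centred at the stop codon
#' (snapped to the nearest DRACH A); otherwise uniform over the transcript's
#' DRACH A's. Expected count is `site_rate * length/1000` per transcript.
#'
#' @param models Named list of `transcript_model` with sequences.
#' @param cfg A [sim_config()].
#' @return `data.table` with columns `transcript_id`, `gene_id`, `tpos`,
#'   `motif`, `region`, `methylation`.
#' @export
plant_m6a_sites <- function(models, cfg) {
  set.seed(cfg$seed + 1L)
  acc_tid <- acc_gid <- acc_motif <- acc_region <- vector("list",
                                                          length(models))
  acc_pos <- acc_meth <- vector("list", length(models))
  k <- 0L
  for (m in models) {
    cand <- drach_positions(m$sequence)
    if (length(cand) == 0L) {
      warning("transcript ", m$transcript_id, " has no DRACH A; no sites")
      next
    }
    n <- rpois(1L, cfg$site_rate * m$length / 1000)
    if (n == 0L) next
    from_stop <- is_coding(m) & runif(n) < cfg$w_stop
    target <- integer(n)
    target[!from_stop] <- sample.int(m$length, sum(!from_stop),
                                     replace = TRUE) - 1L
    if (any(from_stop)) {
      target[from_stop] <- as.integer(round(
        rnorm(sum(from_stop), m$cds_end - 3L, cfg$stop_sd)))
    }
    # snap each target to the nearest DRACH-centred A (cand is sorted)
    i <- findInterval(target, cand)
    lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(cand))
    pos <- ifelse(abs(target - cand[lo]) <= abs(cand[hi] - target),
                  cand[lo], cand[hi])
    pos <- unique(pos)
    k <- k + 1L
    acc_tid[[k]] <- rep(m$transcript_id, length(pos))
    acc_gid[[k]] <- rep(m$gene_id, length(pos))
    acc_pos[[k]] <- pos
    acc_motif[[k]] <- substr_kmer(m$sequence, pos)
    acc_region[[k]] <- if (is_coding(m)) assign_site_region(m, pos)
                       else rep(NA_character_, length(pos))
    acc_meth[[k]] <- runif(length(pos), cfg$meth_range[1], cfg$meth_range[2])
  }
  sites <- data.table(
    transcript_id = unlist(acc_tid), gene_id = unlist(acc_gid),
    tpos = as.integer(unlist(acc_pos)), motif = unlist(acc_motif),
    region = unlist(acc_region), methylation = unlist(acc_meth))
  if (is.null(sites$transcript_id)) sites <- data.table(
    transcript_id = character(0), gene_id = character(0), tpos = integer(0),
    motif = character(0), region = character(0), methylation = numeric(0))
  if (nrow(sites)) setorder(sites, transcript_id, tpos)
  sites[]
}

#' 0-based positions of DRACH-centred adenosines in a sequence
#'
#' Vectorized scan over the integer-coded sequence (equivalent to an IUPAC
#' "DRACH" pattern match).
#'
#' @param seq Character nucleotide sequence (A/C/G/T or U).
#' @return Integer vector of 0-based positions of the central A.
#' @export
drach_positions <- function(seq) {
  v <- utf8ToInt(chartr("Uu", "Tt", toupper(seq)))  # A=65 C=67 G=71 T=84
  L <- length(v)
  if (L < 5L) return(integer(0))
  ok <- v[3:(L - 2L)] == 65L &                      # A
    v[4:(L - 1L)] == 67L &                          # C
    v[2:(L - 3L)] %in% c(65L, 71L) &                # R = A/G
    v[1:(L - 4L)] %in% c(65L, 71L, 84L) &           # D = A/G/T
    v[5:L] %in% c(65L, 67L, 84L)                    # H = A/C/T
  which(ok) + 1L  # 1-based centre is index+2; 0-based is index+1
}

# 5-mer centred at 0-based position p (vectorized)
substr_kmer <- function(seq, p) {
  vapply(p, function(x) substr(seq, x - 1L, x + 3L), character(1))
}

## ---- tag libraries ---------------------------------------------------------

#' Simulate miCLIP and input tag pileups
#'
#' Tags are deduplicated point events recorded at their position, so
#' per-position coverage equals the unique-tag count. Input counts are
#' negative binomial with mean proportional to the transcript's (log-normal)
#' expression; miCLIP counts additionally gain `1 + enrichment * methylation`
#' within the 21-nt window of each true site. Mutations are binomial at the
#' crosslink offset of true sites (rate `crosslink_mutation_rate`) and at the
#' background rate elsewhere.
#'
#' @param models Named list of `transcript_model`.
#' @param truth Truth site table from [plant_m6a_sites()].
#' @param cfg A [sim_config()].
#' @return List with `pileups` (`data.table`: `transcript_id`, `tpos`,
#'   `assay`, `replicate`, `coverage`, `mutation_count`, `unique_tag_count`),
#'   `lib_totals` (`assay`, `replicate`, `lib_total`), and `expression`
#'   (named vector).
#' @export
simulate_miclip_libraries <- function(models, truth, cfg) {
  set.seed(cfg$seed + 2L)
  if (any(c(cfg$depth_miclip, cfg$depth_input) <= 0)) {
    stop("config error: zero library size")
  }
  expr <- setNames(rlnorm(length(models), 0, cfg$expr_sdlog), names(models))
  rows <- vector("list", length(models) * cfg$n_replicates * 2L)
  k <- 0L
  for (m in models) {
    L <- m$length
    s <- truth[truth$transcript_id == m$transcript_id]
    fac <- rep(1, L)
    for (j in seq_len(nrow(s))) {
      idx <- max(0L, s$tpos[j] - 10L):min(L - 1L, s$tpos[j] + 10L)
      fac[idx + 1L] <- fac[idx + 1L] + cfg$enrichment * s$methylation[j]
    }
    cross <- s$tpos + cfg$crosslink_offset
    cross <- cross[cross >= 0L & cross < L]
    for (r in seq_len(cfg$n_replicates)) {
      mu_in <- cfg$input_mean_cov * expr[[m$transcript_id]] *
        cfg$depth_input[r]
      cov_in <- rnbinom(L, mu = mu_in, size = cfg$dispersion)
      mut_in <- rbinom(L, cov_in, cfg$background_mutation_rate)
      mu_mi <- cfg$miclip_bg_cov * expr[[m$transcript_id]] *
        cfg$depth_miclip[r] * fac
      cov_mi <- rnbinom(L, mu = mu_mi, size = cfg$dispersion)
      mut_mi <- rbinom(L, cov_mi, cfg$background_mutation_rate)
      if (length(cross)) {
        mut_mi[cross + 1L] <- rbinom(length(cross), cov_mi[cross + 1L],
                                     cfg$crosslink_mutation_rate)
      }
      for (a in c("input", "miclip")) {
        cv <- if (a == "input") cov_in else cov_mi
        mt <- if (a == "input") mut_in else mut_mi
        keep <- cv > 0L
        if (!any(keep)) next
        k <- k + 1L
        rows[[k]] <- data.table(
          transcript_id = m$transcript_id, tpos = which(keep) - 1L,
          assay = a, replicate = r, coverage = cv[keep],
          mutation_count = mt[keep], unique_tag_count = cv[keep])
      }
    }
  }
  pileups <- rbindlist(rows[seq_len(k)])
  setorder(pileups, assay, replicate, transcript_id, tpos)
  lib_totals <- pileups[, list(lib_total = sum(unique_tag_count)),
                        by = c("assay", "replicate")]
  list(pileups = pileups[], lib_totals = lib_totals[], expression = expr)
}

## ---- translation efficiency ------------------------------------------------

#' True per-gene CDS m6A density from planted sites
#'
#' Sum of methylation stoichiometry over CDS sites divided by CDS length;
#' the generator's ground-truth analogue of coding-sequence SN-uTPM per nt.
#'
#' @param models Named list of `transcript_model`.
#' @param truth Truth table from [plant_m6a_sites()].
#' @return `data.table` with `gene_id`, `transcript_id`, `true_cds_density`.
#' @export
true_cds_density <- function(models, truth) {
  coding <- Filter(is_coding, models)
  info <- data.table(
    gene_id = vapply(coding, `[[`, character(1), "gene_id"),
    transcript_id = vapply(coding, `[[`, character(1), "transcript_id"),
    cds_len = vapply(coding, function(m) m$cds_end - m$cds_start,
                     integer(1)))
  tr <- as.data.table(truth)
  agg <- if (nrow(tr)) {
    tr[tr$region == "cds", list(s = sum(methylation)), by = "transcript_id"]
  } else data.table(transcript_id = character(0), s = numeric(0))
  sums <- setNames(agg$s, agg$transcript_id)[info$transcript_id]
  sums[is.na(sums)] <- 0
  dt <- data.table(gene_id = info$gene_id,
                   transcript_id = info$transcript_id,
                   true_cds_density = unname(sums) / info$cds_len)
  setorder(dt, gene_id)
  dt[]
}

#' Simulate translation efficiencies coupled to true CDS m6A density
#'
#' `log TE = te_alpha + te_beta * standardized(true CDS density) +
#' Normal(0, te_sigma)`; TE is returned on the natural (positive) scale.
#'
#' @param models,truth,cfg As for [true_cds_density()] plus a [sim_config()].
#' @return `data.table` with `gene_id`, `te`, `log_te`, `true_cds_density`.
#' @export
simulate_te <- function(models, truth, cfg) {
  set.seed(cfg$seed + 3L)
  dens <- true_cds_density(models, truth)
  x <- dens$true_cds_density
  z <- if (length(unique(x)) > 1L) (x - mean(x)) / sd(x) else rep(0, length(x))
  log_te <- cfg$te_alpha + cfg$te_beta * z +
    rnorm(nrow(dens), 0, cfg$te_sigma)
  data.table(gene_id = dens$gene_id, te = exp(log_te), log_te = log_te,
             true_cds_density = x)
}

## ---- single-cell counts ----------------------------------------------------

#' Simulate two-condition single-cell count matrices
#'
#' Per-gene per-population negative-binomial means; marker genes elevated
#' `marker_fold`-fold in their own population; cKO means multiplied by
#' `(1 - d)` for the planted down set and `(1 + u)` for the planted up set.
#' The up set is sampled from genes in the top `ko_up_top_frac` of true CDS
#' m6A density (markers excluded from both sets). Deterministic under seed.
#'
#' @param models Named list of `transcript_model`.
#' @param truth Truth table from [plant_m6a_sites()].
#' @param cfg A [sim_config()].
#' @return List with `counts` (sparse genes x cells dgCMatrix, both
#'   conditions), `cells` (`data.table`: `cell_id`, `condition`,
#'   `population`), `markers` (named list population -> gene ids),
#'   `ko_down_set`, `ko_up_set`, `base_mean`.
#' @export
simulate_sc_counts <- function(models, truth, cfg) {
  set.seed(cfg$seed + 4L)
  genes <- sort(unique(vapply(models, `[[`, character(1), "gene_id")))
  G <- length(genes)
  pops <- names(cfg$pop_props)
  # at small gene counts, shrink the marker panel rather than fail
  mpp <- max(1L, min(cfg$markers_per_pop, G %/% (2L * length(pops))))
  n_mark <- mpp * length(pops)
  if (n_mark >= G) stop("config error: more markers than genes")

  base_mean <- setNames(rlnorm(G, cfg$sc_mean_log, cfg$sc_mean_sdlog), genes)
  marker_ids <- sample(genes, n_mark)
  markers <- split(marker_ids, rep(pops, each = mpp))

  dens <- true_cds_density(models, truth)
  dens <- dens[match(genes, dens$gene_id)]
  non_marker <- setdiff(genes, marker_ids)
  up_set <- cfg$ko_up_set
  if (is.null(up_set)) {
    n_up <- max(1L, round(cfg$ko_frac_up * G))
    hi <- dens$gene_id[dens$true_cds_density >=
      quantile(dens$true_cds_density, 1 - cfg$ko_up_top_frac, na.rm = TRUE)]
    pool <- intersect(hi, non_marker)
    if (length(pool) < n_up) pool <- non_marker
    up_set <- sort(sample(pool, n_up))
  }
  down_set <- cfg$ko_down_set
  if (is.null(down_set)) {
    n_down <- max(1L, round(cfg$ko_frac_down * G))
    pool <- setdiff(non_marker, up_set)
    down_set <- sort(sample(pool, min(n_down, length(pool))))
  }

  n_per_pop <- round(cfg$pop_props * cfg$n_cells)
  n_per_pop[1L] <- cfg$n_cells - sum(n_per_pop[-1L])
  pop_of_cell <- rep(pops, n_per_pop)

  cond_mult <- setNames(rep(1, G), genes)
  cond_mult[down_set] <- 1 - cfg$ko_down_effect
  cond_mult[up_set] <- 1 + cfg$ko_up_effect

  make_cond <- function(cond) {
    mult <- if (cond == "cKO") cond_mult else setNames(rep(1, G), genes)
    mats <- lapply(pops, function(p) {
      n <- n_per_pop[[p]]
      mu <- base_mean
      mu[markers[[p]]] <- mu[markers[[p]]] * cfg$marker_fold
      mu <- mu * mult
      matrix(rnbinom(G * n, mu = rep(mu, n), size = cfg$sc_dispersion),
             nrow = G)
    })
    do.call(cbind, mats)
  }
  ctrl <- make_cond("Ctrl")
  cko <- make_cond("cKO")
  counts <- cbind(ctrl, cko)
  cells <- data.table(
    cell_id = c(sprintf("Ctrl_%04d", seq_len(cfg$n_cells)),
                sprintf("cKO_%04d", seq_len(cfg$n_cells))),
    condition = rep(c("Ctrl", "cKO"), each = cfg$n_cells),
    population = rep(pop_of_cell, 2L))
  dimnames(counts) <- list(genes, cells$cell_id)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "dMatrix")
  list(counts = counts, cells = cells[], markers = markers,
       ko_down_set = down_set, ko_up_set = up_set, base_mean = base_mean)
}

#' Simulate gene sets (GMT-style) including the planted knockout sets
#'
#' Builds a named list of gene sets: the planted up and down sets plus
#' `n_random` sets drawn uniformly from the gene universe.
#'
#' @param sc Result of [simulate_sc_counts()].
#' @param genes Character gene universe.
#' @param n_random Number of random decoy sets.
#' @param random_size Size of each decoy set.
#' @param seed Integer seed.
#' @return Named list of character vectors.
#' @export
simulate_gene_sets <- function(sc, genes, n_random = 10L, random_size = 50L,
                               seed = 1L) {
  set.seed(seed + 5L)
  sets <- list(PLANTED_UP = sc$ko_up_set, PLANTED_DOWN = sc$ko_down_set)
  for (i in seq_len(n_random)) {
    sets[[sprintf("RANDOM_%02d", i)]] <-
      sort(sample(genes, min(random_size, length(genes))))
  }
  sets
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper producing every layer (transcriptome, truth sites,
#' tag libraries, translation efficiencies, single-cell counts, gene sets)
#' from one configuration.
#'
#' @param cfg A [sim_config()].
#' @return List with `models`, `genome`, `truth_sites`, `pileups`,
#'   `lib_totals`, `expression`, `te`, `sc`, `gene_sets`, `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  tx <- simulate_transcriptome(cfg)
  truth <- plant_m6a_sites(tx$models, cfg)
  libs <- simulate_miclip_libraries(tx$models, truth, cfg)
  te <- simulate_te(tx$models, truth, cfg)
  sc <- simulate_sc_counts(tx$models, truth, cfg)
  genes <- sort(unique(vapply(tx$models, `[[`, character(1), "gene_id")))
  sets <- simulate_gene_sets(sc, genes, seed = cfg$seed)
  list(models = tx$models, genome = tx$genome, truth_sites = truth,
       pileups = libs$pileups, lib_totals = libs$lib_totals,
       expression = libs$expression, te = te, sc = sc, gene_sets = sets,
       cfg = cfg)
}
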