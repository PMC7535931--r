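#' Match a 5-mer against the DRACH consensus
#'
#' DRACH is the degenerate m6A consensus: D = A/G/U, R = A/G, then the
#' methylated A, C, and H = A/C/U. U and T are equivalent.
#'
#' @param kmer Character vector of 5-mers.
#' @return Logical vector.
#' @export
drach_match <- function(kmer) {
  if (any(nchar(kmer) != 5L)) stop("drach_match expects 5-mers")
  k <- chartr("Uu", "Tt", toupper(kmer))
  d <- substr(k, 1L, 1L); r <- substr(k, 2L, 2L)
  a <- substr(k, 3L, 3L); c5 <- substr(k, 4L, 4L); h <- substr(k, 5L, 5L)
  d %in% c("A", "G", "T") & r %in% c("A", "G") & a == "A" & c5 == "C" &
    h %in% c("A", "C", "T")
}

#' Site-calling parameters for the CIMS-style procedure
#'
#' @param min_coverage Minimum unique-tag coverage at a candidate position.
#' @param r_bounds Admissible mutation-fraction interval `[r_lo, r_hi]`.
#' @param crosslink_offset Offset (nt) of the crosslink mutation 3' of the
#'   methylated A; the inferred A is `position - crosslink_offset`.
#' @param min_replicates_detected Replicates a site must be detected in.
#' @param alpha Benjamini-Hochberg-adjusted significance level of the
#'   one-sided binomial test against the background mutation rate.
#' @param background_rate Background per-tag mutation rate.
#' @return List of class `site_call_params`.
#' @export
site_call_params <- function(min_coverage = 10L, r_bounds = c(0.02, 0.5),
                             crosslink_offset = 1L,
                             min_replicates_detected = 2L,
                             alpha = 0.01, background_rate = 0.001) {
  stopifnot(length(r_bounds) == 2L)
  if (!(r_bounds[1] >= 0 && r_bounds[1] < r_bounds[2] && r_bounds[2] <= 1)) {
    stop("mutation-rate bounds must satisfy 0 <= r_lo < r_hi <= 1")
  }
  structure(list(min_coverage = as.integer(min_coverage),
                 r_bounds = as.numeric(r_bounds),
                 crosslink_offset = as.integer(crosslink_offset),
                 min_replicates_detected = as.integer(min_replicates_detected),
                 alpha = alpha, background_rate = background_rate),
            class = "site_call_params")
}

#' Call m6A sites from miCLIP pileups (CIMS-style with DRACH filter)
#'
#' A position is a candidate crosslink signature in a replicate if its
#' unique-tag coverage reaches `min_coverage`, its mutation fraction lies in
#' `r_bounds`, and a one-sided binomial test against the background rate
#' rejects after Benjamini-Hochberg adjustment across candidate positions at
#' `alpha`. The inferred methylated adenosine is `position -
#' crosslink_offset`; it is kept only if that base is an A whose 5-mer
#' context matches DRACH and it is detected in at least
#' `min_replicates_detected` replicates. Duplicates across replicates are
#' merged by (transcript, position).
#'
#' @param pileups `data.table` with `transcript_id`, `tpos`, `assay`,
#'   `replicate`, `coverage`, `mutation_count` (miCLIP rows are used).
#' @param models Named list of `transcript_model` with sequences.
#' @param params A [site_call_params()].
#' @return `data.table` with `transcript_id`, `gene_id`, `tpos`, `motif`,
#'   `region`, `n_replicates_detected` (no scores; see [score_sites()]).
#' @export
call_sites <- function(pileups, models, params = site_call_params()) {
  pu <- as.data.table(pileups)[assay == "miclip"]
  lens <- vapply(models, `[[`, integer(1), "length")
  if (!all(pu$transcript_id %in% names(models))) {
    stop("pileup rows reference transcripts absent from the models")
  }
  if (any(pu$tpos < 0L | pu$tpos >= lens[pu$transcript_id])) {
    stop("pileup position outside transcript bounds")
  }
  cand <- pu[coverage >= params$min_coverage]
  if (nrow(cand) == 0L) return(empty_site_table())
  cand[, frac := mutation_count / coverage]
  cand[, p_value := pbinom(mutation_count - 1L, coverage,
                           params$background_rate, lower.tail = FALSE)]
  cand[, p_adj := p.adjust(p_value, method = "BH"), by = replicate]
  cand <- cand[p_adj <= params$alpha & frac >= params$r_bounds[1] &
                 frac <= params$r_bounds[2]]
  if (nrow(cand) == 0L) return(empty_site_table())
  cand[, tpos := tpos - params$crosslink_offset]
  cand <- cand[tpos >= 2L & tpos <= lens[transcript_id] - 3L]
  if (nrow(cand) == 0L) return(empty_site_table())
  det <- cand[, list(n_replicates_detected = length(unique(replicate))),
              by = c("transcript_id", "tpos")]
  det <- det[n_replicates_detected >= params$min_replicates_detected]
  if (nrow(det) == 0L) return(empty_site_table())
  det[, motif := {
    m <- models[[transcript_id[1L]]]
    if (is.null(m$sequence)) stop("missing sequence for ", m$transcript_id)
    substr_kmer(m$sequence, tpos)
  }, by = transcript_id]
  det <- det[drach_match(motif)]
  if (nrow(det) == 0L) return(empty_site_table())
  det[, gene_id := vapply(models[transcript_id], `[[`, character(1),
                          "gene_id")]
  det[, region := {
    m <- models[[transcript_id[1L]]]
    if (is_coding(m)) assign_site_region(m, tpos) else NA_character_
  }, by = transcript_id]
  setorder(det, transcript_id, tpos)
  det[, list(transcript_id, gene_id, tpos, motif, region,
             n_replicates_detected)]
}

empty_site_table <- function() {
  data.table(transcript_id = character(0), gene_id = character(0),
             tpos = integer(0), motif = character(0), region = character(0),
             n_replicates_detected = integer(0))
}

#' Window uTPM: unique tags per million in a window around a site
#'
#' Counts unique tags overlapping the window `[tpos - halfwidth,
#' tpos + halfwidth]`, clipped to the transcript bounds (no mirroring), and
#' scales by the library's total unique tags: `uTPM = tags * 1e6 /
#' library_total`. Tags are point events at their recorded position.
#'
#' @param tag_pos Integer positions (0-based) with at least one tag.
#' @param tag_count Unique-tag counts at `tag_pos`.
#' @param tpos Site position (0-based).
#' @param library_total Total unique tags in the library (> 0).
#' @param tlen Transcript length.
#' @param halfwidth Window half-width (default 10, i.e. a 21-nt window).
#' @return uTPM value (non-negative scalar).
#' @export
window_utpm <- function(tag_pos, tag_count, tpos, library_total, tlen,
                        halfwidth = 10L) {
  if (library_total <= 0) stop("library total must be positive")
  lo <- max(0L, tpos - halfwidth)
  hi <- min(tlen - 1L, tpos + halfwidth)
  inw <- tag_pos >= lo & tag_pos <= hi
  sum(tag_count[inw]) * 1e6 / library_total
}

#' Normalized-to-input uTPM ratio
#'
#' `(miclip + eps) / (input + eps)`. With the default `eps = 0`, a site with
#' zero input uTPM is unquantifiable and callers drop it.
#'
#' @param miclip_utpm,input_utpm Non-negative uTPM values.
#' @param eps Pseudocount (default 0).
#' @return Ratio, or `NA` when `input + eps == 0`.
#' @export
normalized_utpm <- function(miclip_utpm, input_utpm, eps = 0) {
  out <- (miclip_utpm + eps) / (input_utpm + eps)
  out[(input_utpm + eps) == 0] <- NA_real_
  out
}

#' Score called sites: per-replicate and mean normalized-to-input uTPM
#'
#' For each site and replicate, computes the 21-nt-window uTPM in the miCLIP
#' and matched input libraries and their ratio. Sites whose input uTPM is
#' zero in any replicate (with `eps = 0`) are excluded with a warning as
#' unquantifiable.
#'
#' @param sites Site table from [call_sites()] (or any table with
#'   `transcript_id`, `tpos`).
#' @param pileups Pileup `data.table` (both assays).
#' @param lib_totals `data.table` with `assay`, `replicate`, `lib_total`.
#' @param models Named list of `transcript_model`.
#' @param halfwidth Window half-width (default 10).
#' @param eps Pseudocount passed to [normalized_utpm()].
#' @return `data.table`: site columns plus `replicate`, `miclip_utpm`,
#'   `input_utpm`, `normalized_utpm` in `$by_replicate`, and per-site means
#'   in `$sites` (adds `mean_normalized_utpm`).
#' @export
score_sites <- function(sites, pileups, lib_totals, models,
                        halfwidth = 10L, eps = 0) {
  sites <- as.data.table(sites)
  pu <- as.data.table(pileups)
  lt <- as.data.table(lib_totals)
  if (any(lt$lib_total <= 0)) stop("library total must be positive")
  reps <- sort(unique(pu$replicate))
  # per (assay, replicate, transcript) cumulative tag counts -> O(1) windows
  cums <- new.env(parent = emptyenv())
  for (grp in split(pu, paste(pu$assay, pu$replicate, pu$transcript_id))) {
    tlen <- models[[grp$transcript_id[1L]]]$length
    v <- numeric(tlen)
    v[grp$tpos + 1L] <- grp$unique_tag_count
    assign(paste(grp$assay[1L], grp$replicate[1L], grp$transcript_id[1L]),
           cumsum(v), envir = cums)
  }
  win_sum <- function(a, r, tid, p, tlen) {
    key <- paste(a, r, tid)
    if (!exists(key, envir = cums)) return(0)
    cs <- get(key, envir = cums)
    lo <- max(0L, p - halfwidth); hi <- min(tlen - 1L, p + halfwidth)
    cs[hi + 1L] - (if (lo > 0L) cs[lo] else 0)
  }
  totals <- setNames(lt$lib_total, paste(lt$assay, lt$replicate))
  per <- rbindlist(lapply(reps, function(r) {
    tlen <- vapply(models[sites$transcript_id], `[[`, integer(1), "length")
    mi <- vapply(seq_len(nrow(sites)), function(i) {
      win_sum("miclip", r, sites$transcript_id[i], sites$tpos[i], tlen[i])
    }, numeric(1))
    ip <- vapply(seq_len(nrow(sites)), function(i) {
      win_sum("input", r, sites$transcript_id[i], sites$tpos[i], tlen[i])
    }, numeric(1))
    data.table(transcript_id = sites$transcript_id, tpos = sites$tpos,
               replicate = r,
               miclip_utpm = mi * 1e6 / totals[[paste("miclip", r)]],
               input_utpm = ip * 1e6 / totals[[paste("input", r)]])
  }))
  if (nrow(per) == 0L) {
    return(list(sites = cbind(sites, mean_normalized_utpm = numeric(0)),
                by_replicate = per))
  }
  per[, normalized_utpm := normalized_utpm(miclip_utpm, input_utpm, eps)]
  agg <- per[, list(mean_normalized_utpm = mean(normalized_utpm)),
             by = c("transcript_id", "tpos")]
  out <- merge(sites, agg, by = c("transcript_id", "tpos"), sort = FALSE)
  bad <- is.na(out$mean_normalized_utpm)
  if (any(bad)) {
    warning(sum(bad), " site(s) with zero input uTPM excluded as ",
            "unquantifiable")
    drop_keys <- paste(out$transcript_id[bad], out$tpos[bad])
    out <- out[!bad]
    per <- per[!paste(transcript_id, tpos) %in% drop_keys]
  }
  setorder(out, transcript_id, tpos)
  list(sites = out[], by_replicate = per[])
}

#' Aggregate site scores into transcript-level SN-uTPM scores
#'
#' SN-uTPM is the sum of mean normalized-to-input uTPM over a transcript's
#' sites; per-region sums and per-nucleotide densities are reported for
#' coding transcripts, and region sums add up to the full-length sum.
#'
#' @param scored_sites Site table with `mean_normalized_utpm` (and `region`).
#' @param models Named list of `transcript_model`.
#' @return `data.table` with one row per transcript: site counts, `snutpm_*`
#'   sums and `density_*` per-nt values for full, utr5, cds, utr3.
#' @export
transcript_scores <- function(scored_sites, models) {
  ss <- as.data.table(scored_sites)
  info <- data.table(
    transcript_id = vapply(models, `[[`, character(1), "transcript_id"),
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    tlen = vapply(models, `[[`, integer(1), "length"),
    cds_start = vapply(models, `[[`, integer(1), "cds_start"),
    cds_end = vapply(models, `[[`, integer(1), "cds_end"))
  agg <- if (nrow(ss)) {
    ss[, list(n = .N, s = sum(mean_normalized_utpm)),
       by = c("transcript_id", "region")]
  } else {
    data.table(transcript_id = character(0), region = character(0),
               n = integer(0), s = numeric(0))
  }
  reg_sum <- function(rg) {
    v <- agg[agg$region == rg]
    setNames(v$s, v$transcript_id)
  }
  pull <- function(vec, ids) {
    out <- unname(vec[ids]); out[is.na(out)] <- 0; out
  }
  tot <- if (nrow(agg)) agg[, list(n = sum(n), s = sum(s)),
                            by = "transcript_id"] else agg
  out <- data.table(
    transcript_id = info$transcript_id, gene_id = info$gene_id,
    n_sites = as.integer(pull(setNames(tot$n, tot$transcript_id),
                              info$transcript_id)),
    snutpm_full = pull(setNames(tot$s, tot$transcript_id),
                       info$transcript_id))
  out[, `:=`(density_full = snutpm_full / info$tlen,
             snutpm_utr5 = pull(reg_sum("utr5"), transcript_id),
             snutpm_cds = pull(reg_sum("cds"), transcript_id),
             snutpm_utr3 = pull(reg_sum("utr3"), transcript_id))]
  u5 <- info$cds_start; cds <- info$cds_end - info$cds_start
  u3 <- info$tlen - info$cds_end
  out[, `:=`(
    density_utr5 = ifelse(u5 > 0L, snutpm_utr5 / u5, 0),
    density_cds = snutpm_cds / cds,
    density_utr3 = ifelse(u3 > 0L, snutpm_utr3 / u3, 0))]
  noncoding <- is.na(info$cds_start)
  for (col in c("snutpm_utr5", "snutpm_cds", "snutpm_utr3",
                "density_utr5", "density_cds", "density_utr3")) {
    out[noncoding, (col) := NA_real_]
  }
  out[]
}

#' Metagene density of sites over normalized 5'UTR/CDS/3'UTR coordinates
#'
#' Each site on a coding transcript maps to `u` in `[0,3)`: `tpos/utr5_len`
#' in the 5' UTR, `1 + (tpos - cds_start)/cds_len` in the CDS and
#' `2 + (tpos - cds_end)/utr3_len` in the 3' UTR, so the start codon sits at
#' `u = 1` and the stop codon boundary at `u = 2`. Sites on a zero-length
#' UTR land on the adjacent segment boundary bin and are counted once. The
#' returned histogram over `3 * n_bins` bins is normalized to sum 1.
#'
#' @param sites Site table with `transcript_id`, `tpos`.
#' @param models Named list of `transcript_model`.
#' @param n_bins Bins per segment (default 20).
#' @return `data.table` with `bin`, `u_lo`, `u_hi`, `u_mid`, `density`.
#' @export
metagene_density <- function(sites, models, n_bins = 20L) {
  st <- as.data.table(sites)
  u <- unlist(lapply(models, function(m) {
    if (!is_coding(m)) return(numeric(0))
    p <- st$tpos[st$transcript_id == m$transcript_id]
    if (length(p) == 0L) return(numeric(0))
    part <- partition_regions(m)
    reg <- assign_site_region(m, p)
    out <- numeric(length(p))
    out[reg == "utr5"] <- if (part[["utr5_len"]] > 0L) {
      p[reg == "utr5"] / part[["utr5_len"]]
    } else 1
    out[reg == "cds"] <- 1 +
      (p[reg == "cds"] - m$cds_start) / part[["cds_len"]]
    out[reg == "utr3"] <- if (part[["utr3_len"]] > 0L) {
      2 + (p[reg == "utr3"] - m$cds_end) / part[["utr3_len"]]
    } else 2
    out
  }))
  breaks <- seq(0, 3, length.out = 3L * n_bins + 1L)
  cnt <- tabulate(findInterval(u, breaks, rightmost.closed = TRUE),
                  nbins = 3L * n_bins)
  dens <- if (sum(cnt) > 0L) cnt / sum(cnt) else rep(0, 3L * n_bins)
  data.table(bin = seq_len(3L * n_bins),
             u_lo = breaks[-length(breaks)], u_hi = breaks[-1L],
             u_mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
             density = dens)
}

#' Pairwise replicate concordance of per-site normalized uTPM
#'
#' Spearman rank correlation over shared sites for every replicate pair.
#'
#' @param by_replicate `$by_replicate` table from [score_sites()].
#' @return `data.table` with `replicate_a`, `replicate_b`, `spearman_rho`.
#' @export
replicate_concordance <- function(by_replicate) {
  br <- as.data.table(by_replicate)
  reps <- sort(unique(br$replicate))
  if (length(reps) < 2L) stop("need at least two replicates")
  br[, site_key := paste(transcript_id, tpos)]
  pairs <- combn(reps, 2L)
  rbindlist(lapply(seq_len(ncol(pairs)), function(j) {
    a <- br[replicate == pairs[1L, j]]
    b <- br[replicate == pairs[2L, j]]
    shared <- intersect(a$site_key, b$site_key)
    if (length(shared) < 2L) stop("fewer than 2 shared sites between ",
                                  "replicates ", pairs[1L, j], " and ",
                                  pairs[2L, j])
    rho <- cor(a$normalized_utpm[match(shared, a$site_key)],
               b$normalized_utpm[match(shared, b$site_key)],
               method = "spearman")
    data.table(replicate_a = pairs[1L, j], replicate_b = pairs[2L, j],
               spearman_rho = rho)
  }))
}

#' Write called sites as transcript-space BED6
#'
#' `chrom` = transcript id, 0-based half-open single-base interval at the
#' methylated A, `name` = motif, `score` = truncated
#' `100 * mean_normalized_utpm`, `strand` = `+` (transcript space).
#'
#' @param scored_sites Site table with `mean_normalized_utpm`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sites_bed <- function(scored_sites, path) {
  ss <- as.data.table(scored_sites)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t+",
                   ss$transcript_id, ss$tpos, ss$tpos + 1L, ss$motif,
                   as.integer(trunc(100 * ss$mean_normalized_utpm)))
  writeLines(lines, path)
  invisible(path)
}
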