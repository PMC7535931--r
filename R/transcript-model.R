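#' Transcript models: exon structure, CDS boundaries and coordinate mapping
#'
#' A `transcript_model` is the package's central annotation object: an ordered
#' exon chain on a chromosome plus (for mRNAs) CDS boundaries expressed in
#' spliced-transcript coordinates. All internal coordinates are 0-based,
#' half-open; GTF input/output uses the standard 1-based closed convention.
#'
#' @param transcript_id,gene_id Character identifiers.
#' @param chrom Chromosome (sequence) name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of genomic `[start, end)` intervals,
#'   0-based half-open, pairwise disjoint. Rows may be given in any genomic
#'   order; they are stored sorted 5'->3' in transcript orientation.
#' @param cds_start,cds_end CDS boundaries as 0-based half-open offsets along
#'   the spliced transcript, or `NA` for non-coding transcripts.
#' @param sequence Optional spliced transcript sequence (character), length
#'   equal to the transcript length.
#'
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds_start = NA_integer_, cds_end = NA_integer_,
                             sequence = NULL) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L)
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-' for transcript ", transcript_id)
  }
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 2L] <= exons[, 1L])) {
    stop("empty or inverted exon interval in transcript ", transcript_id)
  }
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  # store in transcript orientation: minus-strand transcripts start at the
  # 3'-most genomic exon
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  len <- sum(exons[, 2L] - exons[, 1L])
  coding <- !is.na(cds_start) && !is.na(cds_end)
  if (coding) {
    cds_start <- as.integer(cds_start)
    cds_end <- as.integer(cds_end)
    if (!(cds_start >= 0L && cds_start < cds_end && cds_end <= len)) {
      stop("CDS boundaries [", cds_start, ",", cds_end,
           ") outside transcript of length ", len, ": ", transcript_id)
    }
  } else {
    cds_start <- NA_integer_
    cds_end <- NA_integer_
  }
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != len) {
      stop("sequence length ", nchar(sequence), " != transcript length ",
           len, ": ", transcript_id)
    }
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons, length = len,
         cds_start = cds_start, cds_end = cds_end, sequence = sequence),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cds <- if (is_coding(x)) sprintf("CDS [%d,%d)", x$cds_start, x$cds_end)
         else "non-coding"
  cat(sprintf("<transcript_model> %s (%s) %s:%s, %d exon(s), length %d, %s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), x$length, cds))
  invisible(x)
}

#' Test whether a transcript model carries a CDS
#' @param t A `transcript_model`.
#' @return Logical scalar.
#' @export
is_coding <- function(t) !is.na(t$cds_start) && !is.na(t$cds_end)

#' Map a genomic position to a spliced-transcript offset
#'
#' Strand-aware: on the minus strand offsets count from the 3'-most genomic
#' exon end (the first transcribed base).
#'
#' @param t A `transcript_model`.
#' @param gpos Genomic position, 0-based.
#' @return 0-based offset along the spliced transcript.
#' @export
genomic_to_transcript <- function(t, gpos) {
  gpos <- as.integer(gpos)
  ex <- t$exons
  hit <- which(gpos >= ex[, 1L] & gpos < ex[, 2L])
  if (length(hit) != 1L) {
    stop("position ", gpos, " is not exonic in transcript ", t$transcript_id)
  }
  widths <- ex[, 2L] - ex[, 1L]
  before <- if (hit > 1L) sum(widths[seq_len(hit - 1L)]) else 0L
  within <- if (t$strand == "+") gpos - ex[hit, 1L]
            else ex[hit, 2L] - 1L - gpos
  as.integer(before + within)
}

#' Map a spliced-transcript offset back to its genomic position
#'
#' Inverse of [genomic_to_transcript()].
#'
#' @param t A `transcript_model`.
#' @param tpos 0-based transcript offset.
#' @return 0-based genomic position.
#' @export
transcript_to_genomic <- function(t, tpos) {
  tpos <- as.integer(tpos)
  if (tpos < 0L || tpos >= t$length) {
    stop("transcript position ", tpos, " out of range [0,", t$length,
         ") in ", t$transcript_id)
  }
  ex <- t$exons
  widths <- ex[, 2L] - ex[, 1L]
  ends <- cumsum(widths)
  hit <- which(tpos < ends)[1L]
  within <- tpos - (if (hit > 1L) ends[hit - 1L] else 0L)
  if (t$strand == "+") as.integer(ex[hit, 1L] + within)
  else as.integer(ex[hit, 2L] - 1L - within)
}

#' Partition a coding transcript into 5' UTR, CDS and 3' UTR lengths
#'
#' @param t A coding `transcript_model`.
#' @return Named integer vector `c(utr5_len, cds_len, utr3_len)`, summing to
#'   the transcript length.
#' @export
partition_regions <- function(t) {
  if (!is_coding(t)) {
    stop("region partition undefined for non-coding transcript ",
         t$transcript_id)
  }
  c(utr5_len = t$cds_start,
    cds_len = t$cds_end - t$cds_start,
    utr3_len = t$length - t$cds_end)
}

#' Assign a transcript position to a region
#'
#' Half-open interval membership: `[0, cds_start)` is 5' UTR,
#' `[cds_start, cds_end)` is CDS, `[cds_end, length)` is 3' UTR.
#'
#' @param t A coding `transcript_model`.
#' @param tpos Transcript position(s), 0-based. Vectorized.
#' @return Character vector over `{"utr5","cds","utr3"}`.
#' @export
assign_site_region <- function(t, tpos) {
  if (!is_coding(t)) {
    stop("region assignment undefined for non-coding transcript ",
         t$transcript_id)
  }
  tpos <- as.integer(tpos)
  if (any(tpos < 0L | tpos >= t$length)) {
    stop("transcript position out of range in ", t$transcript_id)
  }
  ifelse(tpos < t$cds_start, "utr5",
         ifelse(tpos < t$cds_end, "cds", "utr3"))
}

#' Read transcript models from a GTF file
#'
#' Expects the standard GTF dialect (1-based closed coordinates; `exon` and
#' `CDS` features carrying `gene_id` and `transcript_id` attributes; CDS
#' features nested within exons). Transcripts without CDS features are
#' returned as non-coding models. When `fasta_path` is given, spliced
#' transcript sequences keyed by transcript id are attached.
#'
#' @param gtf_path Path to a GTF file.
#' @param fasta_path Optional path to a FASTA of spliced transcript sequences.
#' @return Named list of `transcript_model` objects (names = transcript ids).
#' @export
read_annotation <- function(gtf_path, fasta_path = NULL) {
  lines <- readLines(gtf_path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1L]]
    stop("malformed GTF line ", bad, " in ", gtf_path,
         ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(df) == 0L) stop("no exon/CDS features in ", gtf_path)

  seqs <- NULL
  if (!is.null(fasta_path)) {
    ss <- Biostrings::readDNAStringSet(fasta_path)
    seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }

  models <- lapply(split(df, df$transcript_id), function(d) {
    txid <- d$transcript_id[1L]
    strand <- as.character(d$strand[1L])
    ex <- d[d$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) stop("transcript ", txid, " has no exon features")
    # GRanges is 1-based closed -> 0-based half-open
    exons <- cbind(ex$start - 1L, ex$end)
    m <- transcript_model(txid, as.character(d$gene_id[1L]),
                          as.character(d$seqnames[1L]), strand, exons)
    cds <- d[d$type == "CDS", , drop = FALSE]
    if (nrow(cds) > 0L) {
      gstarts <- cds$start - 1L
      gends <- cds$end - 1L
      tp <- unlist(lapply(seq_len(nrow(cds)), function(i) {
        c(tryCatch(genomic_to_transcript(m, gstarts[i]),
                   error = function(e) stop("CDS of ", txid,
                                            " falls outside its exons")),
          tryCatch(genomic_to_transcript(m, gends[i]),
                   error = function(e) stop("CDS of ", txid,
                                            " falls outside its exons")))
      }))
      m <- transcript_model(txid, m$gene_id, m$chrom, strand, m$exons,
                            cds_start = min(tp), cds_end = max(tp) + 1L)
    }
    if (!is.null(seqs)) {
      if (!txid %in% names(seqs)) {
        stop("no sequence for transcript ", txid, " in FASTA")
      }
      m$sequence <- toupper(seqs[[txid]])
      if (nchar(m$sequence) != m$length) {
        stop("sequence length mismatch for ", txid)
      }
    }
    m
  })
  models[order(names(models))]
}

#' Write transcript models to a GTF file
#'
#' Emits `transcript`, `exon` and `CDS` features in the 1-based closed GTF
#' convention; output is byte-deterministic for a given model list.
#'
#' @param models Named list of `transcript_model` objects.
#' @param gtf_path Output path.
#' @return Invisibly, `gtf_path`.
#' @export
write_gtf <- function(models, gtf_path) {
  fmt <- function(chrom, feat, start0, end0, strand, gid, tid) {
    sprintf(paste0("%s\tm6apipe\t%s\t%d\t%d\t.\t%s\t.\t",
                   "gene_id \"%s\"; transcript_id \"%s\";"),
            chrom, feat, start0 + 1L, end0, strand, gid, tid)
  }
  out <- unlist(lapply(models, function(m) {
    ex <- m$exons[order(m$exons[, 1L]), , drop = FALSE]
    lines <- c(
      fmt(m$chrom, "transcript", min(ex[, 1L]), max(ex[, 2L]), m$strand,
          m$gene_id, m$transcript_id),
      fmt(m$chrom, "exon", ex[, 1L], ex[, 2L], m$strand,
          m$gene_id, m$transcript_id))
    if (is_coding(m)) {
      gpos <- vapply(c(m$cds_start, m$cds_end - 1L),
                     function(p) transcript_to_genomic(m, p), integer(1))
      glo <- min(gpos); ghi <- max(gpos)
      # intersect genomic CDS span with exons
      keep <- ex[, 2L] > glo & ex[, 1L] <= ghi
      cds <- ex[keep, , drop = FALSE]
      cds[, 1L] <- pmax(cds[, 1L], glo)
      cds[, 2L] <- pmin(cds[, 2L], ghi + 1L)
      lines <- c(lines, fmt(m$chrom, "CDS", cds[, 1L], cds[, 2L], m$strand,
                            m$gene_id, m$transcript_id))
    }
    lines
  }))
  writeLines(out, gtf_path)
  invisible(gtf_path)
}

#' Write spliced transcript sequences to FASTA
#'
#' @param models Named list of `transcript_model` objects with sequences.
#' @param fasta_path Output path.
#' @return Invisibly, `fasta_path`.
#' @export
write_transcript_fasta <- function(models, fasta_path) {
  seqs <- vapply(models, function(m) {
    if (is.null(m$sequence)) stop("no sequence on ", m$transcript_id)
    m$sequence
  }, character(1))
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, fasta_path)
  invisible(fasta_path)
}
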