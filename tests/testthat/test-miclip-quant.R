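test_that("drach_match implements the degenerate consensus", {
  expect_true(drach_match("GGACU"))
  expect_true(drach_match("GGACT"))
  expect_false(drach_match("GCACU"))
  expect_error(drach_match("GGAC"), "5-mers")
  # brute-force enumeration of all 4^5 k-mers
  bases <- c("A", "C", "G", "T")
  all5 <- do.call(paste0, expand.grid(bases, bases, bases, bases, bases))
  expect_identical(sum(drach_match(all5)), 18L)
  # agreement with an independent regular-expression oracle
  expect_identical(drach_match(all5),
                   grepl("^[AGT][AG]AC[ACT]$", all5))
})

test_that("window_utpm follows its definition and clips at bounds", {
  expect_equal(window_utpm(50L, 40L, 50L, 2e6, 1000L), 20)
  expect_equal(window_utpm(integer(0), integer(0), 50L, 2e6, 1000L), 0)
  expect_error(window_utpm(1L, 1L, 1L, 0, 100L), "positive")
  # site at tpos 3: window [0,13], no mirroring below 0
  tagpos <- 0:20; counts <- rep(1L, 21L)
  expect_equal(window_utpm(tagpos, counts, 3L, 1e6, 1000L), 14)
})

test_that("window_utpm equals the brute-force per-tag scan", {
  set.seed(42)
  for (i in 1:50) {
    tlen <- sample(50:1000, 1L)
    npos <- sample(1:30, 1L)
    tag_pos <- sample(seq_len(tlen) - 1L, npos)
    tag_count <- sample(1:20, npos, replace = TRUE)
    tpos <- sample(seq_len(tlen) - 1L, 1L)
    lib <- sample(1e5:1e6, 1L)
    expect_equal(window_utpm(tag_pos, tag_count, tpos, lib, tlen),
                 brute_window_utpm(tag_pos, tag_count, tpos, lib, tlen))
  }
})

test_that("normalized_utpm handles ratios, identities and zero input", {
  expect_equal(normalized_utpm(20, 5), 4)
  expect_equal(normalized_utpm(7, 7), 1)
  expect_equal(normalized_utpm(0, 5), 0)
  expect_true(is.na(normalized_utpm(3, 0)))
  expect_equal(normalized_utpm(3, 0, eps = 1), 4 / 1)
})

test_that("call_sites applies every filter of the CIMS-style procedure", {
  seqstr <- paste(rep("C", 100), collapse = "")
  substr(seqstr, 49, 53) <- "GGACT"  # DRACH centred at 0-based 50
  m <- transcript_model("T1", "G1", "c", "+", rbind(c(0L, 100L)),
                        cds_start = 10L, cds_end = 70L, sequence = seqstr)
  params <- site_call_params(min_replicates_detected = 1L)
  # candidate at p=51, offset +1 -> inferred A at 50 with DRACH context
  pu <- toy_pileup(tpos = c(51L, 60L), coverage = c(100L, 100L),
                   mutation_count = c(20L, 0L))
  out <- call_sites(pu, list(T1 = m), params)
  expect_identical(nrow(out), 1L)
  expect_identical(out$tpos, 50L)
  expect_identical(out$motif, "GGACT")
  expect_identical(out$region, "cds")
  # motif violation (R position = C) rejects the site
  seq2 <- seqstr; substr(seq2, 49, 53) <- "GCACT"
  m2 <- transcript_model("T1", "G1", "c", "+", rbind(c(0L, 100L)),
                         cds_start = 10L, cds_end = 70L, sequence = seq2)
  expect_identical(nrow(call_sites(pu, list(T1 = m2), params)), 0L)
  # zero mutations -> empty
  pu0 <- toy_pileup(51L, 100L, 0L)
  expect_identical(nrow(call_sites(pu0, list(T1 = m), params)), 0L)
  # mutation fraction above r_hi rejected
  pu_hi <- toy_pileup(51L, 100L, 80L)
  expect_identical(nrow(call_sites(pu_hi, list(T1 = m), params)), 0L)
  # coverage below threshold rejected
  pu_lo <- toy_pileup(51L, 5L, 3L)
  expect_identical(nrow(call_sites(pu_lo, list(T1 = m), params)), 0L)
  # replicate support requirement
  params2 <- site_call_params(min_replicates_detected = 2L)
  expect_identical(nrow(call_sites(pu, list(T1 = m), params2)), 0L)
  pu2 <- rbind(pu, toy_pileup(51L, 90L, 18L, replicate = 2L))
  expect_identical(nrow(call_sites(pu2, list(T1 = m), params2)), 1L)
  # out-of-bounds pileup position errors
  pu_bad <- toy_pileup(150L, 50L, 10L)
  expect_error(call_sites(pu_bad, list(T1 = m), params), "outside")
})

test_that("score_sites excludes zero-input sites as unquantifiable", {
  seqstr <- paste(rep("C", 100), collapse = "")
  substr(seqstr, 49, 53) <- "GGACT"
  m <- transcript_model("T1", "G1", "c", "+", rbind(c(0L, 100L)),
                        cds_start = 10L, cds_end = 70L, sequence = seqstr)
  sites <- data.table::data.table(transcript_id = "T1", tpos = 50L,
                                  motif = "GGACT", region = "cds")
  pu <- toy_pileup(50L, 40L, 0L)  # miCLIP only; no input tags at all
  lt <- data.table::data.table(assay = c("miclip", "input"),
                               replicate = 1L, lib_total = c(1e6, 1e6))
  expect_warning(out <- score_sites(sites, pu, lt, list(T1 = m)),
                 "unquantifiable")
  expect_identical(nrow(out$sites), 0L)
  # with input signal the ratio is as defined
  pu2 <- rbind(pu, toy_pileup(52L, 10L, 0L, assay = "input"))
  out2 <- score_sites(sites, pu2, lt, list(T1 = m))
  expect_equal(out2$sites$mean_normalized_utpm, 40 / 10)
})

test_that("transcript_scores sums per region with densities", {
  m <- transcript_model("T1", "G1", "c", "+", rbind(c(0L, 300L)),
                        cds_start = 100L, cds_end = 250L)
  ss <- data.table::data.table(
    transcript_id = "T1", tpos = c(120L, 200L),
    region = c("cds", "cds"), mean_normalized_utpm = c(2, 3))
  out <- transcript_scores(ss, list(T1 = m))
  expect_equal(out$snutpm_cds, 5)
  expect_equal(out$density_cds, 5 / 150)
  expect_equal(out$snutpm_full, 5)
  # no sites -> zeros
  out0 <- transcript_scores(ss[0], list(T1 = m))
  expect_equal(out0$snutpm_full, 0)
  expect_equal(out0$density_cds, 0)
  # single 3' UTR site: full = utr3 sum
  s3 <- data.table::data.table(transcript_id = "T1", tpos = 260L,
                               region = "utr3", mean_normalized_utpm = 1)
  out3 <- transcript_scores(s3, list(T1 = m))
  expect_equal(out3$snutpm_full, out3$snutpm_utr3)
  expect_equal(out3$snutpm_full, 1)
})

test_that("region sums add to the full-length sum on synthetic data", {
  ds <- default_dataset()
  scored <- default_scored()
  tsc <- transcript_scores(scored$sites, ds$models)
  expect_equal(tsc$snutpm_full,
               tsc$snutpm_utr5 + tsc$snutpm_cds + tsc$snutpm_utr3)
})

test_that("metagene coordinates place codon boundaries correctly", {
  m <- transcript_model("T1", "G1", "c", "+", rbind(c(0L, 300L)),
                        cds_start = 100L, cds_end = 250L)
  sites <- data.table::data.table(
    transcript_id = "T1", tpos = c(100L, 250L, 0L))
  mg <- metagene_density(sites, list(T1 = m), n_bins = 10L)
  expect_equal(sum(mg$density), 1)
  hit_bins <- mg$bin[mg$density > 0]
  # tpos 100 (cds_start) -> u = 1.0 -> first CDS bin (bin 11)
  expect_true(11L %in% hit_bins)
  # tpos 250 (cds_end) -> u = 2.0 -> first 3' UTR bin (bin 21)
  expect_true(21L %in% hit_bins)
  # tpos 0 -> u = 0 -> first bin
  expect_true(1L %in% hit_bins)
  # any input normalizes to 1
  ds <- default_dataset()
  mg2 <- metagene_density(ds$truth_sites, ds$models)
  expect_equal(sum(mg2$density), 1)
})

test_that("replicate concordance returns the expected correlations", {
  br <- data.table::data.table(
    transcript_id = "T1", tpos = rep(1:10, 2L),
    replicate = rep(1:2, each = 10L),
    normalized_utpm = c(1:10, 10:1))
  out <- replicate_concordance(br)
  expect_equal(out$spearman_rho, -1)
  br2 <- data.table::copy(br)
  br2$normalized_utpm <- rep(1:10, 2L)
  expect_equal(replicate_concordance(br2)$spearman_rho, 1)
  expect_error(replicate_concordance(br[br$replicate == 1L]),
               "two replicates")
})

test_that("site BED output carries motif and truncated score", {
  ss <- data.table::data.table(transcript_id = "T1", tpos = 5L,
                               motif = "GGACT",
                               mean_normalized_utpm = 1.239)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(ss, bed)
  expect_identical(readLines(bed), "T1\t5\t6\tGGACT\t123\t+")
})
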