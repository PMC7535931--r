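# Shared fixtures. Expensive synthetic runs are generated once per test
# session and cached here.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# full default synthetic dataset (the package's declared study conditions)
default_dataset <- function() {
  cached("default_dataset", simulate_dataset(sim_config(seed = 1)))
}

default_called <- function() {
  cached("default_called", {
    ds <- default_dataset()
    call_sites(ds$pileups, ds$models)
  })
}

default_scored <- function() {
  cached("default_scored", {
    ds <- default_dataset()
    score_sites(default_called(), ds$pileups, ds$lib_totals, ds$models)
  })
}

# two-exon plus-strand toy model used across coordinate tests
toy_model <- function() {
  transcript_model("T1", "G1", "chr1", "+",
                   rbind(c(100L, 200L), c(300L, 400L)),
                   cds_start = 50L, cds_end = 170L)
}

# a minimal pileup table for one transcript/replicate
toy_pileup <- function(tpos, coverage, mutation_count, replicate = 1L,
                       assay = "miclip", transcript_id = "T1") {
  data.table::data.table(
    transcript_id = transcript_id, tpos = as.integer(tpos), assay = assay,
    replicate = as.integer(replicate), coverage = as.integer(coverage),
    mutation_count = as.integer(mutation_count),
    unique_tag_count = as.integer(coverage))
}

# brute-force per-tag window count oracle (tags expanded one by one)
brute_window_utpm <- function(tag_pos, tag_count, tpos, lib_total, tlen,
                              halfwidth = 10L) {
  tags <- rep(tag_pos, tag_count)
  lo <- max(0L, tpos - halfwidth)
  hi <- min(tlen - 1L, tpos + halfwidth)
  sum(tags >= lo & tags <= hi) * 1e6 / lib_total
}
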