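#' Pipeline configuration
#'
#' One object holding every stage's parameters and the shared seed. The
#' single-cell filtering thresholds default to values matched to the
#' synthetic transcriptome's size; for real droplet data pass the
#' conventional `sc_min_genes = 1800`, `sc_min_cells = 10`.
#'
#' @param seed Integer seed driving every stage.
#' @param sim A [sim_config()] (defaults to `sim_config(seed = seed)`).
#' @param site_params A [site_call_params()].
#' @param window m6A quantification window width in nt (odd; default 21).
#' @param top_frac Top fraction for "highly modified"/"highly translated"
#'   selections (default 0.2).
#' @param z_cut Z classification threshold (default 1.96).
#' @param scale Single-cell per-cell normalization scale (default 10000).
#' @param n_perm Permutations for preranked GSEA (default 1000).
#' @param sc_min_genes,sc_min_cells Single-cell filtering thresholds.
#' @param metagene_bins Metagene bins per segment (default 20).
#' @param te_region Region metric used for the TE comparison (default
#'   `"cds"`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = NULL, site_params = NULL,
                            window = 21L, top_frac = 0.2, z_cut = 1.96,
                            scale = 1e4, n_perm = 1000L,
                            sc_min_genes = 20L, sc_min_cells = 10L,
                            metagene_bins = 20L, te_region = "cds") {
  if (window %% 2L != 1L || window < 1L) {
    stop("config error: window must be a positive odd width")
  }
  if (top_frac <= 0 || top_frac > 1) {
    stop("config error: top_frac must be in (0,1]")
  }
  structure(list(
    seed = as.integer(seed),
    sim = if (is.null(sim)) sim_config(seed = seed) else sim,
    site_params = if (is.null(site_params)) site_call_params()
                  else site_params,
    window = as.integer(window), top_frac = top_frac, z_cut = z_cut,
    scale = scale, n_perm = as.integer(n_perm),
    sc_min_genes = as.integer(sc_min_genes),
    sc_min_cells = as.integer(sc_min_cells),
    metagene_bins = as.integer(metagene_bins),
    te_region = te_region), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override [pipeline_config()] defaults; the `sim` and
#' `site_params` blocks override [sim_config()] / [site_call_params()]
#' defaults. Unknown keys are a schema error.
#'
#' @param path YAML file.
#' @param seed Optional seed overriding the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), c("sim", "site_params"))
  bad <- setdiff(names(y), c(known, "sim", "site_params"))
  if (length(bad)) {
    stop("schema error: unknown config key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(seed)) y$seed <- seed
  simargs <- y$sim
  if (!is.null(simargs)) {
    badsim <- setdiff(names(simargs), names(formals(sim_config)))
    if (length(badsim)) {
      stop("schema error: unknown sim key(s): ",
           paste(badsim, collapse = ", "))
    }
  }
  spargs <- y$site_params
  if (!is.null(spargs)) {
    badsp <- setdiff(names(spargs), names(formals(site_call_params)))
    if (length(badsp)) {
      stop("schema error: unknown site_params key(s): ",
           paste(badsp, collapse = ", "))
    }
  }
  seed_used <- if (!is.null(y$seed)) y$seed else formals(pipeline_config)$seed
  simargs$seed <- if (is.null(simargs$seed)) seed_used else simargs$seed
  y$sim <- do.call(sim_config, simargs)
  y$site_params <- do.call(site_call_params, as.list(spargs))
  do.call(pipeline_config, y)
}

stage_dir <- function(outdir, stage) file.path(outdir, stage)

require_stage <- function(outdir, stage, needed_by) {
  d <- stage_dir(outdir, stage)
  if (!dir.exists(d)) {
    stop("missing upstream artifacts for '", needed_by, "': run the '",
         stage, "' stage first (expected ", d, ")")
  }
  d
}

# write stage outputs atomically: build in <dir>.tmp, then rename into place
with_stage_dir <- function(outdir, stage, body) {
  final <- stage_dir(outdir, stage)
  tmp <- paste0(final, ".tmp")
  unlink(tmp, recursive = TRUE)
  dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  body(tmp)
  unlink(final, recursive = TRUE)
  file.rename(tmp, final)
  invisible(final)
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages over one output directory:
#' \describe{
#'   \item{simulate}{generate the synthetic dataset and write all inputs}
#'   \item{callsites}{CIMS-style site calling with DRACH filtering}
#'   \item{quantify}{normalized-to-input uTPM site scores, transcript
#'     SN-uTPM scores, metagene profile, replicate concordance}
#'   \item{integrate-te}{quintile/ECDF/Wilcoxon TE comparison, top-20
#'     overlap enrichment, preranked GSEA}
#'   \item{integrate-sc}{single-cell filtering, normalization, population
#'     classification, per-population Z scores, scatter table, flagged-set
#'     enrichment, occupancy chi-square}
#'   \item{all}{everything, in order}
#' }
#' Every invocation writes `manifest.json` (parameters, seed, output
#' digests, package version) into the output directory; reruns with the
#' same configuration and seed are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @param stage One of `"simulate"`, `"callsites"`, `"quantify"`,
#'   `"integrate-te"`, `"integrate-sc"`, `"all"`.
#' @param log Function used for progress messages (default [message()];
#'   pass `function(...) {}` to silence).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         stage = c("all", "simulate", "callsites", "quantify",
                                   "integrate-te", "integrate-sc"),
                         log = message) {
  stage <- match.arg(stage)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") {
    c("simulate", "callsites", "quantify", "integrate-te", "integrate-sc")
  } else stage

  for (s in stages) {
    log("[m6apipe] stage: ", s)
    switch(s,
      simulate = stage_simulate(config, outdir),
      callsites = stage_callsites(config, outdir),
      quantify = stage_quantify(config, outdir),
      `integrate-te` = stage_integrate_te(config, outdir),
      `integrate-sc` = stage_integrate_sc(config, outdir))
  }
  manifest <- build_manifest(config, outdir, stages)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

stage_simulate <- function(config, outdir) {
  ds <- simulate_dataset(config$sim)
  with_stage_dir(outdir, "simulate", function(d) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(ds$genome),
                                file.path(d, "genome.fa"))
    write_transcript_fasta(ds$models, file.path(d, "transcripts.fa"))
    write_gtf(ds$models, file.path(d, "annotation.gtf"))
    fwrite(ds$pileups, file.path(d, "pileups.tsv"), sep = "\t")
    fwrite(ds$lib_totals, file.path(d, "lib_totals.tsv"), sep = "\t")
    fwrite(ds$truth_sites, file.path(d, "truth_sites.tsv"), sep = "\t")
    fwrite(ds$te[, list(gene_id, te)], file.path(d, "te.tsv"), sep = "\t")
    write_sc_matrix(ds$sc$counts, file.path(d, "sc"), cells = ds$sc$cells)
    write_gmt(ds$gene_sets, file.path(d, "gene_sets.gmt"))
    jsonlite::write_json(
      list(markers = ds$sc$markers, ko_down_set = ds$sc$ko_down_set,
           ko_up_set = ds$sc$ko_up_set,
           expression = as.list(ds$expression),
           te_truth = ds$te[, list(gene_id, log_te, true_cds_density)]),
      file.path(d, "truth.json"), digits = NA)
  })
}

load_models <- function(outdir, needed_by) {
  d <- require_stage(outdir, "simulate", needed_by)
  read_annotation(file.path(d, "annotation.gtf"),
                  file.path(d, "transcripts.fa"))
}

stage_callsites <- function(config, outdir) {
  d <- require_stage(outdir, "simulate", "callsites")
  models <- load_models(outdir, "callsites")
  pileups <- fread(file.path(d, "pileups.tsv"))
  sites <- call_sites(pileups, models, config$site_params)
  with_stage_dir(outdir, "callsites", function(sd) {
    fwrite(sites, file.path(sd, "sites.tsv"), sep = "\t")
  })
}

stage_quantify <- function(config, outdir) {
  d <- require_stage(outdir, "simulate", "quantify")
  cd <- require_stage(outdir, "callsites", "quantify")
  models <- load_models(outdir, "quantify")
  pileups <- fread(file.path(d, "pileups.tsv"))
  lib_totals <- fread(file.path(d, "lib_totals.tsv"))
  sites <- fread(file.path(cd, "sites.tsv"))
  halfwidth <- (config$window - 1L) %/% 2L
  scored <- score_sites(sites, pileups, lib_totals, models,
                        halfwidth = halfwidth)
  tsc <- transcript_scores(scored$sites, models)
  meta <- metagene_density(scored$sites, models,
                           n_bins = config$metagene_bins)
  conc <- replicate_concordance(scored$by_replicate)
  with_stage_dir(outdir, "quantify", function(sd) {
    fwrite(scored$sites, file.path(sd, "site_scores.tsv"), sep = "\t")
    fwrite(scored$by_replicate, file.path(sd, "site_scores_by_replicate.tsv"),
           sep = "\t")
    write_sites_bed(scored$sites, file.path(sd, "sites.bed"))
    fwrite(tsc, file.path(sd, "transcript_scores.tsv"), sep = "\t")
    fwrite(meta, file.path(sd, "metagene.tsv"), sep = "\t")
    fwrite(conc, file.path(sd, "replicate_concordance.tsv"), sep = "\t")
  })
}

stage_integrate_te <- function(config, outdir) {
  d <- require_stage(outdir, "simulate", "integrate-te")
  qd <- require_stage(outdir, "quantify", "integrate-te")
  te <- fread(file.path(d, "te.tsv"))
  scores <- fread(file.path(qd, "transcript_scores.tsv"))
  sets <- read_gmt(file.path(d, "gene_sets.gmt"))
  cmp <- compare_te_by_m6a(scores, te, region = config$te_region)
  # top-20% m6A (chosen region) vs top-20% TE overlap enrichment
  q_te <- bin_quintiles(setNames(te$te, te$gene_id))
  shared <- cmp$quintiles$gene_id
  top_m6a <- cmp$quintiles$gene_id[cmp$quintiles$quintile == 5L]
  top_te <- intersect(q_te$gene_id[q_te$quintile == 5L], shared)
  both <- intersect(top_m6a, top_te)
  enr <- if (length(both)) overlap_enrichment(both, shared, sets) else NULL
  dens <- setNames(scores[[paste0("density_", config$te_region)]],
                   scores$gene_id)
  dens <- dens[is.finite(dens)]
  gsea <- rbindlist(lapply(names(sets), function(nm) {
    hits <- intersect(sets[[nm]], names(dens))
    if (length(hits) == 0L || length(hits) == length(dens)) return(NULL)
    g <- preranked_gsea(dens, sets[[nm]], n_perm = config$n_perm,
                        seed = config$seed)
    data.table(set_name = nm, es = g$es, perm_p = g$perm_p,
               n_hits = g$n_hits)
  }))
  with_stage_dir(outdir, "integrate-te", function(sd) {
    fwrite(cmp$quintiles, file.path(sd, "m6a_quintiles.tsv"), sep = "\t")
    fwrite(cmp$ecdf_top, file.path(sd, "ecdf_top.tsv"), sep = "\t")
    fwrite(cmp$ecdf_bottom, file.path(sd, "ecdf_bottom.tsv"), sep = "\t")
    jsonlite::write_json(
      list(region = config$te_region, U = cmp$U, p = cmp$p,
           median_top = cmp$median_top, median_bottom = cmp$median_bottom,
           n_top = cmp$n_top, n_bottom = cmp$n_bottom),
      file.path(sd, "wilcoxon.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(enr)) {
      fwrite(enr, file.path(sd, "overlap_enrichment.tsv"), sep = "\t")
    }
    if (nrow(gsea)) fwrite(gsea, file.path(sd, "gsea.tsv"), sep = "\t")
  })
}

stage_integrate_sc <- function(config, outdir) {
  d <- require_stage(outdir, "simulate", "integrate-sc")
  qd <- require_stage(outdir, "quantify", "integrate-sc")
  sc <- read_sc_matrix(file.path(d, "sc"))
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  scores <- fread(file.path(qd, "transcript_scores.tsv"))
  sets <- read_gmt(file.path(d, "gene_sets.gmt"))
  filtered <- filter_matrix(sc$counts, config$sc_min_genes,
                            config$sc_min_cells)
  norm <- normalize_log10(filtered, scale = config$scale)
  cells <- sc$cells[match(colnames(norm), sc$cells$cell_id)]
  pred_pop <- classify_cells(norm, truth$markers)
  zr <- rbindlist(lapply(names(truth$markers), function(p) {
    gene_z(norm, cells$condition, pred_pop, p, z_cut = config$z_cut)
  }))
  scatter <- build_scatter(zr, scores, top_frac = config$top_frac,
                           z_cut = config$z_cut)
  enr <- rbindlist(lapply(unique(scatter$population), function(p) {
    e <- flagged_set_enrichment(scatter[population == p], sets,
                                which = "up_top20")
    if (nrow(e)) cbind(population = p, e) else NULL
  }))
  occ <- table(cells$condition, pred_pop)
  occ <- occ[, colnames(occ) != "unassigned", drop = FALSE]
  chi <- chi_square_occupancy(occ)
  with_stage_dir(outdir, "integrate-sc", function(sd) {
    fwrite(data.table(cell_id = colnames(norm), condition = cells$condition,
                      population = pred_pop),
           file.path(sd, "cell_classification.tsv"), sep = "\t")
    fwrite(zr, file.path(sd, "gene_z.tsv"), sep = "\t")
    fwrite(scatter, file.path(sd, "scatter.tsv"), sep = "\t")
    if (nrow(enr)) fwrite(enr, file.path(sd, "enrichment.tsv"), sep = "\t")
    jsonlite::write_json(
      c(list(populations = colnames(occ)), chi),
      file.path(sd, "occupancy_chisq.json"), auto_unbox = TRUE, digits = NA)
  })
}

build_manifest <- function(config, outdir, stages) {
  files <- sort(list.files(outdir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  digests <- as.list(setNames(unname(tools::md5sum(files)),
                              sub(paste0("^", outdir, "/?"), "", files)))
  list(tool = "m6apipe",
       version = as.character(packageVersion("m6apipe")),
       seed = config$seed,
       stages = stages,
       parameters = list(
         window = config$window, top_frac = config$top_frac,
         z_cut = config$z_cut, scale = config$scale,
         n_perm = config$n_perm, sc_min_genes = config$sc_min_genes,
         sc_min_cells = config$sc_min_cells,
         metagene_bins = config$metagene_bins, te_region = config$te_region,
         site_params = unclass(config$site_params),
         sim = unclass(config$sim)),
       outputs = digests)
}
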