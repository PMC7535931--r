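# m6apipe

Transcript-centric analysis of N6-methyladenosine (m6A) epitranscriptomic
data: CIMS-style miCLIP site calling with DRACH filtering, window-based
normalized-to-input uTPM / SN-uTPM quantification, integration with
ribosome-profiling translation efficiency, and integration with
two-condition single-cell RNA-seq expression changes.

## Who this is for

Groups analysing miCLIP (m6A individual-nucleotide-resolution crosslinking
and immunoprecipitation) experiments alongside ribosome profiling and
single-cell RNA-seq — for example, asking whether heavily m6A-modified
mRNAs are more efficiently translated, and how transcripts with high
coding-sequence methylation respond when the m6A writer is knocked out.
All stages run on plain-text interchange formats (GTF, FASTA, TSV pileups,
GMT, MatrixMarket) and are exercised end to end on a built-in synthetic
data generator, so the pipeline is fully testable without any sequencing
data.

## The quantities at the core

For a called site *s* (a DRACH-context adenosine inferred from a
crosslink-induced mutation signature), with a 21-nt window *W(s)* centred
on it:

    uTPM(W)            = (unique tags overlapping W) x 10^6 / library total
    normalized uTPM(s) = uTPM_miCLIP(W(s)) / uTPM_input(W(s))   [per replicate, then averaged]

For a transcript *t* with site set *S(t)* and a region R in
{5' UTR, CDS, 3' UTR, full}:

    SN-uTPM(t, R)        = sum of normalized uTPM over sites of t in R
    SN-uTPM per nt(t, R) = SN-uTPM(t, R) / length(R)

`density_cds` — the *coding sequence SN-uTPM per nt* — is the default
metric joined against translation efficiency (quintile binning, ECDF,
Wilcoxon rank-sum) and against per-population single-cell Z scores
(`z = (mean_cKO − mean_Ctrl) / sqrt(s²_cKO/n_cKO + s²_Ctrl/n_Ctrl)`,
classified down/up at ±1.96).

## Worked example

```r
library(m6apipe)

# synthetic study conditions: 50 transcripts, 3 miCLIP/input replicate
# pairs, stop-codon-biased DRACH sites, planted TE and knockout effects
ds <- simulate_dataset(sim_config(seed = 1))

sites  <- call_sites(ds$pileups, ds$models, site_call_params())
scored <- score_sites(sites, ds$pileups, ds$lib_totals, ds$models)
tsc    <- transcript_scores(scored$sites, ds$models)

truth_keys  <- paste(ds$truth_sites$transcript_id, ds$truth_sites$tpos)
called_keys <- paste(sites$transcript_id, sites$tpos)
cat("precision:", mean(called_keys %in% truth_keys),
    " recall:", round(mean(truth_keys %in% called_keys), 3), "\n")
#> precision: 1  recall: 0.902

replicate_concordance(scored$by_replicate)
#>    replicate_a replicate_b spearman_rho
#> 1:           1           2    0.8511166
#> 2:           1           3    0.8516803
#> 3:           2           3    0.8730787

mg <- metagene_density(scored$sites, ds$models)
mg$u_mid[which.max(mg$density)]      # normalized coordinate: 2 = stop codon
#> [1] 1.975
```

The called sites recover the planted truth with perfect precision and 90%
recall, the per-site normalized uTPM is concordant across replicates
(Spearman rho 0.85–0.87), and the metagene profile peaks immediately 5'
of the stop codon (the modal bin covers the last 5% of the CDS, midpoint
at normalized coordinate 1.975) — the canonical m6A distribution.

Downstream, with a planted coupling between CDS m6A density and
translation efficiency (500 genes):

```r
cfg <- sim_config(seed = 1, n_transcripts = 500)
tx  <- simulate_transcriptome(cfg)
tr  <- plant_m6a_sites(tx$models, cfg)
te  <- simulate_te(tx$models, tr, cfg)
ts  <- data.table::copy(tr); ts$mean_normalized_utpm <- ts$methylation
cmp <- compare_te_by_m6a(transcript_scores(ts, tx$models), te, region = "cds")
cmp$p                                 # top vs bottom m6A quintile, Wilcoxon
#> [1] 2.562144e-34
```

The top m6A quintile is strongly shifted toward higher translation
efficiency when the CDS metric is used (p = 2.6e-34), and not when the 5'
UTR metric is used (p = 0.26) — the region specificity that motivates the
`density_cds` default.

The whole chain can also be driven as a pipeline with one configuration
and seed (`run_pipeline(pipeline_config(seed = 1), outdir = "out",
stage = "all")`, or `Rscript inst/scripts/m6a.R all --outdir out`); each
run writes stage directories plus a `manifest.json` with parameters and
output digests, and reruns with the same seed are byte-identical.

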