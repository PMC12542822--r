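# phosphodiff

Differential phosphoproteomics in R: from search-engine output tables to
differential phosphopeptide calls, localized phosphosites, kinase-motif
information-content matrices, gene-set over-representation, ward.D2
clustering, and a weighted differential analysis of DIA time courses —
plus a synthetic-data generator with full ground truth so the entire
pipeline is testable without any external download.

## Who this is for

Proteomics analysts working with TMT-multiplexed phospho-enrichment
experiments (e.g. a 6-plex contrasting three treated against three
control channels, such as a kinase-inhibition experiment in oocytes) and
with label-free DIA time courses at the protein-group level. The package
starts where the search engine stops: it consumes evidence-style PSM
tables with reporter intensities and phospho-STY localization
probabilities, protein-group tables, DIA report or protein-matrix TSVs,
protein FASTA, GMT gene sets and externally produced kinase-rank tables.

## The model in brief

Phosphopeptide reporter intensities are summed per sequence-PTM
combination and normalized by the parent protein group's corrected
intensity, so phosphorylation changes are separated from abundance
changes:

    r_fc = log2( I_phospho(f, c) / I_protein(f, c) )

Each feature is fit by least squares to the two-group mean model
`beta = mean(treatment) − mean(control)`; residual variances are shrunk
toward a scaled inverse-chi-square prior estimated by trigamma
method-of-moments, giving the moderated statistic

    t = beta / sqrt( s2_post * (1/n_c + 1/n_t) ),
    s2_post = (d0·s0² + d·s²) / (d0 + d)

with p-values on `d0 + d` degrees of freedom and Benjamini–Hochberg
control of the false discovery rate (significant at adjusted p ≤ 0.05).
PSMs are pre-filtered: decoys, contaminants, and PEP ≥ 0.01 are removed.
Localization probabilities are mean-aggregated across PSMs per peptide;
the argmax residue is the phosphosite, around which 15-mer windows feed
an enrichment-only information-content motif matrix scaled to [0, 1].
The DIA branch filters at precursor q ≤ 0.001 and protein-group
q ≤ 0.05, averages technical replicates, imputes missing cells by the
within-group minimum replicate intensity at weight 0.05, and calls a
protein reliably changed when adjusted p ≤ 0.05 *and* |log2FC| ≥ 0.5.
The full account is in `vignettes/phosphoproteomics-methods.Rmd`.

## Worked example

Simulate a 6-plex experiment with 10% of features truly dephosphorylated
(log2FC −1), run the stages, and compare the calls against the planted
truth:

```r
library(phosphodiff)

cfg <- sim_config(n_proteins = 500, peptides_per_protein = 2L,
                  effect_fraction = 0.1, effect_log2fc = -1, seed = 42)
sim <- generate_phospho_dataset(cfg)

fl <- filter_psms(sim$psms)
fl$report
#>   n_input removed_decoy removed_contaminant removed_pep retained
#> 1    1584            32                  32          70     1450

feats <- aggregate_psms_to_features(fl$psms)
rm_ <- compute_log_ratios(feats, sim$protein_groups, sim$design)
rm_
#> ratio_matrix: 972 features x 6 channels; parent match rate 100.0%

res <- diff_test(rm_)
sum(res$significant)
#> [1] 103      # 96 down / 7 up

head(res[order(res$p), c("feature_id", "log2fc", "t_mod", "p_adj")], 3)
#>            feature_id    log2fc     t_mod        p_adj
#>      WTVLMWS(ph)NAHVW -1.631056 -7.857060 8.441127e-07
#>     KWAT(ph)TTFRRKWTG -1.564668 -7.277506 2.790208e-06
#>  NGNLPS(ph)FKPTAETWPC -1.451252 -6.782922 7.517801e-06

truth <- sim$truth
tp <- res$significant &
  truth$true_effect[match(res$feature_id, truth$feature_id)] != 0
sum(tp) / sum(truth$true_effect != 0)   # sensitivity
#> [1] 0.94
mean(res$log2fc[tp])                    # effect recovery
#> [1] -1.049
```

The filter report shows the removal ledger (decoys, contaminants, and
PSMs at PEP ≥ 0.01, each record counted once); the ratio matrix prints
the fraction of phosphopeptides that found a parent-protein intensity;
and the differential table carries the moderated statistics. Here 94% of
planted dephosphorylation events are recovered at FDR 0.05 with the
effect estimated within 5% of its true value, and the calls are
overwhelmingly in the planted (down) direction.

`run_phospho_pipeline()` and `run_dia_pipeline()` execute the same
stages end to end, persisting every intermediate TSV plus a JSON
manifest of seeds, thresholds and per-stage counts; identical configs
give byte-identical outputs.

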