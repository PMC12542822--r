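---
title: "Models and methods behind phosphodiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phosphodiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphodiff)
```

phosphodiff implements a complete differential phosphoproteomics analysis
for two experimental designs: a TMT 6-plex experiment contrasting three
treated against three control reporter channels, and a label-free DIA time
course across developmental stages in two conditions. This vignette
explains the statistical model at each stage, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical conventions adopted where the design was
genuinely open.

## The quantification model

The unit of quantification in the phospho branch is the *sequence-PTM
combination*: a peptide sequence together with a specific placement of its
modifications. All PSMs sharing a modified sequence are summed per
reporter channel (`aggregate_psms_to_features()`), and the per-channel
phosphopeptide intensity is divided by its parent protein group's
corrected intensity before the log2 transform:

$$r_{fc} = \log_2 \frac{I^{\text{phospho}}_{fc}}{I^{\text{protein}}_{fc}}.$$

Dividing by the parent protein separates phosphorylation changes from
protein-abundance changes: a peptide whose protein doubles while its
phosphorylation stoichiometry is constant has a flat ratio profile. Cells
are missing unless both intensities are present and positive; a reporter
intensity of zero is treated as missing on input, following the common
search-engine convention that a zero reporter is an absent measurement,
not a measured zero. Features whose protein group contributes no
intensity in any channel are dropped from the matrix but counted in the
reported `match_rate` denominator, which mirrors how a fraction of
phosphopeptides in a real experiment lacks a total-protein match. An
exact consequence of the ratio construction, asserted in the tests, is
invariance to channel-level scaling: multiplying one channel's
intensities by any constant in both tables cancels in the ratio.

Protein groups are deliberately *not* post-filtered on peptide counts or
q-values (only decoy and contaminant entries are removed), maximizing the
number of phosphopeptides that keep a parent intensity.

## Confidence filtering

`filter_psms()` removes reverse-decoy matches, potential contaminants,
and low-confidence PSMs. The PEP boundary is strict: a record with
posterior error probability exactly equal to the threshold (default 0.01)
is removed, i.e. the retained set is `pep < 0.01`. A record failing
several criteria is counted once in the removal report, with priority
decoy > contaminant > PEP, so the per-reason counts and the retained
count always partition the input — a conservation property the pipeline
manifest records at every filtering stage. In the DIA branch the
precursor and protein-group q-value bounds (0.001 and 0.05) are instead
*inclusive*, matching their usual statement as "Q value ≤ ...".

## The moderated two-group model

For each feature the per-channel ratios are fit by (weighted) least
squares to a two-group mean model. The effect is
$\beta = \bar r_{\text{trt}} - \bar r_{\text{ctl}}$, the residual
variance $s^2$ sits on $d = n_{\text{obs}} - 2$ degrees of freedom, and
the design scale is $v = 1/w_{\text{ctl}} + 1/w_{\text{trt}}$ with
$w_g$ the sum of weights in group $g$; with unit weights this is exactly
the pooled two-sample estimator. Features with fewer than two
observations in either group are excluded before prior estimation and
reported.

Variances are then shrunk toward a scaled inverse-chi-square prior with
hyperparameters $(d_0, s_0^2)$ estimated by method of moments on the log
scale. With

$$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2),$$

the prior degrees of freedom solve
$\psi'(d_0/2) = \operatorname{var}(e) - \overline{\psi'(d_g/2)}$ by
Newton inversion of the trigamma function (tolerance $10^{-8}$), and
$s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$. When the spread of
the log variances does not exceed what sampling noise alone explains, the
prior degrees of freedom are infinite and $s_0^2 = \exp(\bar e)$. The
moderated statistic is

$$\tilde t = \frac{\beta}{\sqrt{\tilde s^2 v}}, \qquad
  \tilde s^2 = \frac{d_0 s_0^2 + d s^2}{d_0 + d},$$

with two-sided p-values from the t distribution on $d_0 + d$ degrees of
freedom (the normal tail when $d_0 = \infty$; the ordinary two-sample t
when $d_0 = 0$). Multiple testing uses the Benjamini–Hochberg step-up
procedure, and a feature is significant when the adjusted p-value is at
or below $\alpha = 0.05$ — the boundary value itself is significant. Two
useful bracketing facts are asserted as properties in the test suite:
$\tilde s^2$ always lies between $\min(s^2, s_0^2)$ and
$\max(s^2, s_0^2)$, and with $d_0 = 0$ the classical pooled t-test is
recovered exactly.

No fold-change threshold is applied in the phospho branch; the DIA branch
adds one (below) because protein-level label-free quantification warrants
an effect-size floor.

## Phosphosite localization and motifs

Per-residue phospho-STY localization probabilities are mean-aggregated
across all PSMs of a peptide sequence, with a position absent from one
PSM's vector contributing zero for that PSM — the denominator is always
the full PSM count. The position with the highest mean is treated as the
phosphosite; exact ties resolve to the lowest position for determinism.
Aggregation is over the plain peptide sequence (not the modified
sequence), so evidence from differently-annotated PSMs of the same
peptide pools into one localization estimate.

Motif analysis centers a $(2w+1)$-mer window from the parent protein
sequence on each phosphosite. The half-width defaults to $w = 7$ (a
15-mer), the conventional kinase-motif window. Terminal overhangs are
padded with `-`, which is excluded from the frequency counts. The
information-content matrix compares foreground windows (significantly
dephosphorylated peptides) to background windows (all dephosphorylated
peptides):

$$\mathrm{IC}_{p,a} = \min\!\left(1,
  \frac{\max\{0,\; f_{p,a} \log_2 (f_{p,a}/b_{p,a})\}}{\log_2 20}\right),$$

an enrichment-only (clipped) logo scaled so a residue fully conserved in
the foreground against a uniform background scores exactly 1.
Kinase-specific motifs subset the foreground to peptides having the
kinase of interest among their top 10 externally-predicted upstream
kinases (rank 10 inclusive); the kinase prediction itself is an external
service whose (peptide, kinase, rank) output is consumed as a table.

## Enrichment and clustering

Over-representation of differential proteins (any significantly changed
peptide promotes its protein into the query) against GMT gene-set
collections uses the one-sided upper-tail hypergeometric test with BH
adjustment across tested terms. The universe defaults to all quantified
protein groups and is configurable; sets are restricted to the universe
before testing. The BH choice replaces service-specific adjustment
strategies and is recorded in the result's metadata. Heatmap preparation
scales each feature's ratios to mean 0 and SD 1 ($n-1$ denominator), and
hierarchical clustering uses Ward's minimum-variance method on Euclidean
distances in the `ward.D2` convention — Lance–Williams updates on squared
dissimilarities, heights reported on the unsquared scale. Merge heights
are validated in the tests against a brute-force agglomeration using the
closed-form Ward cost
$\sqrt{\tfrac{2 n_A n_B}{n_A + n_B}\lVert \bar x_A - \bar x_B \rVert^2}$.

## The DIA time-course branch

DIA protein quantities (protein-level aggregation happens upstream and is
taken as given) are log10-transformed — log10 is the storage and display
scale — and technical replicates are averaged within each (condition,
stage, biological replicate) before modeling, so the model's units are
biological samples and no hierarchical model is needed. Missing cells are
imputed *conservatively by the minimum replicate intensity*: the minimum
observed value among the protein's replicates within the same
(condition, stage) group, falling back to the protein-wide minimum when
the group is empty. Imputed cells carry weight 0.05 against 1 for
observed cells, so they anchor the fit only weakly; the weighted
moderated engine above then tests treatment versus control one stage at a
time. Effects are converted to log2 fold changes
($\text{log2FC} = \beta_{\log 10} \cdot \log_2 10$) and a protein is
called reliably changed when both the adjusted p-value is at most 0.05
and $|\text{log2FC}| \ge 0.5$, the effect-size bound being inclusive.
With no missing values every weight is 1 and the weighted path reproduces
the unweighted engine cell for cell — an exact identity asserted in the
tests.

Two interpretation choices here were genuinely open. First, the scope of
"minimal replicate intensity": the within-(condition, stage) minimum was
chosen over a global minimum because conservative imputation should
reflect the local detection context, with the protein-wide minimum only
as a fallback. Second, the time course is tested as one contrast per
stage rather than a joint model across stages; per-stage contrasts keep
the weighting scheme simple and match how stage-specific effects are
read off a time-course figure.

## What the synthetic data emulate — and what they do not

`generate_phospho_dataset()` emulates the statistical structure of the
TMT design: per-protein log-normal baselines; multiplicative (log-normal)
reporter noise at the PSM level with standard deviation
`reporter_noise_sd` (default 0.25 on the log2 scale, a typical TMT
reporter CV); protein-group channel noise at half that value, since
protein-level intensities aggregate many peptides; a planted minority
(`effect_fraction`, default 10%) of features whose treated-channel
intensities shift by `2^effect_log2fc` relative to their parent protein,
dephosphorylation (negative, default −1) being the default direction to
mirror the strong down/up asymmetry such inhibition experiments show;
PSM multiplicity per peptide; Dirichlet site-probability vectors
restricted to the peptide's S/T/Y positions and peaked at the true site
with concentration `site_prob_concentration` (default 20); posterior
error probabilities drawn from Beta(0.5, 200), which leaves roughly 4.5%
of PSMs above the 0.01 confidence filter so the filter is genuinely
exercised; and decoy/contaminant rows appended at configured fractions
(2% each by default). Every random draw flows from the single mandatory
seed, and generation is bit-reproducible.

`generate_dia_timecourse()` produces runs for stages × two conditions ×
biological × technical replicates, with between-animal variability
exposed as the `bio_sd` knob (default 0.15 on the log2 scale; the
within/between variance decomposition of real oocyte collections is not
asserted, only exposed). A planted minority of proteins acquires a
treatment-versus-control shift at one designated stage; all other
proteins are flat across stages. Missingness is injected at
`missing_rate` with probability enriched in low-abundance proteins, as in
real DIA data.

The generators do not emulate: chromatographic or spectral raw data;
isotope-impurity leakage between reporter channels (intensities are
emitted already corrected); peptides shared between protein groups
(each PSM carries a single group id, the leading/razor convention);
co-eluting interference; or batch effects. Passing tests therefore
demonstrate that the statistical machinery is correct and calibrated
under the stated noise model, not that any particular biological dataset
would reproduce specific counts.

## Numerical choices and degenerate inputs

- Trigamma inversion: Newton iteration started at $0.5 + 1/y$, relative
  tolerance $10^{-8}$, with asymptotic shortcuts for extreme arguments.
- Infinite-d0 prior scale: $s_0^2 = \exp(\bar e)$, the log-scale moment
  estimator, is used for consistency with the finite branch. (limma's
  `fitFDist` returns the arithmetic mean of the variances in this branch;
  the two estimators differ by a Jensen-type factor. The cross-check test
  against limma therefore exercises the finite branch, where the
  formulas coincide.)
- Features with zero residual variance are excluded from prior
  estimation; all-zero variances raise a degenerate-data error.
- Site-localization ties: lowest peptide position wins.
- Motif cells where the foreground shows a residue the un-pseudocounted
  background lacks are scored against a floor background frequency of
  $1/(n_{\text{bg}} + 20)$ and the event is messaged; cells are capped
  at 1. The pipeline uses pseudocount 0.5 so this path is rare.
- Constant rows cannot be scaled to unit variance; `scale_rows()` emits
  zeros with a warning and flags them.
- BH input outside [0, 1] is a validation error, not a silent clamp.
- Clustering refuses non-finite input; the pipeline clusters only
  significant features with complete ratio profiles.

## Problem sizes used in the validation suite

The test suite validates calibration and recovery at sizes chosen to
make the Monte-Carlo bounds tight while keeping a default test run
fast: null-calibration uses twenty simulated datasets of 3,000 features
(3 vs 3 channels), effect recovery uses 2,000 features with 10% planted
at log2FC −1 and reporter noise 0.25, prior recovery uses 5,000
simulated variances, and the oracle equivalences run on thousands of
small random instances. `scripts/acceptance.R` recomputes the same
quantities from scratch for any seed.

## Known limitations

- Only two-group contrasts are supported; no paired/replicate covariate
  (the plain two-group fit reflects how a treated-versus-control TMT
  contrast is usually modeled when pairing is not recorded), no
  multi-factor designs, and no spline or trend modeling across the DIA
  time course.
- The hypergeometric enrichment does no GO-graph propagation or term
  deduplication; terms are tested as given in the GMT.
- Kinase-substrate prediction is consumed, never computed.
- The evidence reader targets the tab-separated evidence dialect
  documented in `read_evidence()`; native binary search-engine outputs
  are out of scope.
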