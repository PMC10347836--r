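# oetomics

Integrative analysis of protein, translation and transcription dynamics
across the mouse oocyte-to-embryo transition (OET).

A fully grown oocyte (FGO) is transcriptionally silent; everything that
happens between oocyte maturation and zygotic genome activation runs on
maternally stockpiled mRNAs and proteins. Stage-resolved measurements of
the proteome (log2 iBAQ intensities from label-free LC-MS/MS), the
translatome (ribosome-protected-fragment FPKM) and the transcriptome
(mRNA FPKM) over seven stages — FGO, MII, 1C, 2C, 4C, 8C, blastocyst —
show these three layers reprogramming on very different schedules. This
package is for researchers who want to quantify that decoupling: how much
of the proteome is stable while translation and transcription churn,
which protein changes are attributable to which regulatory layer, and how
well protein trajectories can be *predicted* from translation plus the
initial oocyte protein stock.

## The model at the core

Per gene, protein abundance p(t) on the linear scale follows mass-action
kinetics with a piecewise-linear translation input r(t) (RPF, interpolated
between stage time points):

$$\frac{dp(t)}{dt} = \alpha\, r(t) - k_d\, p(t), \qquad \alpha, k_d \ge 0$$

with α the synthesis constant and k_d a degradation rate assumed constant
across development. Per-segment integrating-factor closed forms make
simulation exact; fitting minimizes Σᵢ (p(tᵢ) − p̂ᵢ)² over the observed
stages. Two variants are compared: **P0+RPF** (initial condition pinned to
the observed FGO protein level) and **RPF-only** (p0 = 0). Because the
model is linear in α, the fitter profiles α out analytically and searches
k_d in one dimension (dense log scan, Brent refinement of every local
minimum, L-BFGS-B polish) — deterministic and robust for decay-dominated
genes.

Around the model sit the supporting analyses: FGO-anchored batch
correction for the three-batch proteome design, replicate merging and the
analysis gene universe, CV-based dynamic/stable classification (CV > 0.2
of log2 values), trajectory K-means clustering with group merging,
gene-wise and lagged protein–RPF/mRNA concordance, differential-abundance
calling (two-fold + Student's t-test) with attribution of protein changes
to mRNA/RPF changes in a two-transition lag window, FGO-originated
protein persistence, dormant-mRNA identification, allele-specific protein
expression, and intrinsically-disordered-region segmentation. A
synthetic-data generator with known per-gene (p0, α, k_d), planted batch
offsets, detection dropout and planted gene classes makes every stage
testable end to end.

## Worked example

Generate a synthetic study, correct batch effects, build the gene
universe, and fit both kinetic model variants:

```r
library(oetomics)
library(dplyr)

bundle <- generate_bundle(sim_config(n_genes = 400, seed = 1))

factors <- compute_batch_factors(bundle$protein)
factors
#> # A tibble: 3 × 2
#>   batch  offset
#>   <chr>   <dbl>
#> 1 batch1  0
#> 2 batch2  0.655
#> 3 batch3 -0.480

corrected <- apply_batch_correction(bundle$protein, factors)
universe  <- filter_gene_universe(corrected, bundle$rpf, bundle$mrna)
length(universe)
#> [1] 388

protein <- merge_replicates(corrected |> filter(gene_id %in% universe))
rpf     <- merge_replicates(bundle$rpf |> filter(gene_id %in% universe))

fits     <- fit_kinetics(protein, rpf, mode = "p0_rpf")
rpf_only <- fit_kinetics(protein, rpf, mode = "rpf_only")
evaluate_predictions(fits, rpf_only,
  baseline = genewise_correlation(impute_missing(protein), rpf))
#> # A tibble: 3 × 4
#>   mode            n n_undefined median_r
#>   <chr>       <int>       <int>    <dbl>
#> 1 p0_rpf        251           0   1
#> 2 rpf_only      276           0  -0.0714
#> 3 protein_rpf   341          47   0.571
```

The recovered batch offsets sit near the planted (0, +0.7, −0.4); the
universe drops the planted RNA-silent genes plus FGO-inconsistent
detections. The comparison table is the central result: predictions that
include the oocyte protein stock (P0+RPF) rank-correlate near perfectly
with observed trajectories, while the RPF-only variant — translation with
no inherited stock — fails on the stock-buffered majority of the
proteome, and the raw protein–RPF correlation sits in between. Per-gene
parameter estimates are available broom-style:

```r
head(tidy(fits), 3)
#> # A tibble: 3 × 4
#>   gene_id  mode   term   estimate
#>   <chr>    <chr>  <chr>     <dbl>
#> 1 gene0001 p0_rpf p0    72697.
#> 2 gene0001 p0_rpf alpha   300.
#> 3 gene0001 p0_rpf kd        0.393
```

`autoplot(fits, protein)` overlays predicted and observed trajectories;
`autoplot(stage_correlation_matrix(impute_missing(protein)))` draws the
stage-correlation heat map.

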