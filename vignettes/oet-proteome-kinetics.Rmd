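---
title: "Methods: proteome, translatome and transcriptome dynamics across the oocyte-to-embryo transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome, translatome and transcriptome dynamics across the oocyte-to-embryo transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oetomics)
library(dplyr)
```

## The problem

During the mouse oocyte-to-embryo transition (OET), a transcriptionally
silent fully grown oocyte (FGO) matures, is fertilized, and develops to a
blastocyst while the zygotic genome only activates at the 2-cell stage.
Protein abundance over this window is therefore shaped by three partly
decoupled layers: the mRNA pool (transcriptome), its engagement by
ribosomes (translatome, measured as ribosome-protected-fragment (RPF)
FPKM), and the large stock of proteins deposited in the oocyte before
silencing. This package implements an integrated analysis of gene x stage
matrices for these three layers over seven ordered stages (FGO, MII, 1C,
2C, 4C, 8C, BL), centered on a mass-action kinetic model that predicts
protein trajectories from translation plus the initial oocyte protein
stock.

## The kinetic model

For each gene, protein abundance `p(t)` on the linear intensity scale is
modeled as

    dp/dt = alpha * r(t) - kd * p(t)

where `r(t)` is the translation level (RPF), `alpha` converts translation
signal into protein synthesis flux, and `kd` is a first-order degradation
rate, both assumed constant across development. Because RPF is measured
only at the stage time points, `r(t)` is interpolated linearly between
nodes. On each linear segment the ODE has an integrating-factor closed
form, which `simulate_protein()` evaluates exactly; where `kd * dt` is
tiny, a series expansion replaces the `expm1`-based terms to avoid
cancellation (the switch point is `kd * dt < 1e-4`, where the truncated
series is accurate to O(1e-16) relative). The suite verifies the solver
against decay and steady-state closed forms and against a fine-grid
fourth-order Runge-Kutta oracle at 1e-6 relative tolerance.

Two model variants are fitted per gene by least squares over the observed
stages, with `alpha, kd >= 0`:

* **P0+RPF**: the initial condition `p0` is pinned to the observed FGO
  protein level, so the prediction reflects inherited stock plus
  synthesis/degradation;
* **RPF-only**: `p0 = 0`, isolating what translation alone explains.

Missing (undetected) stages are simply dropped from the objective; they
are never imputed for fitting.

### How the optimizer works, and why

The model is *linear in alpha*: by superposition,
`p(t | p0, alpha, kd) = decay(t | p0, kd) + alpha * synth(t | kd)`. For
any fixed `kd` the optimal nonnegative `alpha` is therefore a clamped
least-squares coefficient in closed form (variable projection). The
fitter scans the profiled objective over a dense log-spaced `kd` grid
(41 points spanning eight decades around the reciprocal time range, plus
`kd = 0`), refines *every* local minimum of the scan with Brent's
method, and finishes with a joint bounded L-BFGS-B polish on
`(alpha, kd)`. Refining all scan minima matters: for decay-dominated
genes (large `p0`, weak synthesis) the objective has a deep, narrow basin
near the true `kd` next to a broad shallow plateau at large `kd`, and a
single global-scan pick can land on the plateau. A naive two-dimensional
multi-start over `(alpha, kd)` showed exactly this failure mode, which is
why the profiled one-dimensional search is the shipped design. Fits are
deterministic (no random starts), and a fit is flagged when a parameter
ends at its upper bound (`1e6` in data-scaled units; the scale for
`alpha` is `max(observed) / (max(rpf) * time range)`).

Parameters are fitted on the linear intensity scale (`2^log2iBAQ`)
because mass-action balance is linear in abundance; evaluation uses the
Spearman correlation between predicted and observed trajectories, which
is insensitive to the (arbitrary) intensity scale. Time coordinates
default to the stage index 0..6, so `alpha` and `kd` are in per-stage
units; any strictly increasing time grid (e.g. hours post-hCG) can be
supplied instead via `oet_stage_times()`.

## Preprocessing

Label-free iBAQ proteomics was acquired in three batches, each containing
FGO samples, which anchors an additive log2 batch correction:
`compute_batch_factors()` selects proteins detected in the anchor stage
in *every* batch, summarizes each protein's anchor intensity per batch
(mean over that batch's detected FGO replicates), takes the per-batch
median across these proteins, and subtracts the reference batch's
median. We implement the difference-of-medians reading of this rule (per
batch: median across proteins, then difference against the reference);
for purely additive shifts it coincides with the median-of-differences
alternative, and on noiseless synthetic data it recovers planted offsets
to 1e-9.

`merge_replicates()` averages detected replicates per stage; the
four-replicate FGO stage is first paired into two derived replicates
(default pairing (1,2) and (3,4), matching batch membership) which are
then averaged. Genes detected in exactly one derived FGO replicate are
flagged and excluded by `filter_gene_universe()`; this is the package's
operationalization of cross-batch detection consistency (the predicate
has no single canonical form) — genes never detected in FGO (embryonic
proteins) are deliberately retained. The universe additionally
requires detection (FPKM > 0) at one or more stages in the RPF or mRNA
layer.

For analyses that need complete series (CV, correlations, clustering),
`impute_missing()` replaces undetected protein values with the global
detected minimum minus 1 log2 unit — "not detected" keeps its
lowest-abundance semantics without infinities. Functions that reason
about detection itself (`fgo_originated()`, the universe filter, ASE
categories) run on the unimputed matrix.

## Dynamics, clustering, concordance, differential calls

* **Dynamic vs stable**: a gene is dynamic when the coefficient of
  variation (sample sd / mean) of its per-stage log2 values exceeds 0.2;
  RNA layers are first restricted to expressed genes (FPKM >= 1
  somewhere) and log2(x+1) transformed. The CV is computed on
  stage-averaged values.
* **Clustering**: per-gene z-scored trajectories, Euclidean K-means with
  k = 10 and 100 restarts kept by best within-cluster SSE
  (`stats::kmeans`, Hartigan-Wong; the restart-and-keep-best protocol is
  what the classic clustering tools implement, and the z-scoring reflects
  that trajectory *shape*, not absolute level, defines the groups).
  `merge_to_groups()` reduces clusters to named groups either by explicit
  mapping or by an automated rule that merges clusters sitting below the
  detection floor through 2C and rising afterwards into one "embryonic"
  group — automating a merge that is otherwise curated by hand.
* **Concordance**: per-gene Spearman correlation between protein and
  RPF (or mRNA) trajectories, binned as low (r < 0.2), medium
  (0.2 <= r <= 0.5), high (r > 0.5); the high bin uses a strict
  inequality, so boundary values fall to the lower bin's closed side. Lagged structure is assessed by correlating per-transition log2
  changes across genes at transition offsets 0, 1, 2
  (`lagged_change_correlation()`, `lag_diagonal()`). FPKM changes use a
  log2(x+1) transform (pseudocount 1, so zero FPKM maps to zero signal).
* **Differential calls**: consecutive-stage comparisons use a two-fold
  change plus a classical equal-variance two-tailed t-test at raw
  p < 0.05 (two replicates per group make the pooled-variance test the
  stable choice; Welch with n = 2 is not). No multiple-testing
  correction is applied anywhere in these calls — raw per-test p-values
  are deliberate here, and a caveat for any reuse. When both
  groups have zero variance, p is 1 for equal means and 0 otherwise.
  Cycloheximide-response calls use the same rule at four-fold.
* **Attribution**: because protein changes lag translation and
  transcription, each differential protein at transition i is compared
  with mRNA and RPF changes at transitions i-2..i. Same-direction mRNA
  changes above two-fold anywhere in the window make the DEP
  "mRNA-contributed"; failing that, RPF changes make it "RPF-only";
  otherwise it is "unexplained" (candidate post-translational control).
  Direction matching is required for a change to count as
  corresponding.
* **FGO-originated proteins**: detected in the FGO proteome with RPF
  FPKM < 5 at every stage from 1C onward; persistence is the fraction
  still detected at the blastocyst.
* **Dormant mRNAs**: RPF MII/FGO ratio > 2 with mRNA ratio < 2, on FPKM
  with pseudocount 0.1 against division by zero.
* **Set overlaps** use two-sided Fisher's exact tests; numeric feature
  associations (FGO abundance, half-life) across bins use two-tailed
  Wilcoxon rank-sum tests; binary features (IDR presence) use Fisher.
  Half-lives and per-residue disorder scores are consumed as external
  per-gene inputs; `idr_segments()` applies the strict rule of more than
  30 consecutive residues with score > 0.5.

## Allele-specific expression

`extract_variant_peptide()` builds 61-residue windows (30 each side of a
nonsynonymous variant), clipped at protein termini rather than padded —
padded residues would be biologically meaningless and variable-length
windows are unproblematic downstream. `ase_call()` compares maternal and
paternal allele intensities per stage (equal-variance t-test, ASE at
p < 0.05 and fold change > 2 at one or more embryo stages). A stage
where one allele is entirely undetected is tested after substituting the
table's detected minimum minus 2 log2 units for the absent allele: the
substitute must sit at least one full fold below every observed value,
otherwise a detected-versus-absent contrast could never clear the
two-fold rule. Categories are assigned by detection pattern
(oocyte-specific, oocyte-embryonic, embryonic-maternal/paternal); the
original study assigned these descriptively, so our rule set is an
explicit operationalization.

## The synthetic study generator

`generate_bundle()` creates a complete input bundle with known truth:
nine gene classes (four constitutive subgroups distinguished by RPF
dynamics, maternal, OET down- and up-regulated, embryonic, lowly
expressed) with piecewise-linear FPKM templates; per-gene kinetic
parameters drawn log-uniformly from class-specific ranges; protein
trajectories *forward-simulated through the same mass-action model* and
then log2-transformed, replicated with log-normal noise (default sd 0.1
log2), shifted by additive batch offsets over the three-batch design
(defaults 0, +0.7, -0.4), and masked below a hard detection floor
(default log2 = 10) — the simplest dropout mechanism consistent with
limited MS sensitivity. RPF/mRNA are class-templated FPKMs with
multiplicative noise in two replicates. The bundle also carries an
allele table with planted ASE categories, per-residue disorder scores
with planted disordered runs, and a small planted set of genes never
detected in either RNA layer (default ~0.75% of genes). Each layer draws from its own stream
split from the master seed, so layers regenerate independently.

Class templates and parameter ranges were chosen once to reproduce the
qualitative structure of real OET data: class-defining monotonicity
(maternal decline after MII, dormant-class induction at MII, embryonic
accumulation after zygotic genome activation, stable constitutive
proteins despite dynamic translation), slow maternal protein decay, and
a proteome whose stage-correlation matrix forms a coherent FGO-8C block
with the 8C-to-blastocyst transition as the major break (largest
differential-protein count, dominated by up-regulation). Two qualitative
caveats follow from the design. First, a single-step correlation such as
8C-BL can never drop below a five-step cumulative one (FGO-8C) in a
constant-rate generator with a ~40% stable core, so "block versus break"
is asserted as block-mean versus BL-versus-block-mean rather than as a
single matrix entry. Second, absolute iBAQ scale is arbitrary (it is not calibrated to any
particular instrument or search pipeline), so absolute
CV-dynamic fractions of synthetic data are not meaningful — only
orderings are, and the generator reproduces the key one: the protein
layer is far less dynamic than the translatome and transcriptome.

What the generator does *not* emulate: peptide-level evidence and
peptide-to-protein rollup, intensity-dependent (as opposed to
hard-floor) dropout, batch-by-protein interaction effects, correlated
noise between layers, and post-translational regulation (no planted
"unexplained" attribution class — on default bundles nearly every DEP is
attributable, unlike real data). Passing recovery tests on this
generator therefore validates the estimators' correctness under the
stated model, not their robustness to real-data pathologies.

## Numerical and design choices worth knowing

* Stage times default to indices 0..6; rates are per-stage units.
* Gene counts per class are apportioned deterministically (largest
  remainder), so realized class counts match proportions within 1.
* K-means uses a fixed default seed recorded in the result's attributes.
* Undefined correlations (constant series) are excluded and counted
  rather than silently dropped.
* The differential caller skips (and counts) genes with fewer than two
  detected replicates on either side of a transition.
* Fold-change thresholds are expressed in log2 units throughout
  (`fc_log2 = 1` means two-fold).

## Problem sizes

The shipped tests run the generator at 40-500 genes and fit the kinetic
model for up to 500 genes per mode; the acceptance script analyses a
400-gene bundle end to end. These sizes give stable estimates of every
reported quantity while keeping a full run in the order of a minute; all
operations scale linearly in genes and none of the defaults depend on
the problem size.
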