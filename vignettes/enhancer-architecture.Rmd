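---
title: "Mapping enhancer-transcription QTLs and the bipartite enhancer architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping enhancer-transcription QTLs and the bipartite enhancer architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ernarch)
```

## The measurement and the model

Run-on sequencing of 5′-capped nascent RNA records, at base resolution
and per strand, where RNA polymerase II initiates. Active regulatory
elements — promoters and enhancers alike — show a characteristic
divergent pattern: a minus-strand initiation peak to the left of a
plus-strand peak, flanking a central region where transcription factors
bind. `ernarch` operationalizes this as the *tTRE* (transcribed
transcriptional regulatory element): a pair of opposite-strand nascent
TSS peaks at most 300 bp apart, with the element midpoint halfway
between them.

Two per-element, per-individual phenotypes summarize the signal in
midpoint-relative windows (plus strand offsets 1..250, minus strand
−250..0):

* **initiation level** — the total window count, depth-normalized and
  quantile-normalized (below), measuring overall element activity;
* **directionality index** — `log2((plus + 1)/(minus + 1))`, measuring
  the balance between the two initiation cores while total output
  cancels.

Genetic association of each phenotype with nearby variant dosages is
ordinary least squares with optional principal-component covariates;
the dosage coefficient is tested with a *t* statistic on `n − k − 2`
degrees of freedom and Benjamini–Hochberg control across all tests of
a run. Variants associated with the level are *tiQTLs*, with
directionality *diQTLs*, and with gene expression (same machinery,
200-kb window) *eQTLs*. The central scientific claim this pipeline is
built to examine is architectural: level-associated variants concentrate
at the element center (the TF-binding footprint), directionality
-associated variants at the flanking initiation cores — a bipartite
organization visible in positional enrichment profiles and in the
region partition described below.

### Assumptions

* Counts are 5′ ends; only the initiation position carries signal, so
  all analysis is on per-base count tracks, never read intervals.
* Elements are far enough apart that the ±250 bp quantification
  windows and ±2 kb association windows can be treated independently;
  overlapping elements are not modelled.
* Dosage effects are additive on the (normalized) phenotype scale; no
  dominance terms, no kinship/mixed-model correction (the intended
  populations are unrelated individuals).

## Normalization choices

Depth scaling divides window counts by each sample's total window
counts in millions (RPM). The quantile-normalization reference is built
by the ratio method: each element's count is divided by its across-
sample mean, a sample's size factor is the median of those ratios, the
scaled columns are sorted, and the reference is the rank-wise mean.
Each sample's values are then replaced by reference values at matching
ranks.

Three deliberate details:

* The per-element ratio uses the **arithmetic** across-sample mean —
  implementing the procedure as commonly described for this assay —
  not the geometric mean used by differential-expression tools. A
  consequence worth knowing: rescaling one sample by *c* changes its
  size factor by only approximately *c* (the row means move too);
  rescaling all samples cancels exactly. The tests assert exactly
  that pair of properties.
* **Ties** in quantile normalization receive the mean of the tied
  reference values — deterministic and idempotent. Tie-averaged
  columns preserve their column sums but are no longer bit-identical
  to the reference; the test suite distinguishes tie-free columns
  (exact) from tied ones (sum-preserving).
* The directionality index is computed from **raw** window counts with
  pseudocount 1: the plus/minus ratio cancels sequencing depth, and the
  downstream quantile normalization absorbs any residual scale. A
  pseudocount of 0 is allowed only when no zero counts occur.

## Peak calling and pairing

The supplementary details of the original peak caller are not
recoverable, so the concrete algorithm here is the package's own
design, chosen to be simple and deterministic while honouring the
stated 300-bp pairing constraint:

1. On the aggregate (summed-across-samples) track, candidate bases per
   strand need `min_count` reads (default 5; `min_rpm` expresses the
   threshold in reads per million, with 0.5 RPM a typical deep-track
   choice).
2. Candidates within 60 bp on the same strand merge to the maximum-
   count base, leftmost on ties.
3. Each minus-strand peak pairs with a plus-strand peak strictly to its
   right within 300 bp, greedily by ascending gap (leftmost on ties);
   each peak is used at most once. One nTSS therefore belongs to at
   most one element — the permissive alternative (shared nTSSs) is not
   stated anywhere we could verify, and exclusivity keeps elements
   disjoint for the window analyses.

Promoter/enhancer classification offers both stated routes: distance to
annotated gene TSSs (promoter ≤ 500 bp from either nTSS; enhancer if
both nTSSs > 2 kb; the (500, 2000] gap stays unclassified), and a
stability route where CAGE-like counts at each nTSS are compared to an
empirical background built from nTSSs ≥ 1 kb from annotation
(empirical p = (1 + #background ≥ observed)/(B + 1), BH at FDR 0.1,
promoter if either nTSS is significant). With B background values the
smallest achievable p is 1/(B + 1); small panels therefore need
several simultaneously significant nTSSs before BH can fire, which the
tests construct explicitly.

## QTL mapping details

* Missing dosages are mean-imputed per variant (standard matrix-QTL
  practice; the imputed fraction is messaged).
* Constant-dosage pairs are flagged `skipped`, never tested.
* BH is applied **per run across all tested pairs** — the conservative
  reading when the multiplicity universe is unstated.
* PCs are computed from the element-centered phenotype matrix by SVD,
  orthonormal over individuals, signs fixed by making each component's
  largest-magnitude loading positive. `scan_pc_covariates()` re-runs
  the map over a k-grid and keeps the most productive k — mirroring
  the practice of choosing the covariate count that maximizes
  discoveries — but the default is a fixed k (0) for reproducibility;
  the synthetic data contain no batch structure for PCs to absorb.
* The local-minimum filter tiles the genome with 5-kb windows
  staggered by 1 kb (each SNP in five windows), keeps a window's
  strictly-lowest-p SNP, drops everything in a window whose minimum is
  tied, and retains a SNP if it wins **at least one** of its windows.
  The stricter reading (must win all five) is not what the tiling
  construction suggests; the union reading is implemented and noted
  here as an interpretive choice. Competition is per SNP (best p over
  its elements), matching the stated "independent of which element it
  affects".

## Architecture analyses

Positional profiles bin QTL offsets (default 10-bp bins, ±2 kb; the
per-base profile is one flag away, but 10 bp stabilizes desk-scale
counts) and compare each bin against `n_resample` draws of equally many
SNPs from the same windows' full SNP set; the 0.5%/99.5% quantiles form
the 99% band. Promoter-oriented profiles flip offsets so the dominant
strand (higher summed window count) points downstream.

The region partition fixes precedence center > core > NCNC > out >
far-out, so every offset in the ±2-kb window receives exactly one
label even for narrow elements whose ±25 bp cores overlap the ±25 bp
center. The element's "out" region extends 200 bp beyond the outermost
nTSS before far-out begins — the same ±200 bp convention used for
overlap analyses; the boundary is configurable because the published
diagram is schematic.

## Motif scoring

Frequency matrices (CIS-BP-style, MEME minimal input) are smoothed with
pseudocount 0.8 against the background and converted to log₂ odds
(bits). The "strong match" threshold of 13 is interpreted in **bits
with uniform background** — whether the original scale was natural-log
is not recoverable; the threshold is a parameter. Allele deltas are
evaluated at the best-match placement of the *stronger* allele
(leftmost, forward-strand-first tie-break), which makes the delta
antisymmetric in the allele labels by construction. Initiator
likelihoods re-scale bit scores to natural log before exponentiating,
so the published ">5 likelihood difference" filter applies on the
natural-exponent scale. The TATA tier ("two inversions") is read as
Hamming distance 2 from TATA **within the {A,T} alphabet**: the rule
defines inversions only as A↔T, so any C or G anywhere scores 0.

Exact match p-values use dynamic programming over the column-score
distribution: exact column sums for motifs up to 10 columns (the
distribution is built column-by-column, aggregating equal sums), and a
floor-discretized bracket for longer motifs whose step is refined
until the bracket width drops below `tol` (default 1e-6) — the
mid-bracket value is returned. Scores above the attainable maximum give
p = 0, at or below the minimum p = 1.

## The synthetic-data generator

The generator's defaults *are* the study conditions the pipeline is
tested under: 67 individuals with 8 replicate pairs grown as
independent libraries, 100 non-overlapping elements on a 5-kb grid of
a 1-Mb contig, initiation cores 70 bp either side of each midpoint,
2000 background variants with allele frequencies uniform on
[0.05, 0.5], ~2-fold total initiation change between homozygotes at
planted level-effect variants, and a +1 log-odds strand-allocation
shift per allele at planted directionality variants.

Mechanics, with the reasoning where the choice was open:

* **Counts** are negative binomial (dispersion 0.2, i.e. variance
  `μ + 0.2 μ²`) around a per-element log-normal baseline (σ = 0.5).
  No published variance structure exists for this assay across
  individuals; NB with dispersion ~0.2 is typical of molecular-count
  reproducibility, and dispersion → 0 recovers the Poisson limit
  (asserted in tests).
* **Level effects** act multiplicatively as `fold^(dosage/2)`, so the
  homozygote ratio equals the configured fold exactly.
* **Directionality effects** shift the log-odds of plus-strand
  allocation additively per allele while the total is drawn first —
  directionality is decoupled from level by construction, which is
  what lets the tests assert that planted directionality effects are
  invisible to the level phenotype.
* **Positions** scatter around each nTSS with two-sided geometric decay
  (scale 10 bp), emulating the sharp but not single-base initiation
  focus of real elements.
* **Planted variants** sit at the architectural positions the effects
  act through — level variants within 10 bp of the midpoint,
  directionality variants within 10 bp of one nTSS — and are drawn
  common (MAF 0.2–0.5) so that recovery measures method power rather
  than genotype-sampling noise.
* **Expression** is linear in dosage with Gaussian noise; target genes
  sit within 200 kb of their driver.
* Replicates are independent draws from identical means; the mask
  generator emits a configurable fraction of variant-centered windows.

What the generator does **not** emulate — and hence what passing tests
do not certify about real data: linkage disequilibrium (sites are
independent), allele-specific mappability bias (the mask is an input,
not a simulation of alignment), unidirectional or overlapping elements,
promoter/enhancer chromatin differences, population structure or batch
effects, and any realistic sequence context (motif analyses take
explicit windows, not a genome).

## Statistical power at desk scale

Under the default conditions (2-fold effects, 67 individuals, BH at
FDR 0.1 over ~800 tests), recovery of planted level effects runs
0.6–0.93 across seeds; the acceptance suite asserts ≥ 0.5. This is a
statement about the conditions, not the implementation: at 30
individuals the same 2-fold effects are mostly undetectable after
multiplicity control, so the unit tests that specifically check
*recovery* use a 40-individual, 3-fold fixture, while calibration
(null uniformity, FDR control) is checked at every scale. Test-suite
problem sizes — up to 150 elements, 120–200 individuals for moment
checks, 10,000 p-values for estimator checks — were chosen so each
property is measured well inside its sampling noise.

## The variable-fraction estimator

Variably expressed elements are detected by comparing absolute
deviations within replicate pairs against deviations across
individuals (one-sided rank-sum, normal approximation with continuity
correction; exact small-sample behavior is cross-checked against
enumeration in the tests). The fraction of truly variable elements is
then `1 − π₀`, with π₀ the height of the uniform portion of the
p-value distribution, estimated Storey-style as the mean of
`#{p > λ}/((1 − λ) m)` over λ ∈ {0.5, …, 0.9}.

A caution documented here because the tests surface it: tail-density
estimators recover the *mixture's* tail density, not the nominal null
weight, whenever the alternative retains mass near p = 1. For a 30/70
uniform/Beta(0.1, 1) mixture the Beta component has density 0.1 at
p = 1, so every tail-density estimator converges to ≈ 0.37–0.38, not
0.30 — the estimator is upward-biased for the null weight by exactly
the alternative's tail mass. The unit tests assert agreement with this
analytic expectation; the acceptance suite retains the nominal 0.30 ±
0.05 recovery bound, which consequently documents the bias rather than
a defect.

## Known limitations

* Greedy nearest-gap pairing is order-dependent in pathological
  many-peak clusters; real pipelines with overlapping elements may
  need a matching formulation.
* The OLS map has no mixed-model relatedness correction and no
  conditional fine-mapping; the local-minimum filter is a heuristic
  for "likely primary", not a causal statement.
* Empirical stability p-values are floor-limited at 1/(B + 1);
  classification on small panels is conservative toward "enhancer".
* The discretized PWM p-value path returns a bracket midpoint; for
  motifs longer than ~20 columns with extreme thresholds the refinement
  loop may stop at its iteration cap with a wider-than-`tol` bracket.
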