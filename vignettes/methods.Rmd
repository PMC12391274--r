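---
title: "Models and methods behind hicprog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hicprog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hicprog` analyses binned Hi-C contact matrices from tumour biopsies at
several layers of genome organisation. This vignette describes the models
each stage assumes, the tunable parameters and why their defaults are what
they are, what the synthetic generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The data model

A `ContactMatrix` is a bin table tiling each chromosome at one resolution
(0-based half-open coordinates, the on-disk layout mirroring a cooler dump)
plus upper-triangular sparse triplets of raw counts and optional balancing
weights. Balancing is iterative correction: weights `w` such that every
retained row of `w_i w_j c_ij` has the same marginal sum; bins with fewer
than `min_nnz` (default 10) non-zero pixels are masked first, and weights
are scaled so retained marginals equal 1. Convergence is declared when the
relative marginal spread falls below `tol` (1e-5); non-convergence is
flagged on the weights, never silent. Observed/expected values divide each
balanced pixel by the mean balanced signal at its bin separation — the mean
(not median) over all valid bin pairs including zero pixels, per chromosome
or per arm — or by the chromosome-pair mean in trans. Arms come from a
centromere table; a bin is assigned by its midpoint, centromeric bins are
dropped, and chromosomes without an entry are one arm (with a warning).

## Compartments

Per arm, the compartment score is the leading eigenvector of the Pearson
correlation matrix of the cis O/E matrix, scaled by the square root of the
leading eigenvalue so magnitudes are comparable across arms. The
correlation matrix — not O/E directly — is the construction whose leading
eigenvector tracks the checkerboard. The sign is fixed by requiring a
non-negative correlation with GC content per arm; when a reference sample
is given, arms anti-correlated with the reference are flipped afterwards
(GC is absolute, the reference only resolves residual ambiguity). Arms
with fewer than 20 valid bins are left missing.

Saddle plots rank an arm's bins into Q = 50 equal-occupancy quantiles and
average O/E per quantile pair over all arms. Compartment strength uses the
extreme 20% of quantiles per corner — (AA + BB)/(2·AB) — the corner
fraction being a convention choice exposed as a parameter; the point value
is the mean of per-arm strengths and its uncertainty comes from 1000
bootstrap resamples of arms. Cross-sample comparison uses two scalars:
dissimilarity, the chromosome-length-weighted mean absolute difference of
per-chromosome rank-normalised scores (rank normalisation removes
per-sample scale, which is otherwise arbitrary across eigendecompositions),
and variance explained, the length-weighted squared Pearson correlation
(sign-blind by construction). The differential-region finder flags maximal
runs of at least `min_bins` (10) consecutive bins whose per-pair score
difference exceeds `threshold` (0.25) with one consistent sign across all
supplied sample pairs — the all-pairs-consistent reading of "consistent
changes", the stricter of the two possible rules.

## Insulation, TADs, and boundary similarity

The insulation score of bin i is log2 of the mean balanced signal in the
w×w square spanning (i−w…i−1)×(i+1…i+w), over the chromosome-wide mean of
that statistic; w defaults to 25 bins (500 kb at 20 kb), the window used by
the common insulation implementations, and the score is missing within a
window of ends and where more than half the window is masked. Boundaries
are strict local minima of the 3-bin moving-average-smoothed score — raw
insulation at `min_strength = -Inf` is noisy, so a documented light
smoothing precedes extremum detection — with prominence (the smaller
flanking maximum within 10 bins minus the minimum) filtered at
`min_strength`, default −Inf so every minimum is kept.

Aggregate TAD analysis z-scores the O/E per diagonal, cuts each TAD with
50% flanks, rescales the window to K×K (default 100) with an area-weighted
aggregation operator, and averages element-wise. Per-diagonal moments are
estimated with a 5% end margin excluded: balancing inflates bins near
chromosome ends (they lack long-range partners), and including them shifts
interior z-scores negative — measurably, by about −0.1 strength units on
featureless matrices. Per-TAD strength is the mean central block minus the
two flank-corner blocks, and the bootstrap resamples TADs. Boundary
similarity is a Jaccard index after pooling both sets and transitively
merging positions within 60 kb; chained (single-linkage) merging is the
natural reading of merging boundaries "within 60 kb of another boundary".

## Copy number

Both read ends are counted per 1 Mb tile; covariates are mean GC, mean
mappability and summed restriction-site count. The covariate fit is an
additive smooth Poisson regression (`mgcv::gam`, k = 5 per smooth) — a
member of the local-likelihood family whose exact bandwidth is a free
choice — and is two-pass: tiles whose provisional |log2 ratio| exceeds 0.3
are held out and the model refit on the neutral core, so genuine gains do
not bend the covariate curves (a single pass measurably attenuates a 2×
gain toward log2 ≈ 0.85). Normalised counts are observed over fitted; the
log2 ratio is taken against the genome-wide median, so the median ratio is
0. Tiles with mean mappability below 0.5 are masked throughout, which
keeps telomere/centromere artefacts out of the median. Segmentation is
recursive binary splitting on the maximal two-sample t statistic, a split
accepted when its permutation p value (1000 seeded permutations) is below
0.01, followed by an undo pass that merges adjacent segments whose means
differ by less than 2 noise SDs or 0.1 log2 units, whichever is larger —
the floor reflecting that differences far below the ±0.32 call thresholds
are not callable events. Gains are strictly above log2(1.25), losses
strictly below log2(0.75); boundary values are neutral.

## Translocations

Trans matrices at 500 kb are processed per chromosome pair: bins with at
most 2000 genome-wide reads are removed; a negative binomial GLM of the
per-cell count on the product of log10 row and column means — fitted on a
seeded random subset of up to 1e5 cells, with a quasi-Poisson fallback on
non-convergence — provides the expected value in
log2((obs + φ)/(exp + φ)), φ = 20, which compresses copy-number structure.
Compartment structure is then removed as the leading rank-1 term: for a
rectangular trans image the leading singular pair (the rank-1 component a
symmetric eigendecomposition of the two-block embedding would return)
forms the predictor u·vᵀ, whose coefficient is fitted robustly without
intercept and whose contribution is subtracted. The residual passes a 3×3
median filter (replicated borders), then a 7×7 corner kernel — +1 over one
4×4 quadrant including the centre row/column, the remaining 33 cells
scaled negative so the kernel sums to zero — in all 4 orientations; each
response is floored at 1 before summation, which suppresses anti-patterns.
The kernel carries a gain of 10, calibrated analytically so that corners
of realistic contrast produce responses well above the binarisation
threshold of 100 while the null response stays far below it (the threshold
is scale-coupled to the unprinted kernel weights, so one of the two must
be calibrated; the threshold is kept at its documented value). Note that
this kernel scores long step *edges* slightly above the apex itself (two
orientations match along an edge, one at the apex), which is harmless
because candidate selection inside each binarised, 21×21-dilated,
8-connected area picks the pixel with the maximum raw count — and raw
counts do peak at the apex. Review images with the three manual-triage
criteria in the header can be exported per candidate; manual
classification itself is out of scope.

## PE-SCAn and boundary enrichment

Binding-site clusters are maximal runs of ≥ 3 peaks with successive
midpoint gaps under 20 kb; distance is measured between peak midpoints
(edge-to-edge distance is the other defensible convention; midpoints are
symmetric and stable to peak width). The pile-up averages W×W (21×21,
±200 kb) O/E windows over all same-chromosome cluster pairs separated by
more than 3 Mb — W must exceed the 9×9 foreground with room for the
quadrants; windows over half-masked or crossing a chromosome end are
dropped. Enrichment is the central 9×9 mean minus the four corner-quadrant
mean, bootstrapped over pairs.

For boundary enrichment, each sample's boundaries are expanded to 60 kb
centred on the boundary (centred expansion keeps the original position
inside its range; coordinates are deliberately not clipped at chromosome
starts so the width filter is applied to the nominal expansion), merged
across samples, and merged ranges of 100 kb or more discarded; ubiquity u
counts samples whose original boundaries fall in the surviving range. Per
peak dataset, the expected overlap count of a ubiquity set is its size
times the global per-boundary overlap rate — the simplest exchangeable
null — and the pseudo-counted ratio (obs + 1)/(exp + 1) per level is
tested for a linear trend in u against a constant by a Gaussian likelihood
ratio test (2Δlogℓ against χ² with 1 df), Benjamini–Hochberg corrected
across datasets at FDR 0.001. A negative slope marks features of
sample-specific boundaries, a positive slope sample-invariant ones. Note
the ratio saturates at the reciprocal of the global rate, so very dense
peak datasets compress their own contrast.

## The synthetic generator

The generator's expectation is multiplicative: cis pairs get a power-law
decay (separation + 1)^(−α), a checkerboard factor (1 ± s·contrast) for
same/cross compartment labels (applied in trans as well — A/B segregation
is genome-wide), and a TAD factor that multiplies each crossing of a
boundary of depth d by (1 − 0.8d); trans pairs get a uniform background
(5% of the cis base) plus translocation corners that decay as
(1 + dx + dy)^(−1/2) from the apex with amplitude 20× background — the
reciprocal of the background level, i.e. apex contacts at cis-level
frequency, as expected for covalently fused loci. Copy-number events are
applied as exact coverage scaling: diagonal coefficients are solved by a
damped Sinkhorn iteration so each bin's expected coverage equals its
planted ratio times the CNV-free value (naive r_i·r_j scaling inflates a
2× gain's coverage to ≈3.8× the median and distorts neighbours). Cluster
pairs multiply a ±4-bin neighbourhood of their anchor pixel. Counts are
independent Poisson draws (negative binomial optional), deterministic
given the seed.

What it does not emulate: ligation artefacts and read-level noise,
mappability-driven *systematic* masking patterns (visibility bias is
optional and smooth), sub-compartments, loops, tumour heterogeneity and
subclonal mixtures, and karyotype-scale rearrangement cascades. Passing
tests therefore demonstrate algorithmic correctness against a known
generative model, not robustness to every real-data pathology.

## Problem sizes and reproducibility

The test suite and acceptance script run on genomes of 1–2 chromosomes of
20–100 Mb — roughly 1/25 of a human genome — with read depths scaled to
match typical per-megabase clinical Hi-C density (e.g. 2.4e7 pairs on a
120 Mb genome for the translocation conditions, equivalent to ~600M pairs
genome-wide). Every stochastic step takes an explicit seed; pipeline
outputs carry the configuration hash and seed, and repeated runs are
byte-identical. Known limitations: the compartment eigendecomposition is
dense per arm (arms beyond ~5000 bins become slow); the binary
segmentation is a simplification of full circular binary segmentation
(single change point per recursion, which suffices for contiguous events);
and the LRT for boundary enrichment treats per-level ratios as Gaussian,
which with few ubiquity levels is an approximation best read alongside the
per-level table returned with each test.
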