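---
title: "Comparative Hi-C analysis with hicdelta: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative Hi-C analysis with hicdelta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicdelta)
```

# Scope

`hicdelta` implements a comparative Hi-C analysis between two conditions
(say, a non-tumorigenic and a tumorigenic cell line), starting from valid
interaction pairs or pre-binned contact matrices and ending with
condition-level calls: a standardized differential interaction map, A/B
compartment profiles and their switches, insulation-square TAD boundaries
and their conservation, distance-scaling curves and telomeric end-to-end
interaction statistics. A synthetic generator with planted structure
provides known truth for every stage, so the whole pipeline is testable on
a desk scale.

Wet-lab processing, read mapping and RNA-seq quantification are outside the
package: the pipeline starts at valid pairs (or matrices), and differential
expression tables are consumed as input.

# Data model

All coordinates are 0-based half-open internally (the BED convention);
valid-pairs positions are read as 1-based and converted on ingestion. A
`GenomeBinning` tiles each chromosome with fixed-width bins from 0 to the
chromosome length; terminal bins may be shorter and are kept as ordinary
bins — dropping them would discard precisely the telomeric signal the
scaling analyses quantify. A `ContactMap` is a symmetric matrix on a
binning with a per-bin exclusion mask; masked bins are treated as missing
in every statistic, never as zeros, because zero-filling would bias the
distance-decay expectation downward. Bins with zero marginal (unmappable
regions such as centromeres) are always masked; `mask_low_coverage()`
additionally masks the weakest fraction of covered bins (default 2%) as a
stand-in for a mappability track, which the package does not ship.

# Normalization

## Iterative correction (ICE)

`ice_balance()` removes multiplicative per-bin visibility biases — coverage,
mappability and copy number — by symmetric alternating scaling: per-bin
factors are updated until the coefficient of variation of the unmasked
marginals falls below `tol` (default 1e-5, `max_iter` 200). The corrected
matrix keeps the total sum of the input; dividing by that total yields the
relative form in which copy-number differences between conditions cancel (a
tetraploid chromosome with twice the interactions is scaled back onto the
diploid profile). Convergence is part of the contract: non-convergence
warns with the final CV rather than failing silently.

One caveat the tests make explicit: on short chromosomes the unbiased
expectation itself has unequal marginals (distance-decay truncation at the
ends), so ICE factors are the product of the planted bias and a structural
edge component. Bias-recovery checks therefore compare against the planted
bias after dividing out the structural factor obtained from balancing the
noiseless unbiased expectation.

## Distance-normalized Z-scores

`distance_expected()` models the distance decay: for every genomic distance
`d` the unmasked cis values are collected, an interquartile-range filter
(`iqr_factor` = 1.5) drops outliers, and the per-distance mean and sample
SD (n−1 denominator, fixed so oracle tests are exact) are smoothed by
weighted local regression with span `alpha` = 1%. Two numerical choices
matter here:

* Smoothing is done in log–log space (log mean and log SD versus log d),
  where a power-law decay is exactly linear. Local linear smoothing on the
  natural scale is visibly biased at short distances, where the decay is
  steeply convex, and that bias propagates directly into the z-scores.
  Weights are the per-distance observation counts
  (`limma::weightedLowess`). When fewer than ten distances are defined the
  smoother is skipped; `alpha = 0` disables it explicitly.
* The IQR filter is skipped at distances where the IQR is zero. At large
  distances counts are small integers and the quartiles collapse onto a
  single value; a degenerate band would discard every nonzero observation
  and poison the profile.

`zscore_transform()` standardizes each cis cell against the profile at its
distance; cells are missing (never ±Inf) where the profile is undefined or
the SD is zero. Trans cells are standardized per chromosome pair — the
per-pair mean absorbs translocation-scale level differences least
aggressively while keeping the statistic defined genome-wide. The expected
profile is genome-wide by default with a per-chromosome option; the
convention in the source analyses is not stated, and genome-wide pooling is
the more stable choice at coarse resolutions.

Calibration (per-distance z mean within ±0.05 and SD within 0.9–1.1) is
asserted on structure-free maps, aggregated over distances with at least 30
observations: per-distance values at sparse distances are dominated by
sampling noise, not by miscalibration.

# Differential interactions

`differential_score()` implements the replicate-null standardized
difference at the conventional 6.5-Mb resolution. Per cell, the mean of the
four between-condition z differences (A1−B1, A1−B2, A2−B1, A2−B2) is
standardized against the dispersion of within-condition replicate
differences at `n_null` (default 500,000) cells sampled uniformly without
replacement from the cells defined in all four maps. Two deliberate
choices:

* The null dispersion is the *standard deviation* of the sampled replicate
  differences, not the standard error of their mean — an SE would shrink
  with `n_null` and make the scores diverge.
* The null pool is symmetrized: each sampled cell contributes both signs of
  each replicate difference. Replicate order is arbitrary, so the null is
  symmetric by construction; this makes the null mean exactly zero and the
  score matrix exactly antisymmetric under condition swap, which is the
  property users rely on when reading "condition-A-enriched" off the sign.

The sampling is seeded and reproducible; determinism here is this
package's contract (the random scheme of the original analysis is not
recoverable). By construction the scores are conservatively scaled (the
four cross differences average away replicate noise while the null keeps
it), so the null fraction of |score| > 2 runs well below the nominal 5%.
`subtract_zscores()` provides the plain zA − zB variant, and
`interchrom_set_comparison()` aggregates trans scores for chromosome-set
contrasts (e.g. small gene-rich chromosomes versus the rest) with a
two-sided Wilcoxon rank-sum test.

# Compartments

`call_compartments()` computes, per chromosome, the Pearson correlation
matrix of cis z-score columns and takes the first principal component. The
sign is oriented by gene density (count of caller-supplied gene-interval
midpoints per bin): bins above the median density should sit on the
positive side, which is labelled A. The eigenvector–density correlation is
recorded as orientation evidence; the first component *usually* captures
the compartment plaid, and a weak evidence value flags chromosomes where it
may instead track e.g. a chromosome arm split. The package logs, but never
silently switches to, another component. Eigenvector magnitude is not
thresholded — sign alone defines the label — and chromosomes with fewer
than 10 defined bins stay undefined.

Switch classification is the cross-tabulation of per-bin labels
(condition 1 → condition 2). Enrichment of switching on a chromosome subset
uses the Yates continuity-corrected chi-square on a 2×2 of (subset vs rest)
× (switched-in-direction vs stable), each direction tested separately with
stable = A→A ∪ B→B. Genes are assigned to compartment bins by interval
midpoint (half-open, so a midpoint on a bin edge belongs to the bin
starting there); TSS- or overlap-based assignment would be equally
defensible, and midpoint was chosen as the simplest convention.

# TADs

`insulation()` slides a `w`×`w` square (default 25 bins = 1 Mb at 40-kb
bins) along the diagonal; the raw score of a bin is the mean unmasked value
in the square strictly up/downstream of it (diagonal excluded). Scores are
undefined within `w` bins of a chromosome end or where more than half of
the square is masked, and normalized per chromosome as
log2(raw / chromosome mean).

`call_boundaries()` takes local minima of the normalized track as
candidates, after a light 3-bin running-mean denoising that sharpens valley
localization to the bin level without displacing wide valleys (`smooth_bins
= 0` disables it). Minima at the very edge of the defined region are not
candidates — a monotone slope running into the undefined zone is not a
valley. Boundary strength is the mean depth of the valley below its nearest
flanking local maxima within `peak_window` (500 kb per side; where a flank
has no local maximum its highest value is used). Strength is
implementation-defined here: the source analyses threshold a "boundary
strength" at 0.15 without giving a formula, and valley depth on the
log2-normalized track is the natural reading consistent with such a cutoff.
Published boundary counts are therefore approximate reproduction targets
only. Retained cores are extended by 80 kb per side (200-kb final span, the
convention that absorbs replicate variation) and overlapping extended
intervals merge keeping the stronger core.

TADs are the complement of the merged extended boundary intervals, minus
caller-supplied telomere/centromere exclusions, dropping fragments shorter
than one bin. Cross-sample classification: boundaries are "overlapping"
when extended intervals intersect; TADs are "overlapping" under an
inclusive reciprocal 90% rule (the bedtools `-f 0.90 -r` convention).
`boundary_profile()` averages feature-midpoint counts in 25-kb offset
windows within ±1 Mb of boundary cores — the standard meta-profile for
factor enrichment at boundaries.

# Scaling and telomeres

`scaling_curve()` reports mean unmasked cis contact per log-spaced distance
bin (50 bins by default; the binning is ours, the source does not state
one) at genome, chromosome or arm scope; arm scope requires a centromere
table and uses only cells with both bins on the same arm.
`fit_scaling_slope()` estimates the decay exponent by weighted log–log
regression, and `scaling_upturn()` quantifies a telomeric upturn as the
ratio of observed tail means (top 10% of distances) to the extrapolated
mid-range power law — near 1 when the decay continues to the chromosome
end, well above 1 when the two ends cluster. The per-arm curves of a
telomere-clustered chromosome show no upturn, because end-to-end cells
never lie within one arm; this contrast is the package's localization
argument, mirrored in the acceptance tests.

`telomere_interaction()` takes, per chromosome, the mean ICE-corrected
value over cells pairing bins in the first and last `end_fraction`
(default 5%) of the chromosome length — corrected values so copy number
does not confound the comparison, and first-versus-last paired within each
chromosome (the natural reading of "ends, 5% by length").
`compare_telomere()` tests the per-chromosome vectors of two conditions
with a two-sided Wilcoxon rank-sum test. Degenerate all-tied rank-sum
comparisons return p = 1 throughout the package (the normal approximation
is 0/0 there, and no shift is detectable).

# The synthetic generator

`synthetic_spec()` parameterizes a two-condition, two-replicate study whose
expected intensity is a product of interpretable factors:

| factor | form | default |
|---|---|---|
| cis decay | (distance in bins)^(−α), diagonal set to the distance-1 value | α = 1.0 |
| compartments | 1 + s·e_i·e_j, e ∈ [−1,1] plaid blocks | s = 0.6, 8-bin blocks, ~12% of bins flip sign in condition 2 |
| TADs | ×t within a planted segment | t = 3, spacing 18–30 bins, 85% of boundaries conserved in condition 2 |
| telomeres | ×b on first-end × last-end cells | b = (3, 1): boost in condition 1 only |
| trans floor | constant relative level | 0.05 |
| small chromosomes | × on trans cells within the subset | (2, 1): clustering in condition 1 |
| translocation | × on a trans block | one 8× block in condition 2 |
| bias | lognormal per-bin multiplier | sdlog 0.25 |
| copy number | ×√(c_i·c_j) per cell | all 1 |

The matrix is scaled to an expected total of `depth` read pairs and
replicates are independent Poisson draws — the minimal noise model under
which replicate variability, and hence the differential null, emerges
naturally. Everything is materialized deterministically from one seed.

The defaults emulate the comparative design the package targets: condition
1 behaves like a near-diploid epithelial line (telomere clustering,
small-chromosome trans clustering), condition 2 like an aneuploid tumor
line (translocation, compartment switches toward open on some bins). What
the generator does **not** emulate: restriction-fragment granularity,
ligation artifacts, distance-dependent overdispersion beyond Poisson,
nested/hierarchical TADs, and sequence-driven mappability structure.
Passing the planted-truth tests therefore demonstrates correctness of the
detectors' logic and calibration of their statistics under idealized noise
— not their power on real libraries.

Module-level validations use reduced specs that plant only the structure
the module under test detects (e.g. compartment tests at ~Mb bins disable
sub-bin TAD structure; TAD tests at 40-kb bins disable compartments). This
is resolution-appropriate — each planted feature lives at the scale of its
detector — and keeps every test's failure mode interpretable.

Problem sizes in the tests and the acceptance script are desk-scale by
design: genomes of 25–260 Mb across 1–23 chromosomes, depths of 1e6 per
map (1e7 pooled for the genome-wide telomere quantification, giving
per-cell coverage comparable to a real library on a genome this size), 10
or 20 seeds for stochastic properties. At these sizes the full suite runs
in well under a minute.

# Known limitations

* The boundary-strength formula and the LOWESS weighting dialect are
  interpretations (flagged above); published boundary counts and
  compartment percentages from real libraries are not expected to
  reproduce exactly.
* The insulation square needs `2w+1` bins per chromosome; short
  chromosomes (or very coarse binning) yield undefined tracks, and
  boundaries within `w` bins of a chromosome end are undetectable in
  principle.
* ICE assumes a connected contact graph on unmasked bins; fully
  disconnected blocks are masked with a warning rather than balanced.
* The differential statistic reports standardized scores and set-level
  rank-sum tests; it deliberately stops short of per-cell multiple-testing
  calls.
* Trans z-scores are per-chromosome-pair standardized, so a whole-pair
  level shift (e.g. a whole-arm translocation) is absorbed into the pair
  mean and only its internal structure remains visible.

# The pipeline entry point

`run_pipeline(spec, config, out_dir)` executes the full recipe on a
synthetic study and writes every stage's outputs (bedGraph eigenvectors and
insulation tracks, BED boundaries and switches, TSV score matrices and
curves, the generator truth) plus `manifest.json` with the configuration
echo and an md5 checksum per file; identical spec/config/seed give
byte-identical outputs. `default_config()` carries the conventional
constants — 6.5 Mb / 250 kb / 40 kb analysis resolutions, 25-bin square,
0.15 strength cutoff, 0.90 reciprocal overlap, 5% ends, 500,000 null
interactions, log2FC > 1 and adjusted p < 0.01 expression filters — all
overridable individually or through a YAML file (`read_config()`).
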