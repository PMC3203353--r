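---
title: "Hot-spot detection methods for viral integration site data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hot-spot detection methods for viral integration site data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vishotspot` detects genomic regions where viral vector integration sites
(VIS) cluster. This vignette explains the statistical models the package
implements, the parameters that matter and their defaults, the numerical
conventions adopted where a choice had to be made, and what the synthetic
data used in the test suite does and does not establish.

## The binning substrate

All genome-scale analyses start from a partition of the genome into
consecutive bins of 1 Mb (configurable via `bin_size`). Chromosomes are
concatenated ("strung together") in a fixed order into a single sequence of
`n` bins, so that every bin has a genome-wide index and density context is
shared across chromosomes: a chromosome that is globally VIS-rich can
contribute several hot-spots. Bins are half-open `(start, end]` in 1-based
coordinates; the last bin of each chromosome is a partial bin (ceiling
division), and bins never span chromosome boundaries. For the human hg18
assembly restricted to chr1–22, X and Y this yields exactly 3091 Mb bins;
random and haplotype contigs are excluded. The megabase unit is a
deliberate default: lentiviral hot-spots are often megabase-scale, while
kilobase-scale structure is the CIS method's domain.

A partition can be shifted by `shift` base pairs in `[0, bin_size)`; the
first bin of each chromosome then has width `shift`. Because hot-spot
calls can depend on where the grid falls, `merge_hotspots()` unions results
from several shifts (any overlap ≥ 1 bp merges; statistics are recomputed
from the member VIS of the union, never averaged from the parents).

## z-threshold method

Bin counts `C` are standardised over all `n` bins as
`X_i = (C_i − mean(C)) / SE(C)` with `SE(C) = sd(C)/sqrt(n)` — the standard
error of the mean bin count. The standard-error scale (rather than the
plain standard deviation) is the scale on which the shipped default
threshold of 422 lives: for a ~900-VIS dataset over 3091 bins it
corresponds to roughly 5 VIS in one bin. Thresholds are calibrated, not
universal: `get_threshold()` returns a percentile (default 99.92) of a
reference dataset's z-scores, encoding the principle that acute-infection
or pre-transplant data — which reflect vector-intrinsic integration
preferences but no clonal selection — should produce few or no hot-spots.
Percentiles use linear interpolation between order statistics
(`stats::quantile` type 7), and that convention is recorded in every
`threshold_spec` because calibrated values are only reproducible under it.

Hot-bins are bins whose score *strictly* exceeds the threshold; exact ties
are excluded and reported. Maximal runs of consecutive hot-bins on one
chromosome become hot-spots, and each outer boundary is moved to the VIS
nearest to the bin edge. The nearest VIS may lie outside the run (hot-spots
may extend past a bin edge); when two VIS are equidistant the interior one
is chosen — the tie-break is arbitrary but fixed and documented. A hot-bin
run with no VIS anywhere on its chromosome keeps its bin edges, with a
warning. Runs separated by even one non-hot bin are never merged.

A rate-scale variant divides counts by the dataset total
(`rate_profile()`); rates sum to one and the analogous default threshold is
0.006. It is less size-stable than the z-scale and is provided mainly for
comparison.

Degenerate inputs are refused explicitly: all-equal bin counts have zero
variance and no meaningful z-scores, and an empty dataset has no rates.

## Bayesian change-point (BCP) method

The z-score sequence is modelled with the Barry–Hartigan product-partition
Gaussian model: an unknown partition of the `n` bins into contiguous blocks,
`X_i ~ N(μ_i, σ²)` with a common mean per block, block means drawn around a
grand mean with variance inversely proportional to block length, and
uniform priors on the block-boundary probability `p ∈ (0, p0]` and on the
variance ratio `w = σ²/(σ² + σ0²) ∈ (0, w0]`. Integrating the grand mean,
the error variance, `p` and `w` gives a partition posterior proportional to

    ∫₀^p0 p^(b−1) (1−p)^(n−b) dp · ∫₀^w0 w^((b−1)/2) (W + wB)^(−(n−1)/2) dw

for a partition with `b` blocks, within-block sum of squares `W` and
between-block sum of squares `B`. A Gibbs sampler toggles each internal
boundary indicator from its exact conditional odds. Both one-dimensional
integrals are evaluated in closed incomplete-beta form in log space (the
raw integrals underflow double precision at `n = 3091`); for small `n`,
where the beta-shape condition fails, a log-space Simpson rule over 2000
intervals takes over. Degenerate configurations (zero between-block or
within-block sums of squares) have analytic limits, which are handled
explicitly — a constant signal, for instance, yields change probabilities
at the prior level and flat posterior means.

After each post-burn-in sweep the block means, shrunk toward the genome
mean by the conditional posterior mean of `w` given the partition, are
accumulated; their average is the posterior mean `μ̂_i` per bin, and the
average of the boundary indicators is the change probability `P_i`. The
sampler starts from the single-block partition. Hot-bins are bins with
`μ̂_i` above the *same* threshold used for z-scores (422 by default), and
refinement to hot-spots reuses the z-threshold machinery. `1 − P̄`, one
minus the mean change probability, measures genome-wide clustering.

Defaults: `iterations = 10000` sweeps after `burnin = 50`, `p0 = w0 = 0.2`,
and an explicit `seed`. The conventional 500-sweep default of this model
family is raised because genome-scale runs need the longer chain: across
differently seeded runs, hot-bin posterior means stabilise (SD ≤ 0.007 on
the z scale) from about 5000 sweeps, which `check_convergence()` verifies
for any dataset by re-running the sampler under several seeds and flagging
bins whose hot-bin call is seed-dependent. Burn-in is left at its
conventional value when iterations are raised. Identical seed and
configuration give bit-identical results; the sampler draws exclusively
from R's RNG stream so `set.seed` governs everything.

Chromosome boundaries are *not* forced change-points — the genome is one
sequence. The 23 bins that straddle a chromosome junction could in
principle absorb signal from two chromosomes; in practice junction blocks
are short and the effect has not been observed to change any hot-bin call.

### Method selection

The BCP sampler can miss short signals near the threshold in sparse or
highly clustered data. The package therefore encodes selection rules:
datasets with more than 300 VIS and cluster score `1 − P̄ ≤ 0.98` use BCP;
datasets with 101–300 VIS, or highly clustered ones (`1 − P̄ > 0.98`), use
the z-threshold method; datasets with ≤ 100 VIS are refused outright, since
no defensible rule exists at that size and silently guessing would be
worse. Automatic reroutes are logged with the rule that fired, and results
carry a provenance label (`bcp_via_zthreshold`) so summary tables remain
auditable.

## CIS baseline

The conventional common insertion site definition — by default ≥ 3 VIS
within 50 kb or ≥ 4 within 100 kb, a 1 bp sliding window — is implemented
via the equivalence that a width-`X` window holding `Y` VIS exists iff some
`Y` consecutive sorted VIS span less than `X` bp, giving an O(m) scan whose
results are identical to the literal sliding window (the test suite checks
this against a brute-force 1 bp oracle). The two clauses act as alternative
triggers and their qualifying runs are unioned; overlapping or VIS-sharing
runs merge into maximal disjoint hot-spots whose boundaries are the
outermost member VIS. The merged-interval convention is what makes
hot-spot *counts* well-defined and is recorded because published CIS counts
do not always state it.

## Conservation, clustering and feature statistics

Hot-spot conservation between two datasets is tested on *hot-bins* (not
hot-spots, to control for hot-spot size): a 2×2 table over the shared
partition — hot in both / A only / B only / neither — is evaluated with a
two-sided Fisher exact test, defining the two-sided p-value as the sum of
hypergeometric point probabilities not exceeding the observed one. Under
that convention the package reproduces the worked examples of the original
calibration analysis (p ≤ 2.2e-16, 6.6e-5, 0.007) to their printed
precision; `stats::fisher.test` implements exactly this definition and is
used directly, while the test suite checks it against an exhaustive
enumeration oracle. No multiple-testing correction is applied across a
pairwise conservation matrix; users comparing many datasets should apply
their own. A conservative significance annotation of 0.007 is the default
because an acute-versus-post-transplant comparison with a single
overlapping hot-bin reaches that value — a natural benchmark when no
reference comparison is available.

Two clustering metrics summarise a dataset: `100·max(X)/ΣC` (the "maximum
%", > 8 indicating strong clustering) and the BCP cluster score `1 − P̄`
(> 0.98 indicating strong clustering).

Feature analysis counts, per hot-spot, the features of a user-supplied
BED-like track (genes, CpG islands, repeats) overlapping it by ≥ 1 bp —
each feature counted once per hot-spot, partial overlaps included, since no
principled fraction rule exists for point-like features — and divides by
hot-spot size in Mb. The comparison population is the per-bin density
vector over *all* bins of the partition (a rank-sum test needs a second
sample, and restricting to VIS-bearing bins would condition on the
outcome); hot-spot densities are compared to it with a Wilcoxon rank-sum
test (continuity-corrected normal approximation), Bonferroni-corrected at
0.0025 for the canonical 5-dataset × 4-feature design. Cancer-gene content
is reported as the percentage of hot-spot genes that are cancer-related
(controlling for gene density) with a Fisher exact test against the
genome-wide split; the test choice is recorded in the output because
percentage alone is not a significance statement.

## Synthetic data: what it emulates and what it does not

`generate_synthetic_vis()` draws background VIS uniformly over the genome
(chromosomes weighted by length) and cluster VIS uniformly within declared
windows, keeping ground-truth labels. This emulates the two features the
detectors actually exploit — a diffuse background plus localised excess
density — and supports exact recall/false-positive accounting.

It does not emulate vector-specific integration preferences: transcription
start site bias, gene-body preference of lentiviral vectors, palindromic
motif effects, or chromatin-state covariates. Passing tests on synthetic
data therefore demonstrate that the detectors find density excesses of the
planted magnitude under a uniform null — not that real acute-infection data
is uniform (it is not), nor that the shipped threshold is optimal for any
particular vector. On real data the reference-calibration step absorbs
vector-intrinsic bias into the threshold; that is the method's design, and
it is why thresholds should be recalibrated per study rather than reused.

The test-suite study conditions were fixed in advance of any tuning: a
6 × 50 Mb toy genome (300 bins), a 2400-VIS source cohort of 2112
background VIS plus five single-bin clusters carrying 3/2.5/2.5/2/2 % of
the VIS (mirroring the per-hot-spot VIS shares of published lentiviral
datasets), an acute-style uniform reference of 960 VIS (40 % of the source,
the proportion seen in the calibration study), subsample sizes 200–2000 in
the canonical grid, and 10 replicates per size. BCP runs inside the study
use 600 sweeps — above this model family's conventional 500 — while the
planted-step acceptance fixture exercises the full 10 000-sweep default on
2000 bins. The exact-oracle cross-check enumerates all partitions at
`n = 14` bins; enumeration is exact, and the marginal partition posterior
does not factor over blocks once the variance is integrated out, so a
larger dynamic-programming oracle is not available.

## Numerical conventions, in one place

* Quantiles: type 7 (linear interpolation). Thresholds are meaningless
  without this convention and carry it in their metadata.
* Threshold comparisons: strict `>`; exact ties excluded and reported.
* Boundary refinement ties: interior VIS preferred.
* Coordinates: 1-based positions in, half-open `(start, end]` bins,
  BED (0-based) out; hot-spot tables print Mb with 3 decimals.
* Fisher two-sided p: sum of point probabilities ≤ observed; values quoted
  against a display floor such as 2.2e-16 are tested as `p ≤` that floor.
* BCP integrals: incomplete-beta closed forms in log space; Simpson
  fallback when the second beta shape is non-positive; analytic limits for
  zero sums of squares.
* Degenerate inputs error early and explicitly (constant counts, empty
  datasets, ≤ 100-VIS method selection).
* Duplicate VIS positions are counted but flagged, since published datasets
  are deduplicated upstream.
* Strand, if present in input, is carried through and ignored.

## Known limitations

* The 1 Mb bin width is a tuned default for lentiviral data; murine
  leukemia virus datasets cluster at kilobase scale and may warrant smaller
  bins alongside the CIS baseline.
* Shifted partitions mitigate but do not eliminate grid dependence;
  merging across shifts trades a little specificity for sensitivity.
* The BCP model assumes Gaussian noise on z-scores derived from counts;
  for very sparse datasets the discreteness of counts makes the z scale
  coarse, which is one reason the ≤ 100-VIS refusal and the 300-VIS BCP
  lower bound exist.
* Genome builds other than the bundled hg18 table must be supplied by the
  user as chromosome-size files; no liftover is performed.
* Annotation tracks are user-supplied files; the package performs no
  network retrieval.
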