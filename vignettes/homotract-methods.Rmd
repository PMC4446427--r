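---
title: "Methods: positional mutation analysis of mononucleotide repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: positional mutation analysis of mononucleotide repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and numerical choices
behind `homotract`, in the order the pipeline runs them.

## 1. Tract model and coordinate system

A *tract* is a maximal run of one base (A, C, G or T) of length 4–13 bp on
the reference. Runs of A or G read 5′→3′ on the forward strand
(`purine_strand = "+"`); runs of T or C are the same object seen from the
minus strand (`purine_strand = "-"`). Every position is expressed on the
purine-rich strand: tract bases are numbered 1..n, the 5′ flank is position
0 and the 3′ flank position n+1. For minus tracts the flanks therefore swap
and complement relative to the forward sequence; a reference coordinate x
(0-based) maps to p = x − start + 1 on plus tracts and p = end − x on minus
tracts. This single convention is what makes A- and G-tract spectra, and
tracts on either strand, directly comparable.

Scanner edge rules, each of which changes counts if chosen otherwise:

* **Runs longer than 13 bp are excluded entirely, not truncated.** A
  truncated long run would contribute a spurious "tract" whose flank equals
  its own base, violating maximality.
* **Runs abutting a sequence end are excluded**, because positions 0 and
  n+1 must exist for the positional model.
* **Characters outside A/C/G/T count as N**: N never extends a run, and a
  tract may carry an N flank. Such tracts stay in the per-(class, n) census
  marginals but are excluded from any flank-conditioned stratum and from
  the flank-direction statistic.

The census `N(class, n, flank5, flank3)` is the denominator of every
normalized statistic. When a region mask is supplied (e.g. exons), a tract
counts only if *wholly contained* in a merged mask interval — the tract is
the unit of normalization, so partial overlap would make numerator and
denominator incommensurable. Census comparisons between genomes of
different sizes (`census_percent_difference`) normalize each census to its
per-class total before differencing, because raw counts confound abundance
with sequence coverage; the raw-count difference remains available via
`normalize = FALSE`.

## 2. Variant normalization and assignment

VCF records are split to biallelic, trimmed to the parsimonious
representation, and left-aligned to the leftmost equivalent placement —
the convention of the large population call sets, and the only way
homopolymer indels from different sources land on comparable coordinates.
Records failing the reference-allele check are dropped with a warning;
multi-nucleotide substitutions are out of scope and dropped. Duplicate
sites are removed; counting is site-level (one site = one event), not
weighted by allele or genotype count.

SNVs map directly to purine-strand positions, with the substitution
complemented on minus tracts. A flank SNV whose alternate equals the tract
base is flagged `extends_tract`; position-1 G-tract events with a C flank
are flagged `cpg_context` (the methylation-deamination context).

Indels are classified by **apply-and-rescan**: the edit is applied to a
local window (tract ± 200 bp, enlarged when the edit is larger), the window
is re-scanned, and the run covering the tract locus is compared with the
original. If it has the same base, length n ± 1, and both flanking base
identities unchanged, the event is *slippage* (`slippage_plus` /
`slippage_minus`, named by the length change; ±1 slippage events are
insertions/deletions of one tract unit respectively). Everything else
touching positions 0..n+1 is a general *indel* of 1–200 bp. The two
categories are disjoint by construction: a 1-bp tract-base indel is only
ever slippage, never double-counted.

Choices the data cannot decide, made once and documented:

* **Insertion junctions use the left-aligned placement.** Within a
  homopolymer an insertion's position is inherently ambiguous; the leftmost
  representation is deterministic and matches the input convention. An
  insertion between purine positions j and j+1 gets junction index j ∈
  0..n+1.
* **Deletions are summarized by location class** (`before_tract`,
  `in_tract`, `after_tract`) rather than per-bp, because left-alignment
  makes within-run deletion positions arbitrary. A deletion reaching
  position 0 is `before_tract`; one reaching n+1 is `after_tract`; a
  deletion spanning both flanks is classified `before_tract` (the 5′ purine
  side wins — arbitrary but deterministic).
* For the indel-fraction table, insertion junctions map to the same
  location classes: j = 0 → `before_tract`, j ∈ {n, n+1} → `after_tract`,
  interior junctions → `in_tract`.

## 3. Normalized statistics

All statistics are exact count/denominator ratios with the denominator
drawn from the census stratum matching the numerator's conditioning:

* `F SNV = C(class, n) / (N · n)` — the per-base polymorphic fraction.
* Positional percents `C(class, n, p, from→to) / N × 100`, for p ∈ 0..n+1.
  Flank-conditioned spectra (e.g. the TA[n]T series) divide by the census
  count of the *same* flank stratum.
* Flank-direction bias: among tract SNVs, the fraction whose alternate
  equals the 5′ flank, the 3′ flank, or either.
* `F slip = (plus + minus) / (N · n)` and the +1/−1 ratio (missing, never
  infinite, when there are no −1 events).
* `F Indel = C / (N · n)` along the tract but `C / N` at the flanking
  locations, so per-base and per-site rates are not conflated.
* Insertion junction percents `C(j) / N × 100` over j ∈ 0..n+1.
* Dataset equalization: two call sets of very different depth are placed on
  one axis by the factor that equalizes the anchor stratum (class, n = 4) —
  the shortest, most abundant, least biased stratum.

Per-position "percent" counts events by default; if several SNVs hit one
tract at the same cell the percent can exceed a per-tract probability. The
`per_tract = TRUE` option counts affected tracts instead.

## 4. Nucleosome phasing

Dyad-distance profiles count tract base pairs or tract centers at each
distance d ∈ [−73, 73] from nucleosome midpoint positions. A tract within
reach of several midpoints contributes to each (`nearest_only` restricts to
the closest). Even-length tract centers use the left-of-center base —
deterministic and documented. Extrema of the (running-mean smoothed)
profile alternate maxima/minima; exact plateau ties resolve toward the
smallest |d|. On the integer grid a 10.5-bp cosine over [−73, 73] has 13
interior maxima (at 10.5k, k = −6..6) and 14 interior minima; near-ties at
half-period offsets (e.g. d = 10 vs 11) are resolved by floating-point
comparison of analytically equal values, so either member may be reported —
the count and alternation are stable.

The max/min comparison computes %SNV per tract position within each
extremum site, pairs the k-th maximum with the k-th minimum ordered along
the particle, and runs a paired t-test per position; both raw and
Benjamini–Hochberg-adjusted p-values are reported (raw values are the
primary readout, matching common practice for these profile contrasts).

Orientation ratios divide C-forward (purine strand "−") by G-forward ("+")
G-tract counts per d. Smoothing uses tricube-weighted local polynomial
regression with span 0.100 and degree 3; `stats::loess` caps the local
degree at 2, so the smoother is implemented in-package and agrees with
`loess` at degrees ≤ 2. Periodicity is estimated by least-squares harmonic
power on a dense period grid (8–13 bp, 0.01-bp steps, valid off the Fourier
grid), refined by quadratic interpolation of the power maximum, with
significance from a permutation null (series values shuffled, maximum power
re-measured; 1,000 shuffles, seedable).

## 5. Structure statistics

`V_step` summarizes base-pair-step fluctuation as the product of the square
roots of the six eigenvalues of the sample covariance of (shift, slide,
rise, tilt, roll, twist) — algebraically √det Σ, in Å³deg³. The unbiased
(n−1) covariance normalization is used so values are comparable across
runs; at least 7 frames are required for a full-rank covariance, and a
singular covariance reports 0 with a warning rather than an error.

Groove widths are Euclidean phosphate–phosphate distances per frame and
position, averaged over frames. The pairing convention is configurable —
cross-strand with residue offset (default 3) or within-strand — with an
optional constant subtraction (e.g. 5.8 Å for two phosphate radii), and the
convention used is recorded on the output, because groove-width conventions
differ across the literature and raw ~14 Å values are only interpretable
with the convention attached. Water-bridge occupancy is the per-position
fraction of frames with exactly one and exactly two bridging waters, from
pre-tabulated counts; identifying bridging waters in raw trajectories is
out of scope.

## 6. The synthetic-data generator

The generator exists so every stage can be validated by parameter recovery.
It emulates, with known parameters:

* genomes with planted maximal tracts of controlled (class, n, flank5,
  flank3, strand), separated by run-free background (no run ≥ 4 anywhere
  outside the planted set, enforced by iterative resampling and junction
  constraints), so the truth table and the scanner output reconcile
  *exactly*;
* SNVs with per-position weights w(class, n, p), flank-directed A-tract
  substitutions (probability θ; the undirected remainder is drawn from
  non-tract, non-flank bases so the flank-direction statistic recovers θ
  exactly), and a G-tract substitution spectrum;
* slippage with a bell-shaped per-base rate over length and a +1/−1 odds
  parameter, emitted as left-aligned records (at most one per tract and
  sign, because left-aligned slippage records at one tract are identical
  and counting is site-level);
* general indels with a plateau rate for long tracts and geometric sizes;
  inserted sequences use non-tract bases so junction placement stays
  unambiguous under left-alignment;
* nucleosome midpoints placed relative to tract centers with density
  ∝ 1 + a·cos(2πd/P), and an optional in-phase C-forward orientation
  preference;
* multivariate-normal step-parameter ensembles with known covariance.

Default parameters are the generator's study conditions, chosen once to
match the magnitudes reported for human population data: SNV rates peaking
at length 9 (A) and 8 (G) with F SNV maxima near 0.017 and 0.067; edge
hotspots (p = 1, n) for A-tracts and p ∈ {2, 3} for G-tracts with 6:1
weight; θ = 0.9; slippage bells centered at 8 (A) and 9 (G) with peak
F slip near 0.02 and +1:−1 odds of 2; indel plateaus for n ≥ 7 an order of
magnitude higher for G-tracts (0.03 vs 0.003 per base); phasing period
10.5 bp. All are overridable.

What the generator does *not* emulate — and hence what passing recovery
tests do not show about real data: genomic base composition and
interspersed repeats (background is run-free by construction),
linkage/haplotype structure, allele frequencies, sequencing and calling
error, mutation-rate heterogeneity beyond the modeled covariates, and any
coupling between nucleosome occupancy and mutation rate other than the one
explicitly injected in validation studies.

## 7. Validation design and problem sizes

The test suite validates each stage against an independent oracle:
a lookaround-regex maximal-run finder for the scanner (1,000 random 10-kb
sequences, plus exact reverse-complement invariance), `bcftools norm` for
left-alignment, direct run-walking on edited sequences for every slippage
call (>10,000 cases), closed-form √det Σ for `V_step` (100 random
covariances at 10⁻⁹ relative tolerance), and `stats::loess` for the
smoother at degree 2. End-to-end recovery runs 100,000 planted tracts under
the default model and requires the positional profile to correlate with
truth at r > 0.95, θ recovered within ±0.03, slippage peak lengths exactly,
and an injected 10.5-bp phasing period within ±0.2 bp; a dedicated
phasing sub-study (60,000 length-5 A-tracts, 60,000 midpoints) injects a
20% SNV excess at profile minima and requires the paired t-test to detect
it at p < 0.05. These sizes make every recovery check statistically
well-powered while keeping the whole suite runnable on a laptop in
minutes; `scripts/acceptance.R` re-runs the same study from a command-line
seed and writes the recovered quantities as JSON.

## 8. Known limitations

* Paper-scale genomic numbers (full-genome censuses, population F SNV
  tables) require the corresponding reference assembly and call-set
  downloads; the package computes them given those inputs but ships no
  genome data.
* The slippage classifier trusts left-aligned input; records aligned by
  other conventions should pass through `normalize_variants` first (always
  done by `run_pipeline`).
* Insertion junction indices for slippage insertions are degenerate (any
  placement within the run is equivalent); they are reported at j = 0, the
  leftmost placement, in the insertion matrix.
* The paired max/min t-test assumes site-level %SNV values are
  exchangeable across extremum sites; strong covariates along the particle
  (e.g. GC gradients in real data) would violate this and are not modeled.
* `estimate_period`'s permutation null shuffles positions independently,
  which tests against white noise, not against autocorrelated backgrounds.
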