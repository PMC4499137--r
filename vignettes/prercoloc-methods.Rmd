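---
title: "Methods: windowed co-localization, signal tracks, and synthetic data"
author: "prercoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed co-localization, signal tracks, and synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prercoloc)
```

This vignette is the package's account of the statistical procedures it
implements, the choices that were genuinely open, and what the synthetic-data
tests do and do not establish about real sequencing data.

## Coordinates and data model

All coordinates are 0-based half-open (BED native): an interval `[start,
end)` covers bases `start … end − 1`. On the minus strand the TSS is
`tx_end − 1`, the last covered base, so a TSS is always a valid coordinate.
Peaks on chromosomes missing from the genome model are an error rather than
a silent drop — a quietly shrunken peak set would bias every shuffle-based
null below. The genome model's total length is the single source of truth
for all density and mean-interval arithmetic.

## Windowed co-localization

"A has B within *d*" means the *edge gap* — the distance between the nearest
edges, zero for overlapping or abutting intervals — is at most *d* (500 bp
by default). Edge gap is the more inclusive of the two common readings for
broad peaks; a center-to-center metric is available behind
`metric = "center"` for sensitivity analysis. Distances across chromosomes
are infinite. Equidistant nearest neighbours are ties in distance only; the
distance value is what every downstream operation consumes.

`select_within(A, B, d)` partitions A into `A_w{d/1000}_B` and
`A_wo{d/1000}_B`; chaining it builds nested classes such as
`CDC6_w0.5_MCM7_w0.5_sGRWD1`. The sweep implementation (per chromosome:
subjects sorted by start, prefix running maximum of ends for the left side,
first later start for the right side) is exactly equivalent to the all-pairs
minimum; the test suite verifies this equivalence on hundreds of random
fixtures and against `IRanges::distanceToNearest` as an independent
implementation.

### The shuffled null and its chi-square

The null model for "co-localization by chance" is a length-preserving
shuffle: the same number of peaks with the same multiset of lengths placed
uniformly at random — per chromosome by default (`same_chrom`), or across
chromosomes drawn proportionally to length (`genome_wide`). `coloc_test`
counts A-peaks with a B-neighbour within *d*, pools the same count over
`n_shuffles` shuffles, scales the pooled count back to one set's worth, and
applies a Pearson chi-square (df = 1, no continuity correction) to the 2×2
table of with/without counts.

Two calibration facts, both measured in this package's test suite, matter
for interpretation:

- With a **single** shuffle realization the test's type-I rate sits at the
  nominal level (≈0.06 measured at α = 0.05 over 200 null runs).
- Pooling more shuffles (the default is 10) *reduces* the variance of the
  null fraction, while the chi-square keeps assuming a full-variance second
  sample; the test therefore becomes conservative (type-I ≈0.01 at 10
  shuffles). This is a deliberate trade: a stabler null estimate at the
  cost of conservatism. The null-calibration study in the acceptance suite
  is run at one shuffle, the design the test statistic is exact for.

No multiple-testing correction is applied across a battery of reports; each
comparison is reported as a single test, and callers emitting many reports
can apply `p.adjust` themselves.

## Signal tracks

Coverage is a moving average: reads (represented by single reference points)
are counted in a 1 kb window evaluated every 0.1 kb. Windows are centered on
bin centers — the symmetric choice that keeps aggregation profiles unbiased
— and truncated, not rescaled, at chromosome ends; this affects fewer than
`window/step` bins per end. An interior read is counted in exactly
`window/step` windows, giving the exact conservation law
`sum(bins) = interior_reads × window/step` that the tests assert literally.

Normalization is a one-way state machine, `raw → rpm → {rpm_ratio,
rpm_diff}`:

- **RPM**: values × 10⁶ / total mapped reads.
- **ratio to input** (ChIP): `(chip + c) / (input + c)` per bin with
  pseudocount `c = 0.5` RPM. The pseudocount is the package's choice for
  zero-input bins — it bounds ratios and makes a bin empty in both tracks
  equal exactly 1 — and is exposed as a parameter.
- **input subtraction** (FAIRE): `faire − input`, floored at zero by
  default since openness is non-negative by construction;
  `floor_at_zero = FALSE` keeps signed residuals for diagnostics.

The division by input happens between two matched moving-average tracks
(smooth first, then divide); smoothing the ratio of raw counts instead would
change edge behaviour at sparse bins.

## Profiles

**Aggregation** uses interval midpoints as reference points on both sides —
the summit-free, symmetric choice, since peak summits are not part of the
data model. Peak-density profiles divide per-offset mean counts by an
expected density, either the analytic genome density (default) or the mean
count around one shuffled copy of the anchors; on uniform data the two
baselines agree within a few percent. Anchors near chromosome ends
contribute only their valid offsets (per-offset denominators, no padding).

**Metagene** profiles orient genes by strand: 50 fixed 100-bp bins upstream
of the TSS, 100 body bins linearly rescaled per gene, 50 bins downstream of
the TES. Region boundaries are half-open so no midpoint is double-counted.
The reported value is mean peak density per bp per gene — "frequency" axes
in the literature are rarely defined; density per bp is the normalization
under which a uniform peak set is flat across flanks and body alike, which
is the property the tests check. Genes shorter than the body bin count are
skipped (scaling them up would alias bins) and reported in `n_skipped`.

**Two-condition comparison** (`faire_compare`) averages the track in a
±2 kb window around each site, in each condition, and tests the per-site
pairs. The default paired Wilcoxon signed-rank test is robust to the heavy
right skew of coverage; a paired t-test is available. With identical inputs
the percent change is exactly 0 and p is reported as 1.

## Synthetic data: what it emulates

The generator exists so that every downstream claim has a known ground
truth.

- **Peaks**: uniform lengths in 300–1500 bp (broad-peak scale; the length
  distribution is a free parameter, not fitted to any dataset). With a
  co-localization fraction *f* and window *d*, `round(f · n)` peaks are
  placed with a signed edge gap uniform on `[−overlap, d]` from a uniformly
  chosen anchor, and the rest are placed uniformly *rejecting* anything
  within *d* of an anchor. Selection against the anchors therefore recovers
  `round(f · n)/n` exactly; the statistical content of the recovery tests
  is that the placement machinery (bounds, rejection, chaining) never leaks
  peaks across the boundary. `distinct_anchors = TRUE` samples anchors
  without replacement, which additionally pins the *anchor-side* fraction —
  needed when a nested class is defined from the anchors' point of view.
  Rejection sampling caps at 1000 attempts per peak and then raises a
  capacity error: failing loudly beats silently biasing *f*.
- **Reads**: per-peak Poisson counts with mean `enrichment × effect`,
  uniform within the peak; the remaining budget is uniform background, so
  the emitted total equals `n_reads` exactly (an enriched demand exceeding
  the budget is an error, not a truncation). The per-site `effect` factor
  is how knockdown conditions are built; the matched input is purely
  uniform with its own budget. There is no fragment-length, GC or
  mappability structure, and no paired ends — reads are points.
- **Annotation**: non-overlapping genes, uniform lengths, fair-coin
  strands.

All generators are pure functions of their inputs and seed; repeated calls
are byte-identical. What passing tests show is that the *pipeline* is
correct and calibrated under these idealized conditions; they cannot show
robustness to the structure real libraries have (duplicate reads,
mappability holes, copy-number variation, summit asymmetry). The FAIRE
effect-recovery loop — plant factor *g* at 10³ sites, measure
`percent_change ≈ 100(g−1)` within ±5 points — closes end to end for
*g* ∈ {0.5, 0.7, 0.9}; the residual ~1-point attenuation comes from the
zero-floored background around sites, which adds a small equal baseline to
both conditions.

## Pipeline and reproducibility

`run_pipeline` drives genome → peak layers → nested selection → tests →
profiles → FAIRE comparison from one R list or YAML file. Every stochastic
stage derives its seed as a 31-bit hash of (master seed, stage name), so
inserting a stage never shifts a sibling's random stream, and two runs with
the same master seed produce byte-identical BED/TSV/JSON outputs (the
manifest additionally records timings, which differ). The demo configuration
uses a 3 × 20 Mb genome, 2000-peak layers with a 0.27 co-localized fraction,
and a FAIRE condition pair of 10⁵ reads at the nested sites — sizes chosen
so a full run completes in seconds while every per-offset and per-site
statistic retains enough counts to be tested at tight tolerances.

## Known limitations

- Peak summits are not modelled; all reference points are midpoints. If
  summit offsets matter, profiles will be broader than summit-anchored ones.
- The chi-square null treats shuffled counts as an independent sample; at
  the default 10 pooled shuffles the test is conservative (see above).
- Edge bins use truncated windows without rescaling; per-bp signal near
  chromosome ends is underestimated by up to the truncated fraction.
- The synthetic read model is intentionally minimal (points, Poisson,
  uniform background); it validates bookkeeping and statistics, not
  robustness to library artefacts.
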