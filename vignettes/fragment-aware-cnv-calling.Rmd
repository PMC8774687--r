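---
title: "Fragment-aware fetal CNV calling: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-aware fetal CNV calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragcnv)
```

## The problem

Non-invasive prenatal testing screens for fetal chromosomal abnormalities
from shallow (~0.25x) paired-end WGS of cell-free DNA in maternal plasma. The
sample is a mixture: a fetal fraction *ff* (typically 2-20%) of the fragments
derive from the placenta, the rest are maternal. A fetal trisomy inflates the
read count of the affected chromosome by a factor `1 + ff/2` — a percent-level
effect that must be separated from percent-level technical bias.

Paired-end data carries a second, independent signal. Fetal cfDNA fragments
are systematically shorter than maternal ones, so on a gained region, where
the local fetal content rises from *ff* to `ff' = 3ff / (2 + ff)`, the mean
fragment size drops by `(ff' - ff) * delta`, with `delta` the maternal-fetal
component gap. fragcnv scores both signals with the same within-sample
normalization machinery and combines them per bin.

## Within-sample normalization

Between-run technical variation makes direct comparison against a pooled
baseline fragile. Instead, each bin is judged against the bins that behave
most similarly *within the same sample*:

1. From a panel of negative controls, bins are profiled across samples
   (normalized read counts; per-bin mean fragment sizes).
2. Uninformative bins are masked from the controls' normalized counts (median
   coverage below 10% of the genome-wide median, or zero counts in more than
   10% of controls) — these appear at centromeres and repetitive regions. No
   predefined exclusion list is used.
3. Shared technical bias (GC and friends) is learned as the top
   principal components of the control matrix, one PCA per datatype, and
   removed from every vector (controls and queries alike) by projecting out
   the component subspace.
4. For every bin, the `K = 300` most similar bins **on other chromosomes**
   (Euclidean distance between across-control profiles) become its reference
   set, weighted by inverse distance. Restricting to other chromosomes keeps
   the reference clean when an event spans a large part of one chromosome.
5. In a query, the bin's Z-score is its observation against the weighted
   mean/SD of its reference bins *in the same sample*:
   `Z_q = (x_q - mu_w) / sigma_w`.

The read-count and fragment-size pipelines run in parallel: separate masks,
separate PCAs, separate neighbor lists. The fragment-size Z is sign-flipped
(`orient_fs()`) so that gains push both tracks positive.

## Combination, segmentation, calling

Per bin, the two Z-scores are combined (`combine_z()`):

- **Fisher** (default): one-sided upper-tail p-values, `X = -2(ln p_rc + ln
  p_fs)` against chi-square with 4 df, mapped back to a normal quantile; the
  lower tail is treated symmetrically and the combined Z takes the sign of the
  stronger side. Note a quirk inherited from one-sided Fisher combination:
  at `(0, 0)` the combined value is -0.24, not 0, and exact gain/loss ties
  resolve to the gain orientation. Bins valid for one datatype only (e.g.
  fragment-size-filtered bins) fall back to the other track's Z.
- **Stouffer**: `(z_rc + z_fs) / sqrt(2)`, available via `combine =
  "stouffer"`.

Per chromosome, the combined track is segmented with circular binary
segmentation (`cbs_segment()`): the arc maximizing the standardized
arc-vs-complement mean difference is cut if its permutation p-value is below
`alpha`, recursively. Segment evidence is aggregated by Stouffer over bins
(`Z_seg = sum(z_i) / sqrt(m)`), following the lineage of within-sample
callers this package builds on — the published method does not specify the
aggregation rule. Events are thresholded at two published operating points:
mode I (span > 10 Mb, `Z >= 5`, gains) and mode II (span > 1 Mb, `|Z| >= 5`).

### Numerical choices

- *CBS statistic*: arc mean minus complement mean over
  `s * sqrt(1/n_arc + 1/n_rest)` with `s` the segment SD; `s` is permutation
  invariant so the permutation test is exact for the mean-difference part.
- *Determinism*: the permutation stream of the segment covering positions
  `lo..hi` is seeded with `cbs_perm_seed(seed, lo, hi)`; this is part of the
  function contract so independent implementations can replay decisions. The
  test suite holds the recursion to a naive brute-force oracle on arrays up
  to 20 bins.
- *Early termination*: a split test stops as soon as the exceedance count
  makes `p >= alpha` certain; this can only shorten the stream consumed, never
  change a decision.
- *Defaults*: `alpha = 0.01`, `n_perm = 1000`, `min_bins = 2` — the published
  method cites CBS without parameters; these are package choices.
- *Ties* in neighbor distances break by lower bin index; weights use
  `1/(d + 1e-9)` to stay finite at distance zero.
- *Degenerate inputs*: zero neighbor spread invalidates a bin; zero-variance
  segments are never split; segments without valid bins are dropped.
- `n_comp = 5` PCs per datatype by default: the published method defers
  component counts to an unavailable appendix; five captures the dominant
  low-rank bias of shallow WGS panels and must stay below the control count.
- Mask fractions (0.1/0.1) and the fragment-size reliability bounds
  (`min_frags = 10`, `max_cov_z = 3` SD of normalized coverage) are likewise
  documented stand-ins for appendix-deferred values, all exposed in
  `default_config()`.

## The simulator's stated world

`simulate_cohort()` generates bin-level cohorts (no reads) so that
400-sample panels run in seconds; a small SAM emitter (`write_toy_sam()`)
exists only for alignment-parsing tests.

| Parameter | Default | Why |
|---|---|---|
| grid | 22 chromosomes x 45 Mb, 750 kb bins | 750 kb is the best-performing published scale; 45 Mb ~ chromosome-21 size, keeps whole-chromosome events > 40 Mb and > 300 cross-chromosome candidates per bin |
| coverage | `0.25 * bin_size / (2*36)` ~ 2604 fragments/bin | 0.25x depth with 36 bp paired-end reads, the cohort's sequencing design |
| `ff` | 0.075 (or a `c(lo, hi)` uniform range) | cohort-average fetal fraction 7.5%; the reported range 1.48-19.15% is available as `ff = c(0.0148, 0.1915)` |
| `mu_maternal`, `sigma_fs` | calibrated (~176.2, ~55.1) | solved so the zero-truncated mixture at ff = 7.5% has mean 173 bp and SD 56 bp, the cohort's fragment statistics |
| `delta` | 45.5 bp | see below |
| `n_bias`, `bias_sd` | 2 profiles, scalar SD 0.05 | two shared multiplicative bias directions giving ~7% cross-bin bias, dominating Poisson noise at 0.25x as real GC bias does |
| counts | Poisson(`coverage * bias_b * cn_b`) | `cn_b = 1 + ff/2` on gains, `1 - ff/2` on losses |
| sizes | per-fragment mixture draw, fetal prob `ff` (`ff'` on events) | every fragment drawn individually, truncated at zero |

**Choice of `delta`.** The size gap between the maternal and fetal component
means is not printed by the source cohort; what is printed is a ~1.52 bp
chromosome-wide shift toward shorter fragments for trisomic samples at a mean
fetal fraction of 7.5%. Inverting the shift formula `(ff' - ff) * delta` at
`ff = 0.075` gives `delta ~ 45.5 bp`, which this package adopts as the
default. A much smaller gap (say 10 bp) would make the fragment-size track
analytically too weak (`z_fs ~ (delta/sigma) * z_rc ~ 0.18 z_rc`) for
combination ever to beat read counts alone — inconsistent with the observed
behaviour the method exploits. Both `delta` and the fetal-fraction setting
remain explicit knobs, since the chromosome-wide shift conflates the two.

**What the generator does *not* emulate**, and hence what a green test does
not establish: the true bimodal nucleosomal size ladder (a truncated-normal
mixture is enough because the pipeline only consumes per-bin means, but
distribution-shape methods cannot be assessed on it); GC-dependent bias with
its real covariance structure (bias is planted as generic low-rank
log-linear profiles); mappability holes, sex chromosomes, mosaicism, maternal
CNVs; library-prep batch effects beyond low-rank structure. Detection-power
results on simulation translate to real cohorts only to the extent that the
real bias is low-rank and the per-bin size means are unbiased.

The simulator applies no 300 bp cap: the cap is an alignment-input filter,
and the calibration targets the uncapped mixture (about 1.1% of its mass
lies above 300 bp). Whether the cohort's printed 173/56 were computed before
or after capping is ambiguous in the source; this is the package's reading.

## Known limitations

- References and queries must share the exact bin grid (enforced by a grid
  hash); multi-scale analyses are run per scale.
- Bins where any control lacks fragment-size data are excluded from the
  fragment-size arm entirely.
- With panels much smaller than ~20 controls the PCA bias estimates get
  noisy; the neighbor distances then partially reflect sampling noise and
  per-bin Z-scores lose a little power (they stay calibrated, since query
  and neighbors share the inflation).
- Mode I is deliberately one-sided (gains); losses at whole-chromosome scale
  are only reported in mode II, mirroring the published operating points.
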