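---
title: "Maternal CNV detection from low-coverage cfDNA: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maternal CNV detection from low-coverage cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niptcnv)
```

## The signal model

Cell-free DNA in maternal plasma is a mixture: a fetal (placental)
fraction *ff*, typically 5–25% in the screening window, on a maternal
background. At 0.12–0.5× coverage the informative signal is read depth
per genomic bin. `niptcnv` works on a fixed 20 kb grid; for a bin with
maternal copy number $m$ and fetal copy number $f$ the expected
normalized depth ratio is

$$c = (1 - \mathit{ff})\,\frac{m}{2} + \mathit{ff}\,\frac{f}{2}.$$

A heterozygous *maternal* CNV is inherited by the fetus on the maternal
haplotype, so $f = m$ and the ratio is $m/2$ — exactly 1.5 or 0.5,
independent of fetal fraction. A *fetal-only* CNV perturbs the ratio by
only $\pm ff/2 \le 0.125$. This separation is what the calling threshold
exploits: a segment whose deviation from 1, expressed as a fraction of
the heterozygous shift 0.5, exceeds 75% (ratio outside
$[0.625, 1.375]$) cannot be fetal at screening-range fetal fractions
and is designated maternal. We read "signal deviation exceeding 75%" as
75% *of the heterozygous single-copy shift*; it is the only reading
under which maternal het CNVs (deviation 100%) pass while fetal events
(deviation ≈ *ff*) fail, which is precisely how the calls acquire their
"maternal" label. Alternative readings (raw ratio departure, a z-based
cut) would either call nothing or stop excluding fetal signal.

## Normalization

Raw bin counts carry two dominant artifacts.

**GC bias** is corrected first, with a locally weighted regression of
count on GC fraction (tricube weights, local degree 1, three robustness
iterations), fitted on autosomal mappable bins and evaluated everywhere
by interpolation (clamped at the GC support edges). The span default of
0.3 is wide enough to keep the fit from tracking CNVs and narrow enough
to follow a unimodal bias curve; it is exposed in
`loess_gc_correct(span=)`. Corrected ratios are rescaled so the
autosomal median is exactly 1.

**Higher-order population artifacts** (flow-cell and batch structure,
residual mappability effects) are removed by reference-panel PCA on
autosomes: the panel's ratio matrix is mean-centered and decomposed, the
top-*k* right singular directions are kept (sign-fixed so the fit is
deterministic), and each profile is replaced by
$1 + (r - \bar r) - \sum_k \langle r - \bar r, v_k\rangle v_k$, then
rescaled to autosomal median 1. The default $k = 3$ covers the rank-2
batch structure of the synthetic generator plus one spare direction;
real cohorts should set *k* by inspecting the singular-value spectrum.
The X chromosome is deliberately excluded from fitting and projection —
the artifact model is learned on autosomes, and in a cohort of pregnant
women X is expected diploid — so X bins are median-scaled only.

Two design points deserve emphasis:

* **Leave-one-out panels.** When the analysed sample is part of the
  cohort, its panel is fitted on the other samples. Self-projection
  demonstrably erases the sample's own CNVs; leave-one-out prevents
  that at the cost of one SVD per sample.
* **CNV-sparsity of the panel.** A variant present at frequency $f$
  *among the panel samples* contaminates the panel mean at its bins by
  $f \times 0.5$ ratio units, attenuating every carrier by that amount;
  at high density the carrier-indicator direction can even enter the
  top-*k* components and be subtracted outright. The method is designed
  for the regime of large cohorts with variants at ≲2% frequency, where
  the attenuation (≤0.01) is negligible. Desk-scale cohorts of tens of
  samples with variants at ≥10% frequency are outside this envelope;
  the test suite keeps its small cohorts sparse and matches *k* to the
  simulated batch rank for exactly this reason.

The per-profile noise scale is $1.4826 \times$ the median absolute
deviation of autosomal ratios — robust to the CNV bins themselves,
unlike a plain SD.

## Segmentation

Circular binary segmentation splits each chromosome into equal-level
segments. For the current segment of length $n$, every arc $(i, j]$ of
the circularized signal is scored with

$$Z_{ij} = \frac{\bar x_{\text{in}} - \bar x_{\text{out}}}
  {s\sqrt{1/k + 1/(n-k)}},$$

where $k$ is the arc length and $s$ the two-group pooled SD. The
maximal $|Z|$ is assessed by permutation: the p-value is the fraction of
`n_perm` (default 1000) shuffles whose own maximal statistic reaches the
observed one; at $p \le \alpha$ (default 0.01, the conventional
changepoint significance level) the arc boundaries become breakpoints —
two for an interior arc, one when the arc touches the segment edge —
and the parts are segmented recursively.

Numerical and procedural choices:

* Values are mean-centered before scanning (the statistic is
  shift-invariant; centering conditions the sum-of-squares
  cancellation), and an exactly constant segment is defined to have
  $T_{\max} = 0$ — there is nothing to segment.
* Complementary edge arcs ($[0,k)$ vs $[k,n)$) have *exactly* equal
  $|Z|$; ties are resolved toward the smallest $i$, then smallest $j$,
  using a relative improvement margin of $10^{-12}$ so floating-point
  noise cannot flip the tie-break.
* The permutation loop stops early once the exceedance count guarantees
  $p > \alpha$; the split/no-split decision is provably identical to
  the full run, and the RNG stream stays deterministic under the seed.
  No approximate (hybrid) p-value is used.
* Segments shorter than `min_width` bins (default 2) are never created:
  the split arc is re-maximised under that constraint. No post-hoc
  "undo" pruning is applied by default.
* A noiseless step yields $s = 0$ on the true arc and $T_{\max} =
  \infty$; the permutation p-value is then ~0 and the boundary exact.

Each final segment carries the approximated z-score
$z = (\bar r - 1)\sqrt{n_{\text{bins}}} / \sigma_{\text{noise}}$, i.e.
the departure from diploidy in units of the standard error implied by
the profile's robust per-bin noise.

## Cohort statistics

**MOV clustering.** Two calls are "the same variant" when they are the
same type, on the same chromosome, and their reciprocal overlap
($\min(|A\cap B|/|A|, |A\cap B|/|B|)$) reaches 0.75; connected
components of this relation form clusters, and clusters observed in two
or more samples are multiple occurring variants (MOVs). Exact-coordinate
matching would be too strict under ±1-bin breakpoint jitter, while 0.75
still keeps a 1.6 Mb deletion and a 480 kb duplication at the same locus
apart, as a cohort report should. Gains and losses are never merged.
The representative interval of a cluster is its modal exact interval
(ties: leftmost, then shortest), and frequencies are reported as
$100\,n/N$, rounded to 3 decimals for display.

**Database contrasts.** Population databases publish frequencies, not
counts, so the database carrier count is reconstructed as
`round(freq/100 × N_db)` and the 2×2 carriers × cohort/database table is
tested with Pearson's chi-squared, 1 df, *without* continuity
correction. A table with an empty margin (both frequencies zero) is
flagged degenerate rather than tested.

**Density screen.** Per chromosome, the number of distinct variants is
divided by the *effective* length (size after removing unmappable and
repetitive regions) in Mb. Across chromosomes these densities are
modelled as normal; the mean and the *sample* (n−1) standard deviation
are estimated, and each chromosome gets the lower-tail probability
$\Phi((x-\mu)/s)$, flagged at $p < 0.05$. The sample-SD and lower-tail
choices are pinned down by the packaged report fixture: with the printed
counts and effective lengths they reproduce the printed p-values to six
decimals (`load_report_fixture("density")`), which a population-SD
variant does not. Only depletion is flagged by default — a chromosome
with unusually *many* variants per Mb (in the packaged table, X at
p = 0.9989) is left unflagged, mirroring how such screens report;
`two_sided = TRUE` flags both tails. When all densities are equal the
test is degenerate and every p is reported as 0.5 with a warning.

## The synthetic-cohort generator

`simulate_cohort()` emulates the binned read-count data this pipeline
consumes: expected bin weight = GC bias × low-rank batch artifact ×
copy ratio, with

* **coverage** 0.12–0.5× (reads = coverage × genome / read length; the
  5-million-read floor is enforced relative to genome size so the
  desk-scale toy genome can run at the same coverage),
* **GC bias** a log-quadratic curve peaking near GC 0.42
  (`exp(-strength (gc - 0.42)^2)`, strength 15) — any smooth unimodal
  curve the LOESS stage must invert,
* **batch artifacts** rank-2 orthonormalized Gaussian loadings with
  per-bin amplitude 0.08 (log scale) and per-sample N(0,1) scores,
* **noise** negative-binomial with dispersion 0.005
  (variance $\mu + 0.005\mu^2$; dispersion 0 gives an exact multinomial
  partition of the total reads), matching the overdispersion seen in
  cfDNA counts,
* **fetal fraction** normal(0.10, 0.04) truncated to [0.01, 0.25], the
  screening-range regime,
* **carriers** drawn per variant by independent Bernoulli trials at the
  catalog frequency; one heterozygous event per carrier
  (Hardy-Weinberg homozygotes at these frequencies are negligible and
  not modelled). Maternal variants set fetal copies equal to maternal
  copies (maternal-haplotype inheritance), fetal-only variants leave
  the maternal genome diploid. Twin pregnancies are not modelled.

The default test genome (`toy_genome()`) is four autosomes plus X,
30–48 Mb each with a 2 Mb centromere-like mask, so a full pipeline run
takes seconds to minutes; real hg19-scale grids are accepted through
`build_genome_model()`.

What passing tests on this generator do **not** show: real cfDNA has
waviness correlated across samples beyond rank 2, mappability artifacts
correlated with GC, mosaicism, and occasional malignancy signatures;
none of these are emulated. Recovery results on the synthetic cohort
demonstrate the pipeline's statistical machinery, not clinical
performance.

## Problem sizes used by the packaged checks

The study-condition recovery run uses 100 samples on the toy genome at
~0.25× with maternal het CNVs of 300–500 kb at catalog frequencies 1%
and 0.5% plus fetal-only events at 5%; the CBS type-I calibration uses
500 seeded flat-noise segments of 100 bins at α = 0.01 with 1000
permutations; the exhaustive-search agreement check uses 1000 random
arrays of length ≤ 30. These sizes keep a complete run in the
single-digit minutes on one CPU while leaving every statistical claim
testable at meaningful power.

## Known limitations

* Calls are bin-aligned; breakpoints below 20 kb resolution are out of
  reach by construction, and segments spanning an unmappable gap
  include it in their reported length.
* The ≥200 kb, >75% thresholds target heterozygous *maternal* events;
  homozygous-state inference, mosaicism and sub-threshold fetal events
  are out of scope, as are annotation, pathogenicity classification and
  genome-build liftover.
* The permutation CBS is exact but $O(n^2)$ per scan; chromosomes of
  ~4000 bins with strong signal cost a few seconds each. Hybrid
  approximations were deliberately not implemented.
* Whether a real cohort's PCA should be fitted per batch or cohort-wide
  is data-dependent; the implementation fits cohort-wide (leave-one-out)
  and exposes the panel explicitly (`fit_reference_panel()`) for users
  who need per-batch panels.
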