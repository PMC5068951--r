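---
title: "Models and methods behind barseqtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind barseqtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`barseqtools` analyses pooled fitness screens read out by barcode
sequencing. This vignette explains the statistical model each stage
implements, the tunable parameters and their defaults, what the built-in
simulator does and does not emulate, and the numerical choices made where
the design was genuinely open. It states no result that the package's test
suite and acceptance script do not themselves compute.

## The experiment being modelled

A library of ~3000 barcoded deletion mutants is pooled and grown
competitively for about five generations with and without a compound at a
mildly inhibitory dose (chosen so that wild-type growth is reduced by
10–20%; see *Dose selection* below). Each mutant carries two independent
barcodes (uptag and dntag) which are amplified and sequenced separately per
sample, with a short 3–4 nt sample index at the start of each read. A
mutant whose deletion sensitises the cell to the compound is progressively
depleted from the treated pool; sequencing depth converts that depletion
into a measurable statistic.

## Growth-inhibition score

Let `c_i` and `t_i` be mutant *i*'s normalized endpoint abundances
(counts-per-million after a pseudocount) in the control and treatment
arms, and `d` the number of pool doublings during the screen. The score is

```
GI_i = log2(c_i / t_i) / d
```

* `GI = 0`: the mutant kept pace with the pool under treatment.
* `GI ≈ 1`: the mutant stopped dividing entirely — it is depleted `2^d`-fold
  relative to the pool over `d` doublings.
* `GI < 0`: relative enrichment (resistance); not used for hit calling.

Comparing treatment against the *control endpoint* (rather than the
inoculum) cancels intrinsic growth defects: a slow-growing but
treatment-indifferent mutant is equally depleted in both arms. Two
consequences are worth knowing:

* **Pseudocount bias.** The pseudocount (default 1, configurable) guards
  `log2` against zeros but shrinks extreme ratios. A fully arrested mutant
  whose endpoint treatment count falls near the pseudocount is pulled
  below its true GI; the effect scales with depth per mutant.
* **Compositional offset.** Abundances are pool-relative, so depleting some
  mutants necessarily enriches the rest. With a fraction *q* of strongly
  sensitive mutants, every GI is shifted by roughly `-log2(1/(1-q))/d`.
  At the ~5% sensitive fraction typical of these screens the shift is
  below 0.015 and is absorbed by the median-centring of the Z-scores.
  For the same reason the endpoint comparison gives a fully arrested
  mutant `GI = 1` exactly only in the infinite-pool limit; at 3000 mutants
  the value is 0.9999.

`d` defaults to 5 and is a per-screen parameter in the screen manifest.

## Robust Z and the empirical null

Within one screen, sensitivity is judged relative to the bulk of the
library, which is assumed mostly null:

```
Z_i = (GI_i - median(GI)) / NIQR,   NIQR = IQR / 1.349
```

`1.349 = 2 * qnorm(0.75)` makes the NIQR a consistent estimator of the
standard deviation under normality while ignoring the tails, so genuinely
sensitive mutants do not inflate the scale they are judged against. A
screen with NIQR 0 (at least 75% identical GI values) is degenerate and
raises an error rather than producing infinite scores.

Tail-area false discovery rates are computed from a two-component
(null + alternative) model on `|Z|`:

1. the central bulk (`|Z|` below its 0.75 quantile, configurable) is fitted
   with a half-normal of scale `sigma0` by truncated maximum likelihood;
2. the implied null proportion is
   `pi0 = (fraction below cutoff) / P0(|Z| <= cutoff)`, capped at 1;
3. `Fdr(z) = min(1, pi0 * P0(|Z| >= |z|) / Fhat(|Z| >= |z|))`, with `Fhat`
   the empirical exceedance.

The raw curve is forced monotone non-increasing in `|z|` by assigning each
score the largest raw Fdr at or beyond it — the conservative direction: a
weaker score is never reported as more significant than a stronger one.
This is a deliberate re-implementation of the tail-area-FDR idea built on
a half-normal empirical null; it is not a binding of any particular
published software, and second-decimal differences from other
implementations are expected. The fit refuses to proceed when more than
half of the mass lies in the tail, which signals that the null model does
not describe the screen.

## Hit calling and expressivity

For each compound a mutant is a **hit** when `Fdr <= cutoff` (default 0.1)
*and* `GI > 0` in **every** screen in which it was assayed. The depletion
direction requirement excludes enriched (resistant) mutants whose |Z| is
also extreme. Mutants missing from a screen (absent from a library
version, or unscoreable) are judged on the screens where they are present
— missing data never silently becomes evidence either way. Mutants
significant in at least one but not all screens are emitted as
**rescreen candidates**: the set a follow-up plate assay would re-test,
not an automatic call in either direction.

Hits are graded by mean GI into expressivity classes with two cutoffs,
default `low < 0.25 <= medium < 0.6 <= high`. The cutoffs are
configuration, not biology: they split the observable range between
"unaffected" (GI ≈ 0) and "complete growth failure" (GI ≈ 1), and sit
between the planted effect sizes the simulator uses (0.1 / 0.4 / 1.0) so
that class recovery is a meaningful test.

## Overlap, clustering, enrichment

**Fisher overlap.** Two hit lists A and B in a universe of N genes form a
2×2 table `(k, |A|-k, |B|-k, N-|A|-|B|+k)`. The two-sided p-value follows
the point-probability criterion — every table with the observed margins
whose hypergeometric probability does not exceed the observed table's
contributes — accumulated in log space so that extreme overlaps
(p ~ 1e-35) do not underflow. The test suite checks the implementation
against exhaustive enumeration and `stats::fisher.test`.

**Clustering.** GI profiles (mutants × screens) are compared with the
uncentered correlation distance
`d = 1 - sum(xy)/sqrt(sum(x^2) sum(y^2))`, which respects the meaningful
zero of the GI scale (no centring), and clustered with unweighted
average linkage (UPGMA). Missing GI values are dropped pairwise at the
distance step, with at least two complete positions required per pair;
the clustering step itself rejects missing distances. Uncentered
correlation violates the triangle inequality; it is a dissimilarity, not
a metric, which UPGMA accepts.

**Enrichment.** Over-representation of annotation terms in a hit list of
size *n* from a universe of size *N*: fold enrichment `(k/n)/(K/N)`,
upper-tail hypergeometric `P(X >= k)` and BH q-values across terms
(significance flag at q ≤ 0.01 by default). Only over-representation is
tested. The background universe is explicit and material: the same list
is substantially more "enriched" against all protein-coding genes than
against only the assayed mutants, so the collection carries its universe
and the output records N. Term members outside the universe are dropped
with a logged count.

## Dose selection from growth curves

Screens are run at doses inhibiting wild-type growth by 10–20% so that
both healthy and mildly impaired mutants remain measurable. Rates are in
doublings/hr — the slope of `log2(OD)` during exponential growth — and
percent inhibition is `100 * (1 - rate_treated / rate_control)`.

How to extract "the" rate from a saturating plate-reader curve is an open
design choice. A best-R² contiguous log-linear window was evaluated and
rejected: on logistic curves the highest-R² window sits on the saturation
shoulder (biasing rates low, differentially across doses), and under
measurement noise short lucky windows win the R² comparison, making the
estimate unstable. `growth_rate()` instead (1) returns the exact
log-linear slope when the whole curve is log-linear (pure exponential or
flat data); (2) otherwise fits a three-parameter logistic
`OD(t) = Asym/(1 + exp((xmid - t)/scal))` by Levenberg–Marquardt least
squares and reports its exponential-phase rate `1/(scal ln 2)`;
(3) falls back to the best-R² window scan if the fit does not converge.
The test suite verifies that a noiseless 15%-inhibited logistic curve
yields exactly 85% of the control rate and that a dose at 12% true
inhibition is selected inside the [10, 20] band in at least 95% of noisy
replicates (OD noise SD 0.005).

## Barcode counting rules

* **Index matching is exact** (case-insensitive, no mismatch tolerance):
  indices are only 3–4 nt, where one substitution can cross samples;
  safety is preferred over yield. Index sets within a file must be
  prefix-free, validated at load.
* **Barcode matching tolerates at most one mismatch** (default 1), with
  strict ambiguity rejection: two catalog entries at the minimal distance
  make the read `ambiguous`, never an arbitrary assignment. The
  implementation hashes every catalog barcode and its single-substitution
  neighbours; neighbour collisions are pre-marked ambiguous, reproducing
  the minimum-distance tie rule. A quadratic brute-force matcher serves
  as the oracle in tests.
* **QC conservation**: per FASTQ file,
  `total = assigned + unassigned_index + unassigned_barcode + ambiguous`.
  Reads shorter than index+spacer+barcode count as unassigned-barcode.
  Unassigned-index reads belong to no sample, so conservation is defined
  (and checked) at file level.
* **Tag combination**: uptag and dntag counts of the same pool are summed
  by default (maximising depth), with `uptag`-only, `dntag`-only and
  `keep-separate` modes available.

## The simulator and its limits

`generate_library()`, `fitness_model()`, `simulate_counts()`,
`write_reads()`, `simulate_growth_curves()` and `generate_annotations()`
generate every input the pipeline consumes, with known ground truth:

* Barcodes are random 20-mers with pairwise Hamming distance ≥ 3 within a
  tag class, making 1-mismatch matching provably unambiguous. Real
  catalogs may violate this; the counter's ambiguity rule exists for that
  case.
* Pool growth is deterministic in expectation: after `d` doublings mutant
  *i*'s relative abundance is proportional to `a0_i * 2^(g_i d)`, with
  `g_i` the baseline rate (1 = wild type) under control and
  `baseline_rate * f_i` under treatment, `f_i ∈ [0, 1]` the planted
  treatment fitness. With baseline 1 the expected GI is `1 - f_i`, the
  identity parameter-recovery tests rely on. Initial abundances default
  to equal, with a log-normal spread option for uneven pooling.
* Planted sensitivity classes default to `f = 0.9 / 0.6 / 0.0`
  (low/medium/high), i.e. expected GI 0.1 / 0.4 / 1.0 — spanning mild
  impairment to complete growth failure.
* Observed counts are one multinomial draw per sample over the endpoint
  proportions; reads are index+spacer+barcode padded to 42 nt, with
  i.i.d. per-base substitution errors at a configurable rate, and a JSON
  manifest records layout, seed and parameters. Fixed seeds give
  byte-identical FASTQ.

Not emulated: indels and quality scores, PCR amplification bias,
tag-chimera artefacts, batch effects between library versions, and overly
dispersed counts (real Bar-seq counts are often super-multinomial).
Passing the recovery tests therefore demonstrates correctness of the
estimators under the stated noise model, not performance on any
particular real data set. The read layout is likewise a defined
convention of the simulator (index, then a constant spacer, then the
barcode), shared with the counter through the design object — not a claim
about any specific sequencing protocol.

## Problem sizes and numerical choices in the test suite

The suite exercises the study-scale configuration where the property being
tested requires it, and smaller pools where it does not:

* hit recovery: 3 replicate screens × 3000 mutants, 150 planted fully
  sensitive, depth 10^6 reads/sample, five seeds;
* estimator consistency: 600 mutants at depth 10^6 with a 5% planted
  fraction (larger fractions shift all scores by the compositional
  offset discussed above);
* the finite-depth GI ≈ 1 check uses a 100-mutant pool: at 3000 mutants a
  fully depleted mutant retains only ~10 endpoint reads at depth 10^6 and
  pseudocount-plus-counting noise alone spans the tolerance band, so the
  smaller pool isolates what the check is about — depth convergence of
  the estimator;
* NIQR calibration: 10^5 standard-normal draws, within 1% of 1;
* counting equals its brute-force oracle on 1000-read fixtures.

Seeds are fixed throughout; every stochastic routine accepts a seed and
restores the caller's RNG state.

## Known limitations

* The FDR machinery assumes a unimodal, symmetric null on Z; screens with
  heavy contamination of true effects (>50% in the tail) are rejected
  rather than fitted.
* GI scores are pool-relative; absolute fitness requires spike-ins or
  time-zero samples, which the manifest can carry but the default
  scoring deliberately ignores (the endpoint comparison already cancels
  intrinsic growth rates).
* Enrichment arithmetic operates on flat gene sets; GO graph propagation
  (ancestor closure) is out of scope, so results depend on the closure
  state of the supplied GMT.
* The counter loads catalogs into a neighbour hash; catalogs with
  duplicated barcodes are rejected outright rather than resolved.
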