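---
title: "Methods: copy-number-based glioma classification in gcnaclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number-based glioma classification in gcnaclass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcnaclass)
```

This vignette documents the models, parameter choices and numerical
conventions behind `gcnaclass`, and what its synthetic-data tests do and do
not establish.

## The classification model

Adult diffuse gliomas separate into three molecular clusters determined by
two markers: *IDH1*/*IDH2* hotspot mutation and combined whole-arm loss of
chromosome arms 1p and 19q. `assign_cluster()` encodes this as a total
rule: IDH-mutant with codeletion is the oligodendroglial cluster,
IDH-mutant without codeletion the IDH-mutant astrocytic cluster, and
everything else the IDH-wildtype astrocytic cluster. A codeletion call in
an IDH-wildtype sample contradicts the definitions; we surface it as a
flagged discordance rather than reclassifying, because silent reassignment
would hide an upstream calling problem.

Within the astrocytic clusters, a handful of CNAs further stratifies
survival. `gcnaclass` expresses this as *ordered decision tables*
(`default_rule_tables()`), one per cluster:

* IDH-wildtype (W1–W4): `cdk4_mdm2_coamp → W4`, `chr1_gain → W1`,
  `chr19_gain → W3`, else `W2`.
* IDH-mutant (M1–M3): `cdk4_amp ∨ cdkn2a_homodel → M1`,
  `chr14_gain → M2`, else `M3`.

The marker sets are established; the exact branch order within each table
is a package design decision: the published account of these subtypes is a
graphical algorithm whose full branch structure is not recoverable from
text. Our ordering is chosen to be consistent with the published marker
lists, with the A/B/C subgrouping rules (A on chromosome 1 gain or *TP53*
mutation, then B/C split on chromosome 19 gain), and with the published
survival ordering of the subtypes — in particular, co-amplification of
*CDK4*/*MDM2* is treated as an overriding modifier (evaluated first), and
chromosome 19 gain marks the best-prognosis non-co-amplified wildtype
group, in line with reports that chromosome 19/20 co-gain marks long-term
glioblastoma survivors. Because the true tree may differ, the classifier
consumes a declarative rule table (JSON-serializable, `--rules` on the
CLI); alternative trees need no code change. Every table must end in a
catch-all, and totality is enforced by an exhaustive-enumeration test.

## Copy-number calling

Two substrates are supported, with the threshold regimes used by their
respective communities (all log2-scale, all comparisons inclusive, so a
boundary value calls as an event — a deterministic, documented tie rule):

| context | gain | loss | amplification | homozygous deletion |
|---|---|---|---|---|
| GISTIC gene scores | ≥ +0.5 | ≤ −0.5 | ≥ +0.6 | ≤ −0.6 |
| segment medians (after baseline correction) | ≥ +0.1 | ≤ −0.1 | ≥ +0.6 | ≤ −0.6 |

Region values are medians: on the GISTIC route, the plain median of the
member genes of a region (a proxy for "median of probe states" without a
probe manifest); on the segment route, the *length-weighted* median of the
segment portions overlapping the region. The weighted median uses an
explicit tie rule — if a prefix of the sorted values holds exactly half
the weight, the median is the midpoint to the next value — which makes
`baseline_correct()` exactly idempotent and two equal-weight values at 0.1
and 0.3 yield 0.2.

The baseline-correction algorithm applied upstream of methylation-derived
segment profiles is not publicly specified; we implement it as per-sample
centering on the length-weighted median of autosomal segments (strategy
switch `median | mode`, the latter centering on the most populated
0.1-wide log2 histogram bin). Centering on the autosomal weighted median
assumes less than half the (length-weighted) autosomal genome is altered;
for heavily aneuploid genomes the mode strategy is the safer choice.

Codeletion is whole-arm: both 1p and 19q must call "loss" at the active
regime. Chromosome-level gain/loss is the whole-chromosome median state,
matching the "polysomy/monosomy" reading; 9p is handled as an arm region.
Arm boundaries ship as GRCh37 cytoband-derived coordinates in
`default_regions()` and are overrideable.

## Classical MDS

`classical_mds()` is the Torgerson procedure: `B = -1/2 J D² J` with
`J = I − 11ᵀ/n`, symmetric eigendecomposition, coordinates
`v_k √λ_k`. Numerical conventions: eigenvalues within `±1e-12` of zero
give zero coordinates silently (the centering null space); negative
eigenvalues among the requested axes give zero coordinates *with a
warning* (non-Euclidean input is reported, never imputed); each axis' sign
is fixed by making its largest-magnitude loading positive, so output is
reproducible across runs and BLAS implementations. The default distance is
Euclidean on the mutation/CNA matrix (codes {0,1} and {−1,0,+1}); the
prior work that fixed the original feature construction is not restated in
its successor, so the metric is configuration (`euclidean` or Jaccard on
binarized profiles), not a claim.

## Survival methods

`km_estimate()` is the product-limit estimator; the median is the first
event time with `S(t) ≤ 0.5` (standard convention) and undefined when the
curve never reaches 0.5 — undefined medians are errors in normalization,
not silently dropped groups. `cox_ph()` maximizes the partial likelihood
by Newton–Raphson (convergence `max|score| < 1e-9`, cap 50 iterations,
step damping at 5 per iteration), with Efron tie handling by default
(Breslow available); the original analyses name only the software package,
not the tie method, and Efron is that package's default. Confidence
intervals are Wald at 95%. Monotone likelihood (complete separation) is
detected as `|β| > 15` and flagged as an effectively infinite hazard
ratio rather than silently reporting a huge finite number. The age split
is `< 45` versus `≥ 45` (boundary to the older group); grade enters
adjusted models as the binary II versus III/IV contrast, Karnofsky as
≥ 90 versus < 90.

Cross-cohort validation merges a candidate subtype pair when their
pairwise Cox p-value exceeds α (default 0.05; α = 0 disables merging),
normalizes each group's KM median by the median of the pooled baseline
records, and regresses cohort B's normalized values on cohort A's by
ordinary least squares (free intercept by default; a through-origin
variant exists because the original figure does not state which was used).
Normalization is exactly scale-invariant, so cohorts with different
absolute survival can be compared.

## The synthetic generator: a stated world

`generate_cohort()` emulates the data structure the analysis assumes, not
any real cohort:

* **Cluster sizes** default to 176 / 251 / 351, the published composition
  of the discovery cohort.
* **Markers** are Bernoulli draws at per-cluster prevalences with
  structural constraints: *IDH1*/*IDH2* mutually exclusive (a single
  uniform draw decides which), IDH mutation absent from the wildtype
  cluster and present by definition in the other two (if neither gene is
  drawn in an IDH-defined cluster, *IDH1* is set), codeletion only in the
  oligodendroglial cluster. Per-cluster prevalences are **not** published
  quantities; the defaults are one-time choices from the field's common
  knowledge (e.g. chromosome 7 gain ~0.8 and chromosome 10 loss ~0.75 in
  IDH-wildtype tumors, *TP53* ~0.8 and *ATRX* ~0.7 in IDH-mutant
  astrocytomas, chromosome 4 loss ~0.25 in oligodendrogliomas) and were
  frozen before the test thresholds were evaluated.
* **Subtype truth** is derived by running the default decision tables on
  the drawn flags, so recovery tests close the loop end to end.
* **Survival** is exponential with rate `ln 2 / median` — the published
  record is medians only, and the exponential is the simplest law matching
  a median. Defaults: W1/W2/W3 = 6.6/12.7/15.2, M1/M2/M3 = 23.3/63.0/94.5
  months (published); W4 = 20.0 and the oligodendroglial cluster = 120.0
  months (package defaults, unpublished: co-amplification is described as
  a survival-modifying subgroup and the codeleted cluster as the
  longest-surviving entity). **Censoring** exposes each sample with
  probability `censoring_rate` (default 0.3) to an independent uniform
  clock on `[0, 2 × max median]`; this realizes approximately (slightly
  below) the configured fraction and is non-informative. Grade and
  Karnofsky are drawn independently of subtype, so adjusted models on
  synthetic data have null grade effects by construction.
* **Ages** are normal mixtures: wildtype N(59.5, 8), IDH-mutant N(29, 7)
  (placing the modal 7-year bins at the published 56–63 and 26–32 ranges),
  and the codeleted cluster 0.5·N(38, 5) + 0.5·N(56, 5), which lands the
  two peaks in the published 35–41 and 53–59 bins with a median near 45.
* **Copy-number signal** is gain +1.0, loss −1.0, amplification +2.0,
  homozygous deletion −2.0, plus N(0, `noise_sd`) (default 0.1). The
  segment table carries the same events as GRCh37 intervals, split into
  `n_seg_pieces` chunks with independent noise (so region medians average
  noise down, mimicking many probes per region). Focal genes (*CDK4*,
  *MDM2*, *CDKN2A*, *EGFR*) carry **only** their focal signal, never the
  surrounding broad signal: a −1.0 arm loss overlapping *CDKN2A* would
  otherwise cross the −0.6 focal cutoff and mis-call a homozygous
  deletion. This is a deliberate idealization; real profiles superimpose
  focal on broad events, and the ±0.6 regime implicitly assumes focal
  events are read against a locally corrected baseline.

What a green test establishes: with zero noise and zero censoring the
pipeline recovers ground truth exactly (thresholds, rules, plumbing are
self-consistent); at the configured noise the statistical layers behave
nominally (KM medians within tolerance, Cox estimates unbiased with
nominal CI coverage, cross-cohort regression near identity). What it does
not establish: concordance with real TCGA/GGN assignments (those require
the frozen external releases and the exact published rule tree), realistic
correlation structure between markers (draws are independent within
cluster), tumor purity effects, or methylation-derived preprocessing
artifacts.

## Known limitations

* The W1/W2/W3-versus-W4 and M1 branch structures are assumptions
  (config-overridable), as discussed above.
* The generator draws markers independently within a cluster; real
  co-occurrence (e.g. chromosome 7 gain with chromosome 10 loss) is
  stronger, so synthetic MDS clusters are somewhat more diffuse than real
  ones.
* Config files are JSON only (the environment provides no YAML parser);
  the CLI accepts the same structures `jsonlite` writes.
* No log-rank tests, time-varying covariates or competing risks: group
  comparisons are Cox-based throughout, matching the upstream analyses.
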