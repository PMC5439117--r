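# gcnaclass

Copy-number-based molecular classification and survival analysis of adult
diffuse gliomas.

## The problem

Since 2016, the WHO classification of diffuse gliomas is molecular first:
the combination of *IDH1*/*IDH2* mutation status and 1p/19q codeletion
splits these tumors into three clinically distinct groups —
oligodendroglial tumors (IDH-mutant, 1p/19q-codeleted), IDH-mutant
astrocytic gliomas/glioblastomas, and IDH-wildtype astrocytic
gliomas/glioblastomas. Within the two astrocytic groups, a small set of
additional copy-number alterations (CNAs) carries further prognostic
information. `gcnaclass` implements that whole chain as a tested pipeline,
for computational neuro-oncologists who have gene-level copy-number scores
(GISTIC2.0-style), segment tables (SEG-style, GRCh37) and mutation calls,
and want reproducible cluster labels, CNA subtypes and survival statistics.

## What it computes

- **CNA calling** at the three threshold regimes used in practice:
  broad gains/losses at ±0.5 on GISTIC gene scores, or at ±0.1 on
  length-weighted region medians of baseline-corrected segment profiles;
  focal amplification / homozygous deletion at ±0.6. All comparisons are
  inclusive. Derived flags include 1p/19q codeletion (both arms called
  "loss"), whole-chromosome gains/losses and *CDK4*/*MDM2*/*CDKN2A*
  focal events.
- **Classical MDS** (Torgerson): the alteration matrix (binary mutation
  indicators, ternary CNA states) is embedded via the double-centered Gram
  matrix `B = -1/2 J D² J`, eigendecomposition, coordinates
  `v_k · sqrt(λ_k)`, with deterministic per-axis signs.
- **Cluster assignment**: IDH-mutant ∧ codeleted → oligodendroglial
  cluster; IDH-mutant → IDH-mutant astrocytic; else IDH-wildtype, plus the
  canonical 2016 integrated-diagnosis strings.
- **CNA subtypes** via ordered, overridable decision tables:
  W1–W4 for the IDH-wildtype cluster (chromosome 1 gain, chromosome 19
  gain, *CDK4*/*MDM2* co-amplification) and M1–M3 for the IDH-mutant
  cluster (*CDK4* amplification or *CDKN2A* homozygous deletion,
  chromosome 14 gain), plus the A/B/C spatial subgrouping rules.
- **Survival**: own implementations of the Kaplan–Meier product-limit
  estimator (median = first event time with `S(t) ≤ 0.5`) and Cox
  proportional-hazards regression (Newton–Raphson on the partial
  likelihood, Efron or Breslow ties, Wald 95% CIs), cross-checked in the
  test suite against the `survival` package and brute-force oracles.
- **Cross-cohort validation**: merge statistically indistinguishable
  subtypes (pairwise Cox), normalize median OS to a baseline subtype, and
  regress normalized values between cohorts.
- **A synthetic-cohort generator** reproducing the statistical structure
  the analysis assumes (three clusters, configurable marker prevalences,
  cluster-specific age mixtures, subtype-dependent exponential survival
  with censoring), so every stage is testable without external data.

## Worked example

```r
library(gcnaclass)

cfg    <- default_generator_config(seed = 7)   # 176 / 251 / 351 samples
cohort <- generate_cohort(cfg)
pl     <- run_pipeline(gistic = cohort$gistic,
                       mutations = cohort$mutations, source = "gistic")
table(pl$subtypes$subtype)
#>       M1       M2       M3 OLIGO_NA       W1       W2       W3       W4
#>       56       39      156      176       56      213       80        2

m   <- merge(cohort$clinical, pl$subtypes, by = "sample_id")
mut <- m[m$cluster == "ASTRO_IDHmut", ]
compare_groups(mut$os_months, mut$event, mut$subtype)
#>  group   n events median_os
#>     M1  56     50    27.129
#>     M2  39     32    56.752
#>     M3 156    139    89.179
#>  Pairwise Cox:
#>  group1 group2        HR    ci_low   ci_high            p
#>      M1     M2 0.3835118 0.2347576 0.6265241 1.296675e-04
#>      M1     M3 0.2562841 0.1785379 0.3678856 1.561082e-13
#>      M2     M3 0.6799205 0.4600977 1.0047691 5.285708e-02

merged_subtype_model(mut$os_months, mut$event, mut$subtype,
                     grade = mut$who_grade)
#> Cox proportional hazards (efron ties): n = 251, events = 221
#>          term    HR          ci        p
#>          M1/2 2.283 1.712-3.043 1.83e-08
#>  grade_III_IV 0.916 0.693-1.211     0.54
```

The M1–M3 Kaplan–Meier medians (27.1 / 56.8 / 89.2 months) estimate the
generator's configured medians (23.3 / 63.0 / 94.5) and preserve their
prognostic ordering; the merged M1/2-versus-M3 hazard ratio of 2.28 shows
the subtype split carries survival signal. The grade coefficient is null
here because the generator draws grade independently of subtype (see the
methods vignette).

## Command line

```sh
gcnaclass simulate --config cfg.json --seed 7 --out sim/
gcnaclass call-cna --gistic sim/gistic.tsv --out calls/
gcnaclass classify --mutations sim/mutations.tsv \
    --calls calls/calls.tsv --clinical sim/clinical.tsv --out clusters/
gcnaclass subtype --clusters clusters/clusters.tsv \
    --calls calls/calls.tsv --out subtypes/
gcnaclass survive --clinical sim/clinical.tsv \
    --groups subtypes/subtypes.tsv --group-col subtype --out surv/
gcnaclass validate --cohort-a a.tsv --cohort-b b.tsv --baseline W1 --out val/
```

All outputs are TSV plus a JSON run manifest (config, seed, version);
reruns with the same seed and config are byte-identical. Segment
coordinates are 1-based inclusive (SEG convention), GRCh37.

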