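---
title: "Methods: two-feature neoantigen prioritization from TCRβ repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-feature neoantigen prioritization from TCRβ repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoprior)
```

## The problem and the model

Conventional neoantigen pipelines rank candidate peptides by predicted
peptide–HLA (pHLA) binding alone. That criterion captures presentation
but not recognition: a presented peptide is only immunogenic if some T
cell receptor in the patient's repertoire engages the peptide–HLA
complex. `neoprior` implements a two-feature classification and
prioritization scheme that combines:

* **pHLA percentile rank** — the predicted binding strength of the
  peptide to a class-I HLA allele, on a 0–100 percentile scale where
  lower is stronger (NetMHCpan-class tools); and
* **pHLA-TCR rank** — the predicted engagement rank of a CDR3β sequence
  with the peptide–HLA complex, on the same 0–100 lower-is-better scale
  (pMTNet-class tools; their native fractional ranks are rescaled ×100
  at the adapter boundary so the conventional "below 2%" binder cutoff
  reads identically for both features).

Both features are *minimum-aggregated* before modeling: the pHLA rank of
a peptide is the minimum over its alleles and prediction tools (its
strongest predicted presentation), and the pHLA-TCR rank of a pHLA is
the minimum over the patient's CDR3β repertoire (its best predicted
engagement by any TCR the patient actually carries). Minimum aggregation
is monotone — adding alleles, tools, or TCRs can only strengthen a
candidate — and this invariant is tested against a brute-force scan.

A binary classifier (logistic regression, random forest, or gradient
boosting; selected by mean ROC AUC under stratified 10-fold
cross-validation, ties broken XGB → RF → LR) maps the two ranks to an
immunogenicity score in [0, 1]. Operating points are fixed on the
discovery data at target specificities (default 0.95 and 0.99; the
alternative 0.90/0.95 pair is available in `model_config()` because both
pairs are defensible conventions for low-false-positive screening). The
stored cutoff is the smallest observed score whose realized specificity
*strictly exceeds* the target, so the calibration-side guarantee
`specificity > target` holds by construction.

## Repertoire statistics

The repertoire module computes the standard descriptive statistics of a
TCRβ clonotype table: Shannon entropy $H=-\sum_i p_i\ln p_i$ (nats),
clonality $1-H/\ln n$, singleton/expanded clone counts, V/J segment
usage and pairing, CDR3 length summaries, cross-sample clonotype
sharing, and rarefaction curves by without-replacement read subsampling
(multivariate hypergeometric, seeded, 100 replicates by default).
Clonotype identity defaults to the (CDR3 amino-acid sequence, V call,
J call) triple; sharing analysis offers a CDR3-only mode because
cross-patient comparisons are commonly done on the CDR3 sequence alone.
Counts are assumed UMI-collapsed upstream; no further error correction
is attempted. D-segment assignment is not attempted — the truncation of
the D region during rearrangement makes unambiguous assignment
infeasible from CDR3 sequence alone.

## Dataset assembly

Labeled (peptide, HLA, CDR3β) complexes are assembled from positive
records plus a constructed negative set: each distinct positive pHLA is
paired with `negatives_per_phla` (default 10) CDR3β sequences drawn
uniformly *without replacement* from a background TCR pool, excluding
any TCR known to form an immunogenic complex with that pHLA. Exclusion
prevents mislabeled negatives; sampling from a real pool (rather than
synthesizing sequences) matches how published negative sets are sourced
from repertoire databases. A shortfall after exclusion is a hard error
naming the pHLA — never a silently smaller negative set.

The discovery/validation split (default 70/30) is label-stratified.
The default split unit is the *peptide*: all complexes sharing a peptide
land on the same side, which prevents peptide-level information leakage
between training and evaluation. A complex-level mode exists for literal
replication of protocols that only guarantee complex-level disjointness.
Per-stratum discovery sizes use floor + largest-remainder so the overall
discovery count is exactly `round(fraction × n)`.

## Quadrant analysis

At a fixed percentile cutoff (default 2), labeled complexes fall into
four groups: Q1 (both ranks below cutoff), Q2 (pHLA only), Q4 (pHLA-TCR
only), Q3 (neither). Which single-binder group is called "Q2" versus
"Q4" is a package convention, stated in the printed output. The module
reports PPV/sensitivity/specificity for the three binder rules (pHLA
binder, pHLA-TCR binder, Q1) and a 2×2 Pearson chi-square of binder
status against label per feature, without continuity correction — the
intended use is large compilation-scale tables where the correction is
negligible and the uncorrected statistic is the convention. On a
degenerate margin (e.g. no binders at all) the statistic is reported as
`NA`, never as a silent zero.

## Rank coverage score

Prioritization quality is scored by the rank coverage statistic. For a
ranked list of $T$ candidates with experimentally validated labels,

$$\mathrm{RCS}=\sum_{n\in\mathrm{neg}}\frac{\mathrm{rank}(n)}{T\cdot\mathrm{num}(n)}\cdot\mathrm{cov}(\mathrm{neg})-\sum_{p\in\mathrm{pos}}\frac{\mathrm{rank}(p)}{T\cdot\mathrm{num}(p)}\cdot\mathrm{cov}(\mathrm{pos}),\qquad \mathrm{cov}(g)=\frac{\max_{k\in g}\mathrm{rank}(k)}{T}.$$

The printed form of this statistic is ambiguous about the scoping of the
coverage factor; we read $\mathrm{cov}(g)$ as a *group-level constant*
(the group's maximum rank over $T$) multiplying that group's sum. This
reading reproduces the intended qualitative behavior — positives at
small ranks give a high score — and under it the perfect ordering
uniquely maximizes the score and the inverted ordering uniquely
minimizes it, which the test suite proves by exhaustive enumeration for
all $T\le 7$ and all label placements, along with adjacent-swap
monotonicity for every enumerated state. An element-level variant
($\mathrm{cov}(k)=\mathrm{rank}(k)/T$ per element) is available via
`coverage = "element"` for sensitivity checks; it preserves the sign
convention but not the exact worked values.

For a pooled "overall" score across patients, per-patient lists are
concatenated with their within-patient ranks retained and the formula is
applied to the pooled multiset with $T$ equal to the pooled entry count.
The publication-style pooling rule is not derivable from any printed
description we know of; this choice is deterministic, symmetric across
methods (both arms contribute identical rank multisets, so only the
label-by-rank pattern differs), and reported as such. Its absolute
magnitude shrinks as patients are added — only comparisons between
methods on the same pool are meaningful.

## ELISpot calls

Immunogenicity is confirmed when the mutant long peptide elicits at
least a `fold_cutoff` (default 2) increase in IFN-γ spots over its
matched wild-type peptide. The published convention is stated both as
"a fold change of two was selected as the cutoff" and as a ">twofold
increase"; we adopt `fold >= 2` as the default and expose
`strict = TRUE` for the strict reading. A zero wild-type well gets a
pseudocount denominator of 1 and a flag (policy `"undefined"` instead
marks the record non-evaluable). DMSO background is reported but not
subtracted by default, because the fold change is defined against the
wild-type peptide; `subtract_dmso = TRUE` enables subtraction for
sensitivity analysis.

## The synthetic world

Real inputs to this analysis — patient TCRβ repertoires and the
multi-database pHLA-TCR compilation — are access-restricted and cannot
be redistributed, so the package carries a first-class generator module
whose defaults *are* the stated world of the tests:

* **Repertoires** (`simulate_repertoire()`): Zipf-ranked clone counts
  (exponent 1.2 by default — a conventional heavy-tail for clonally
  expanded repertoires; each clone keeps at least one read so clonotype
  counts are exact), CDR3 lengths from a rounded normal (mean 14, sd 3)
  clipped to [4, 43], uniform usage over 59 V and 13 J segments, total
  reads 5× the clonotype count (which yields a realistic majority of
  singleton clonotypes). The sd and read-depth values are package
  choices — only the median/range and segment counts are externally
  fixed.
* **Complexes** (`simulate_complexes()`): class-conditional rank
  features. Positives draw each feature from an exponential
  concentrated below the 2% cutoff (scales 2.0 for pHLA, 3.0 for
  pHLA-TCR) with 30% uniform contamination; negatives from a 0.2/0.8
  mixture of the same low component and a uniform on [0, 100]. Features
  are conditionally independent given the class — the weakest
  dependence assumption that still makes the combination strictly
  informative. Label noise defaults to 0; it is a user dial, not part
  of the stated world. Negatives are constructed through the real
  `make_negatives()` pairing path, so the generator also exercises the
  assembly rules.
* **ELISpot** (`simulate_elispot()`): Poisson counts,
  wild-type mean 20, mutant mean 20 × true fold.

A green test on this world establishes that the *procedure* behaves as
designed — the combined model dominates each single feature, Q1
precision beats single-binder precision, operating points respect their
targets — not that any real-data headline number is reproduced. The
generator does not emulate VDJ recombination, biophysical binding, HLA
allele structure in the features, or inter-feature correlation within a
class; claims that depend on those properties are out of reach of these
tests, and the published performance figures (AUCs near 0.82/0.84,
PPV orderings, rank coverage values) are echoed only as qualitative
orderings.

The end-to-end acceptance check of the ranking comparison uses a
*pTCR-informative regime* (pHLA scale 8, pHLA-TCR scale 2): the
situation the combined method exists for, where pHLA binding alone
under-ranks immunogenic peptides and repertoire information adds power.
With both defaults reversed toward a strongly informative pHLA feature,
the pHLA-only arm is already near-optimal and the comparison is
uninformative.

## Numerical choices and degenerate inputs

* Natural logarithms throughout the diversity indices; clonality is
  undefined (error) below two clonotypes.
* Frequency vectors must be strictly positive and sum to 1 within 1e-9.
* AUC uses the Mann–Whitney rank statistic with average ranks (ties earn
  half credit); its confidence interval is a stratified bootstrap (2000
  resamples by default, seeded) — the CI method is a package choice, as
  interval methods are rarely stated alongside published AUCs.
* The random forest and gradient-boosting learners are implemented
  in-package (bagged variance-reduction CARTs; Newton boosting with
  logistic loss and L2-regularized leaves) because no tree-ensemble
  package is available in the supported environment. With two features,
  exact split search is cheap and the implementations are small enough
  to test directly. Defaults: RF 100 trees, depth 8, minimum node 10;
  boosting 100 rounds, learning rate 0.1, depth 3, λ = 1.
* All stochastic steps take explicit seeds and save/restore the
  caller's RNG state (`with_seed()`), so package calls never perturb a
  session's random stream and byte-identical reruns are an invariant
  under test.
* Unreachable specificity targets (all scores tied) yield an `Inf`
  cutoff sentinel with a warning — sensitivity 0, never a silently
  wrong threshold.

## Known limitations

* Only the TCRβ chain is modeled; α-chain and paired-chain information
  is out of scope.
* The feature adapters are lookup/synthetic only; the package never runs
  NetMHCpan, pMTNet, or epitope enumeration itself.
* The rank coverage pooling rule and the Q2/Q4 naming are package
  conventions (documented above) where the field has no fixed standard.
* Statistical association of diversity with clinical covariates is
  deliberately not implemented: those are findings about restricted
  cohort data, not reusable procedure.
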