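# neoprior

Neoantigen prioritization that combines peptide–HLA (pHLA) binding
percentile ranks with peptide–HLA–TCR (pHLA-TCR) engagement ranks.

## Who this is for

Tumor immunologists and immunoinformaticians selecting neoantigen
candidates for validation or vaccine design. Pipelines that rank
candidates by predicted pHLA binding alone model *presentation* but not
*recognition*: whether any T-cell receptor the patient actually carries
engages the peptide–HLA complex. `neoprior` implements the full
downstream analysis for a two-feature approach — TCRβ repertoire
profiling, labeled dataset assembly, classifier training with
fixed-specificity operating points, candidate ranking, and ELISpot
confirmation calls — with a synthetic-data module so every stage runs
and is testable without access-restricted patient data.

## The statistics at the core

* **Repertoire diversity.** For clone frequencies $p_i$ over $n$
  clonotypes: Shannon entropy $H=-\sum_i p_i \ln p_i$ and clonality
  $1-H/\ln n$; plus rarefaction (seeded without-replacement read
  subsampling), V/J segment usage, CDR3 length summaries, and
  cross-patient clonotype sharing.
* **Two-feature classification.** Each (peptide, HLA, CDR3β) complex is
  represented by two percentile ranks in [0, 100] (lower = stronger):
  minimum pHLA rank over alleles/tools and minimum pHLA-TCR rank over
  the repertoire. LR/RF/XGB candidates are compared by mean ROC AUC
  under stratified 10-fold cross-validation; score cutoffs are fixed on
  discovery data so realized specificity strictly exceeds targets
  (default 0.95, 0.99). A fixed-cutoff quadrant analysis (both ranks
  < 2% = Q1) reports binder-rule PPV/sensitivity/specificity with
  Pearson chi-square tests.
* **Rank coverage score.** For a validated ranking of $T$ candidates,
  $\mathrm{RCS}=\sum_{n\in\mathrm{neg}}\frac{\mathrm{rank}(n)}{T\,\mathrm{num}(n)}\mathrm{cov}(\mathrm{neg})-\sum_{p\in\mathrm{pos}}\frac{\mathrm{rank}(p)}{T\,\mathrm{num}(p)}\mathrm{cov}(\mathrm{pos})$
  with $\mathrm{cov}(g)=\max_{k\in g}\mathrm{rank}(k)/T$. Higher is
  better; the perfect ordering is the unique maximizer (proved
  exhaustively in the tests for $T\le7$).
* **ELISpot calls.** Immunogenic iff mutant/wild-type IFN-γ spot fold
  change ≥ 2 (strict > available), with explicit zero-wild-type policy.

## Worked example

The whole pipeline — simulate a labeled complex set, assemble negatives
by random TCR pairing, split 70/30 peptide-disjoint, select a classifier
by 10-fold CV, calibrate operating points, rank candidates for eight
patients with the combined model versus a pHLA-only baseline, and call a
simulated ELISpot round — runs from one seed:

```r
library(neoprior)
res <- run_pipeline(list(seed = 1))

res$cv$cv_table
#>   algorithm  mean_auc     sd_auc
#> 1        LR 0.7841497 0.05494878
#> 2        RF 0.7820295 0.05412891
#> 3       XGB 0.7809864 0.05757323

res$evaluation
#> <evaluation_report> n=990 AUC 0.829 (95% CI 0.783-0.874)
#>  operating_point target_specificity    cutoff sensitivity specificity       ppv
#>        spec_0.95               0.95 0.2673645   0.4888889   0.9511111 0.5000000
#>        spec_0.99               0.99 0.2931535   0.1666667   0.9844444 0.5172414
#>        npv tp fp fn  tn
#>  0.9490022 44 44 46 856
#>  0.9219563 15 14 75 886

res$ranking$overall
#>    combined   phla_only
#> 0.003399884 0.002459491

res$elispot$summary$per_method
#>      method n_nominated n_confirmed
#> 1  combined          24          12
#> 2 phla_only          24          10
```

Reading the output: the three algorithms are nearly tied on this small
default world (LR selected at mean CV AUC 0.784); on the held-out 30%
the combined model reaches AUC 0.829, and at the 0.95-specificity
operating point it recovers 49% of immunogenic complexes at 95.1%
realized specificity. The combined arm out-ranks the pHLA-only baseline
on pooled rank coverage (0.0034 vs 0.0025 — only the comparison, not the
magnitude, is meaningful) and confirms more nominated candidates in the
simulated ELISpot round (12 vs 10 of 24).

Individual stages are plain functions: `read_airr_table()`,
`filter_by_count()`, `shannon_entropy()`, `clonality()`,
`rarefaction_curve()`, `clonotype_sharing()`, `segment_usage()`;
`load_complexes()`, `make_negatives()`, `deduplicate_complexes()`,
`split_discovery_validation()`; `aggregate_min_phla()`,
`aggregate_min_tcr()`, `wildtype_filter()`, `build_feature_table()`;
`cross_validate_select()`, `fit_final()`, `threshold_at_specificity()`,
`evaluate_report()`, `quadrant_analysis()`; `rank_candidates()`,
`rank_coverage_score()`, `compare_methods()`;
`fold_changes_and_calls()`, `validation_summary()`; and the simulators
`simulate_repertoire()`, `simulate_complexes()`, `simulate_elispot()`.
A batch CLI wrapper lives at `inst/cli/neoprior.R`.

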