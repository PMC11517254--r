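Package: neoprior
Title: Neoantigen Prioritization from TCR-Beta Repertoires and
    Peptide-HLA/Peptide-HLA-TCR Binding Ranks
Version: 0.1.0
Authors@R:
    person("Neoprior", "Developers", email = "neoprior@example.org",
           role = c("aut", "cre"))
Description: Tools for prioritizing immunogenic neoantigens by integrating
    peptide-HLA (pHLA) binding percentile ranks with peptide-HLA-TCR
    (pHLA-TCR) engagement ranks. Reads AIRR-style TCR-beta clonotype
    tables and computes repertoire diversity statistics (Shannon entropy,
    clonality, rarefaction, V/J segment usage, clonotype sharing);
    assembles labeled pHLA-TCR training sets with random-TCR negative
    pairing and peptide-disjoint discovery/validation splits; trains and
    evaluates two-feature immunogenicity classifiers (logistic
    regression, random forest, gradient boosting) with fixed-specificity
    operating points and fixed-cutoff quadrant analysis; scores candidate
    rankings with the rank coverage statistic; and calls immunogenicity
    from ELISpot mutant/wild-type spot counts. A synthetic-data module
    generates every input format so the full pipeline runs and is
    testable without access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
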