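# Synthetic-data generators. These emulate the statistical structure the
# analysis assumes — heavy-tailed clonal expansion, class-conditional
# concentration of binding ranks below the 2% cutoff, Poisson ELISpot
# counts — so every pipeline stage runs and is testable without the
# access-restricted patient data.

random_aa_strings <- function(n, lengths) {
  vapply(lengths, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
  }, character(1))[seq_len(n)]
}

#' Simulate a TCR-beta clonotype table
#'
#' Clone counts follow a Zipf-type ranked distribution (count of the i-th
#' clone proportional to i^-s plus a guaranteed single read, so exactly
#' `n_clonotypes` distinct clonotypes appear); CDR3 amino-acid sequences
#' are random over the 20-letter alphabet with lengths from a rounded
#' normal clipped to `[cdr3_min, cdr3_max]`; V and J segment calls are
#' drawn uniformly from `n_v_segments` / `n_j_segments` segment names.
#' Defaults reproduce the observed repertoire structure: 59 V segments,
#' 13 J segments, CDR3 length median 14, range 4-43.
#'
#' @param n_clonotypes number of distinct clonotypes.
#' @param zipf_exponent Zipf exponent of the ranked count distribution
#'   (> 0; default 1.2).
#' @param n_v_segments,n_j_segments segment pool sizes (defaults 59, 13).
#' @param cdr3_length_mean,cdr3_length_sd,cdr3_min,cdr3_max CDR3 length
#'   model (defaults 14, 3, 4, 43).
#' @param total_reads total UMI-collapsed reads to distribute (default
#'   `5 * n_clonotypes`).
#' @param sample_id sample name.
#' @param seed RNG seed.
#' @return A [clonotype_table()].
#' @export
simulate_repertoire <- function(n_clonotypes = 1000L,
                                zipf_exponent = 1.2,
                                n_v_segments = 59L,
                                n_j_segments = 13L,
                                cdr3_length_mean = 14,
                                cdr3_length_sd = 3,
                                cdr3_min = 4L,
                                cdr3_max = 43L,
                                total_reads = 5L * n_clonotypes,
                                sample_id = "SIM",
                                seed = 1L) {
  stopifnot(n_clonotypes >= 1, zipf_exponent > 0,
            total_reads >= n_clonotypes)
  with_seed(seed, {
    p <- (seq_len(n_clonotypes))^(-zipf_exponent)
    p <- p / sum(p)
    extra <- stats::rmultinom(1, total_reads - n_clonotypes, p)[, 1]
    counts <- 1L + extra
    lens <- round(stats::rnorm(4L * n_clonotypes, cdr3_length_mean,
                               cdr3_length_sd))
    lens <- pmin(pmax(lens, cdr3_min), cdr3_max)
    v <- sample(sprintf("TRBV%d", seq_len(n_v_segments)), n_clonotypes,
                replace = TRUE)
    j <- sample(sprintf("TRBJ%d", seq_len(n_j_segments)), n_clonotypes,
                replace = TRUE)
    cdr3 <- unique(random_aa_strings(4L * n_clonotypes, lens))
    if (length(cdr3) < n_clonotypes) {
      stop("could not generate enough unique clonotypes; increase CDR3 length",
           call. = FALSE)
    }
    cdr3 <- cdr3[seq_len(n_clonotypes)]
    clonotype_table(sample_id, data.frame(
      cdr3_aa = cdr3, v_call = v, j_call = j, count = counts,
      stringsAsFactors = FALSE
    ))
  })
}

# Class-conditional rank draws: low-concentrated exponential for the
# binding-competent component, uniform background otherwise.
draw_ranks <- function(n, low_weight, scale, rank_max = 100) {
  low <- stats::runif(n) < low_weight
  x <- ifelse(low, stats::rexp(n, rate = 1 / scale),
              stats::runif(n, 0, rank_max))
  pmin(pmax(x, 0), rank_max)
}

#' Simulate a labeled pHLA-TCR complex dataset with features
#'
#' Generates `n_positive` immunogenic complexes (unique peptide/HLA pairs,
#' CDR3-beta partners drawn from a background pool), builds the negative
#' set through the standard random-TCR pairing rule
#' ([make_negatives()], `neg_ratio` per pHLA), then draws the two
#' percentile-rank features conditionally on class: positives concentrate
#' below the 2% cutoff (exponential scales `pos_phla_scale`,
#' `pos_ptcr_scale`, with a `pos_contamination` uniform fraction),
#' negatives are mostly uniform on `[0, 100]` with a `neg_low_weight`
#' exponential component. Features are conditionally independent given
#' class. Optional label noise flips a fraction of labels last.
#'
#' @param n_positive number of immunogenic complexes.
#' @param neg_ratio negatives per positive pHLA (default 10).
#' @param pos_phla_scale,pos_ptcr_scale exponential scales of the
#'   immunogenic feature components (defaults 2.0 and 3.0 percentiles).
#' @param pos_contamination uniform fraction among positives (default 0.3).
#' @param neg_low_weight weight of the low-rank exponential component among
#'   negatives (default 0.2).
#' @param label_noise fraction of labels flipped at the end (default 0).
#' @param hla_alleles HLA allele pool.
#' @param tcr_pool_size background CDR3-beta pool size.
#' @param seed RNG seed.
#' @return List with `complexes` (data.frame) and `features` (a
#'   `feature_table` with one row per complex, labels attached).
#' @export
simulate_complexes <- function(n_positive = 100L,
                               neg_ratio = 10L,
                               pos_phla_scale = 2.0,
                               pos_ptcr_scale = 3.0,
                               pos_contamination = 0.3,
                               neg_low_weight = 0.2,
                               label_noise = 0,
                               hla_alleles = c("HLA-A*02:01", "HLA-A*11:01",
                                               "HLA-B*07:02", "HLA-B*40:01",
                                               "HLA-C*07:01"),
                               tcr_pool_size = max(200L, 3L * neg_ratio),
                               seed = 1L) {
  stopifnot(n_positive >= 1, neg_ratio >= 1,
            label_noise >= 0, label_noise < 1)
  with_seed(seed, {
    # unique peptides, lengths 8-11
    pep <- unique(random_aa_strings(3L * n_positive,
                                    sample(8:11, 3L * n_positive, replace = TRUE)))
    if (length(pep) < n_positive) {
      stop("peptide collision; reduce n_positive", call. = FALSE)
    }
    pep <- pep[seq_len(n_positive)]
    pool <- unique(random_aa_strings(2L * tcr_pool_size,
                                     sample(10:18, 2L * tcr_pool_size,
                                            replace = TRUE)))
    if (length(pool) < tcr_pool_size) {
      stop("TCR pool collision; reduce tcr_pool_size", call. = FALSE)
    }
    pool <- pool[seq_len(tcr_pool_size)]
    positives <- data.frame(
      peptide = pep,
      hla = sample(hla_alleles, n_positive, replace = TRUE),
      cdr3b = sample(pool, n_positive, replace = TRUE),
      label = "immunogenic", source = "synthetic",
      stringsAsFactors = FALSE
    )
    neg_seed <- sample.int(.Machine$integer.max, 1)
    negatives <- make_negatives(
      positives, pool,
      assembly_config(negatives_per_phla = neg_ratio, seed = neg_seed)
    )
    negatives$source <- "synthetic_pairing"
    complexes <- rbind(positives, negatives)
    is_pos <- complexes$label == "immunogenic"
    n <- nrow(complexes)
    phla <- numeric(n); ptcr <- numeric(n)
    phla[is_pos] <- draw_ranks(sum(is_pos), 1 - pos_contamination,
                               pos_phla_scale)
    ptcr[is_pos] <- draw_ranks(sum(is_pos), 1 - pos_contamination,
                               pos_ptcr_scale)
    phla[!is_pos] <- draw_ranks(sum(!is_pos), neg_low_weight, pos_phla_scale)
    ptcr[!is_pos] <- draw_ranks(sum(!is_pos), neg_low_weight, pos_ptcr_scale)
    if (label_noise > 0) {
      flip <- stats::runif(n) < label_noise
      complexes$label[flip] <- ifelse(complexes$label[flip] == "immunogenic",
                                      "non_immunogenic", "immunogenic")
    }
    features <- data.frame(
      peptide = complexes$peptide, hla = complexes$hla,
      cdr3b = complexes$cdr3b,
      phla_rank = phla, ptcr_rank = ptcr,
      label = complexes$label, stringsAsFactors = FALSE
    )
    class(features) <- c("feature_table", "data.frame")
    list(complexes = complexes, features = features)
  })
}

#' Simulate ELISpot spot-count records
#'
#' Wild-type wells draw from Poisson(`lambda_wildtype`), mutant wells from
#' Poisson(`lambda_wildtype * true_fold`); DMSO and anti-CD3 control wells
#' from Poisson(`lambda_dmso`) and Poisson(`lambda_anti_cd3`).
#'
#' @param n_records number of peptide records.
#' @param lambda_wildtype mean wild-type spot count (default 20).
#' @param true_fold true fold change, scalar or one value per record.
#' @param lambda_dmso,lambda_anti_cd3 control-well means (defaults 2, 150).
#' @param patient_ids recycled over records.
#' @param seed RNG seed.
#' @return data.frame of ELISpot records including the latent `true_fold`.
#' @export
simulate_elispot <- function(n_records = 20L,
                             lambda_wildtype = 20,
                             true_fold = 1.0,
                             lambda_dmso = 2,
                             lambda_anti_cd3 = 150,
                             patient_ids = "PT01",
                             seed = 1L) {
  stopifnot(n_records >= 1, lambda_wildtype > 0, all(true_fold > 0))
  tf <- rep_len(true_fold, n_records)
  with_seed(seed, {
    data.frame(
      patient_id = rep_len(patient_ids, n_records),
      peptide_id = sprintf("PEP%03d", seq_len(n_records)),
      mutant_spots = stats::rpois(n_records, lambda_wildtype * tf),
      wildtype_spots = stats::rpois(n_records, lambda_wildtype),
      dmso_spots = stats::rpois(n_records, lambda_dmso),
      anti_cd3_spots = stats::rpois(n_records, lambda_anti_cd3),
      true_fold = tf,
      stringsAsFactors = FALSE
    )
  })
}

#' Write complexes / features / ELISpot tables in the pipeline's formats
#'
#' Convenience writers emitting the exact TSV/CSV schemas the readers
#' consume, so simulated data round-trips through the file interfaces.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_complexes_tsv <- function(x, path) {
  utils::write.table(x[, COMPLEX_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_complexes_tsv
#' @export
write_features_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature table TSV written by [write_features_tsv()]
#'
#' @param path TSV path.
#' @return A `feature_table` data.frame.
#' @export
read_features_tsv <- function(path) {
  df <- read_tsv_checked(path, c("phla_rank", "ptcr_rank"), "features")
  if (any(df$phla_rank < 0 | df$phla_rank > 100 |
          df$ptcr_rank < 0 | df$ptcr_rank > 100)) {
    stop("feature ranks outside [0, 100] in ", path, call. = FALSE)
  }
  class(df) <- c("feature_table", "data.frame")
  df
}
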