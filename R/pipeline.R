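#' Default end-to-end pipeline configuration
#'
#' Returns the full configuration of [run_pipeline()] as a named list;
#' every field can be overridden by a YAML or JSON config file. Scales are
#' percentile units; see the package vignette for the rationale behind each
#' default.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @return Named list of pipeline parameters.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    # training-set generator
    n_positive = 300L, neg_ratio = 10L,
    pos_phla_scale = 2.0, pos_ptcr_scale = 3.0,
    pos_contamination = 0.3, neg_low_weight = 0.2, label_noise = 0,
    # assembly / split
    split_fraction = 0.7, split_unit = "peptide",
    # model
    algorithms = c("LR", "RF", "XGB"), cv_folds = 10L,
    specificity_targets = c(0.95, 0.99),
    # per-patient prioritization
    n_patients = 8L, candidates_per_patient = 12L,
    positives_per_patient = 3L, top_k = 3L,
    # elispot
    lambda_wildtype = 20, elispot_fold_cutoff = 2.0,
    true_fold_positive = 4.0, true_fold_negative = 1.0
  )
}

read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stop("YAML config requires the yaml package; use JSON instead",
         call. = FALSE)
  }
  base <- default_pipeline_config(seed = cfg$seed %||% 1L)
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(base, cfg)
}

# Simulate one patient's candidate set with ground-truth labels; features
# are drawn from the same class-conditional distributions as training data.
simulate_patient_candidates <- function(cfg, patient_id, seed) {
  n <- cfg$candidates_per_patient
  n_pos <- cfg$positives_per_patient
  stopifnot(n_pos >= 1, n - n_pos >= 1)
  with_seed(seed, {
    lab <- c(rep("immunogenic", n_pos), rep("non_immunogenic", n - n_pos))
    lab <- sample(lab)
    is_pos <- lab == "immunogenic"
    phla <- ptcr <- numeric(n)
    phla[is_pos] <- draw_ranks(sum(is_pos), 1 - cfg$pos_contamination,
                               cfg$pos_phla_scale)
    ptcr[is_pos] <- draw_ranks(sum(is_pos), 1 - cfg$pos_contamination,
                               cfg$pos_ptcr_scale)
    phla[!is_pos] <- draw_ranks(sum(!is_pos), cfg$neg_low_weight,
                                cfg$pos_phla_scale)
    ptcr[!is_pos] <- draw_ranks(sum(!is_pos), cfg$neg_low_weight,
                                cfg$pos_ptcr_scale)
    data.frame(
      patient_id = patient_id,
      candidate = sprintf("%s_CAND%02d", patient_id, seq_len(n)),
      phla_rank = phla, ptcr_rank = ptcr,
      label = lab,
      validation_label = ifelse(is_pos, "positive", "negative"),
      stringsAsFactors = FALSE
    )
  })
}

#' Run the full neoantigen prioritization pipeline on synthetic data
#'
#' Executes every stage end to end: simulate a labeled pHLA-TCR complex
#' set (positives plus random-TCR-paired negatives), deduplicate, split
#' 70/30 peptide-disjoint, select a classifier by 10-fold cross-validation,
#' fit and calibrate fixed-specificity operating points, evaluate on the
#' validation side, run the fixed-cutoff quadrant analysis, then simulate
#' per-patient candidate sets, rank them with the combined model and with
#' the pHLA-rank-only baseline, compare the two arms by rank coverage, and
#' simulate/call an ELISpot validation round for the nominated candidates.
#'
#' @param config a config list ([default_pipeline_config()]), or a path to
#'   a YAML/JSON file overriding its fields.
#' @return List with elements `data` (split), `cv`, `model`, `evaluation`,
#'   `quadrants`, `ranking` (per-patient and pooled rank coverage per arm),
#'   `elispot` (annotated records and per-method summary), `config`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else {
    utils::modifyList(default_pipeline_config(), config)
  }
  seeds <- with_seed(cfg$seed, sample.int(2^31 - 1, 6))

  ## 1. simulate + assemble
  sim <- simulate_complexes(
    n_positive = cfg$n_positive, neg_ratio = cfg$neg_ratio,
    pos_phla_scale = cfg$pos_phla_scale, pos_ptcr_scale = cfg$pos_ptcr_scale,
    pos_contamination = cfg$pos_contamination,
    neg_low_weight = cfg$neg_low_weight, label_noise = cfg$label_noise,
    seed = seeds[1]
  )
  feats <- deduplicate_complexes(sim$features)
  acfg <- assembly_config(
    negatives_per_phla = cfg$neg_ratio, split_fraction = cfg$split_fraction,
    split_unit = cfg$split_unit, seed = seeds[2]
  )
  split <- split_discovery_validation(feats, acfg)

  ## 2. train on discovery
  mcfg <- model_config(
    algorithms = cfg$algorithms, cv_folds = cfg$cv_folds,
    feature_set = "combined",
    specificity_targets = cfg$specificity_targets, seed = seeds[3]
  )
  cv <- cross_validate_select(split$discovery, mcfg)
  model <- fit_final(split$discovery, cv$selected, mcfg,
                     cv_mean_auc = max(cv$cv_table$mean_auc))
  evaluation <- evaluate_report(model, split$validation,
                                n_boot = 500L, boot_seed = seeds[4])
  quadrants <- quadrant_analysis(split$validation)

  ## 3. per-patient prioritization: combined model vs pHLA-rank baseline
  patients <- sprintf("PT%02d", seq_len(cfg$n_patients))
  lists <- list()
  nominated <- list()
  for (i in seq_along(patients)) {
    cand <- simulate_patient_candidates(cfg, patients[i], seeds[5] + i)
    comb_scores <- stats::setNames(stats::predict(model, cand), cand$candidate)
    phla_scores <- stats::setNames(cand$phla_rank, cand$candidate)
    rl_comb <- rank_candidates(comb_scores, "higher_better", cfg$top_k,
                               patient_id = patients[i], method = "combined")
    rl_phla <- rank_candidates(phla_scores, "lower_better", cfg$top_k,
                               patient_id = patients[i], method = "phla_only")
    vlab <- stats::setNames(cand$validation_label, cand$candidate)
    rl_comb$validation_label <- unname(vlab[rl_comb$candidate])
    rl_phla$validation_label <- unname(vlab[rl_phla$candidate])
    lists <- c(lists, list(rl_comb, rl_phla))
    nominated[[i]] <- rbind(
      data.frame(patient_id = patients[i], method = "combined",
                 candidate = rl_comb$candidate[rl_comb$top_k],
                 positive = rl_comb$validation_label[rl_comb$top_k] == "positive"),
      data.frame(patient_id = patients[i], method = "phla_only",
                 candidate = rl_phla$candidate[rl_phla$top_k],
                 positive = rl_phla$validation_label[rl_phla$top_k] == "positive")
    )
  }
  ranking <- compare_methods(lists)
  nominated <- do.call(rbind, nominated)

  ## 4. ELISpot validation of the nominated candidates
  nom_key <- unique(nominated[, c("patient_id", "candidate", "positive")])
  methods_of <- tapply(nominated$method,
                       paste(nominated$patient_id, nominated$candidate),
                       function(m) paste(sort(unique(m)), collapse = ";"))
  es <- simulate_elispot(
    n_records = nrow(nom_key), lambda_wildtype = cfg$lambda_wildtype,
    true_fold = ifelse(nom_key$positive, cfg$true_fold_positive,
                       cfg$true_fold_negative),
    patient_ids = nom_key$patient_id, seed = seeds[6]
  )
  es$peptide_id <- nom_key$candidate
  es$methods <- unname(methods_of[paste(nom_key$patient_id, nom_key$candidate)])
  es_annot <- fold_changes_and_calls(
    es, elispot_config(fold_cutoff = cfg$elispot_fold_cutoff)
  )
  es_summary <- validation_summary(es_annot, c("combined", "phla_only"))

  list(
    config = cfg, data = split, cv = cv, model = model,
    evaluation = evaluation, quadrants = quadrants,
    ranking = ranking, nominated = nominated,
    elispot = list(records = es_annot, summary = es_summary)
  )
}
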