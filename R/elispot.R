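#' ELISpot call configuration
#'
#' @param fold_cutoff positivity cutoff on the mutant/wild-type fold change
#'   (default 2, the published cutoff).
#' @param zero_wildtype_policy `"pseudocount_one"` (default: a zero
#'   wild-type well contributes a denominator of 1 and the record is
#'   flagged) or `"undefined"` (record marked non-evaluable and excluded
#'   from summaries).
#' @param strict if `TRUE`, require fold strictly greater than the cutoff;
#'   default `FALSE` calls fold >= cutoff positive.
#' @param subtract_dmso if `TRUE`, subtract the DMSO background from both
#'   wells (clamped at 0) before the ratio; off by default — the fold
#'   change is defined against the wild-type peptide, not DMSO.
#' @return A list of class `elispot_config`.
#' @export
elispot_config <- function(fold_cutoff = 2.0,
                           zero_wildtype_policy = c("pseudocount_one", "undefined"),
                           strict = FALSE,
                           subtract_dmso = FALSE) {
  zero_wildtype_policy <- match.arg(zero_wildtype_policy)
  if (fold_cutoff <= 0) stop("fold_cutoff must be > 0", call. = FALSE)
  structure(list(
    fold_cutoff = fold_cutoff,
    zero_wildtype_policy = zero_wildtype_policy,
    strict = strict,
    subtract_dmso = subtract_dmso
  ), class = "elispot_config")
}

check_spots <- function(x, what) {
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop(what, " spot counts must be non-negative integers", call. = FALSE)
  }
}

#' Fold changes and immunogenicity calls from ELISpot counts
#'
#' Computes, per record, the IFN-gamma fold change of the mutant long
#' peptide over its matched wild-type peptide and calls immunogenicity at
#' the configured cutoff.
#'
#' @param records data.frame with columns `patient_id`, `peptide_id`,
#'   `mutant_spots`, `wildtype_spots`, and optionally `dmso_spots`,
#'   `anti_cd3_spots`, `methods` (semicolon-separated nominating methods).
#' @param config an [elispot_config()].
#' @return The records annotated with `fold_change`, `call` (logical),
#'   `zero_wildtype` (flag), `evaluable`, and `assay_valid` (anti-CD3 >
#'   DMSO when both controls are present, else NA).
#' @export
fold_changes_and_calls <- function(records, config = elispot_config()) {
  stopifnot(inherits(config, "elispot_config"))
  req <- c("patient_id", "peptide_id", "mutant_spots", "wildtype_spots")
  if (!all(req %in% names(records))) {
    stop("records need columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  check_spots(records$mutant_spots, "mutant")
  check_spots(records$wildtype_spots, "wildtype")
  mut <- as.numeric(records$mutant_spots)
  wt <- as.numeric(records$wildtype_spots)
  if (config$subtract_dmso && "dmso_spots" %in% names(records)) {
    mut <- pmax(mut - records$dmso_spots, 0)
    wt <- pmax(wt - records$dmso_spots, 0)
  }
  zero_wt <- wt == 0
  evaluable <- rep(TRUE, nrow(records))
  if (config$zero_wildtype_policy == "pseudocount_one") {
    denom <- ifelse(zero_wt, 1, wt)
    fold <- mut / denom
  } else {
    fold <- ifelse(zero_wt, NA_real_, mut / wt)
    evaluable <- !zero_wt
  }
  call <- ifelse(evaluable,
                 if (config$strict) fold > config$fold_cutoff
                 else fold >= config$fold_cutoff,
                 NA)
  assay_valid <- if (all(c("dmso_spots", "anti_cd3_spots") %in% names(records))) {
    records$anti_cd3_spots > records$dmso_spots
  } else {
    rep(NA, nrow(records))
  }
  out <- records
  out$fold_change <- fold
  out$call <- call
  out$zero_wildtype <- zero_wt
  out$evaluable <- evaluable
  out$assay_valid <- assay_valid
  out
}

#' Per-method and per-patient validation summary
#'
#' Counts, for each nominating method, how many peptides it nominated and
#' how many were confirmed immunogenic; candidates nominated by several
#' methods count for each. Non-evaluable records are excluded.
#'
#' @param records annotated records from [fold_changes_and_calls()], with a
#'   `methods` column of semicolon-separated method tags.
#' @param methods character vector of known method names; an unknown tag in
#'   the records is an error.
#' @return List with `per_method` (method, n_nominated, n_confirmed) and
#'   `per_patient` (patient_id x method confirmed counts).
#' @export
validation_summary <- function(records, methods) {
  if (!"methods" %in% names(records)) {
    stop("records need a `methods` column of nominating method tags",
         call. = FALSE)
  }
  if (!"call" %in% names(records)) {
    stop("records must be annotated by fold_changes_and_calls() first",
         call. = FALSE)
  }
  tags <- strsplit(as.character(records$methods), ";", fixed = TRUE)
  tags <- lapply(tags, trimws)
  if (any(lengths(tags) == 0L)) {
    stop("every record needs at least one method tag", call. = FALSE)
  }
  unknown <- setdiff(unique(unlist(tags)), methods)
  if (length(unknown) > 0L) {
    stop("unknown method tag(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- records$evaluable %||% rep(TRUE, nrow(records))
  per_method <- do.call(rbind, lapply(methods, function(m) {
    nom <- vapply(tags, function(t) m %in% t, logical(1)) & keep
    data.frame(
      method = m,
      n_nominated = sum(nom),
      n_confirmed = sum(nom & records$call %in% TRUE)
    )
  }))
  patients <- unique(records$patient_id)
  per_patient <- do.call(rbind, lapply(patients, function(p) {
    row <- data.frame(patient_id = p, stringsAsFactors = FALSE)
    for (m in methods) {
      nom <- vapply(tags, function(t) m %in% t, logical(1)) & keep &
        records$patient_id == p
      row[[m]] <- sum(nom & records$call %in% TRUE)
    }
    row
  }))
  list(per_method = per_method, per_patient = per_patient)
}
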