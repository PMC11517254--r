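#' Predictor adapters for pHLA and pHLA-TCR ranks
#'
#' The pipeline never runs binding predictors itself; it consumes their
#' percentile ranks through an adapter. Two modes exist:
#' `"table"` looks ranks up in a user-supplied score table (users run
#' NetMHCpan-class and pMTNet-class tools externally) and errors on any
#' missing key; `"synthetic"` returns a deterministic hash-seeded rank in
#' `[0, 100)` so the pipeline is testable with no external model.
#'
#' @param mode `"table"` or `"synthetic"`.
#' @param table for table mode: data.frame with the key columns and a
#'   `rank` column (percentile, 0-100). pMTNet-style fractional ranks in
#'   `[0, 1]` should be rescaled with `rescale_fraction = TRUE`.
#' @param key_cols character vector of key columns, e.g.
#'   `c("peptide", "hla")` or `c("peptide", "hla", "cdr3b")`.
#' @param rescale_fraction multiply table ranks by 100 (adapter boundary
#'   rescaling so the 2 percent cutoff reads identically for both features).
#' @param name adapter label.
#' @return An object of class `predictor_adapter`.
#' @export
predictor_adapter <- function(mode = c("synthetic", "table"),
                              table = NULL,
                              key_cols = c("peptide", "hla"),
                              rescale_fraction = FALSE,
                              name = mode[1]) {
  mode <- match.arg(mode)
  if (mode == "table") {
    if (is.null(table) || !all(c(key_cols, "rank") %in% names(table))) {
      stop("table mode needs a data.frame with columns ",
           paste(c(key_cols, "rank"), collapse = ", "), call. = FALSE)
    }
    rank <- as.numeric(table$rank)
    if (rescale_fraction) rank <- rank * 100
    if (any(!is.finite(rank)) || any(rank < 0) || any(rank > 100)) {
      stop("ranks must be finite percentiles in [0, 100]", call. = FALSE)
    }
    lookup <- stats::setNames(rank, do.call(paste, c(table[key_cols], sep = "|")))
  } else {
    lookup <- NULL
  }
  structure(list(mode = mode, key_cols = key_cols, lookup = lookup, name = name),
            class = "predictor_adapter")
}

# Resolve percentile ranks for a data.frame of keys
adapter_query <- function(adapter, keys_df) {
  stopifnot(inherits(adapter, "predictor_adapter"))
  key <- do.call(paste, c(keys_df[adapter$key_cols], sep = "|"))
  if (adapter$mode == "table") {
    r <- adapter$lookup[key]
    if (anyNA(r)) {
      stop("adapter '", adapter$name, "' has no score for key(s): ",
           paste(utils::head(key[is.na(r)], 5), collapse = "; "),
           call. = FALSE)
    }
    unname(r)
  } else {
    # deterministic pure function of the key: hash -> uniform [0, 100)
    (hash31(paste0(adapter$name, "::", key)) %% 100000L) / 1000
  }
}

#' Per-peptide minimum pHLA percentile rank
#'
#' Aggregates pHLA binding percentile ranks to one value per unique
#' peptide by taking the minimum over all alleles and prediction tools —
#' the strongest predicted presentation of that peptide.
#'
#' @param scores data.frame with columns `peptide`, `rank`, and optionally
#'   `hla` and `tool` (any extra grouping columns are simply minimized over).
#' @return Named numeric vector: peptide -> minimum percentile.
#' @export
aggregate_min_phla <- function(scores) {
  stopifnot(all(c("peptide", "rank") %in% names(scores)))
  if (nrow(scores) == 0L) stop("empty score set", call. = FALSE)
  r <- as.numeric(scores$rank)
  if (any(!is.finite(r))) stop("non-finite rank", call. = FALSE)
  out <- tapply(r, scores$peptide, min)
  stats::setNames(as.numeric(out), names(out))
}

#' Per-pHLA minimum TCR engagement rank over a repertoire
#'
#' For each (peptide, HLA) pair, returns the minimum pHLA-TCR rank over
#' the supplied CDR3-beta repertoire: the best predicted engagement by any
#' TCR the patient carries.
#'
#' @param ranks data.frame with columns `peptide`, `hla`, `cdr3b`, `rank`.
#' @param repertoire character vector of CDR3-beta sequences to minimize
#'   over; every (pHLA, repertoire TCR) pair queried must be present.
#' @return data.frame with columns `peptide`, `hla`, `min_rank`.
#' @export
aggregate_min_tcr <- function(ranks, repertoire) {
  stopifnot(all(c("peptide", "hla", "cdr3b", "rank") %in% names(ranks)))
  repertoire <- unique(as.character(repertoire))
  if (length(repertoire) == 0L) stop("empty repertoire", call. = FALSE)
  sub <- ranks[ranks$cdr3b %in% repertoire, , drop = FALSE]
  phlas <- unique(ranks[, c("peptide", "hla")])
  got <- tapply(sub$cdr3b, phla_key(sub), function(x) length(unique(x)))
  want <- phla_key(phlas)
  short <- want[!(want %in% names(got)) | got[want] < length(repertoire)]
  if (length(short) > 0L) {
    stop("missing pHLA-TCR ranks for repertoire TCRs at pHLA(s): ",
         paste(utils::head(short, 5), collapse = "; "), call. = FALSE)
  }
  agg <- tapply(sub$rank, phla_key(sub), min)
  data.frame(
    peptide = phlas$peptide, hla = phlas$hla,
    min_rank = as.numeric(agg[want]),
    stringsAsFactors = FALSE
  )
}

#' Mutant-versus-wild-type binding filter
#'
#' Retains candidates whose mutant peptide has a strictly lower (stronger)
#' binding percentile than the matched wild-type peptide; ties drop.
#'
#' @param pairs data.frame with columns `key`, `mutant_rank`,
#'   `wildtype_rank`.
#' @return Character vector of retained keys.
#' @export
wildtype_filter <- function(pairs) {
  stopifnot(all(c("key", "mutant_rank", "wildtype_rank") %in% names(pairs)))
  miss <- !is.finite(pairs$wildtype_rank)
  if (any(miss)) {
    stop("missing wild-type score for key(s): ",
         paste(pairs$key[miss], collapse = ", "), call. = FALSE)
  }
  pairs$key[pairs$mutant_rank < pairs$wildtype_rank]
}

#' Build the two-feature table for a set of complexes
#'
#' Resolves each complex's pHLA percentile rank and pHLA-TCR rank through
#' the two adapters, yielding one feature row per complex. Both features
#' are percentiles in `[0, 100]`, lower = stronger predicted
#' binding/engagement.
#'
#' @param complexes data.frame of complexes (columns `peptide`, `hla`,
#'   `cdr3b`, optionally `label`).
#' @param phla_adapter [predictor_adapter()] keyed on (peptide, hla).
#' @param ptcr_adapter [predictor_adapter()] keyed on (peptide, hla, cdr3b).
#' @return data.frame of class `feature_table`: key columns plus
#'   `phla_rank`, `ptcr_rank` and `label` (NA when unlabeled).
#' @export
build_feature_table <- function(complexes,
                                phla_adapter = predictor_adapter("synthetic", name = "phla"),
                                ptcr_adapter = predictor_adapter(
                                  "synthetic",
                                  key_cols = c("peptide", "hla", "cdr3b"),
                                  name = "ptcr"
                                )) {
  stopifnot(nrow(complexes) > 0L)
  out <- data.frame(
    peptide = complexes$peptide,
    hla = complexes$hla,
    cdr3b = complexes$cdr3b,
    phla_rank = adapter_query(phla_adapter, complexes),
    ptcr_rank = adapter_query(ptcr_adapter, complexes),
    label = if ("label" %in% names(complexes)) complexes$label else NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(out$phla_rank < 0 | out$phla_rank > 100 |
          out$ptcr_rank < 0 | out$ptcr_rank > 100)) {
    stop("feature ranks outside [0, 100]", call. = FALSE)
  }
  class(out) <- c("feature_table", "data.frame")
  out
}
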