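#' Assembly configuration for the labeled pHLA-TCR dataset
#'
#' @param negatives_per_phla negatives drawn per distinct positive
#'   (peptide, HLA) pair (default 10, the published pairing rule).
#' @param split_fraction discovery-set fraction (default 0.70).
#' @param split_unit `"peptide"` (default; all complexes sharing a peptide
#'   land on the same side, preventing peptide leakage) or `"complex"`.
#' @param seed RNG seed used for negative sampling and splitting.
#' @return A list of class `assembly_config`.
#' @export
assembly_config <- function(negatives_per_phla = 10L,
                            split_fraction = 0.70,
                            split_unit = c("peptide", "complex"),
                            seed = 1L) {
  split_unit <- match.arg(split_unit)
  if (negatives_per_phla < 1) stop("negatives_per_phla must be >= 1", call. = FALSE)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(
    negatives_per_phla = as.integer(negatives_per_phla),
    split_fraction = split_fraction,
    split_unit = split_unit,
    seed = as.integer(seed)
  ), class = "assembly_config")
}

COMPLEX_COLS <- c("peptide", "hla", "cdr3b", "label", "source")
LABELS <- c("immunogenic", "non_immunogenic")

validate_complexes <- function(df, drop_invalid = TRUE) {
  ok_pep <- is_valid_aa(df$peptide) & nchar(df$peptide) >= 8 & nchar(df$peptide) <= 11
  ok_cdr3 <- is_valid_aa(df$cdr3b)
  ok_hla <- !is.na(df$hla) & nzchar(df$hla)
  bad_label <- !(df$label %in% LABELS)
  if (any(bad_label) && !drop_invalid) {
    stop("unknown immunogenicity label(s): ",
         paste(unique(df$label[bad_label]), collapse = ", "), call. = FALSE)
  }
  reasons <- character(nrow(df))
  reasons[!ok_cdr3] <- "cdr3b alphabet"
  reasons[!ok_hla] <- "missing hla"
  reasons[!is_valid_aa(df$peptide)] <- "peptide alphabet"
  reasons[is_valid_aa(df$peptide) & !ok_pep] <- "peptide length"
  keep <- ok_pep & ok_cdr3 & ok_hla
  list(keep = keep, reasons = reasons)
}

#' Normalize HLA class-I allele names
#'
#' Canonicalizes strings like `"A0201"`, `"HLA-A02:01"`, `"hla-a*02:01"`
#' to `"HLA-A*02:01"`. With `resolution = "two-digit"` the protein field is
#' dropped (`"HLA-A*02"`), matching two-digit HLA typing.
#'
#' @param x character vector of allele names.
#' @param resolution `"four-digit"` (default) or `"two-digit"`.
#' @return Normalized character vector.
#' @export
normalize_hla <- function(x, resolution = c("four-digit", "two-digit")) {
  resolution <- match.arg(resolution)
  y <- toupper(trimws(x))
  y <- sub("^HLA-", "", y)
  y <- gsub("[*]", "", y)
  gene <- sub("^([A-Z]+).*$", "\\1", y)
  digits <- sub("^[A-Z]+", "", y)
  digits <- gsub("[^0-9:]", "", digits)
  parts <- strsplit(digits, ":")
  out <- vapply(seq_along(y), function(i) {
    p <- parts[[i]]
    p <- p[nzchar(p)]
    if (length(p) == 1L && nchar(p[1]) >= 4L) {
      p <- c(substr(p[1], 1, 2), substr(p[1], 3, nchar(p[1])))
    }
    if (length(p) == 0L) return(sprintf("HLA-%s", gene[i]))
    if (resolution == "two-digit" || length(p) == 1L) {
      sprintf("HLA-%s*%s", gene[i], p[1])
    } else {
      sprintf("HLA-%s*%s:%s", gene[i], p[1], p[2])
    }
  }, character(1))
  out
}

#' Load labeled pHLA-TCR complex tables
#'
#' Reads one or more complexes TSVs (columns `peptide`, `hla`, `cdr3b`,
#' `label`, `source`) and concatenates them. Rows violating the type
#' invariants (peptide length outside 8-11, non-amino-acid characters,
#' missing HLA) are dropped with per-reason counts attached as attribute
#' `"dropped"`. Duplicates across files are kept; deduplication is a
#' separate step ([deduplicate_complexes()]).
#'
#' @param paths character vector of TSV paths (`.gz` transparent).
#' @return data.frame of complexes.
#' @export
load_complexes <- function(paths) {
  dfs <- lapply(paths, function(p) {
    df <- read_tsv_checked(p, COMPLEX_COLS, "complexes")
    df[, COMPLEX_COLS]
  })
  df <- do.call(rbind, dfs)
  df$peptide <- toupper(as.character(df$peptide))
  df$cdr3b <- toupper(as.character(df$cdr3b))
  df$label <- as.character(df$label)
  bad_label <- !(df$label %in% LABELS) & !is.na(df$label) & nzchar(df$label)
  if (any(bad_label)) {
    stop("unknown immunogenicity label(s): ",
         paste(unique(df$label[bad_label]), collapse = ", "), call. = FALSE)
  }
  v <- validate_complexes(df)
  out <- df[v$keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- table(v$reasons[!v$keep])
  out
}

complex_key <- function(df) paste(df$peptide, df$hla, df$cdr3b, sep = "|")
phla_key <- function(df) paste(df$peptide, df$hla, sep = "|")

#' Construct the negative set by random TCR pairing
#'
#' For each distinct positive (peptide, HLA) pair, draws
#' `negatives_per_phla` CDR3-beta sequences uniformly without replacement
#' from a background TCR pool, excluding any TCR known to form an
#' immunogenic complex with that pHLA, and labels the resulting complexes
#' non-immunogenic.
#'
#' @param positives data.frame of immunogenic complexes (columns `peptide`,
#'   `hla`, `cdr3b`; extra columns ignored).
#' @param tcr_pool character vector of background CDR3-beta sequences.
#' @param config an [assembly_config()].
#' @return data.frame of negative complexes with `source = "random_pairing"`.
#' @export
make_negatives <- function(positives, tcr_pool, config = assembly_config()) {
  stopifnot(inherits(config, "assembly_config"))
  if (nrow(positives) == 0L) stop("`positives` is empty", call. = FALSE)
  k <- config$negatives_per_phla
  tcr_pool <- unique(as.character(tcr_pool))
  if (length(tcr_pool) < k) {
    stop("TCR pool smaller than negatives_per_phla", call. = FALSE)
  }
  phlas <- unique(positives[, c("peptide", "hla")])
  pos_partner <- split(positives$cdr3b, phla_key(positives))
  with_seed(config$seed, {
    neg <- lapply(seq_len(nrow(phlas)), function(i) {
      key <- paste(phlas$peptide[i], phlas$hla[i], sep = "|")
      pool <- setdiff(tcr_pool, pos_partner[[key]])
      if (length(pool) < k) {
        stop(sprintf(
          "TCR pool too small for pHLA %s after excluding %d known positive partner(s)",
          key, length(pos_partner[[key]])
        ), call. = FALSE)
      }
      data.frame(
        peptide = phlas$peptide[i], hla = phlas$hla[i],
        cdr3b = sample(pool, k, replace = FALSE),
        label = "non_immunogenic", source = "random_pairing",
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, neg)
  })
}

#' Deduplicate pHLA-TCR complexes
#'
#' Collapses records to unique (peptide, HLA, cdr3b) triples. When the
#' same triple carries conflicting labels, the immunogenic label wins and
#' the conflict count is attached as attribute `"n_label_conflicts"`.
#'
#' @param records data.frame of complexes.
#' @return Deduplicated data.frame.
#' @export
deduplicate_complexes <- function(records) {
  key <- complex_key(records)
  lab_by_key <- tapply(records$label == "immunogenic", key, any)
  first <- records[!duplicated(key), , drop = FALSE]
  fkey <- complex_key(first)
  resolved <- ifelse(lab_by_key[fkey], "immunogenic", "non_immunogenic")
  n_conflict <- sum(tapply(records$label, key, function(l) length(unique(l)) > 1L))
  first$label <- unname(resolved)
  rownames(first) <- NULL
  attr(first, "n_label_conflicts") <- n_conflict
  first
}

#' Split complexes into discovery and validation sets
#'
#' Label-stratified random split at `split_fraction` (default 70/30). With
#' `split_unit = "peptide"` all complexes sharing a peptide are assigned to
#' the same side (stratified by whether the peptide has any immunogenic
#' complex), preventing peptide leakage between sides. Per-stratum
#' discovery sizes use floor + largest-remainder so the overall discovery
#' count equals `round(fraction * n)`.
#'
#' @param records data.frame of labeled complexes (>= 10 rows).
#' @param config an [assembly_config()].
#' @return A list of class `split_dataset`: `discovery`, `validation`
#'   (data.frames), `split_seed`, `split_unit`.
#' @export
split_discovery_validation <- function(records, config = assembly_config()) {
  stopifnot(inherits(config, "assembly_config"))
  if (nrow(records) < 10L) stop("need at least 10 records to split", call. = FALSE)
  frac <- config$split_fraction
  if (config$split_unit == "complex") {
    strata <- records$label
    units <- seq_len(nrow(records))
    unit_of_record <- units
  } else {
    peptides <- unique(records$peptide)
    has_pos <- tapply(records$label == "immunogenic", records$peptide, any)
    strata <- ifelse(has_pos[peptides], "with_positive", "negative_only")
    units <- peptides
    unit_of_record <- match(records$peptide, peptides)
  }
  stratum_of_unit <- as.character(strata)
  tab <- table(stratum_of_unit)
  if (config$split_unit == "complex" && any(table(records$label) < 2L)) {
    stop("each label class needs >= 2 records for a stratified split",
         call. = FALSE)
  }
  # per-stratum discovery sizes: floor + largest remainder to hit round(frac*N)
  target_total <- round(frac * length(units))
  raw <- frac * as.numeric(tab)
  base <- floor(raw)
  rem <- target_total - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(raw - base, decreasing = FALSE)
    base[ord[seq_len(-rem)]] <- base[ord[seq_len(-rem)]] - 1
  }
  names(base) <- names(tab)
  in_discovery <- logical(length(units))
  with_seed(config$seed, {
    for (s in names(tab)) {
      idx <- which(stratum_of_unit == s)
      take <- base[[s]]
      if (take > 0) in_discovery[idx[sample.int(length(idx), take)]] <- TRUE
    }
  })
  disc <- records[in_discovery[unit_of_record], , drop = FALSE]
  val <- records[!in_discovery[unit_of_record], , drop = FALSE]
  rownames(disc) <- rownames(val) <- NULL
  # hard assertion of the disjointness invariant
  if (length(intersect(complex_key(disc), complex_key(val))) > 0L) {
    stop("internal error: discovery and validation share complexes", call. = FALSE)
  }
  if (config$split_unit == "peptide" &&
      length(intersect(disc$peptide, val$peptide)) > 0L) {
    stop("internal error: peptide leakage across split sides", call. = FALSE)
  }
  structure(list(
    discovery = disc, validation = val,
    split_seed = config$seed, split_unit = config$split_unit
  ), class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf(
    "<split_dataset> unit=%s seed=%d | discovery %d (%d pos) / validation %d (%d pos)\n",
    x$split_unit, x$split_seed,
    nrow(x$discovery), sum(x$discovery$label == "immunogenic"),
    nrow(x$validation), sum(x$validation$label == "immunogenic")
  ))
  invisible(x)
}

#' Write a split manifest JSON
#'
#' Records the seed, fraction, unit, per-side counts and a checksum of the
#' member keys, so a split can be verified byte-identically.
#'
#' @param split a `split_dataset`.
#' @param config the [assembly_config()] used.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, config, path) {
  keys <- c(sort(complex_key(split$discovery)), "||",
            sort(complex_key(split$validation)))
  jsonlite::write_json(list(
    seed = split$split_seed,
    fraction = config$split_fraction,
    unit = split$split_unit,
    n_discovery = nrow(split$discovery),
    n_validation = nrow(split$validation),
    key_checksum = sum(hash31(keys))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
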