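#' Construct a clonotype table
#'
#' A clonotype table holds one sample's TCR-beta clonotypes: the CDR3
#' amino-acid sequence, V and J segment calls, and a UMI-collapsed read
#' count per clonotype. It is the unit of all repertoire statistics.
#'
#' @param sample_id sample identifier string.
#' @param clonotypes data.frame with columns `cdr3_aa`, `v_call`, `j_call`,
#'   `count`. Rows must be unique on (cdr3_aa, v_call, j_call); counts must
#'   be positive integers; CDR3 sequences must use the 20 standard
#'   amino-acid letters (stop codons `*` are rejected upstream).
#' @return An object of class `clonotype_table` with elements `sample_id`,
#'   `clonotypes` and `total_reads`.
#' @export
clonotype_table <- function(sample_id, clonotypes) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  req <- c("cdr3_aa", "v_call", "j_call", "count")
  if (!is.data.frame(clonotypes) || !all(req %in% names(clonotypes))) {
    stop("`clonotypes` must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(clonotypes) == 0L) {
    stop("empty clonotype table for sample ", sample_id, call. = FALSE)
  }
  if (!all(is_valid_aa(clonotypes$cdr3_aa))) {
    stop("clonotype CDR3 sequences must be non-empty strings over the 20 ",
         "standard amino acids", call. = FALSE)
  }
  if (any(!nzchar(clonotypes$v_call)) || any(!nzchar(clonotypes$j_call))) {
    stop("v_call and j_call must be non-empty", call. = FALSE)
  }
  cnt <- clonotypes$count
  if (any(is.na(cnt)) || any(cnt < 1) || any(cnt != round(cnt))) {
    stop("counts must be integers >= 1", call. = FALSE)
  }
  key <- clonotype_key(clonotypes)
  if (anyDuplicated(key)) {
    stop("duplicate clonotype keys; merge rows before construction",
         call. = FALSE)
  }
  clonotypes <- clonotypes[, req]
  rownames(clonotypes) <- NULL
  structure(
    list(
      sample_id = sample_id,
      clonotypes = clonotypes,
      total_reads = sum(as.numeric(cnt))
    ),
    class = "clonotype_table"
  )
}

clonotype_key <- function(df, cdr3_only = FALSE) {
  if (cdr3_only) df$cdr3_aa else paste(df$cdr3_aa, df$v_call, df$j_call, sep = "|")
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat(sprintf(
    "<clonotype_table> sample %s: %d clonotypes, %s reads\n",
    x$sample_id, nrow(x$clonotypes), format(x$total_reads, big.mark = ",")
  ))
  invisible(x)
}

#' Clone frequencies of a clonotype table
#'
#' @param table a [clonotype_table()].
#' @return Numeric vector of frequencies `p_i = count_i / total_reads`
#'   summing to 1.
#' @export
clone_frequencies <- function(table) {
  stopifnot(inherits(table, "clonotype_table"))
  table$clonotypes$count / table$total_reads
}

#' Read a TCR-beta clonotype TSV
#'
#' Reads an AIRR Rearrangement style table (columns `junction_aa`,
#' `v_call`, `j_call`, `duplicate_count`) or a generic TSV with a
#' user-supplied column map. Rows sharing the same (CDR3, V, J) key are
#' merged by summing counts; rows with an empty/invalid CDR3 or a
#' non-positive count are skipped and counted.
#'
#' @param path TSV file path; `.gz` files are read transparently.
#' @param dialect `"airr"` (default) or `"generic"`.
#' @param columns for `dialect = "generic"`, a named list mapping the
#'   canonical names `cdr3_aa`, `v_call`, `j_call`, `count` to the file's
#'   column names.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @return A [clonotype_table()]; the number of skipped rows is attached
#'   as attribute `"n_skipped"`.
#' @export
read_airr_table <- function(path,
                            dialect = c("airr", "generic"),
                            columns = NULL,
                            sample_id = NULL) {
  dialect <- match.arg(dialect)
  map <- switch(dialect,
    airr = list(cdr3_aa = "junction_aa", v_call = "v_call",
                j_call = "j_call", count = "duplicate_count"),
    generic = {
      need <- c("cdr3_aa", "v_call", "j_call", "count")
      if (is.null(columns) || !all(need %in% names(columns))) {
        stop("generic dialect requires a `columns` map naming ",
             paste(need, collapse = ", "), call. = FALSE)
      }
      columns
    }
  )
  df <- read_tsv_checked(path, unlist(map), "clonotype")
  out <- data.frame(
    cdr3_aa = as.character(df[[map$cdr3_aa]]),
    v_call = as.character(df[[map$v_call]]),
    j_call = as.character(df[[map$j_call]]),
    count = suppressWarnings(as.numeric(df[[map$count]])),
    stringsAsFactors = FALSE
  )
  ok <- is_valid_aa(out$cdr3_aa) & !is.na(out$count) & out$count >= 1 &
    out$count == round(out$count) & nzchar(out$v_call) & nzchar(out$j_call)
  n_skipped <- sum(!ok)
  out <- out[ok, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no valid clonotype rows remain after filtering: ", path,
         call. = FALSE)
  }
  # merge duplicate keys by summing counts
  key <- clonotype_key(out)
  if (anyDuplicated(key)) {
    agg <- rowsum(out$count, group = key, reorder = FALSE)
    first <- out[!duplicated(key), c("cdr3_aa", "v_call", "j_call")]
    out <- cbind(first, count = as.vector(agg[match(
      clonotype_key(first), rownames(agg)
    ), ]))
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  }
  tab <- clonotype_table(sample_id, out)
  attr(tab, "n_skipped") <- n_skipped
  tab
}

#' Filter clonotypes by minimum read count
#'
#' Retains clonotypes whose UMI-collapsed count is at least `min_count`;
#' frequencies renormalize over the retained clones.
#'
#' @param table a [clonotype_table()].
#' @param min_count integer >= 1.
#' @return A filtered [clonotype_table()].
#' @export
filter_by_count <- function(table, min_count = 1L) {
  stopifnot(inherits(table, "clonotype_table"))
  if (min_count < 1) stop("`min_count` must be >= 1", call. = FALSE)
  keep <- table$clonotypes$count >= min_count
  if (!any(keep)) {
    stop("all clonotypes removed at min_count = ", min_count, call. = FALSE)
  }
  clonotype_table(table$sample_id, table$clonotypes[keep, , drop = FALSE])
}

#' Shannon entropy of clone frequencies
#'
#' Computes the diversity index \eqn{H = -\sum_i p_i \ln p_i} in nats over
#' a clone frequency vector.
#'
#' @param freqs numeric vector of clone frequencies; all positive, summing
#'   to 1 within 1e-9.
#' @return Non-negative entropy in nats; 0 for a single clone.
#' @export
shannon_entropy <- function(freqs) {
  validate_freqs(freqs)
  -sum(freqs * log(freqs))
}

#' Clonality index
#'
#' The normalized complement of Shannon entropy,
#' \eqn{1 - H / \ln n}: 0 for a perfectly even repertoire, approaching 1
#' under extreme clonal expansion.
#'
#' @inheritParams shannon_entropy
#' @return Clonality in `[0, 1]`.
#' @export
clonality <- function(freqs) {
  validate_freqs(freqs)
  n <- length(freqs)
  if (n < 2L) {
    stop("clonality is undefined for fewer than 2 clones", call. = FALSE)
  }
  1 - shannon_entropy(freqs) / log(n)
}

validate_freqs <- function(freqs) {
  if (length(freqs) == 0L || any(!is.finite(freqs)) || any(freqs <= 0)) {
    stop("frequencies must be finite and strictly positive", call. = FALSE)
  }
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop("frequencies must sum to 1 (tolerance 1e-9); got ",
         format(sum(freqs), digits = 12), call. = FALSE)
  }
  invisible(TRUE)
}

#' Rarefaction curve of clonotype richness
#'
#' Subsamples reads without replacement at each depth and reports the mean
#' and standard deviation (over replicates) of the number of distinct
#' clonotypes observed, mirroring saturation analysis of repertoire
#' sequencing depth.
#'
#' @param table a [clonotype_table()].
#' @param depths increasing vector of subsampling depths, each `<=`
#'   `total_reads`.
#' @param n_reps replicates per depth (default 100).
#' @param seed RNG seed.
#' @return data.frame with columns `depth`, `mean_richness`, `sd_richness`.
#' @export
rarefaction_curve <- function(table, depths, n_reps = 100L, seed = 1L) {
  stopifnot(inherits(table, "clonotype_table"), n_reps >= 1)
  depths <- as.numeric(depths)
  if (is.unsorted(depths, strictly = TRUE)) {
    stop("`depths` must be strictly increasing", call. = FALSE)
  }
  if (any(depths < 1) || any(depths > table$total_reads)) {
    stop("depths must lie in [1, total_reads = ", table$total_reads, "]",
         call. = FALSE)
  }
  counts <- table$clonotypes$count
  n_clone <- length(counts)
  total <- table$total_reads
  with_seed(seed, {
    res <- lapply(depths, function(d) {
      rich <- vapply(seq_len(n_reps), function(r) {
        if (d == total) return(n_clone)  # exhaustive draw
        # multivariate hypergeometric subsample of the read pool
        drawn <- read_subsample(counts, d)
        sum(drawn > 0)
      }, numeric(1))
      c(depth = d, mean_richness = mean(rich), sd_richness = stats::sd(rich))
    })
    out <- as.data.frame(do.call(rbind, res))
    out$sd_richness[is.na(out$sd_richness)] <- 0
    out
  })
}

# Draw `d` reads without replacement from clones with the given counts;
# returns per-clone drawn counts (multivariate hypergeometric via a
# sequential conditional scheme).
read_subsample <- function(counts, d) {
  n <- length(counts)
  remaining <- sum(counts)
  take <- d
  drawn <- numeric(n)
  for (i in seq_len(n - 1L)) {
    if (take == 0) break
    drawn[i] <- stats::rhyper(1, counts[i], remaining - counts[i], take)
    take <- take - drawn[i]
    remaining <- remaining - counts[i]
  }
  drawn[n] <- take
  drawn
}

#' Clonotype sharing across samples
#'
#' Over the union of clonotypes in two or more samples, counts how many
#' are private (seen in exactly one sample) versus shared (two or more).
#'
#' @param tables list of [clonotype_table()] objects (length >= 2).
#' @param cdr3_only if `TRUE`, clonotype identity is the CDR3 sequence
#'   alone; default `FALSE` uses (CDR3, V, J).
#' @return List with `per_clonotype` (data.frame: key, n_samples),
#'   `n_private`, `n_shared`, `fraction_private`, `fraction_shared`.
#' @export
clonotype_sharing <- function(tables, cdr3_only = FALSE) {
  if (!is.list(tables) || length(tables) < 2L) {
    stop("need at least 2 clonotype tables", call. = FALSE)
  }
  stopifnot(all(vapply(tables, inherits, logical(1), "clonotype_table")))
  keys <- lapply(tables, function(t) unique(clonotype_key(t$clonotypes, cdr3_only)))
  tab <- table(unlist(keys))
  per <- data.frame(
    key = names(tab), n_samples = as.integer(tab),
    stringsAsFactors = FALSE, row.names = NULL
  )
  n_private <- sum(per$n_samples == 1L)
  n_shared <- sum(per$n_samples >= 2L)
  list(
    per_clonotype = per,
    n_private = n_private,
    n_shared = n_shared,
    fraction_private = n_private / nrow(per),
    fraction_shared = n_shared / nrow(per)
  )
}

#' Repertoire profile: diversity, usage and CDR3 length summary
#'
#' Computes the full per-sample summary: singleton/expanded split, Shannon
#' entropy and clonality of the clone frequency vector, per-segment V and J
#' clone counts, the V-by-J pairing matrix, and the CDR3 length summary.
#'
#' @param table a [clonotype_table()].
#' @return An object of class `repertoire_profile` (a list; see fields in
#'   the details) suitable for JSON export.
#' @details Fields: `sample_id`, `n_clonotypes`, `n_singletons`, `n_multi`,
#'   `total_reads`, `shannon`, `clonality` (NA when fewer than 2
#'   clonotypes), `cdr3_length_summary` (median/min/max), `v_usage`,
#'   `j_usage` (named clone-count vectors), `vj_pairing` (matrix).
#' @export
segment_usage <- function(table) {
  stopifnot(inherits(table, "clonotype_table"))
  cl <- table$clonotypes
  freqs <- clone_frequencies(table)
  lens <- nchar(cl$cdr3_aa)
  structure(list(
    sample_id = table$sample_id,
    n_clonotypes = nrow(cl),
    n_singletons = sum(cl$count == 1),
    n_multi = sum(cl$count >= 2),
    total_reads = table$total_reads,
    shannon = shannon_entropy(freqs),
    clonality = if (nrow(cl) >= 2L) clonality(freqs) else NA_real_,
    cdr3_length_summary = c(
      median = stats::median(lens), min = min(lens), max = max(lens)
    ),
    v_usage = table_to_named(cl$v_call),
    j_usage = table_to_named(cl$j_call),
    vj_pairing = table(cl$v_call, cl$j_call)
  ), class = "repertoire_profile")
}

table_to_named <- function(x) {
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.repertoire_profile <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<repertoire_profile> %s\n",
      "  clonotypes: %d (%d singletons, %d expanded)\n",
      "  shannon: %.4f nats, clonality: %s\n",
      "  CDR3 length median %d (range %d-%d); %d V / %d J segments\n"
    ),
    x$sample_id, x$n_clonotypes, x$n_singletons, x$n_multi,
    x$shannon,
    if (is.na(x$clonality)) "NA" else sprintf("%.4f", x$clonality),
    x$cdr3_length_summary["median"], x$cdr3_length_summary["min"],
    x$cdr3_length_summary["max"], length(x$v_usage), length(x$j_usage)
  ))
  invisible(x)
}

#' Write a repertoire profile to JSON
#'
#' @param profile a `repertoire_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(profile, path) {
  stopifnot(inherits(profile, "repertoire_profile"))
  x <- unclass(profile)
  x$vj_pairing <- as.data.frame.matrix(x$vj_pairing)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
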