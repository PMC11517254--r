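#' Rank neoantigen candidates
#'
#' Orders candidates by score in the stated direction with a documented
#' deterministic tie-break (secondary score if provided, then lexicographic
#' candidate key) and flags the top-k entries.
#'
#' @param scores named numeric vector: candidate key -> score.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param top_k number of candidates to flag (default 3, the per-method
#'   nomination count).
#' @param secondary optional named numeric vector of secondary scores used
#'   to break ties (same direction).
#' @param patient_id,method optional annotations carried on the output.
#' @return data.frame of class `ranked_candidate_list` with columns
#'   `patient_id`, `method`, `candidate`, `rank`, `score`, `top_k`.
#' @export
rank_candidates <- function(scores,
                            direction = c("higher_better", "lower_better"),
                            top_k = 3L, secondary = NULL,
                            patient_id = NA_character_,
                            method = NA_character_) {
  direction <- match.arg(direction)
  if (length(scores) == 0L) stop("no candidates", call. = FALSE)
  if (any(!is.finite(scores))) stop("non-finite score", call. = FALSE)
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("scores must be a named vector of candidates", call. = FALSE)
  }
  if (top_k < 1) stop("top_k must be >= 1", call. = FALSE)
  key <- names(scores)
  s <- if (direction == "higher_better") -scores else scores
  s2 <- if (is.null(secondary)) rep(0, length(scores)) else {
    sec <- secondary[key]
    if (anyNA(sec)) stop("secondary scores missing for some candidates",
                         call. = FALSE)
    if (direction == "higher_better") -sec else sec
  }
  ord <- order(s, s2, key, method = "radix")
  out <- data.frame(
    patient_id = patient_id, method = method,
    candidate = key[ord], rank = seq_along(key),
    score = unname(scores[ord]),
    top_k = seq_along(key) <= top_k,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ranked_candidate_list", "data.frame")
  out
}

#' Rank coverage score of a validated candidate ranking
#'
#' Scores how well a ranking places experimentally positive candidates
#' ahead of negative ones:
#' \deqn{RCS = \sum_{n \in neg} \frac{rank(n)}{T\,num(n)} \cdot cov(neg)
#'       - \sum_{p \in pos} \frac{rank(p)}{T\,num(p)} \cdot cov(pos)}
#' where `T` is the total number of candidates, `num(g)` the group size and
#' `cov(g) = max rank in g / T` a group-level constant (the default
#' reading; an element-level variant with `cov(k) = rank(k)/T` is available
#' via `coverage = "element"`). Higher is better: positives concentrated at
#' small ranks push the score up.
#'
#' @param ranked a `ranked_candidate_list` or data.frame with columns
#'   `rank` and `validation_label` (`"positive"`/`"negative"`).
#' @param coverage `"group"` (default) or `"element"`.
#' @param n_total total candidate count `T`; defaults to the number of
#'   entries (override for pooled multisets where ranks are per-patient).
#' @return The rank coverage score.
#' @export
rank_coverage_score <- function(ranked, coverage = c("group", "element"),
                                n_total = nrow(ranked)) {
  coverage <- match.arg(coverage)
  if (!all(c("rank", "validation_label") %in% names(ranked))) {
    stop("`ranked` needs columns rank and validation_label", call. = FALSE)
  }
  lab <- as.character(ranked$validation_label)
  if (anyNA(lab) || !all(lab %in% c("positive", "negative"))) {
    stop("every entry needs a positive/negative validation label",
         call. = FALSE)
  }
  if (!any(lab == "positive") || !any(lab == "negative")) {
    stop("rank coverage undefined without both positive and negative entries",
         call. = FALSE)
  }
  group_term <- function(r) {
    if (coverage == "group") {
      sum(r) / (n_total * length(r)) * (max(r) / n_total)
    } else {
      sum(r / (n_total * length(r)) * (r / n_total))
    }
  }
  group_term(ranked$rank[lab == "negative"]) -
    group_term(ranked$rank[lab == "positive"])
}

#' Compare prioritization methods by rank coverage
#'
#' Given one labeled ranked list per (patient, method), computes the rank
#' coverage score per patient for each method, plus a pooled "overall"
#' score per method: the per-patient lists are concatenated with their
#' within-patient ranks retained, `T` set to the pooled entry count, and
#' the formula applied to the pooled multiset. Patients missing from any
#' method are reported and excluded from the pooled comparison.
#'
#' @param lists list of `ranked_candidate_list` objects, each carrying
#'   `patient_id`, `method` and a `validation_label` column.
#' @param coverage passed to [rank_coverage_score()].
#' @return List with `per_patient` (data.frame patient_id x method),
#'   `overall` (named numeric per method), `missing` (patient/method
#'   combinations absent).
#' @export
compare_methods <- function(lists, coverage = "group") {
  stopifnot(length(lists) >= 1L)
  df <- do.call(rbind, lapply(lists, function(l) {
    if (!all(c("patient_id", "method", "rank", "validation_label") %in% names(l))) {
      stop("each list needs patient_id, method, rank, validation_label",
           call. = FALSE)
    }
    as.data.frame(l)[, c("patient_id", "method", "rank", "validation_label")]
  }))
  methods <- unique(df$method)
  patients <- unique(df$patient_id)
  have <- table(df$patient_id, df$method) > 0
  complete <- patients[rowSums(have[patients, , drop = FALSE]) == length(methods)]
  missing <- expand.grid(patient_id = patients, method = methods,
                         stringsAsFactors = FALSE)
  missing <- missing[!mapply(function(p, m) have[p, m],
                             missing$patient_id, missing$method), ]
  per_patient <- do.call(rbind, lapply(patients, function(p) {
    row <- data.frame(patient_id = p, stringsAsFactors = FALSE)
    for (m in methods) {
      sub <- df[df$patient_id == p & df$method == m, ]
      row[[m]] <- if (nrow(sub) == 0) NA_real_ else {
        rank_coverage_score(sub, coverage = coverage)
      }
    }
    row
  }))
  overall <- vapply(methods, function(m) {
    sub <- df[df$method == m & df$patient_id %in% complete, ]
    rank_coverage_score(sub, coverage = coverage, n_total = nrow(sub))
  }, numeric(1))
  list(per_patient = per_patient, overall = overall,
       missing = missing, pooled_patients = complete)
}
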