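# Independent brute-force oracles. These deliberately avoid the package's
# code paths: direct summation loops, all-pairs scans, and stats::chisq.test.

oracle_shannon <- function(p) {
  s <- 0
  for (pi in p) s <- s - pi * log(pi)
  s
}

oracle_clonality <- function(p) 1 - oracle_shannon(p) / log(length(p))

# all-pairs concordance with 0.5 tie credit
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (a in pos) {
    for (b in neg) {
      total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

oracle_chisq <- function(tab) {
  unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic)
}

# direct evaluation of the rank coverage formula, term by term
oracle_rcs <- function(ranks, labels, n_total = length(ranks)) {
  neg <- ranks[labels == "negative"]
  pos <- ranks[labels == "positive"]
  term <- function(r) {
    acc <- 0
    for (k in r) acc <- acc + k / (n_total * length(r))
    acc * (max(r) / n_total)
  }
  term(neg) - term(pos)
}

# random frequency vector (strictly positive, sums to 1)
random_freqs <- function(n) {
  x <- stats::rexp(n) + 1e-6
  x / sum(x)
}

# small labeled feature table for classifier tests
toy_features <- function(n_pos = 40, n_neg = 200, seed = 1) {
  neoprior:::with_seed(seed, {
    data.frame(
      phla_rank = c(pmin(rexp(n_pos, 1 / 2), 100), runif(n_neg, 0, 100)),
      ptcr_rank = c(pmin(rexp(n_pos, 1 / 3), 100), runif(n_neg, 0, 100)),
      label = rep(c("immunogenic", "non_immunogenic"), c(n_pos, n_neg)),
      stringsAsFactors = FALSE
    )
  })
}

write_tsv_tmp <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

airr_df <- function(junction_aa, v_call, j_call, duplicate_count) {
  data.frame(junction_aa = junction_aa, v_call = v_call, j_call = j_call,
             duplicate_count = duplicate_count, stringsAsFactors = FALSE)
}
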