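# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals never
#' perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# 20 standard amino acids, one-letter codes
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

is_valid_aa <- function(x) {
  !is.na(x) & nzchar(x) & !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), x)
}

# Open a (possibly gzipped) text file as a connection for read.delim
open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  con <- open_text(path)
  on.exit(close(con))
  df <- utils::read.delim(con, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s file %s is missing required column(s): %s",
      what, path, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  df
}

# FNV-1a string hash folded to a 31-bit integer; drives the synthetic
# predictor adapter so scores are a pure function of the key.
hash31 <- function(x) {
  vapply(x, function(s) {
    h <- 2166136261
    for (b in utf8ToInt(s)) {
      h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
      h <- (h * 16777619) %% 2^31
    }
    as.integer(h %% 2^31)
  }, integer(1), USE.NAMES = FALSE)
}
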