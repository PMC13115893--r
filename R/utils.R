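#' @keywords internal
"_PACKAGE"

# Internal validation helpers shared across modules.

stop_oam <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    stop_oam("'%s' must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x)) {
    stop_oam("'%s' must be a single finite number", name)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_oam("'%s' = %g is outside its allowed range", name, x)
  }
  as.numeric(x)
}

#' Order chromosome names genomically
#'
#' Sorts chromosome labels in the conventional genomic order: autosomes
#' `chr1` to `chr22` numerically, then `chrX`, `chrY`, and any remaining
#' labels lexicographically after those.
#'
#' @param chrom Character vector of chromosome names (with or without a
#'   `"chr"` prefix).
#' @return An integer rank per element; ties share a rank.
#' @keywords internal
chrom_rank <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  n <- suppressWarnings(as.integer(x))
  rank_num <- ifelse(!is.na(n), n, NA_integer_)
  rank_num[toupper(x) == "X"] <- 23L
  rank_num[toupper(x) == "Y"] <- 24L
  # unknown labels sort after chrY, lexicographically
  unk <- is.na(rank_num)
  if (any(unk)) {
    lev <- sort(unique(x[unk]))
    rank_num[unk] <- 24L + match(x[unk], lev)
  }
  rank_num
}

# Seed derivation: stage seeds are a deterministic function of the global
# seed, kept well below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(offset)) %% 2147483629)
}
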