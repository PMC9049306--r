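# Internal helpers shared across modules.

`%||%` <- rlang::`%||%`

#' Derive a reproducible substream seed
#'
#' One master seed feeds every stochastic stage through named substreams so
#' stages can be re-run independently yet reproducibly. The derived seed is
#' always a non-negative integer below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param key Character stream name (e.g. `"generate"`, `"calibrate"`).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  h <- rlang::hash(list(as.double(seed), key))
  as.integer(strtoi(substr(h, 1L, 7L), base = 16L) %% 2147483646L + 1L)
}

# Per-individual seed: affine in the individual index so that growing a cohort
# leaves earlier individuals' streams untouched.
person_seed <- function(seed, i) {
  as.integer((as.double(seed) + 1000003 * as.double(i)) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

clamp01 <- function(x) clamp(x, 0, 1)

logit <- function(p) stats::qlogis(p)

inv_logit <- function(x) stats::plogis(x)

# ICD codes are compared after stripping dots and upper-casing.
normalize_icd <- function(code) toupper(gsub(".", "", code, fixed = TRUE))

has_prefix <- function(code, prefixes) {
  if (length(prefixes) == 0L) return(rep(FALSE, length(code)))
  pat <- paste0("^(", paste(sub("", "", prefixes), collapse = "|"), ")")
  grepl(pat, code)
}

abort_sim <- function(msg, class) {
  rlang::abort(msg, class = paste0("sicklesim_", class))
}

# month index helpers (months since 0000-01); enrollment is month-granular
ym_index <- function(date) {
  d <- as.POSIXlt(date)
  (d$year + 1900L) * 12L + d$mon
}

ym_to_date <- function(idx) {
  as.Date(sprintf("%04d-%02d-01", idx %/% 12L, idx %% 12L + 1L))
}
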