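# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multiplicative log-normal noise with unit mean and given CV
#'
#' Draws n log-normal multipliers with E[x] = 1 and coefficient of variation
#' `cv`. With `cv = 0` returns exactly 1 (no RNG consumed), so noise-free
#' simulations satisfy their defining equations bit-exactly.
#'
#' @param n number of draws
#' @param cv coefficient of variation (>= 0)
#' @return numeric vector of length n
#' @keywords internal
rlnorm_cv <- function(n, cv) {
  stopifnot(is.numeric(cv), length(cv) == 1L, cv >= 0)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Deterministic per-generator substream seed derived from one master seed.
# Keeps the result a positive 32-bit integer.
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(master) * 977 + h * 10007) %% 2147483629L + 1)
}

# Columns of a feature table that are metadata rather than run abundances.
FEATURE_META_COLS <- c("feature_id", "peptide_sequence", "site_id",
                       "n_phospho", "site_localized", "charge", "mz", "rt")

#' Run identifiers of a feature table
#'
#' @param table a feature table (see [simulate_feature_table()])
#' @return character vector of run ids (the abundance columns)
#' @export
feature_runs <- function(table) {
  setdiff(colnames(table), FEATURE_META_COLS)
}

# Abundance matrix (features x runs) of a feature table.
abundance_matrix <- function(table) {
  runs <- feature_runs(table)
  m <- as.matrix(table[, runs, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$feature_id
  m
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Standard error of the mean; NA for n < 2.
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
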