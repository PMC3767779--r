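# Independent oracles used to check the package's computations by a
# different route than the implementation takes.

# Textbook pooled-variance two-sample t-test: statistic from first
# principles, p-value from the t CDF.
oracle_student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}

# Brute-force median-ratio normalization oracle: grid search over candidate
# log factors, picking the one that minimizes the median absolute log ratio
# after scaling. Independent of the recursive-median implementation.
oracle_norm_factor <- function(ab_ref, ab_run, grid_n = 50001) {
  shared <- !is.na(ab_ref) & !is.na(ab_run)
  d <- log(ab_ref[shared] / ab_run[shared])
  grid <- seq(min(d), max(d), length.out = grid_n)
  obj <- vapply(grid, function(m) median(abs(d - m)), numeric(1))
  exp(grid[which.min(obj)])
}

# Exact binomial enumeration of the tetramer capture model: expected input
# and IP signals per channel, and the apparent occupancy they imply.
oracle_apparent_oc <- function(p, n_sub, capture_eff = 1) {
  k <- 0:n_sub
  w <- dbinom(k, n_sub, p)
  pcap <- 1 - (1 - capture_eff)^k
  p_input <- sum(w * k)           # expected phospho subunits per channel
  t_input <- n_sub
  p_ip <- sum(w * pcap * k)       # over captured channels
  t_ip <- sum(w * pcap * n_sub)
  if (p_input == 0) return(0)
  (p_input / t_input) * (t_ip / p_ip) * 100
}

# Closed-form r-squared: squared Pearson correlation.
oracle_r2 <- function(x, y) cor(x, y)^2

# Minimal feature table with explicit per-run abundances (one row per call).
feature_row <- function(feature_id, site_id, abundances, n_phospho = 1L,
                        site_localized = TRUE, charge = 2L) {
  cbind(data.frame(feature_id = feature_id, peptide_sequence = feature_id,
                   site_id = site_id, n_phospho = n_phospho,
                   site_localized = site_localized, charge = charge,
                   mz = 500, rt = 10, stringsAsFactors = FALSE),
        as.data.frame(as.list(abundances)))
}

# Design with n runs per condition, single enzyme/genotype.
simple_design <- function(n_per_cond = 9, conditions = c("light", "dark")) {
  runs <- unlist(lapply(conditions, function(cond)
    sprintf("%s%02d", cond, seq_len(n_per_cond))))
  data.frame(run_id = runs,
             genotype = "wt",
             condition = rep(conditions, each = n_per_cond),
             bio_replicate = rep(seq_len(n_per_cond), length(conditions)),
             tech_replicate = 1L, enzyme = "trypsin", scale_factor = 1,
             stringsAsFactors = FALSE)
}
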