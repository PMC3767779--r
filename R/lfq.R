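# Label-free relative quantification of phosphopeptides: charge filtering,
# run normalization, eligibility/variant selection, per-condition relative
# abundance with unpaired t-tests, and light-dependence classification.

#' Filter features by charge state
#'
#' Before quantification the feature set is reduced to signals with charge
#' states +2 through +5; singly charged ions and charges above +5 are
#' discarded. Row order is preserved.
#'
#' @param table feature table
#' @param charges charge states to keep
#' @return filtered feature table
#' @export
filter_charge <- function(table, charges = 2:5) {
  if (!"charge" %in% colnames(table)) stop_input("feature table lacks a charge column")
  out <- table[table$charge %in% charges, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize run abundances by a recursive median of log ratios
#'
#' For each run r and the reference run, the log abundance ratios
#' d_i = log(ab_ref,i / ab_r,i) are computed over the features observed in
#' both. The normalization factor is a robust location estimate of this
#' distribution, obtained by a recursive median: starting from the median m
#' of all d_i, the median is recomputed over the subset
#' \{i : |d_i - m| <= 1.48 * MAD\} until it changes by less than `tol` or
#' `max_iter` is reached. The factor is exp(m) and normalized abundances are
#' raw * factor; the reference run is unchanged (factor 1). This rests on the
#' assumption that most features show no change in abundance between runs.
#'
#' @param table feature table (typically after [filter_charge()])
#' @param reference_run run id to normalize against; default the first run id
#'   in lexicographic order
#' @param method `"recursive_median"` (default) or `"median"` (plain median of
#'   log ratios, no trimming)
#' @param max_iter maximum recursion depth
#' @param tol convergence tolerance on the median of log ratios
#' @return object of class `lfq_norm`: list with `factors` (named per-run),
#'   `reference_run`, `normalized` (feature table), `method`, `iterations`
#' @export
normalize_runs <- function(table, reference_run = NULL,
                           method = c("recursive_median", "median"),
                           max_iter = 50L, tol = 1e-10) {
  method <- match.arg(method)
  runs <- feature_runs(table)
  if (length(runs) == 0L) stop_input("feature table has no run columns")
  if (is.null(reference_run)) reference_run <- sort(runs)[1]
  if (!reference_run %in% runs)
    stop_input("reference run '%s' not in table", reference_run)
  ab <- abundance_matrix(table)
  ref <- ab[, reference_run]

  factors <- stats::setNames(rep(NA_real_, length(runs)), runs)
  iters <- stats::setNames(rep(0L, length(runs)), runs)
  factors[reference_run] <- 1
  for (r in setdiff(runs, reference_run)) {
    x <- ab[, r]
    if (all(is.na(x)))
      stop_input("run '%s' has no observed abundances", r)
    shared <- !is.na(ref) & !is.na(x) & ref > 0 & x > 0
    if (!any(shared))
      stop_input("run '%s' shares no observed features with reference '%s'",
                 r, reference_run)
    d <- log(ref[shared] / x[shared])
    m <- stats::median(d)
    it <- 0L
    if (method == "recursive_median") {
      repeat {
        it <- it + 1L
        mad <- stats::mad(d, center = m)
        keep <- abs(d - m) <= 1.48 * mad
        if (!any(keep)) break
        m_new <- stats::median(d[keep])
        if (abs(m_new - m) < tol || it >= max_iter) { m <- m_new; break }
        m <- m_new
        d <- d[keep]
      }
    }
    factors[r] <- exp(m)
    iters[r] <- it
  }
  normalized <- table
  for (r in runs) normalized[[r]] <- table[[r]] * factors[r]
  structure(list(factors = factors, reference_run = reference_run,
                 normalized = normalized, method = method,
                 iterations = iters),
            class = "lfq_norm")
}

#' @export
print.lfq_norm <- function(x, ...) {
  cat(sprintf("Run normalization (%s), reference '%s'\n", x$method,
              x$reference_run))
  print(round(x$factors, 4))
  invisible(x)
}

# Eligibility of a single feature row: singly phosphorylated, unambiguously
# localized, and observed in every run of at least one condition.
feature_eligible <- function(row, ab, design) {
  if (row$n_phospho != 1L || !isTRUE(row$site_localized)) return(FALSE)
  for (cond in unique(design$condition)) {
    runs <- design$run_id[design$condition == cond]
    if (length(runs) && all(!is.na(ab[runs]))) return(TRUE)
  }
  FALSE
}

#' Select the quantifiable peptide variant for each phosphosite
#'
#' A site is quantifiable if at least one of its peptide variants is singly
#' phosphorylated, has an unambiguous site assignment, and is present
#' (non-missing) in all runs of at least one light condition. Among eligible
#' variants the one with the highest mean normalized abundance over its
#' non-missing runs is chosen; ties break to the lexicographically smallest
#' feature_id.
#'
#' @param table normalized feature table
#' @param design run design restricted to the runs being quantified
#' @return data.frame with columns site_id, feature_id (NA when not
#'   quantifiable), quantifiable
#' @export
select_quantifiable <- function(table, design) {
  design <- validate_run_design(design)
  runs <- intersect(feature_runs(table), design$run_id)
  if (length(runs) == 0L) stop_input("no design runs present in table")
  design <- design[design$run_id %in% runs, , drop = FALSE]
  sites <- unique(table$site_id[table$site_id != "background"])
  out <- data.frame(site_id = sites, feature_id = NA_character_,
                    quantifiable = FALSE, stringsAsFactors = FALSE)
  ab <- abundance_matrix(table)[, runs, drop = FALSE]
  for (i in seq_along(sites)) {
    rows <- which(table$site_id == sites[i])
    elig <- rows[vapply(rows, function(j)
      feature_eligible(table[j, ], ab[j, ], design), logical(1))]
    if (length(elig) == 0L) next
    means <- vapply(elig, function(j) mean(ab[j, ], na.rm = TRUE), numeric(1))
    best <- elig[means == max(means)]
    chosen <- best[order(table$feature_id[best])][1]
    out$feature_id[i] <- table$feature_id[chosen]
    out$quantifiable[i] <- TRUE
  }
  out
}

star_code <- function(p, thresholds = c(0.05, 0.01, 0.001)) {
  ifelse(is.na(p), "n.d.",
         ifelse(p < thresholds[3], "***",
                ifelse(p < thresholds[2], "**",
                       ifelse(p < thresholds[1], "*", "n.s."))))
}

# Quantify one chosen feature row: per-condition means, relative abundance
# with the higher condition set to 100%, unpaired t-test, class label.
quantify_one <- function(ab, design, test = c("student", "welch"),
                         alpha = 0.05) {
  test <- match.arg(test)
  conds <- unique(design$condition)
  stopifnot(length(conds) == 2L)
  vals <- lapply(conds, function(cond) {
    v <- ab[design$run_id[design$condition == cond]]
    v[!is.na(v)]
  })
  names(vals) <- conds
  n <- vapply(vals, length, integer(1))
  means <- vapply(vals, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1))
  if (any(n < 2L)) {
    return(list(n = n, means = means,
                rel = stats::setNames(rep(NA_real_, 2), conds),
                p = NA_real_, stars = "n.d.", class = "not_quantifiable"))
  }
  rel <- 100 * means / max(means)
  p <- if (stats::sd(vals[[1]]) == 0 && stats::sd(vals[[2]]) == 0) {
    # degenerate zero-variance samples: limit of the t statistic
    if (isTRUE(all.equal(means[[1]], means[[2]]))) 1 else 0
  } else {
    stats::t.test(vals[[1]], vals[[2]],
                  var.equal = (test == "student"))$p.value
  }
  hi <- conds[which.max(means)]
  class <- if (p < alpha) paste0(hi, "_elevated") else "not_light_dependent"
  list(n = n, means = means, rel = rel, p = p, stars = star_code(p),
       class = class)
}

#' Quantify relative phosphopeptide abundance per site
#'
#' For each quantifiable site, the mean abundance of its chosen peptide
#' variant is computed over the runs of each light condition (missing values
#' excluded in the condition that is not fully observed), the higher
#' condition mean is set to 100%, and a two-sided unpaired t-test
#' (equal-variance Student by default, Welch optional) compares the two
#' conditions. Sites are classified as light- or dark-elevated at p < alpha,
#' otherwise not light-dependent; sites without an eligible variant, or with
#' fewer than two observations in a condition, are not quantifiable.
#'
#' When the design contains several digestion enzymes, quantification is done
#' per enzyme (each enzyme's runs form their own panel) unless
#' `split_by_enzyme = FALSE`.
#'
#' @param norm an `lfq_norm` object from [normalize_runs()] (or a normalized
#'   feature table)
#' @param design run design
#' @param test `"student"` (pooled variance, default) or `"welch"`
#' @param alpha significance level for the light-dependence call
#' @param split_by_enzyme quantify each digestion enzyme separately
#' @return data.frame of class `site_quant`: enzyme, site_id, peptide,
#'   n_<condition> counts, mean and relative (%) abundance per condition,
#'   p_value, stars, class
#' @export
quantify_sites <- function(norm, design, test = c("student", "welch"),
                           alpha = 0.05, split_by_enzyme = TRUE) {
  test <- match.arg(test)
  table <- if (inherits(norm, "lfq_norm")) norm$normalized else norm
  design <- validate_run_design(design)
  design <- design[design$run_id %in% feature_runs(table), , drop = FALSE]
  if (nrow(design) == 0L) stop_input("no design runs present in table")
  enzymes <- if (split_by_enzyme) unique(design$enzyme) else "all"
  conds <- unique(design$condition)
  if (length(conds) != 2L)
    stop_input("quantification compares exactly 2 conditions, got %d",
               length(conds))

  res <- list()
  for (enz in enzymes) {
    dsub <- if (identical(enz, "all")) design else
      design[design$enzyme == enz, , drop = FALSE]
    sel <- select_quantifiable(table, dsub)
    ab <- abundance_matrix(table)
    for (i in seq_len(nrow(sel))) {
      if (sel$quantifiable[i]) {
        j <- match(sel$feature_id[i], table$feature_id)
        q <- quantify_one(ab[j, ], dsub, test = test, alpha = alpha)
      } else {
        q <- list(n = stats::setNames(c(0L, 0L), conds),
                  means = stats::setNames(rep(NA_real_, 2), conds),
                  rel = stats::setNames(rep(NA_real_, 2), conds),
                  p = NA_real_, stars = "n.d.", class = "not_quantifiable")
      }
      row <- data.frame(enzyme = enz, site_id = sel$site_id[i],
                        peptide = sel$feature_id[i], stringsAsFactors = FALSE)
      for (cond in conds) {
        row[[paste0("n_", cond)]] <- q$n[[cond]]
        row[[paste0("mean_", cond)]] <- q$means[[cond]]
        row[[paste0("rel_", cond, "_pct")]] <- q$rel[[cond]]
      }
      row$p_value <- q$p
      row$stars <- q$stars
      row$class <- q$class
      res[[length(res) + 1L]] <- row
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("site_quant", "data.frame")
  out
}

#' @export
print.site_quant <- function(x, digits = 3, ...) {
  cat(sprintf("Relative phosphopeptide quantification: %d site(s)\n", nrow(x)))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Tabulate site classifications
#'
#' Counts sites per light-dependence class (light_elevated, dark_elevated,
#' not_light_dependent, not_quantifiable), the summary behind a
#' phosphosite-map figure.
#'
#' @param results `site_quant` data.frame from [quantify_sites()]
#' @return named integer vector of class counts
#' @export
classify_sites <- function(results) {
  levels <- c("light_elevated", "dark_elevated", "not_light_dependent",
              "not_quantifiable")
  if (nrow(results) == 0L)
    return(stats::setNames(integer(length(levels)), levels))
  table(factor(results$class, levels = levels))
}
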