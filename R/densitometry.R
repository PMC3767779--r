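# Quantitative Western-blot computations: phospho/total normalization,
# dilution-series linearity QC, relative phosphorylation vs a same-membrane
# control, and time-course scaling.

#' Phospho/total ratio per lane
#'
#' The phosphospecific-antibody signal of each lane is divided by the generic
#' (total) antibody signal of the same sample, removing loading differences.
#'
#' @param panel blot panel data.frame with columns phospho_signal,
#'   total_signal and (for error messages) lane_id
#' @return numeric vector of ratios, one per lane
#' @export
normalize_lane <- function(panel) {
  bad <- which(!(panel$total_signal > 0))
  if (length(bad)) {
    ids <- if (!is.null(panel$lane_id)) panel$lane_id[bad] else bad
    stop_input("non-positive total signal in lane(s): %s",
               paste(ids, collapse = ", "))
  }
  if (any(panel$phospho_signal < 0)) stop_input("negative phospho signal")
  panel$phospho_signal / panel$total_signal
}

#' Dilution-series linearity check
#'
#' Ordinary least squares of each antibody signal on the amount of target
#' protein loaded (head equivalents). A blot is usable quantitatively when
#' the signal is linear in the loaded amount; the check reports slope,
#' intercept and r-squared per antibody and flags passes at a configurable
#' r-squared threshold.
#'
#' @param panel blot panel covering >= 3 distinct loaded amounts
#'   (`heads_loaded`), e.g. from [dilution_series_lanes()]
#' @param signals which signal columns to regress
#' @param threshold minimum r-squared to pass
#' @param force_zero fit through the origin instead of with an intercept
#' @return data.frame of class `linearity_report`: antibody, slope,
#'   intercept, r_squared, pass
#' @export
linearity_check <- function(panel, signals = c("total_signal", "phospho_signal"),
                            threshold = 0.95, force_zero = FALSE) {
  amounts <- panel$heads_loaded
  if (length(unique(amounts)) < 3L)
    stop_input("linearity check needs >= 3 distinct loaded amounts")
  rows <- lapply(signals, function(sig) {
    y <- panel[[sig]]
    if (is.null(y)) stop_input("panel lacks signal column '%s'", sig)
    fit <- if (force_zero) stats::lm(y ~ amounts + 0) else stats::lm(y ~ amounts)
    co <- stats::coef(fit)
    # r^2 computed directly; a zero-variance signal carries no linearity
    # information and is scored 0
    sst <- if (force_zero) sum(y^2) else sum((y - mean(y))^2)
    r2 <- if (sst == 0) 0 else 1 - sum(stats::residuals(fit)^2) / sst
    data.frame(antibody = sub("_signal$", "", sig),
               slope = unname(co[["amounts"]]),
               intercept = if (force_zero) 0 else unname(co[["(Intercept)"]]),
               r_squared = r2, pass = r2 >= threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("linearity_report", "data.frame")
  out
}

#' @export
print.linearity_report <- function(x, ...) {
  cat("Dilution-series linearity:\n")
  y <- as.data.frame(x)
  y$r_squared <- round(y$r_squared, 4)
  print(y, row.names = FALSE)
  invisible(x)
}

parse_control <- function(control) {
  if (length(control) == 1L && grepl(":", control))
    control <- strsplit(control, ":", fixed = TRUE)[[1]]
  if (length(control) != 2L)
    stop_input("control must be c(genotype, condition) or \"genotype:condition\"")
  control
}

#' Relative phosphorylation versus a same-membrane control
#'
#' Each lane's phospho/total ratio is expressed as a percentage of the
#' control lane's ratio on the same membrane (control set to 100%), then
#' averaged over replicate membranes. Signals from different membranes are
#' never compared directly, because antibody and detection gains differ per
#' membrane.
#'
#' @param panel blot panel; columns genotype, condition, membrane_id,
#'   phospho_signal, total_signal (lane_id, replicate optional)
#' @param control the reference genotype and condition, e.g. `"wt:light"`
#' @return list of class `relphos`: `per_lane` (each lane's percentage) and
#'   `summary` (mean, SEM and n per genotype x condition over membranes)
#' @export
relative_phosphorylation <- function(panel, control = "wt:light") {
  ctl <- parse_control(control)
  panel <- as.data.frame(panel)
  panel$.ratio <- normalize_lane(panel)
  is_ctl <- panel$genotype == ctl[1] & panel$condition == ctl[2]
  pct <- rep(NA_real_, nrow(panel))
  for (m in unique(panel$membrane_id)) {
    on_m <- panel$membrane_id == m
    ctl_m <- on_m & is_ctl
    if (!any(ctl_m))
      stop_input("membrane '%s' has no control lane (%s, %s)", m, ctl[1], ctl[2])
    pct[on_m] <- 100 * panel$.ratio[on_m] / mean(panel$.ratio[ctl_m])
  }
  per_lane <- cbind(panel[setdiff(colnames(panel), ".ratio")],
                    relative_phospho_pct = pct)
  agg <- stats::aggregate(pct,
                          by = list(genotype = panel$genotype,
                                    condition = panel$condition),
                          FUN = function(v) c(mean = mean(v), sem = sem(v),
                                              n = length(v)))
  summary <- data.frame(agg[c("genotype", "condition")],
                        mean_pct = agg$x[, "mean"], sem_pct = agg$x[, "sem"],
                        n = as.integer(agg$x[, "n"]), stringsAsFactors = FALSE)
  structure(list(per_lane = per_lane, summary = summary, control = ctl),
            class = "relphos")
}

#' @export
print.relphos <- function(x, digits = 3, ...) {
  cat(sprintf("Relative phosphorylation (control %s:%s = 100%%):\n",
              x$control[1], x$control[2]))
  y <- x$summary
  y$mean_pct <- signif(y$mean_pct, digits)
  y$sem_pct <- signif(y$sem_pct, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Time-course scaling of phosphorylation levels
#'
#' Phospho/total ratios along a light/dark switching time course are scaled
#' so the anchor timepoint (e.g. 4 h of light adaptation) equals 100%.
#' Scaling is applied per replicate (each replicate anchored to its own
#' anchor lane) and the per-timepoint mean and SEM are reported; a pooled
#' variant, anchoring the timepoint means directly, is reported alongside.
#'
#' @param panel blot panel with columns timepoint (minutes), replicate,
#'   phospho_signal, total_signal
#' @param anchor the timepoint whose level defines 100%
#' @return data.frame: timepoint, mean_pct, sem_pct, n, pooled_pct
#' @export
timecourse_normalize <- function(panel, anchor) {
  if (!any(panel$timepoint == anchor, na.rm = TRUE))
    stop_input("anchor timepoint %s not present in panel", format(anchor))
  panel <- as.data.frame(panel)
  panel$.ratio <- normalize_lane(panel)
  pct <- rep(NA_real_, nrow(panel))
  for (rep_i in unique(panel$replicate)) {
    on_r <- panel$replicate == rep_i
    a <- on_r & panel$timepoint == anchor
    if (!any(a))
      stop_input("replicate %s lacks the anchor timepoint %s", rep_i,
                 format(anchor))
    pct[on_r] <- 100 * panel$.ratio[on_r] / mean(panel$.ratio[a])
  }
  tp <- sort(unique(panel$timepoint))
  pooled_mean <- vapply(tp, function(t)
    mean(panel$.ratio[panel$timepoint == t]), numeric(1))
  anchor_mean <- pooled_mean[match(anchor, tp)]
  data.frame(
    timepoint = tp,
    mean_pct = vapply(tp, function(t) mean(pct[panel$timepoint == t]), numeric(1)),
    sem_pct = vapply(tp, function(t) sem(pct[panel$timepoint == t]), numeric(1)),
    n = vapply(tp, function(t) sum(panel$timepoint == t), integer(1)),
    pooled_pct = 100 * pooled_mean / anchor_mean)
}
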