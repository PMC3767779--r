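# Candidate-screen hit calling: fold-change thresholds on the initial
# screen, rescreen confirmation over three experiments, and per-site
# summaries.

#' Mutant records from a screen blot panel
#'
#' Converts lane-level screen blots into per-mutant records: on each
#' membrane the mutant lane's phospho/total ratio is expressed as a
#' percentage of the wild-type control lane on the same membrane (same
#' antibody and light condition). Replicate 1 is the initial screen; all
#' replicates form the rescreen.
#'
#' @param panel lane-level screen panel, e.g. `simulate_screen_panel()$panel`
#' @param wt_genotype genotype label of the control lanes
#' @return data.frame of mutant records: mutant_id, gene, site_id, condition,
#'   stage (initial/rescreen), replicate, relative_phospho_pct
#' @export
screen_records <- function(panel, wt_genotype = "wt") {
  panel <- as.data.frame(panel)
  ratio <- normalize_lane(panel)
  is_wt <- panel$genotype == wt_genotype
  wt_ratio <- stats::setNames(ratio[is_wt], panel$membrane_id[is_wt])
  if (anyDuplicated(panel$membrane_id[is_wt]))
    stop_input("more than one control lane on a membrane")
  mut <- panel[!is_wt, , drop = FALSE]
  ctl <- wt_ratio[mut$membrane_id]
  if (anyNA(ctl))
    stop_input("membrane(s) without a %s control lane: %s", wt_genotype,
               paste(unique(mut$membrane_id[is.na(ctl)]), collapse = ", "))
  rec <- data.frame(mutant_id = mut$mutant_id, gene = mut$gene,
                    site_id = mut$site_id, condition = mut$condition,
                    replicate = mut$replicate,
                    relative_phospho_pct = 100 * ratio[!is_wt] / ctl,
                    stringsAsFactors = FALSE)
  initial <- rec[rec$replicate == 1L, , drop = FALSE]
  initial$stage <- "initial"
  rec$stage <- "rescreen"
  out <- rbind(initial, rec)
  rownames(out) <- NULL
  out[c("mutant_id", "gene", "site_id", "condition", "stage", "replicate",
        "relative_phospho_pct")]
}

#' Call initial screen hits
#'
#' A mutant is an initial hit when, for any phosphosite and light condition,
#' its phosphorylation relative to the wild-type control is up-regulated at
#' least `up`-fold (inclusive) or down-regulated below `down`-fold
#' (exclusive). Fold change is `relative_phospho_pct / wt_reference`.
#'
#' @param records mutant records (stage "initial" rows are used)
#' @param wt_reference the percentage corresponding to wild type (100)
#' @param up up-regulation threshold (hit when fold >= up)
#' @param down down-regulation threshold (hit when fold < down)
#' @return object of class `screen_hits`: list with `calls` (per
#'   mutant x site x condition fold and hit flag) and `hits` (mutant ids)
#' @export
call_initial_hits <- function(records, wt_reference = 100, up = 2, down = 0.5) {
  rec <- records[records$stage == "initial", , drop = FALSE]
  if (nrow(rec) == 0L) stop_input("no initial-stage records")
  if (any(rec$relative_phospho_pct < 0))
    stop_input("relative phosphorylation must be non-negative")
  calls <- data.frame(mutant_id = rec$mutant_id, site_id = rec$site_id,
                      condition = rec$condition,
                      fold = rec$relative_phospho_pct / wt_reference,
                      stringsAsFactors = FALSE)
  calls$hit <- calls$fold >= up | calls$fold < down
  calls$direction <- ifelse(calls$fold >= up, "up",
                            ifelse(calls$fold < down, "down", "none"))
  hits <- sort(unique(calls$mutant_id[calls$hit]))
  structure(list(calls = calls, hits = hits,
                 thresholds = c(up = up, down = down)),
            class = "screen_hits")
}

#' @export
print.screen_hits <- function(x, ...) {
  cat(sprintf("Initial screen: %d hit(s) of %d mutant(s) (fold >= %g or < %g)\n",
              length(x$hits), length(unique(x$calls$mutant_id)),
              x$thresholds["up"], x$thresholds["down"]))
  if (length(x$hits)) cat(" ", paste(x$hits, collapse = ", "), "\n")
  invisible(x)
}

# One-sample two-sided t-test of replicate percentages against the wild-type
# reference. Blot noise is multiplicative, so the test runs on log
# percentages (vs log reference); degenerate zero-variance samples are
# resolved by the limit of the t statistic (p = 1 at the reference, p = 0
# away from it).
pct_ttest <- function(x, mu, log_scale = TRUE) {
  if (length(x) < 2L) return(NA_real_)
  if (log_scale && all(x > 0)) { x <- log(x); mu <- log(mu) }
  if (stats::sd(x) == 0) return(if (isTRUE(all.equal(mean(x), mu))) 1 else 0)
  stats::t.test(x, mu = mu)$p.value
}

#' Confirm initial hits from rescreen replicates
#'
#' Each initial hit is retested so that `n_required` experiments are
#' available per phosphosite and light condition. A hit is confirmed for a
#' site when, in some condition, the fold-change criterion holds on the mean
#' of the replicates and (in `"ttest"` mode) a one-sample two-sided t-test of
#' the replicate percentages against the wild-type reference gives
#' p < `alpha`. `"threshold"` mode applies the fold criterion on the mean
#' alone. Mutants with fewer than `n_required` rescreen replicates are
#' flagged unconfirmable rather than dropped.
#'
#' @param records mutant records (stage "rescreen" rows are used)
#' @param hits `screen_hits` from [call_initial_hits()] (or mutant ids)
#' @param n_required rescreen experiments required per mutant
#' @param mode `"ttest"` (default) or `"threshold"`
#' @param alpha significance level of the confirmation test
#' @param wt_reference wild-type percentage (100)
#' @param up,down fold thresholds as in [call_initial_hits()]
#' @param log_scale run the confirmation t-test on log percentages (blot
#'   noise is multiplicative); set FALSE for the raw-scale test
#' @return data.frame of class `screen_result`, one row per initial-hit
#'   mutant x site x condition: mean_pct, sem_pct, n, fold, p_value,
#'   confirmed (per-condition), direction, unconfirmable
#' @export
confirm_hits <- function(records, hits, n_required = 3,
                         mode = c("ttest", "threshold"), alpha = 0.05,
                         wt_reference = 100, up = 2, down = 0.5,
                         log_scale = TRUE) {
  mode <- match.arg(mode)
  if (inherits(hits, "screen_hits")) hits <- hits$hits
  rec <- records[records$stage == "rescreen" & records$mutant_id %in% hits, ,
                 drop = FALSE]
  rows <- list()
  for (m in hits) {
    rm <- rec[rec$mutant_id == m, , drop = FALSE]
    for (s in unique(rm$site_id)) for (cond in unique(rm$condition)) {
      x <- rm$relative_phospho_pct[rm$site_id == s & rm$condition == cond]
      n <- length(x)
      unconf <- n < n_required
      mean_pct <- if (n) mean(x) else NA_real_
      fold <- mean_pct / wt_reference
      p <- pct_ttest(x, wt_reference, log_scale = log_scale)
      crosses <- !is.na(fold) && (fold >= up || fold < down)
      confirmed <- !unconf && crosses &&
        (mode == "threshold" || (!is.na(p) && p < alpha))
      rows[[length(rows) + 1L]] <- data.frame(
        mutant_id = m, site_id = s, condition = cond, n = n,
        mean_pct = mean_pct, sem_pct = sem(x), fold = fold, p_value = p,
        confirmed = confirmed,
        direction = if (!is.na(fold) && fold >= up) "up"
                    else if (!is.na(fold) && fold < down) "down" else "none",
        unconfirmable = unconf, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mutant_id = character(), site_id = character(),
               condition = character(), n = integer(), mean_pct = numeric(),
               sem_pct = numeric(), fold = numeric(), p_value = numeric(),
               confirmed = logical(), direction = character(),
               unconfirmable = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

#' @export
print.screen_result <- function(x, digits = 3, ...) {
  conf <- x[x$confirmed, , drop = FALSE]
  cat(sprintf("Rescreen: %d confirmed effect(s) across %d mutant x site pair(s)\n",
              nrow(conf), nrow(unique(conf[c("mutant_id", "site_id")]))))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Summarize confirmed screen hits per site and direction
#'
#' Counts mutants with a confirmed effect for each phosphosite (a mutant
#' altered at both sites counts once per site) and tabulates directions.
#'
#' @param result `screen_result` from [confirm_hits()]
#' @return data.frame: site_id, direction, n_confirmed
#' @export
summarize_screen <- function(result) {
  conf <- result[result$confirmed, , drop = FALSE]
  if (nrow(conf) == 0L)
    return(data.frame(site_id = character(), direction = character(),
                      n_confirmed = integer(), stringsAsFactors = FALSE))
  # one row per mutant x site; direction from the strongest confirmed condition
  key <- paste(conf$mutant_id, conf$site_id)
  pick <- vapply(split(seq_len(nrow(conf)), key), function(i)
    i[which.max(abs(log(conf$fold[i])))], integer(1))
  u <- conf[pick, , drop = FALSE]
  agg <- stats::aggregate(list(n_confirmed = u$mutant_id),
                          by = list(site_id = u$site_id,
                                    direction = u$direction),
                          FUN = length)
  agg[order(agg$site_id, agg$direction), , drop = FALSE]
}
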