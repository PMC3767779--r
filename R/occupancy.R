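# Phosphate occupancy from immunoprecipitation signal quadruples, and a
# binomial tetramer model of the co-precipitation bias that inflates the
# naive estimate.

# The occupancy formula on raw signals:
# OC = (pTRP_input / TRP_input) * (TRP_IP / pTRP_IP) * 100.
# The input ratio measures phospho epitopes per subunit up to antibody gains;
# the IP ratio cancels those gains, because the immunoprecipitate is
# (assumed) pure phospho-TRP, for which both antibodies see the same protein.
oc_formula <- function(p_input, t_input, p_ip, t_ip) {
  if (any(t_input <= 0)) stop_input("TRP input signal must be positive")
  oc <- numeric(length(p_input))
  zero <- p_input == 0
  oc[zero] <- 0
  if (any(!zero)) {
    if (any(p_ip[!zero] <= 0))
      stop_input("pTRP IP signal must be positive when phospho input is non-zero")
    oc[!zero] <- (p_input[!zero] / t_input[!zero]) *
      (t_ip[!zero] / p_ip[!zero]) * 100
  }
  oc
}

#' Phosphate occupancy from IP signal quadruples
#'
#' Computes the apparent phosphate occupancy
#' `OC = (pTRP_input / TRP_input) x (TRP_IP / pTRP_IP) x 100%`
#' from phosphospecific- and generic-antibody signals measured on the input
#' extract and on the immunoprecipitate. The IP ratio corrects for the
#' different reactivities of the two antibodies, under the assumption that
#' every molecule in the immunoprecipitate is phosphorylated. Because the
#' channel is a tetramer, co-precipitated unphosphorylated subunits violate
#' that assumption and bias OC upward; see [apparent_occupancy()] and
#' [invert_occupancy()] for the model-based correction.
#'
#' @param exp an `ip_experiment` from [simulate_ip()], or a data.frame with
#'   columns p_input, t_input, p_ip, t_ip and optionally site_id, replicate
#' @return data.frame of class `occupancy_result` with per-replicate `oc_pct`
#'   and an attached per-site summary (mean, SEM, n) in
#'   `attr(, "summary")`
#' @export
occupancy <- function(exp) {
  if (inherits(exp, "ip_experiment"))
    exp <- data.frame(site_id = exp$site_id, replicate = exp$replicate,
                      p_input = exp$p_input, t_input = exp$t_input,
                      p_ip = exp$p_ip, t_ip = exp$t_ip,
                      stringsAsFactors = FALSE)
  need <- c("p_input", "t_input", "p_ip", "t_ip")
  miss <- setdiff(need, colnames(exp))
  if (length(miss)) stop_input("IP table lacks columns: %s",
                               paste(miss, collapse = ", "))
  if (is.null(exp$site_id)) exp$site_id <- "site"
  if (is.null(exp$replicate)) exp$replicate <- seq_len(nrow(exp))
  exp$oc_pct <- oc_formula(exp$p_input, exp$t_input, exp$p_ip, exp$t_ip)
  agg <- stats::aggregate(exp$oc_pct, by = list(site_id = exp$site_id),
                          FUN = function(v) c(mean = mean(v), sem = sem(v),
                                              n = length(v)))
  summary <- data.frame(site_id = agg$site_id, mean_oc_pct = agg$x[, "mean"],
                        sem_oc_pct = agg$x[, "sem"],
                        n = as.integer(agg$x[, "n"]), stringsAsFactors = FALSE)
  structure(exp, summary = summary, class = c("occupancy_result", "data.frame"))
}

#' @export
print.occupancy_result <- function(x, digits = 3, ...) {
  cat("Phosphate occupancy (apparent, per-subunit bias uncorrected):\n")
  s <- attr(x, "summary")
  s$mean_oc_pct <- signif(s$mean_oc_pct, digits)
  s$sem_oc_pct <- signif(s$sem_oc_pct, digits)
  print(s, row.names = FALSE)
  invisible(x)
}

capture_prob <- function(k, capture_eff) 1 - (1 - capture_eff)^k

#' Apparent occupancy under the binomial multimer capture model
#'
#' If subunits of an n-mer are phosphorylated independently with probability
#' p and the phosphospecific antibody captures a channel with probability
#' `1 - (1 - capture_eff)^k` (k = phospho-subunits in the channel), the
#' expected apparent occupancy returned by the signal-ratio formula is
#' `OC_app = 100 * p * n * sum_k B(k; n, p) P_cap(k) / sum_k k B(k; n, p) P_cap(k)`,
#' computed by exact binomial enumeration. With `capture_eff = 1` this
#' reduces to the closed form `100 * (1 - (1 - p)^n)`: every channel with at
#' least one phosphorylated subunit is captured, and its unphosphorylated
#' subunits inflate the generic-antibody IP signal. For n = 1 (monomer) the
#' estimate is unbiased, OC_app = 100 p.
#'
#' @param p per-subunit phosphorylation probability in \[0, 1\] (vectorized)
#' @param n_subunits subunits per channel (4 = tetramer)
#' @param capture_eff per-phospho-subunit capture efficiency in (0, 1]
#' @param cross_reactivity additive phospho-antibody signal fraction from
#'   unphosphorylated subunits (default 0, a perfectly specific antibody)
#' @return apparent occupancy in percent
#' @export
apparent_occupancy <- function(p, n_subunits = 4, capture_eff = 1,
                               cross_reactivity = 0) {
  if (any(p < 0 | p > 1)) stop_input("p must lie in [0, 1]")
  if (capture_eff <= 0 || capture_eff > 1)
    stop_input("capture_eff must lie in (0, 1]")
  if (cross_reactivity < 0 || cross_reactivity > 1)
    stop_input("cross_reactivity must lie in [0, 1]")
  n <- as.integer(n_subunits)
  if (n < 1) stop_input("n_subunits must be >= 1")
  cr <- cross_reactivity
  if (capture_eff == 1 && cr == 0) return(100 * (1 - (1 - p)^n))
  vapply(p, function(pi) {
    if (pi == 0 && cr == 0) return(0)
    if (pi == 0)
      # continuity limit as p -> 0: captures are dominated by k = 1 channels
      return(100 * cr * n / (1 + cr * (n - 1)))
    k <- 0:n
    w <- stats::dbinom(k, n, pi)
    pcap <- capture_prob(k, capture_eff)
    psig <- k + cr * (n - k)         # phospho-antibody signal per channel
    input_ratio <- sum(w * psig) / n
    ip_ratio <- sum(w * pcap) * n / sum(w * pcap * psig)
    100 * input_ratio * ip_ratio
  }, numeric(1))
}

#' Invert the apparent-occupancy model
#'
#' Recovers the per-subunit phosphorylation probability p from an apparent
#' occupancy. With `capture_eff = 1` the closed form
#' `p = 1 - (1 - OC/100)^(1/n)` applies; otherwise the strictly increasing
#' model curve is inverted by bisection to absolute tolerance `tol`.
#'
#' @param oc_pct apparent occupancy in percent, in \[0, 100\] (vectorized)
#' @param n_subunits subunits per channel
#' @param capture_eff per-phospho-subunit capture efficiency
#' @param cross_reactivity additive cross-reactive signal fraction (see
#'   [apparent_occupancy()])
#' @param tol bisection tolerance on p
#' @return per-subunit phosphorylation probability
#' @export
invert_occupancy <- function(oc_pct, n_subunits = 4, capture_eff = 1,
                             cross_reactivity = 0, tol = 1e-10) {
  if (any(oc_pct < 0 | oc_pct > 100))
    stop_input("apparent occupancy must lie in [0, 100]")
  n <- as.integer(n_subunits)
  if (capture_eff == 1 && cross_reactivity == 0)
    return(1 - (1 - oc_pct / 100)^(1 / n))
  vapply(oc_pct, function(oc) {
    if (oc <= apparent_occupancy(0, n, capture_eff, cross_reactivity))
      return(0)
    if (oc == 100) return(1)
    lo <- 0; hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (apparent_occupancy(mid, n, capture_eff, cross_reactivity) < oc)
        lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Measured occupancy and model-corrected p from a simulated IP
#'
#' Applies the signal-ratio occupancy formula to a simulated IP experiment
#' and inverts the capture-bias model to recover the per-subunit
#' phosphorylation probability. Monte-Carlo standard errors come from
#' splitting the channels into blocks and recomputing both quantities per
#' block.
#'
#' @param sim `ip_experiment` from [simulate_ip()]
#' @param n_blocks number of channel blocks for the MC standard error
#' @return list: `oc_measured` (%), `oc_se`, `p_hat`, `p_se`, `truth`
#' @export
occupancy_from_simulation <- function(sim, n_blocks = 10) {
  stopifnot(inherits(sim, "ip_experiment"))
  n_sub <- sim$truth$subunits
  ce <- sim$truth$capture_eff
  cr <- sim$truth$cross_reactivity
  oc <- oc_formula(sim$p_input, sim$t_input, sim$p_ip, sim$t_ip)
  p_hat <- invert_occupancy(min(oc, 100), n_sub, ce, cr)

  nc <- length(sim$k)
  psig <- sim$k + cr * (n_sub - sim$k)
  block <- ((seq_len(nc) - 1L) %% n_blocks) + 1L
  oc_b <- p_b <- rep(NA_real_, n_blocks)
  for (b in seq_len(n_blocks)) {
    i <- block == b
    cap <- sim$captured & i
    s_in <- sum(psig[i]); s_cap <- sum(psig[cap])
    ocb <- if (s_in == 0 || s_cap == 0) 0 else
      (s_in / (sum(i) * n_sub)) * (sum(cap) * n_sub / s_cap) * 100
    oc_b[b] <- ocb
    p_b[b] <- invert_occupancy(min(ocb, 100), n_sub, ce, cr)
  }
  list(oc_measured = oc, oc_se = stats::sd(oc_b) / sqrt(n_blocks),
       p_hat = p_hat, p_se = stats::sd(p_b) / sqrt(n_blocks),
       truth = sim$truth)
}
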