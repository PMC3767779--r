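# Synthetic-data generators: LC-MS feature tables, Western-blot panels,
# immunoprecipitation experiments and candidate-screen panels, all with
# known ground truth so downstream stages have a parameter-recovery surface.

#' True phosphosite state for simulation
#'
#' Ground truth for one phosphorylation site: its relative abundance in each
#' light condition (max-normalized to 1) and, optionally, the per-subunit
#' phosphorylation probability used by the tetramer occupancy model.
#'
#' @param site_id site label, e.g. "T849"
#' @param condition_effect named numeric vector, condition -> relative true
#'   abundance in (0, 1]; exactly one condition must equal 1
#' @param subunit_prob optional named numeric vector, condition -> per-subunit
#'   phosphorylation probability in \[0, 1\]
#' @return an object of class `site_state`
#' @examples
#' site_state("T849", c(light = 1, dark = 0.25))
#' @export
site_state <- function(site_id, condition_effect, subunit_prob = NULL) {
  if (is.null(names(condition_effect)) || any(names(condition_effect) == ""))
    stop_input("condition_effect must be a named vector")
  if (any(condition_effect <= 0) || any(condition_effect > 1))
    stop_input("site %s: relative abundances must lie in (0, 1]", site_id)
  if (max(condition_effect) != 1)
    stop_input("site %s: relative abundances are max-normalized, so the largest must be 1", site_id)
  if (!is.null(subunit_prob) && (any(subunit_prob < 0) || any(subunit_prob > 1)))
    stop_input("site %s: subunit_prob must lie in [0, 1]", site_id)
  structure(list(site_id = site_id, condition_effect = condition_effect,
                 subunit_prob = subunit_prob),
            class = "site_state")
}

#' Build a run design table
#'
#' One row per LC-MS run with genotype, light condition, replicate indices,
#' digestion enzyme and a run-level scale factor (injection/loading
#' multiplier). The default reproduces nine runs per condition, the number of
#' runs entering each per-condition mean in the relative quantification.
#'
#' @param genotype genotype label(s)
#' @param conditions light conditions (default light/dark)
#' @param n_bio number of biological replicates
#' @param n_tech number of technical replicates
#' @param enzymes digestion enzyme label(s)
#' @param scale_factors optional numeric vector of per-run scale factors
#'   (recycled); default 1 for all runs
#' @return data.frame with columns run_id, genotype, condition, bio_replicate,
#'   tech_replicate, enzyme, scale_factor
#' @export
run_design <- function(genotype = "wt", conditions = c("light", "dark"),
                       n_bio = 3, n_tech = 3, enzymes = "trypsin",
                       scale_factors = NULL) {
  d <- expand.grid(genotype = genotype, condition = conditions,
                   bio_replicate = seq_len(n_bio), tech_replicate = seq_len(n_tech),
                   enzyme = enzymes, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$run_id <- sprintf("%s_%s_%s_b%d_t%d", d$genotype, d$condition,
                      substr(d$enzyme, 1, 4), d$bio_replicate, d$tech_replicate)
  d$scale_factor <- if (is.null(scale_factors)) 1 else
    rep_len(scale_factors, nrow(d))
  validate_run_design(d)
}

validate_run_design <- function(design) {
  need <- c("run_id", "genotype", "condition", "bio_replicate",
            "tech_replicate", "enzyme", "scale_factor")
  miss <- setdiff(need, colnames(design))
  if (length(miss)) stop_input("run design lacks columns: %s",
                               paste(miss, collapse = ", "))
  if (nrow(design) == 0L) stop_input("run design is empty")
  if (any(design$scale_factor <= 0)) stop_input("scale factors must be positive")
  if (anyDuplicated(design$run_id)) stop_input("duplicate run_id in design")
  key <- do.call(paste, design[c("genotype", "condition", "bio_replicate",
                                 "tech_replicate", "enzyme")])
  if (anyDuplicated(key)) stop_input("duplicate (genotype, condition, replicate, enzyme) in design")
  design[, need]
}

#' Simulation configuration
#'
#' @param n_background_features number of non-phospho background features;
#'   these carry the normalization assumption that most features do not change
#' @param background_change_fraction fraction of background features that do
#'   change between conditions (must stay below 0.5, the majority assumption)
#' @param noise_cv multiplicative log-normal noise CV applied per measurement
#' @param detect_prob probability that a measured feature is reported
#'   (missing-at-random); constant in (0, 1]
#' @param seed master seed; all generator substreams derive from it
#' @param charge_weights sampling weights for charge states 1..6
#' @param n_variants peptide variants emitted per phosphosite (different
#'   charge/missed cleavage)
#' @param multi_phospho_fraction fraction of extra site variants emitted as
#'   multiply phosphorylated (ineligible for quantification)
#' @param ambiguous_fraction fraction of extra site variants emitted with
#'   non-localized site assignment (ineligible)
#' @param background_fold_range fold-change range for the changing minority of
#'   background features
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_background_features = 200,
                       background_change_fraction = 0.1,
                       noise_cv = 0.2, detect_prob = 1, seed = 1,
                       charge_weights = c(1, 8, 6, 3, 1.5, 0.5),
                       n_variants = 2,
                       multi_phospho_fraction = 0,
                       ambiguous_fraction = 0,
                       background_fold_range = c(2, 8)) {
  if (background_change_fraction < 0 || background_change_fraction >= 0.5)
    stop_input("background_change_fraction must lie in [0, 0.5)")
  if (noise_cv < 0) stop_input("noise_cv must be >= 0")
  if (detect_prob <= 0 || detect_prob > 1)
    stop_input("detect_prob must lie in (0, 1]")
  if (length(charge_weights) != 6L || any(charge_weights < 0))
    stop_input("charge_weights must be 6 non-negative weights for charges 1..6")
  structure(list(n_background_features = n_background_features,
                 background_change_fraction = background_change_fraction,
                 noise_cv = noise_cv, detect_prob = detect_prob,
                 seed = as.integer(seed), charge_weights = charge_weights,
                 n_variants = n_variants,
                 multi_phospho_fraction = multi_phospho_fraction,
                 ambiguous_fraction = ambiguous_fraction,
                 background_fold_range = background_fold_range),
            class = "sim_config")
}

#' Simulate an aligned LC-MS feature table
#'
#' Generates the post-alignment feature table that label-free quantification
#' consumes: one row per feature (peptide variant), one abundance column per
#' run. Each observed abundance is
#' `base * condition_effect * scale_factor * lognormal(1, noise_cv)`,
#' reported as missing with probability `1 - detect_prob`. Background features
#' have no condition effect except a configurable minority, which anchors the
#' normalization assumption that most features do not change.
#'
#' @param truth list of [site_state()] objects (may be empty list for a
#'   background-only table, but not NULL)
#' @param design run design from [run_design()]
#' @param cfg configuration from [sim_config()]
#' @return data.frame feature table; metadata columns
#'   feature_id, peptide_sequence, site_id, n_phospho, site_localized, charge,
#'   mz, rt, followed by one numeric abundance column per run (NA = missing)
#' @export
simulate_feature_table <- function(truth, design, cfg = sim_config()) {
  if (is.null(truth)) stop_input("truth must be a list of site_state objects")
  design <- validate_run_design(design)
  if (nrow(design) < 2L) stop_input("need at least 2 runs")
  if (length(truth) == 0L && cfg$n_background_features == 0L)
    stop_input("nothing to simulate: no sites and no background features")
  conditions <- unique(design$condition)

  set.seed(substream_seed(cfg$seed, "features"))

  rows <- list()
  effects <- list()   # per feature: named condition effect vector

  # Background (non-phospho) features; a minority change between conditions.
  nbg <- cfg$n_background_features
  if (nbg > 0) {
    base <- stats::rlnorm(nbg, meanlog = log(1000), sdlog = 1)
    changer <- stats::runif(nbg) < cfg$background_change_fraction
    for (i in seq_len(nbg)) {
      eff <- stats::setNames(rep(1, length(conditions)), conditions)
      if (changer[i]) {
        cond <- sample(conditions, 1L)
        fold <- stats::runif(1, cfg$background_fold_range[1],
                             cfg$background_fold_range[2])
        eff[cond] <- fold
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = sprintf("bg%05d", i),
        peptide_sequence = sprintf("BGPEPTIDE%05d", i),
        site_id = "background", n_phospho = 0L, site_localized = TRUE,
        base = base[i], stringsAsFactors = FALSE)
      effects[[length(effects) + 1L]] <- eff
    }
  }

  # Phosphosite features: >= 1 eligible variant per site plus optional
  # multiply-phosphorylated / ambiguous-localization variants.
  for (s in truth) {
    stopifnot(inherits(s, "site_state"))
    miss <- setdiff(conditions, names(s$condition_effect))
    if (length(miss)) stop_input("site %s lacks condition effect for: %s",
                                 s$site_id, paste(miss, collapse = ", "))
    nv <- max(1L, cfg$n_variants)
    base <- stats::rlnorm(nv, meanlog = log(5000), sdlog = 0.8)
    for (v in seq_len(nv)) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = sprintf("%s_v%d", s$site_id, v),
        peptide_sequence = sprintf("PEP%s_V%d", s$site_id, v),
        site_id = s$site_id, n_phospho = 1L, site_localized = TRUE,
        base = base[v], stringsAsFactors = FALSE)
      effects[[length(effects) + 1L]] <- s$condition_effect[conditions]
    }
    extras <- c(multi = cfg$multi_phospho_fraction > 0 &&
                  stats::runif(1) < cfg$multi_phospho_fraction,
                ambig = cfg$ambiguous_fraction > 0 &&
                  stats::runif(1) < cfg$ambiguous_fraction)
    if (extras[["multi"]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = sprintf("%s_multi", s$site_id),
        peptide_sequence = sprintf("PEP%s_MULTI", s$site_id),
        site_id = s$site_id, n_phospho = 2L, site_localized = TRUE,
        base = stats::rlnorm(1, log(1000), 0.8), stringsAsFactors = FALSE)
      effects[[length(effects) + 1L]] <- s$condition_effect[conditions]
    }
    if (extras[["ambig"]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = sprintf("%s_ambig", s$site_id),
        peptide_sequence = sprintf("PEP%s_AMBIG", s$site_id),
        site_id = s$site_id, n_phospho = 1L, site_localized = FALSE,
        base = stats::rlnorm(1, log(1000), 0.8), stringsAsFactors = FALSE)
      effects[[length(effects) + 1L]] <- s$condition_effect[conditions]
    }
  }

  meta <- do.call(rbind, rows)
  nf <- nrow(meta)
  meta$charge <- sample(1:6, nf, replace = TRUE, prob = cfg$charge_weights)
  meta$mz <- stats::runif(nf, 250, 1800)
  meta$rt <- stats::runif(nf, 0, 120)

  effmat <- do.call(rbind, effects)             # features x conditions
  colnames(effmat) <- conditions
  ab <- matrix(NA_real_, nf, nrow(design),
               dimnames = list(meta$feature_id, design$run_id))
  for (j in seq_len(nrow(design))) {
    eff <- effmat[, design$condition[j]]
    ab[, j] <- meta$base * eff * design$scale_factor[j] *
      rlnorm_cv(nf, cfg$noise_cv)
  }
  if (cfg$detect_prob < 1) {
    drop <- matrix(stats::runif(length(ab)) > cfg$detect_prob, nf)
    ab[drop] <- NA_real_
  }

  out <- cbind(meta[, c("feature_id", "peptide_sequence", "site_id",
                        "n_phospho", "site_localized", "charge", "mz", "rt")],
               as.data.frame(ab))
  rownames(out) <- NULL
  out
}

#' Simulate a quantitative Western-blot panel
#'
#' Each lane receives `total = gain_total * amount * noise` and
#' `phospho = gain_phospho * amount * fraction * noise`, with independent
#' multiplicative log-normal noise per signal. Gains are per-membrane
#' constants, so phospho/total ratios compared within a membrane are
#' gain-free.
#'
#' @param lanes data.frame with columns genotype, condition, heads_loaded and
#'   optionally timepoint, membrane_id, replicate
#' @param fractions data.frame with columns genotype, condition, fraction
#'   (phospho signal fraction in \[0, 1\]) and optionally timepoint
#' @param noise_cv log-normal noise CV per signal
#' @param seed RNG seed
#' @param gain_total,gain_phospho mean antibody/detection gains
#' @param gain_cv per-membrane gain variability (CV); 0 = identical gains
#' @return data.frame blot panel: lane_id, genotype, condition, timepoint,
#'   heads_loaded, replicate, membrane_id, phospho_signal, total_signal
#' @export
simulate_blot_panel <- function(lanes, fractions, noise_cv = 0.15, seed = 1,
                                gain_total = 1, gain_phospho = 1,
                                gain_cv = 0) {
  if (nrow(lanes) == 0L) stop_input("empty lane design")
  if (any(lanes$heads_loaded < 0)) stop_input("negative amounts loaded")
  if (any(fractions$fraction < 0 | fractions$fraction > 1))
    stop_input("signal fractions must lie in [0, 1]")
  lanes <- as.data.frame(lanes)
  if (is.null(lanes$membrane_id)) lanes$membrane_id <- "m1"
  if (is.null(lanes$replicate)) lanes$replicate <- 1L
  if (is.null(lanes$timepoint)) lanes$timepoint <- NA_real_

  by <- c("genotype", "condition")
  if (!is.null(fractions$timepoint) && any(!is.na(lanes$timepoint)))
    by <- c(by, "timepoint")
  idx <- match(do.call(paste, lanes[by]), do.call(paste, fractions[by]))
  if (anyNA(idx))
    stop_input("no signal fraction for lane(s): %s",
               paste(unique(do.call(paste, lanes[by])[is.na(idx)]), collapse = ", "))
  frac <- fractions$fraction[idx]

  set.seed(substream_seed(seed, "blot"))
  membranes <- unique(lanes$membrane_id)
  gt <- stats::setNames(gain_total * rlnorm_cv(length(membranes), gain_cv), membranes)
  gp <- stats::setNames(gain_phospho * rlnorm_cv(length(membranes), gain_cv), membranes)
  n <- nrow(lanes)
  total <- gt[lanes$membrane_id] * lanes$heads_loaded * rlnorm_cv(n, noise_cv)
  phospho <- gp[lanes$membrane_id] * lanes$heads_loaded * frac * rlnorm_cv(n, noise_cv)

  data.frame(lane_id = sprintf("lane%03d", seq_len(n)),
             genotype = lanes$genotype, condition = lanes$condition,
             timepoint = lanes$timepoint, heads_loaded = lanes$heads_loaded,
             replicate = lanes$replicate, membrane_id = lanes$membrane_id,
             phospho_signal = unname(phospho), total_signal = unname(total),
             stringsAsFactors = FALSE)
}

#' Dilution-series lane design for blot linearity QC
#'
#' The classic design loads a constant total protein amount while the amount
#' of the target protein is titrated (default 3, 1.5, 0.75, 0.375 head
#' equivalents) by mixing wild-type extract with extract from a null mutant.
#'
#' @param amounts head equivalents of target protein per lane
#' @param genotype,condition labels for the titrated lanes
#' @return lane design data.frame for [simulate_blot_panel()]
#' @export
dilution_series_lanes <- function(amounts = c(3, 1.5, 0.75, 0.375),
                                  genotype = "wt", condition = "light") {
  data.frame(genotype = genotype, condition = condition,
             heads_loaded = amounts, membrane_id = "dilution", replicate = 1L,
             stringsAsFactors = FALSE)
}

#' Simulate a phosphospecific-antibody immunoprecipitation experiment
#'
#' Channels are tetramers (or n-mers) whose subunits are phosphorylated
#' i.i.d. Bernoulli(p). Input signals are proportional to total
#' phospho-subunits (phospho antibody) and total subunits (generic antibody).
#' A channel is captured by the phosphospecific antibody with probability
#' `1 - (1 - capture_eff)^k` where k is its phospho-subunit count; IP signals
#' sum over captured channels only. Co-capture of unphosphorylated subunits
#' within captured multimers is what biases the naive occupancy estimate
#' upward.
#'
#' @param p per-subunit phosphorylation probability in \[0, 1\]
#' @param n_channels number of channels simulated
#' @param subunits_per_channel subunits per channel (4 = tetramer)
#' @param capture_eff per-phospho-subunit capture efficiency in (0, 1]
#' @param cross_reactivity fraction of the phosphospecific antibody's signal
#'   contributed by an unphosphorylated subunit (dark-condition residual
#'   signal); 0 = perfectly specific antibody
#' @param seed RNG seed
#' @param site_id,replicate labels carried into the result
#' @return object of class `ip_experiment`: list with signals p_input,
#'   t_input, p_ip, t_ip, per-channel phospho counts `k`, capture indicator
#'   `captured`, and the simulation truth
#' @export
simulate_ip <- function(p, n_channels, subunits_per_channel = 4,
                        capture_eff = 1, cross_reactivity = 0, seed = 1,
                        site_id = "site", replicate = 1L) {
  if (p < 0 || p > 1) stop_input("p must lie in [0, 1]")
  if (capture_eff <= 0 || capture_eff > 1)
    stop_input("capture_eff must lie in (0, 1]")
  if (cross_reactivity < 0 || cross_reactivity > 1)
    stop_input("cross_reactivity must lie in [0, 1]")
  if (n_channels < 1) stop_input("need at least one channel")
  set.seed(substream_seed(seed, "ip"))
  n_sub <- as.integer(subunits_per_channel)
  k <- stats::rbinom(n_channels, n_sub, p)
  captured <- stats::runif(n_channels) < (1 - (1 - capture_eff)^k)
  # phospho-antibody signal per channel: k true epitopes plus an additive
  # cross-reactive contribution from the n-k unphosphorylated subunits
  psig <- k + cross_reactivity * (n_sub - k)
  structure(list(
    site_id = site_id, replicate = replicate,
    p_input = sum(psig), t_input = as.numeric(n_channels) * n_sub,
    p_ip = sum(psig[captured]), t_ip = as.numeric(sum(captured)) * n_sub,
    k = k, captured = captured,
    truth = list(p = p, n_channels = n_channels, subunits = n_sub,
                 capture_eff = capture_eff,
                 cross_reactivity = cross_reactivity)),
    class = "ip_experiment")
}

#' @export
print.ip_experiment <- function(x, ...) {
  cat(sprintf("IP experiment (%s, replicate %s): %d channels of %d subunits\n",
              x$site_id, x$replicate, x$truth$n_channels, x$truth$subunits))
  cat(sprintf("  signals: pTRP_input=%g TRP_input=%g pTRP_IP=%g TRP_IP=%g\n",
              x$p_input, x$t_input, x$p_ip, x$t_ip))
  invisible(x)
}

#' Simulate a kinase/phosphatase candidate-screen panel
#'
#' Generates lane-level blot data for a mutant screen: for every mutant,
#' phosphosite antibody and light condition, each replicate membrane carries
#' one wild-type control lane and one mutant lane. Mutant effects enter as
#' fold changes on the phospho/total ratio relative to wild type in the same
#' condition. Replicate 1 is the initial screen; all `replicates` membranes
#' form the rescreen.
#'
#' @param effects NULL (all-null panel) or data.frame with columns mutant_id,
#'   site_id, condition, fold (fold change of the phospho fraction vs WT)
#' @param n_mutants number of mutants in the panel
#' @param sites phosphosite antibody labels
#' @param conditions light conditions
#' @param wt_fraction named per-condition wild-type phospho signal fraction
#' @param replicates total experiments per mutant (initial + rescreens)
#' @param noise_cv log-normal noise CV per lane signal
#' @param gain_cv per-membrane gain CV (ratios within a membrane are gain-free)
#' @param seed RNG seed
#' @return list with `panel` (lane-level data.frame: mutant_id, gene, site_id,
#'   condition, replicate, membrane_id, lane genotype, phospho_signal,
#'   total_signal) and `truth` (the effects table used)
#' @export
simulate_screen_panel <- function(effects = NULL, n_mutants = 85,
                                  sites = c("T849", "T864"),
                                  conditions = c("light", "dark"),
                                  wt_fraction = c(light = 0.5, dark = 0.1),
                                  replicates = 3, noise_cv = 0.15,
                                  gain_cv = 0.3, seed = 1) {
  if (!is.null(effects)) {
    if (any(effects$fold <= 0)) stop_input("fold changes must be positive")
    extra <- setdiff(effects$mutant_id, sprintf("mut%03d", seq_len(n_mutants)))
    if (length(extra)) stop_input("effects name unknown mutants: %s",
                                  paste(extra, collapse = ", "))
  }
  mutants <- sprintf("mut%03d", seq_len(n_mutants))
  grid <- expand.grid(mutant_id = mutants, site_id = sites,
                      condition = conditions, replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$membrane_id <- sprintf("%s_%s_%s_r%d", grid$mutant_id, grid$site_id,
                              grid$condition, grid$replicate)
  fold <- rep(1, nrow(grid))
  if (!is.null(effects)) {
    key <- paste(grid$mutant_id, grid$site_id, grid$condition)
    ekey <- paste(effects$mutant_id, effects$site_id, effects$condition)
    hit <- match(key, ekey)
    fold[!is.na(hit)] <- effects$fold[hit[!is.na(hit)]]
  }
  wt_frac <- wt_fraction[grid$condition]

  set.seed(substream_seed(seed, "screen"))
  n <- nrow(grid)
  gt <- rlnorm_cv(n, gain_cv)           # per-membrane total-antibody gain
  gp <- rlnorm_cv(n, gain_cv)           # per-membrane phospho-antibody gain
  amount <- 3                           # head equivalents per lane
  lane <- function(genotype, frac) {
    data.frame(grid[c("mutant_id", "site_id", "condition", "replicate",
                      "membrane_id")],
               gene = sub("^mut", "gene", grid$mutant_id),
               genotype = genotype,
               phospho_signal = gp * amount * frac * rlnorm_cv(n, noise_cv),
               total_signal = gt * amount * rlnorm_cv(n, noise_cv),
               stringsAsFactors = FALSE)
  }
  panel <- rbind(lane("wt", wt_frac), lane("mutant", wt_frac * fold))
  panel <- panel[order(panel$membrane_id, panel$genotype), ]
  rownames(panel) <- NULL
  list(panel = panel,
       truth = effects %||% data.frame(mutant_id = character(),
                                       site_id = character(),
                                       condition = character(),
                                       fold = numeric()))
}
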