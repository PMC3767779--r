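# End-to-end driver: synthetic truth -> LFQ -> densitometry -> occupancy ->
# screen, with a manifest that makes any output reproducible from the
# configuration and master seed alone.

#' Default demonstration truth: a phosphosite map with 13 light-elevated
#' sites and one dark-elevated site
#'
#' Site labels follow the C-terminal phosphosite nomenclature of the TRP
#' channel; the dark-elevated site plays the role of the one site that is
#' predominantly phosphorylated in the dark. Effects default to 4-fold.
#'
#' @param fold condition effect (higher/lower condition abundance ratio)
#' @return list of [site_state()] objects
#' @export
demo_truth <- function(fold = 4) {
  light_sites <- c("S721", "S726", "T849", "T864", "S872", "S958", "S961",
                   "S964", "T998", "T1036", "T1049", "S1123", "S1254")
  dark_sites <- "S936"
  c(lapply(light_sites, function(s)
      site_state(s, c(light = 1, dark = 1 / fold))),
    lapply(dark_sites, function(s)
      site_state(s, c(light = 1 / fold, dark = 1))))
}

#' Default screen truth: four confirmed-effect mutants per phosphosite
#'
#' Mirrors a screen outcome in which four mutants alter phosphorylation of
#' each of the two sites in the light: for the PKC-site antibody two mutants
#' with reduced phosphorylation (kinase-like, the strongest at the 6.7-fold
#' scale of an eye-PKC null) and two with enhanced phosphorylation
#' (phosphatase-pathway-like); for the second site four reduced. All planted
#' effects are at least 4-fold.
#'
#' @return effects data.frame for [simulate_screen_panel()]
#' @export
demo_screen_truth <- function() {
  data.frame(
    mutant_id = c("mut005", "mut012", "mut023", "mut034",
                  "mut041", "mut052", "mut063", "mut074"),
    site_id = rep(c("T849", "T864"), each = 4),
    condition = "light",
    fold = c(0.15, 0.2, 5, 5, 0.15, 0.2, 0.15, 0.2),
    stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline stages with its default. The
#' object serializes losslessly to JSON and back ([write_config()],
#' [read_config()]).
#'
#' @param seed master seed; all stage substreams derive from it
#' @param lfq list: reference_run (NULL = first lexicographically),
#'   normalizer, test, alpha, n_bio, n_tech, enzymes, noise_cv,
#'   n_background_features, background_change_fraction, detect_prob,
#'   effect_fold
#' @param blot list: noise_cv, amounts (dilution series), linearity_threshold
#' @param occupancy_model list: p, n_subunits, capture_eff, n_channels
#' @param screen list: n_mutants, replicates, noise_cv, up, down, mode
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1,
                            lfq = list(),
                            blot = list(),
                            occupancy_model = list(),
                            screen = list()) {
  defaults <- list(
    seed = as.integer(seed),
    lfq = list(reference_run = NULL, normalizer = "recursive_median",
               test = "student", alpha = 0.05, n_bio = 3, n_tech = 3,
               enzymes = "trypsin", noise_cv = 0.2,
               n_background_features = 200,
               background_change_fraction = 0.1, detect_prob = 1,
               effect_fold = 4),
    blot = list(noise_cv = 0.15, amounts = c(3, 1.5, 0.75, 0.375),
                linearity_threshold = 0.95),
    occupancy_model = list(p = 0.2, n_subunits = 4, capture_eff = 1,
                           n_channels = 100000),
    screen = list(n_mutants = 85, replicates = 3, noise_cv = 0.15,
                  up = 2, down = 0.5, mode = "ttest"))
  cfg <- defaults
  cfg$lfq[names(lfq)] <- lfq
  cfg$blot[names(blot)] <- blot
  cfg$occupancy_model[names(occupancy_model)] <- occupancy_model
  cfg$screen[names(screen)] <- screen
  if (cfg$screen$up <= 0 || cfg$screen$down <= 0 || cfg$lfq$alpha <= 0)
    stop_input("thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#' @param config `pipeline_config` object
#' @param path JSON file path
#' @return `write_config()` the path invisibly; `read_config()` the config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("config file does not exist: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(seed = x$seed, lfq = x$lfq %||% list(),
                  blot = x$blot %||% list(),
                  occupancy_model = x$occupancy_model %||% list(),
                  screen = x$screen %||% list())
}

#' Run the full pipeline on synthetic data
#'
#' Generates synthetic inputs from the configured ground truth and executes
#' every analysis stage: feature-table simulation, charge filtering,
#' run normalization, site quantification and classification; dilution-series
#' blot simulation and linearity QC; IP simulation, occupancy measurement and
#' model-based inversion; screen simulation, hit calling, rescreen
#' confirmation and summary. All intermediate tables, a JSON manifest
#' (configuration + seed + package version) and a plain-text summary are
#' written under `out_dir`. The same configuration and seed reproduce the
#' bundle byte for byte.
#'
#' @param config a [pipeline_config()] or path to its JSON serialization
#' @param out_dir output directory (created if needed)
#' @param quiet suppress stage-level progress messages
#' @return invisibly, a list with the in-memory results of every stage
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed

  # --- LFQ stage ------------------------------------------------------
  lcfg <- config$lfq
  truth <- demo_truth(fold = lcfg$effect_fold)
  design <- run_design(n_bio = lcfg$n_bio, n_tech = lcfg$n_tech,
                       enzymes = lcfg$enzymes)
  set.seed(substream_seed(seed, "design_scales"))
  design$scale_factor <- stats::runif(nrow(design), 0.5, 2)
  cfg <- sim_config(n_background_features = lcfg$n_background_features,
                    background_change_fraction = lcfg$background_change_fraction,
                    noise_cv = lcfg$noise_cv, detect_prob = lcfg$detect_prob,
                    seed = substream_seed(seed, "lfq"))
  features <- simulate_feature_table(truth, design, cfg)
  say("simulate: %d features x %d runs", nrow(features), nrow(design))
  filtered <- filter_charge(features)
  say("lfq: charge filter kept %d of %d features", nrow(filtered), nrow(features))
  norm <- normalize_runs(filtered, reference_run = lcfg$reference_run,
                         method = lcfg$normalizer)
  quant <- quantify_sites(norm, design, test = lcfg$test, alpha = lcfg$alpha)
  classes <- classify_sites(quant)
  say("lfq: %s", paste(names(classes), classes, sep = "=", collapse = ", "))

  # --- Densitometry stage ---------------------------------------------
  bcfg <- config$blot
  blot <- simulate_blot_panel(
    dilution_series_lanes(amounts = bcfg$amounts),
    fractions = data.frame(genotype = "wt", condition = "light",
                           fraction = 0.5),
    noise_cv = bcfg$noise_cv, seed = substream_seed(seed, "blotpanel"))
  linearity <- linearity_check(blot, threshold = bcfg$linearity_threshold)
  say("densitometry: linearity r^2 = %s",
      paste(round(linearity$r_squared, 4), collapse = ", "))

  # --- Occupancy stage ------------------------------------------------
  ocfg <- config$occupancy_model
  ip <- simulate_ip(ocfg$p, ocfg$n_channels, ocfg$n_subunits,
                    ocfg$capture_eff, seed = substream_seed(seed, "ipsim"))
  oc <- occupancy_from_simulation(ip)
  say("occupancy: measured %.2f%%, model-corrected p = %.4f",
      oc$oc_measured, oc$p_hat)

  # --- Screen stage ---------------------------------------------------
  scfg <- config$screen
  sim_screen <- simulate_screen_panel(demo_screen_truth(),
                                      n_mutants = scfg$n_mutants,
                                      replicates = scfg$replicates,
                                      noise_cv = scfg$noise_cv,
                                      seed = substream_seed(seed, "screensim"))
  records <- screen_records(sim_screen$panel)
  hits <- call_initial_hits(records, up = scfg$up, down = scfg$down)
  confirmed <- confirm_hits(records, hits, n_required = scfg$replicates,
                            mode = scfg$mode, up = scfg$up, down = scfg$down)
  screen_summary <- summarize_screen(confirmed)
  say("screen: %d initial hit(s), %d confirmed effect(s)",
      length(hits$hits), sum(confirmed$confirmed))

  # --- Outputs --------------------------------------------------------
  write_table(features, file.path(out_dir, "features.tsv"))
  write_table(design, file.path(out_dir, "design.tsv"))
  write_table(data.frame(run_id = names(norm$factors),
                         factor = unname(norm$factors)),
              file.path(out_dir, "normalization_factors.tsv"))
  write_table(quant, file.path(out_dir, "site_quant.tsv"))
  write_table(data.frame(class = names(classes),
                         n_sites = as.integer(classes)),
              file.path(out_dir, "site_classes.tsv"))
  write_table(blot, file.path(out_dir, "blot_panel.tsv"))
  write_table(linearity, file.path(out_dir, "linearity.tsv"))
  write_table(data.frame(site_id = ip$site_id, replicate = ip$replicate,
                         p_input = ip$p_input, t_input = ip$t_input,
                         p_ip = ip$p_ip, t_ip = ip$t_ip),
              file.path(out_dir, "ip_signals.tsv"))
  write_table(data.frame(oc_measured_pct = oc$oc_measured, oc_se = oc$oc_se,
                         p_hat = oc$p_hat, p_se = oc$p_se,
                         p_true = ocfg$p),
              file.path(out_dir, "occupancy.tsv"))
  write_table(records, file.path(out_dir, "screen_records.tsv"))
  write_table(confirmed, file.path(out_dir, "screen_confirmed.tsv"))
  write_table(screen_summary, file.path(out_dir, "screen_summary.tsv"))

  manifest <- list(package = "trpquant",
                   version = as.character(utils::packageVersion("trpquant")),
                   seed = seed, config = unclass(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  summary_lines <- c(
    "trpquant pipeline summary",
    sprintf("seed: %d", seed),
    sprintf("features simulated: %d (runs: %d)", nrow(features), nrow(design)),
    sprintf("site classes: %s",
            paste(names(classes), classes, sep = "=", collapse = ", ")),
    sprintf("linearity r^2: %s",
            paste(sprintf("%s=%.4f", linearity$antibody, linearity$r_squared),
                  collapse = ", ")),
    sprintf("apparent occupancy: %.2f%% (true per-subunit p %.3f, recovered %.4f)",
            oc$oc_measured, ocfg$p, oc$p_hat),
    sprintf("screen: %d initial hit(s); confirmed per site: %s",
            length(hits$hits),
            if (nrow(screen_summary)) paste(screen_summary$site_id,
                                            screen_summary$n_confirmed,
                                            sep = "=", collapse = ", ")
            else "none"))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(features = features, design = design, norm = norm,
                 quant = quant, classes = classes, blot = blot,
                 linearity = linearity, ip = ip, occupancy = oc,
                 screen_records = records, hits = hits,
                 confirmed = confirmed, screen_summary = screen_summary,
                 manifest = manifest))
}
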