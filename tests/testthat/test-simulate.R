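# Synthetic-data generators: construction fidelity with noise off,
# determinism under a fixed seed, and agreement with exact enumeration.

test_that("noise-free feature tables satisfy their defining equation exactly", {
  truth <- list(site_state("T849", c(light = 1, dark = 0.25)))
  design <- run_design(n_bio = 2, n_tech = 1)
  cfg <- sim_config(n_background_features = 5, background_change_fraction = 0,
                    noise_cv = 0, detect_prob = 1, seed = 42, n_variants = 1)
  tab <- simulate_feature_table(truth, design, cfg)

  site <- tab[tab$site_id == "T849", ]
  light_runs <- design$run_id[design$condition == "light"]
  dark_runs <- design$run_id[design$condition == "dark"]
  light_ab <- unlist(site[light_runs])
  dark_ab <- unlist(site[dark_runs])
  expect_equal(unname(light_ab), unname(4 * dark_ab))
  # every light-run value identical (no noise, equal scale factors)
  expect_equal(length(unique(light_ab)), 1L)

  # doubling one run's scale factor doubles every feature of that run
  design2 <- design
  design2$scale_factor[design2$run_id == light_runs[1]] <- 2
  tab2 <- simulate_feature_table(truth, design2, cfg)
  expect_equal(tab2[[light_runs[1]]], 2 * tab[[light_runs[1]]])
  expect_equal(tab2[[dark_runs[1]]], tab[[dark_runs[1]]])
})

test_that("feature simulation is bit-identical under a fixed seed", {
  truth <- list(site_state("T849", c(light = 1, dark = 0.25)))
  design <- run_design(n_bio = 2, n_tech = 1)
  cfg <- sim_config(n_background_features = 30, noise_cv = 0.2,
                    detect_prob = 0.8, seed = 7)
  expect_identical(simulate_feature_table(truth, design, cfg),
                   simulate_feature_table(truth, design, cfg))
  cfg2 <- sim_config(n_background_features = 30, noise_cv = 0.2,
                     detect_prob = 0.8, seed = 8)
  expect_false(identical(simulate_feature_table(truth, design, cfg),
                         simulate_feature_table(truth, design, cfg2)))
})

test_that("background changer fraction matches the configured rate", {
  design <- run_design(n_bio = 2, n_tech = 1)
  cfg <- sim_config(n_background_features = 2000,
                    background_change_fraction = 0.1, noise_cv = 0,
                    seed = 3)
  tab <- simulate_feature_table(list(), design, cfg)
  light <- design$run_id[design$condition == "light"][1]
  dark <- design$run_id[design$condition == "dark"][1]
  changed <- abs(log(tab[[light]] / tab[[dark]])) > 1e-12
  # binomial: 2000 trials at 0.1, +/- 4 sd
  expect_lt(abs(mean(changed) - 0.1), 4 * sqrt(0.1 * 0.9 / 2000))
})

test_that("feature simulation rejects invalid inputs", {
  design <- run_design(n_bio = 2, n_tech = 1)
  expect_error(simulate_feature_table(NULL, design), "site_state")
  expect_error(simulate_feature_table(list(), design[0, ], sim_config()),
               "empty")
  expect_error(site_state("x", c(light = 1, dark = 0)), "\\(0, 1\\]")
  expect_error(site_state("x", c(light = 0.5, dark = 0.8)), "max")
  expect_error(sim_config(background_change_fraction = 0.6), "0.5")
})

test_that("noise-free blot panels have constant phospho/total ratios", {
  lanes <- data.frame(genotype = "wt", condition = "light",
                      heads_loaded = c(1, 2), membrane_id = "m1")
  fr <- data.frame(genotype = "wt", condition = "light", fraction = 0.5)
  panel <- simulate_blot_panel(lanes, fr, noise_cv = 0, seed = 1)
  ratio <- panel$phospho_signal / panel$total_signal
  expect_equal(ratio[1], ratio[2])
  expect_equal(ratio[1], 0.5)

  expect_identical(simulate_blot_panel(lanes, fr, noise_cv = 0.2, seed = 5),
                   simulate_blot_panel(lanes, fr, noise_cv = 0.2, seed = 5))
  expect_error(simulate_blot_panel(transform(lanes, heads_loaded = -1), fr),
               "negative")
  expect_error(simulate_blot_panel(lanes, transform(fr, fraction = 1.5)),
               "\\[0, 1\\]")
})

test_that("IP simulator honours boundary cases and matches enumeration", {
  sim0 <- simulate_ip(0, 1000, seed = 1)
  expect_equal(sim0$p_input, 0)
  expect_equal(sim0$t_ip, 0)

  sim1 <- simulate_ip(1, 1000, capture_eff = 1, seed = 1)
  res1 <- occupancy(sim1)
  expect_equal(res1$oc_pct, 100)

  # at capture_eff = 1, observed signal ratios match exact binomial
  # enumeration for several subunit counts (MC error bounds via blocks)
  for (n_sub in c(2, 4, 6)) {
    p <- 0.3
    sim <- simulate_ip(p, 2e5, subunits_per_channel = n_sub, seed = n_sub)
    oc <- occupancy_from_simulation(sim)
    expect_lt(abs(oc$oc_measured - oracle_apparent_oc(p, n_sub)),
              4 * oc$oc_se)
    # captured channel fraction matches 1 - (1-p)^n
    expect_lt(abs(mean(sim$captured) - (1 - (1 - p)^n_sub)), 0.005)
  }
  expect_error(simulate_ip(1.2, 10), "\\[0, 1\\]")
})

test_that("screen panel generator: nulls yield no hits, planted effects are flagged", {
  sim <- simulate_screen_panel(NULL, n_mutants = 20, noise_cv = 0, seed = 1)
  rec <- screen_records(sim$panel)
  hits <- call_initial_hits(rec)
  expect_length(hits$hits, 0)

  # 6.7-fold reduction scenario: fold 0.15 in the light
  eff <- data.frame(mutant_id = "mut003", site_id = "T849",
                    condition = "light", fold = 0.15)
  sim2 <- simulate_screen_panel(eff, n_mutants = 20, noise_cv = 0, seed = 1)
  rec2 <- screen_records(sim2$panel)
  hits2 <- call_initial_hits(rec2)
  expect_identical(hits2$hits, "mut003")

  expect_identical(simulate_screen_panel(eff, n_mutants = 10, seed = 2),
                   simulate_screen_panel(eff, n_mutants = 10, seed = 2))
  expect_error(simulate_screen_panel(transform(eff, fold = -1), n_mutants = 10),
               "positive")
})
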