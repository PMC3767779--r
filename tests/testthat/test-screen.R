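# Candidate-screen hit calling: boundary semantics, rescreen confirmation,
# monotonicity and null specificity.

mk_records <- function(mutant, pct, site = "T849", condition = "light",
                       stage = "initial", replicate = seq_along(pct)) {
  data.frame(mutant_id = mutant, gene = mutant, site_id = site,
             condition = condition, stage = stage, replicate = replicate,
             relative_phospho_pct = pct, stringsAsFactors = FALSE)
}

test_that("initial hit boundaries: >= 2-fold inclusive, < 0.5-fold exclusive", {
  rec <- rbind(mk_records("m_up2", 200), mk_records("m_up_just_under", 199.99),
               mk_records("m_half", 50), mk_records("m_down", 49.99),
               mk_records("m_null", 100))
  hits <- call_initial_hits(rec)
  expect_identical(hits$hits, c("m_down", "m_up2"))
  calls <- hits$calls
  expect_true(calls$hit[calls$mutant_id == "m_up2"])     # fold 2.0 is a hit
  expect_false(calls$hit[calls$mutant_id == "m_half"])   # fold 0.5 is not
  expect_false(calls$hit[calls$mutant_id == "m_null"])
})

test_that("hit calling is monotone in the fold change", {
  folds <- seq(0.1, 4, 0.05)
  rec <- mk_records(sprintf("m%03d", seq_along(folds)), 100 * folds)
  calls <- call_initial_hits(rec)$calls
  up <- calls$fold >= 1
  # once a fold is a hit in the up direction, larger folds stay hits
  expect_true(all(diff(calls$hit[up][order(calls$fold[up])]) >= 0))
  down <- calls$fold <= 1
  expect_true(all(diff(calls$hit[down][order(calls$fold[down],
                                             decreasing = TRUE)]) >= 0))
})

test_that("rescreen confirmation applies fold rule on the mean plus the t-test", {
  rec <- rbind(mk_records("mA", 15, stage = "initial", replicate = 1),
               mk_records("mA", c(15, 20, 10), stage = "rescreen"))
  hits <- call_initial_hits(rec)
  conf <- confirm_hits(rec, hits)
  expect_equal(conf$mean_pct, 15)
  expect_equal(conf$sem_pct, sd(c(15, 20, 10)) / sqrt(3))
  expect_equal(conf$fold, 0.15)
  expect_equal(conf$p_value, t.test(log(c(15, 20, 10)), mu = log(100))$p.value)
  expect_lt(conf$p_value, 0.05)
  expect_true(conf$confirmed)
  expect_identical(conf$direction, "down")

  # mean crosses no boundary: not confirmed despite wild replicates
  rec2 <- rbind(mk_records("mB", 210, stage = "initial", replicate = 1),
                mk_records("mB", c(45, 210, 60), stage = "rescreen"))
  conf2 <- confirm_hits(rec2, call_initial_hits(rec2))
  expect_false(conf2$confirmed)

  # all replicates at exactly 100%: not confirmed (p = 1 by the degenerate limit)
  rec3 <- rbind(mk_records("mC", 200, stage = "initial", replicate = 1),
                mk_records("mC", c(100, 100, 100), stage = "rescreen"))
  conf3 <- confirm_hits(rec3, call_initial_hits(rec3))
  expect_false(conf3$confirmed)
  expect_equal(conf3$p_value, 1)

  # < 3 rescreen replicates: flagged unconfirmable, not dropped
  rec4 <- rbind(mk_records("mD", 15, stage = "initial", replicate = 1),
                mk_records("mD", c(15, 20), stage = "rescreen"))
  conf4 <- confirm_hits(rec4, call_initial_hits(rec4))
  expect_true(conf4$unconfirmable)
  expect_false(conf4$confirmed)

  # threshold mode confirms on the mean alone
  conf5 <- confirm_hits(rec4, call_initial_hits(rec4), n_required = 2,
                        mode = "threshold")
  expect_true(conf5$confirmed)
})

test_that("summaries count confirmed mutants once per site; empty input is empty", {
  rec <- rbind(
    mk_records("mA", 15, stage = "initial", replicate = 1),
    mk_records("mA", c(15, 20, 10), stage = "rescreen"),
    mk_records("mA", 10, site = "T864", stage = "initial", replicate = 1),
    mk_records("mA", c(10, 12, 9), site = "T864", stage = "rescreen"),
    mk_records("mB", 400, stage = "initial", replicate = 1),
    mk_records("mB", c(400, 300, 500), stage = "rescreen"))
  conf <- confirm_hits(rec, call_initial_hits(rec))
  s <- summarize_screen(conf)
  expect_equal(s$n_confirmed[s$site_id == "T849" & s$direction == "down"], 1L)
  expect_equal(s$n_confirmed[s$site_id == "T849" & s$direction == "up"], 1L)
  expect_equal(s$n_confirmed[s$site_id == "T864" & s$direction == "down"], 1L)

  empty <- summarize_screen(confirm_hits(rec[0, ], character(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("under a null panel the rescreen filters initial false positives", {
  n_initial <- 0L; n_confirmed <- 0L
  for (seed in 1:60) {
    sim <- simulate_screen_panel(NULL, n_mutants = 40, noise_cv = 0.2,
                                 seed = seed)
    rec <- screen_records(sim$panel)
    hits <- call_initial_hits(rec)
    conf <- confirm_hits(rec, hits)
    n_initial <- n_initial + length(hits$hits)
    n_confirmed <- n_confirmed +
      nrow(unique(conf[conf$confirmed, c("mutant_id", "site_id")]))
  }
  expect_gt(n_initial, 0)
  expect_lt(n_confirmed, n_initial)
})

test_that("screen calls are deterministic for fixed input tables", {
  sim <- simulate_screen_panel(demo_screen_truth(), seed = 5)
  rec <- screen_records(sim$panel)
  c1 <- confirm_hits(rec, call_initial_hits(rec))
  c2 <- confirm_hits(rec, call_initial_hits(rec))
  expect_identical(c1, c2)
})
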