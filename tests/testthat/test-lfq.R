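# Label-free quantification: charge filter, recursive-median normalization,
# eligibility/variant selection, t-test quantification and classification.

test_that("charge filter keeps +2..+5 and preserves row order", {
  tab <- do.call(rbind, lapply(1:6, function(z)
    feature_row(paste0("f", z), "background", c(r1 = 10, r2 = 20),
                n_phospho = 0L, charge = z)))
  kept <- filter_charge(tab)
  expect_identical(kept$charge, 2:5)
  expect_identical(kept$feature_id, paste0("f", 2:5))

  expect_identical(nrow(filter_charge(tab[0, ])), 0L)
  all2 <- tab[tab$charge == 2, ]
  expect_equal(filter_charge(all2), all2, ignore_attr = TRUE)
  expect_error(filter_charge(tab[, -6]), "charge")
})

test_that("normalization undoes a pure run scaling and is idempotent", {
  set.seed(1)
  base <- rlnorm(12, log(1000), 1)
  tab <- do.call(rbind, lapply(seq_along(base), function(i)
    feature_row(sprintf("f%02d", i), "background",
                c(A = base[i], B = 2 * base[i]), n_phospho = 0L)))
  n <- normalize_runs(tab, reference_run = "A")
  expect_equal(unname(n$factors["B"]), 0.5, tolerance = 1e-12)
  expect_equal(n$normalized$B, n$normalized$A, tolerance = 1e-12)
  expect_equal(unname(n$factors["A"]), 1)

  # idempotence: normalizing the normalized table gives unit factors
  n2 <- normalize_runs(n$normalized, reference_run = "A")
  expect_equal(unname(n2$factors), c(1, 1), tolerance = 1e-9)

  # single-run table: factor 1, identity
  one <- tab[, 1:9]
  n1 <- normalize_runs(one, reference_run = "A")
  expect_equal(unname(n1$factors), 1)
  expect_equal(n1$normalized$A, tab$A)
})

test_that("normalization is robust to a 10% changing minority and matches the brute-force oracle", {
  set.seed(2)
  base <- rlnorm(20, log(1000), 1)
  scales <- c(A = 1, B = 2, C = 0.5, D = 1.25, E = 0.8, F = 3)
  tab <- do.call(rbind, lapply(seq_along(base), function(i)
    feature_row(sprintf("f%02d", i), "background",
                vapply(scales, function(s) s * base[i], numeric(1)),
                n_phospho = 0L)))
  tab$B[1:2] <- tab$B[1:2] * 8          # 10% of features change in run B
  n <- normalize_runs(tab, reference_run = "A")
  expect_equal(unname(n$factors), unname(1 / scales), tolerance = 1e-9)
  # independent brute-force oracle per run
  for (r in names(scales)[-1])
    expect_equal(unname(n$factors[r]), oracle_norm_factor(tab$A, tab[[r]]),
                 tolerance = 1e-3)
})

test_that("normalization is invariant to rescaling a run and errors cleanly", {
  set.seed(3)
  base <- rlnorm(10, log(500), 1)
  tab <- do.call(rbind, lapply(seq_along(base), function(i)
    feature_row(sprintf("f%02d", i), "background",
                c(A = base[i], B = base[i] * 1.7), n_phospho = 0L)))
  n <- normalize_runs(tab, reference_run = "A")
  tab_scaled <- tab; tab_scaled$B <- tab_scaled$B * 5
  n_scaled <- normalize_runs(tab_scaled, reference_run = "A")
  expect_equal(n_scaled$normalized$B, n$normalized$B, tolerance = 1e-9)

  tab_bad <- tab
  tab_bad$B <- NA_real_
  expect_error(normalize_runs(tab_bad, reference_run = "A"), "B")
  tab_disjoint <- tab
  tab_disjoint$A[6:10] <- NA; tab_disjoint$B[1:5] <- NA
  expect_error(normalize_runs(tab_disjoint, reference_run = "A"),
               "shares no observed features")
})

test_that("eligibility rule is exact over the full presence/phospho/localization grid", {
  design <- simple_design(9)
  light_runs <- design$run_id[design$condition == "light"]
  dark_runs <- design$run_id[design$condition == "dark"]
  for (n_phospho in c(1L, 2L)) for (localized in c(TRUE, FALSE))
    for (nl in c(0L, 5L, 8L, 9L)) for (nd in c(0L, 5L, 8L, 9L)) {
      ab <- setNames(rep(NA_real_, 18), c(light_runs, dark_runs))
      if (nl > 0) ab[light_runs[seq_len(nl)]] <- 100
      if (nd > 0) ab[dark_runs[seq_len(nd)]] <- 50
      tab <- feature_row("f1", "S1", ab, n_phospho = n_phospho,
                         site_localized = localized)
      sel <- select_quantifiable(tab, design)
      expected <- n_phospho == 1L && localized && (nl == 9L || nd == 9L)
      expect_identical(sel$quantifiable, expected,
                       label = sprintf("n_phospho=%d loc=%s nl=%d nd=%d",
                                       n_phospho, localized, nl, nd))
    }
})

test_that("variant selection takes the highest mean normalized abundance, ties by feature_id", {
  design <- simple_design(3)
  runs <- design$run_id
  ab_low <- setNames(rep(100, 6), runs)
  ab_high <- setNames(rep(250, 6), runs)
  tab <- rbind(feature_row("v2", "S1", ab_high),
               feature_row("v1", "S1", ab_low))
  sel <- select_quantifiable(tab, design)
  expect_identical(sel$feature_id, "v2")

  # an ineligible variant with even higher abundance is never chosen
  tab2 <- rbind(tab, feature_row("v0", "S1", ab_high * 10, n_phospho = 2L))
  expect_identical(select_quantifiable(tab2, design)$feature_id, "v2")

  tie <- rbind(feature_row("vB", "S1", ab_high),
               feature_row("vA", "S1", ab_high))
  expect_identical(select_quantifiable(tie, design)$feature_id, "vA")
})

test_that("site quantification scales the higher condition to 100% and tests correctly", {
  design <- simple_design(3)
  runs <- design$run_id
  ab <- setNames(c(4, 4, 4, 1.01, 1, 0.99), runs)
  tab <- feature_row("f1", "S1", ab)
  q <- quantify_sites(tab, design)
  expect_equal(q$rel_light_pct, 100)
  expect_equal(q$rel_dark_pct, 25, tolerance = 0.01)
  expect_identical(q$class, "light_elevated")
  expect_identical(q$stars, "***")

  # identical samples in both conditions: degenerate t -> p = 1
  flat <- feature_row("f1", "S1", setNames(rep(7, 6), runs))
  qf <- quantify_sites(flat, design)
  expect_equal(qf$p_value, 1)
  expect_identical(qf$class, "not_light_dependent")
})

test_that("p-values equal the textbook pooled-variance t-test", {
  light <- c(10, 12, 11, 9, 10, 11, 10, 12, 11)
  dark <- c(5, 6, 5, 7, 6, 5, 6, 5, 6)
  design <- simple_design(9)
  ab <- setNames(c(light, dark), design$run_id)
  q <- quantify_sites(feature_row("f1", "S1", ab), design)
  expect_equal(q$p_value, oracle_student_t(light, dark), tolerance = 1e-12)
  expect_identical(q$stars, "***")
})

test_that("relative abundances are invariant under global rescaling", {
  design <- simple_design(4)
  set.seed(5)
  ab <- setNames(rlnorm(8, log(100), 0.3), design$run_id)
  q1 <- quantify_sites(feature_row("f1", "S1", ab), design)
  q2 <- quantify_sites(feature_row("f1", "S1", ab * 1000), design)
  expect_equal(q1$rel_light_pct, q2$rel_light_pct, tolerance = 1e-12)
  expect_equal(q1$rel_dark_pct, q2$rel_dark_pct, tolerance = 1e-12)
  expect_equal(q1$p_value, q2$p_value, tolerance = 1e-12)
})

test_that("classification tabulates classes and handles sparse conditions", {
  design <- simple_design(3)
  runs <- design$run_id
  # complete in light, single dark observation: not quantifiable
  ab <- setNames(c(5, 5, 5, 4, NA, NA), runs)
  q <- quantify_sites(feature_row("f1", "S1", ab), design)
  expect_identical(q$class, "not_quantifiable")
  expect_true(is.na(q$p_value))
  counts <- classify_sites(q)
  expect_equal(unname(counts["not_quantifiable"]), 1L, ignore_attr = TRUE)
  empty <- classify_sites(q[0, ])
  expect_true(all(empty == 0L))
})
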