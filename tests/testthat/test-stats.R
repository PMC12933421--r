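test_that("contingency tables derive their totals and reject bad input", {
  tab <- reference_counts()
  expect_equal(length(tab$row_labels), 16)
  expect_equal(unname(tab$col_totals), c(206, 3344))
  expect_equal(tab$grand_total, 3550)
  expect_equal(tab$row_totals, rowSums(tab$counts))
  expect_error(build_table(data.frame(condition_id = "a", evacuated = -1,
                                      not_evacuated = 5)), "nonnegative")
  expect_error(build_table(data.frame(condition_id = character(0),
                                      evacuated = integer(0),
                                      not_evacuated = integer(0))), "empty")
  # simulated results keep design order
  design <- lapply(c("T2", "C1", "M1"), condition_spec, n_agents = 40,
                   n_replications = 1, seed = 3)
  tab2 <- build_table(run_experiment(design,
                                     default_population_config(n_agents = 40)))
  expect_equal(tab2$row_labels, c("T2", "C1", "M1"))
})

test_that("chi-square test matches an independent textbook implementation", {
  set.seed(41)
  for (rows in c(2, 3, 6)) {
    tab <- random_table(rows)
    got <- chi_square_test(tab)
    want <- textbook_chisq(tab$counts)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
    expect_equal(got$df, want$df)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-9)
    expect_equal(unname(got$adjusted_residuals),
                 unname(want$adjusted_residuals), tolerance = 1e-9)
  }
})

test_that("chi-square is zero under identical row proportions and permutation-invariant", {
  flat <- build_table(data.frame(condition_id = c("a", "b", "c"),
                                 evacuated = c(10, 20, 30),
                                 not_evacuated = c(90, 180, 270)))
  res <- chi_square_test(flat)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_true(all(abs(res$adjusted_residuals) < 1e-9))
  tab <- reference_counts()
  perm <- build_table(data.frame(condition_id = rev(tab$row_labels),
                                 evacuated = rev(tab$counts[, 1]),
                                 not_evacuated = rev(tab$counts[, 2])))
  expect_equal(chi_square_test(perm)$statistic,
               chi_square_test(tab)$statistic, tolerance = 1e-12)
  zero <- build_table(data.frame(condition_id = c("a", "b"),
                                 evacuated = c(0, 0),
                                 not_evacuated = c(5, 5)))
  expect_error(chi_square_test(zero), "marginal")
})

test_that("adjusted residuals recombine to zero column deviations", {
  res <- chi_square_test(reference_counts())
  tab <- reference_counts()
  n <- tab$grand_total
  den <- sqrt(res$expected * outer(1 - tab$row_totals / n,
                                   1 - tab$col_totals / n))
  expect_true(all(abs(colSums(res$adjusted_residuals * den)) < 1e-9))
})

test_that("framing rates pool conditions and validate the mapping", {
  rates <- framing_rates(reference_counts())
  r <- stats::setNames(rates$rate_pct, rates$framing)
  expect_equal(unname(r["fear"]), 100 * 6 / 666, tolerance = 1e-12)
  # a single-condition group equals that row's percentage
  single_map <- c(stats::setNames(rep("rest", 15),
                                  setdiff(reference_counts()$row_labels, "M2")),
                  M2 = "m2_alone")
  r2 <- framing_rates(reference_counts(), single_map)
  expect_equal(r2$rate_pct[r2$framing == "m2_alone"], 100 * 44 / 222,
               tolerance = 1e-12)
  # an all-zero group reports 0%
  zero_tab <- build_table(data.frame(condition_id = c("a", "b"),
                                     evacuated = c(0, 5),
                                     not_evacuated = c(10, 5)))
  rz <- framing_rates(zero_tab, c(a = "none", b = "some"))
  expect_equal(rz$rate_pct[rz$framing == "none"], 0)
  expect_error(framing_rates(reference_counts(), c(C1 = "control")),
               "no framing mapping")
})

test_that("grouped logistic odds ratios equal the closed-form cross-product ratio", {
  set.seed(43)
  for (i in 1:5) {
    tab <- random_table(4)
    map <- stats::setNames(c("ref", "g1", "g2", "g2"), tab$row_labels)
    fit <- fit_grouped_logistic(tab, map, reference = "ref")
    pooled <- rbind(ref = tab$counts[1, ],
                    g1 = tab$counts[2, ],
                    g2 = colSums(tab$counts[3:4, ]))
    for (g in c("g1", "g2")) {
      cpr <- (pooled[g, 1] * pooled["ref", 2]) /
        (pooled[g, 2] * pooled["ref", 1])
      expect_equal(fit$estimates$odds_ratio[fit$estimates$framing == g],
                   unname(cpr), tolerance = 1e-8)
    }
    expect_true(all(fit$estimates$ci_low <= fit$estimates$odds_ratio &
                      fit$estimates$odds_ratio <= fit$estimates$ci_high))
  }
})

test_that("identical group rates give an odds ratio of exactly one", {
  tab <- build_table(data.frame(condition_id = c("a", "b"),
                                evacuated = c(12, 24),
                                not_evacuated = c(48, 96)))
  fit <- fit_grouped_logistic(tab, c(a = "ref", b = "g"), reference = "ref")
  expect_equal(fit$estimates$odds_ratio, 1, tolerance = 1e-10)
})

test_that("zero cells trigger the continuity-corrected fallback with a warning", {
  tab <- build_table(data.frame(condition_id = c("a", "b"),
                                evacuated = c(5, 0),
                                not_evacuated = c(95, 100)))
  expect_warning(fit <- fit_grouped_logistic(tab, c(a = "ref", b = "g"),
                                             reference = "ref"),
                 "Haldane")
  est <- fit$estimates
  expect_true(est$continuity_corrected)
  expect_equal(est$odds_ratio, (0.5 * 95.5) / (100.5 * 5.5), tolerance = 1e-12)
  # a reference with an empty outcome column is refused outright
  expect_error(fit_grouped_logistic(tab, c(a = "g", b = "ref"),
                                    reference = "ref"), "reference")
})

test_that("sample-size computation matches the noncentral chi-square oracle", {
  expect_equal(required_sample_size(w = 0.3, alpha = 0.05, power = 0.80,
                                    df = 1), 88L)
  # per-group size for a six-group design at 95% power
  expect_equal(required_sample_size(w = 0.3, alpha = 0.05, power = 0.95,
                                    df = 5), 220L)
  # huge effects need almost no observations
  expect_lte(required_sample_size(w = 5, alpha = 0.05, power = 0.80, df = 1), 2L)
  # n scales approximately as 1/w^2
  ratio <- required_sample_size(0.1, 0.05, 0.8, 1) /
    required_sample_size(0.2, 0.05, 0.8, 1)
  expect_gt(ratio, 3.8); expect_lt(ratio, 4.2)
  expect_error(required_sample_size(1e-5, 0.05, 0.8, 1, n_max = 1000),
               "unreachable")
})
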