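test_that("interaction index is the signed relative deviation", {
  # coculture equal to the monoculture average (values on the scale of the
  # two slow species' AUC summaries) -> exactly 0
  expect_equal(interaction_index(17.1, 18.7, 15.5), 0)
  expect_equal(interaction_index(12, 10, 10), 0.2)
  # symmetry under monoculture swap
  expect_equal(interaction_index(20, 30, 10), interaction_index(20, 10, 30))
  # zero monoculture average -> undefined
  expect_true(is.na(interaction_index(1, 0, 0)))
})

test_that("classifier assigns the trivial separations to B and C", {
  m1 <- c(20, 20.1, 19.9)
  m2 <- c(25, 25.2, 24.8)
  b <- classify_coculture(c(30, 30.1, 29.9, 30.2), m1, m2)
  expect_equal(b$outcome, "B")
  expect_gt(b$index, 0)
  c_ <- classify_coculture(c(10, 10.1, 9.9, 10.05), m1, m2)
  expect_equal(c_$outcome, "C")
  expect_lt(c_$index, 0)
  # between the monocultures but off the average -> D
  d <- classify_coculture(c(24, 24.1, 23.9, 24.05), m1, m2)
  expect_equal(d$outcome, "D")
  # all three p-values always reported
  for (r in list(b, c_, d)) {
    expect_true(all(is.finite(c(r$p_avg, r$p_max, r$p_min))))
  }
  # symmetry: swapping monocultures changes neither outcome nor index
  b2 <- classify_coculture(c(30, 30.1, 29.9, 30.2), m2, m1)
  expect_equal(b2$outcome, b$outcome)
  expect_equal(b2$index, b$index)
})

test_that("classifier calls A at ~ the nominal rate under the null", {
  set.seed(77)
  n_sim <- 400
  out <- replicate(n_sim, {
    m1 <- rnorm(3, 20, 0.5)
    m2 <- rnorm(3, 24, 0.5)
    co <- rnorm(4, 22, 0.5) # true mean = monoculture average
    classify_coculture(co, m1, m2)$outcome
  })
  a_rate <- mean(out == "A")
  se <- sqrt(0.95 * 0.05 / n_sim)
  expect_gte(a_rate, 1 - 2 * 0.05)
  expect_lt(abs(a_rate - 0.95), 3 * se + 0.01)
  expect_lte(mean(out == "B"), 0.025 + 2 * sqrt(0.025 * 0.975 / n_sim))
  expect_lte(mean(out == "C"), 0.025 + 2 * sqrt(0.025 * 0.975 / n_sim))
})

test_that("classifier p-values equal an independent Welch computation", {
  set.seed(12)
  for (i in 1:100) {
    m1 <- rnorm(3, 20, 1)
    m2 <- rnorm(4, 22, 2)
    co <- rnorm(4, 21, 1.5)
    cl <- classify_coculture(co, m1, m2)
    npair <- min(length(m1), length(m2))
    avg <- (m1[1:npair] + m2[1:npair]) / 2
    hi <- if (mean(m1) >= mean(m2)) m1 else m2
    lo <- if (mean(m1) >= mean(m2)) m2 else m1
    expect_equal(cl$p_avg, welch_oracle(co, avg, "two.sided"),
                 tolerance = 1e-10)
    expect_equal(cl$p_max, welch_oracle(co, hi, "greater"),
                 tolerance = 1e-10)
    expect_equal(cl$p_min, welch_oracle(co, lo, "less"),
                 tolerance = 1e-10)
  }
})

test_that("effect direction follows the index sign, inverted for latency", {
  expect_equal(effect_direction("auc", 0.2, "D"), "positive")
  expect_equal(effect_direction("latency", 0.3, "D"), "negative")
  expect_equal(effect_direction("latency", -0.3, "B"), "positive")
  expect_equal(effect_direction("r", -0.1, "A"), "neutral")
  expect_equal(effect_direction("max_od", -0.1, "C"), "negative")
})

test_that("analyze_interactions covers every pair exactly once per parameter", {
  ds <- mini_dataset(seed = 31)
  params <- dplyr::inner_join(ds$layout, fit_growth(ds$curves), by = "well")
  rec <- analyze_interactions(params)
  n_pairs <- choose(6, 2)
  counts <- table(rec$parameter)
  expect_true(all(counts == n_pairs))
  # exhaustive and exclusive outcome classes
  expect_true(all(rec$outcome %in% c("A", "B", "C", "D")))
  s <- outcome_summary(rec)
  totals <- tapply(s$n, s$parameter, sum)
  expect_true(all(totals == n_pairs))
  expect_true(all(abs(tapply(s$percent, s$parameter, sum) - 100) < 1e-9))
})

test_that("planted strong effects are recovered as B / C", {
  set.seed(55)
  times <- seq(0, 24, 0.5)
  mono1 <- replicate(3, {
    od <- pmax(curve_with_auc(30) + rnorm(49, 0, 0.01), 0)
    extract_growth_parameters(times, od)$auc_odh
  })
  mono2 <- replicate(3, {
    od <- pmax(curve_with_auc(26) + rnorm(49, 0, 0.01), 0)
    extract_growth_parameters(times, od)$auc_odh
  })
  co_boost <- replicate(4, {
    od <- pmax(curve_with_auc(28 * 1.3) + rnorm(49, 0, 0.01), 0)
    extract_growth_parameters(times, od)$auc_odh
  })
  co_drop <- replicate(4, {
    od <- pmax(curve_with_auc(28 * 0.7) + rnorm(49, 0, 0.01), 0)
    extract_growth_parameters(times, od)$auc_odh
  })
  up <- classify_coculture(co_boost, mono1, mono2)
  dn <- classify_coculture(co_drop, mono1, mono2)
  expect_equal(up$outcome, "B")
  expect_gt(up$index, 0)
  expect_equal(dn$outcome, "C")
  expect_lt(dn$index, 0)
})
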