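times <- seq(0, 24, by = 0.5)

test_that("logistic fit recovers exact-model parameters", {
  od <- logistic_od(times, K = 2.0, r = 0.4, N0 = 0.01)
  f <- fit_logistic(times, od)
  expect_true(f$converged)
  expect_equal(f$K, 2.0, tolerance = 1e-6)
  expect_equal(f$r, 0.4, tolerance = 1e-6)
  expect_equal(f$N0, 0.01, tolerance = 1e-6)

  # property: recovery across the design's parameter ranges (noiseless)
  set.seed(101)
  for (i in 1:40) {
    K <- runif(1, 1, 2.5)
    r <- runif(1, 0.15, 0.5)
    N0 <- runif(1, 0.005, 0.05)
    f <- fit_logistic(times, logistic_od(times, K, r, N0))
    expect_lt(max(abs(c(f$K - K, f$r - r, f$N0 - N0) / c(K, r, N0))), 1e-5)
  }
})

test_that("flat curves are flagged non-growing, not fitted", {
  f <- fit_logistic(times, rep(0.05, length(times)))
  expect_false(f$converged)
  expect_identical(f$note, "non_growing")
  expect_true(is.na(f$r))
})

test_that("growth rate is recovered under plate-reader noise", {
  set.seed(202)
  errs <- replicate(60, {
    od <- pmax(logistic_od(times, 2, 0.4, 0.01) + rnorm(length(times), 0, 0.02), 0)
    f <- fit_logistic(times, od)
    abs(f$r - 0.4) / 0.4
  })
  expect_lt(median(errs), 0.05)
})

test_that("closed-form AUC matches adaptive quadrature and scales", {
  f <- list(K = 2.0, r = 0.4, N0 = 0.1)
  q <- integrate(function(x) logistic_od(x, 2, 0.4, 0.1), 0, 24,
                 rel.tol = 1e-10)$value
  expect_equal(logistic_auc(f, 24), q, tolerance = 1e-6)

  # constant curve at K: AUC = K * t_end
  expect_equal(logistic_auc(list(K = 1, r = 0.3, N0 = 1), 24), 24)

  # doubling K doubles AUC at fixed r and N0/K ratio
  a1 <- logistic_auc(list(K = 1, r = 0.3, N0 = 0.01), 24)
  a2 <- logistic_auc(list(K = 2, r = 0.3, N0 = 0.02), 24)
  expect_equal(a2, 2 * a1, tolerance = 1e-12)

  expect_error(logistic_auc(f, 0), "positive")

  # dense trapezoid on the fitted curve agrees to < 1e-3 relative
  tt <- seq(0, 24, 0.01)
  emp <- sum(diff(tt) * (head(logistic_od(tt, 2, 0.4, 0.1), -1) +
                           tail(logistic_od(tt, 2, 0.4, 0.1), -1)) / 2)
  expect_lt(abs(logistic_auc(f, 24) - emp) / emp, 1e-3)
})

test_that("latency finds the threshold crossing", {
  # already above the threshold at t = 0
  expect_equal(latency(times, seq(0.3, 2, length.out = length(times)), 0.25), 0)
  # never exceeded -> undefined
  expect_true(is.na(latency(times, rep(0.1, length(times)), 0.25)))

  # interpolated crossing matches the closed-form root of the logistic
  K <- 2; r <- 0.43; N0 <- 0.01
  od <- logistic_od(times, K, r, N0)
  t_true <- log(((K - N0) / N0) * 0.25 / (K - 0.25)) / r
  expect_equal(latency(times, od, 0.25, interpolate = TRUE), t_true,
               tolerance = 0.01)
  # step-function variant lands on the sampling grid, at/after the root
  t_step <- latency(times, od, 0.25, interpolate = FALSE)
  expect_true(t_step %in% times && t_step >= t_true)

  # monotone: higher threshold never gives a smaller latency
  set.seed(33)
  od_noisy <- pmax(od + rnorm(length(times), 0, 0.02), 0)
  ths <- seq(0.1, 1.5, by = 0.05)
  lats <- vapply(ths, function(th) latency(times, od_noisy, th), numeric(1))
  lats <- lats[!is.na(lats)]
  expect_true(all(diff(lats) >= 0))
})

test_that("max_od reports the in-window peak, not the final value", {
  od <- c(seq(0.1, 1.9, length.out = 40), seq(1.85, 1.7, length.out = 9))
  expect_equal(max_od(times, od), 1.9)
  # window restriction
  expect_equal(max_od(times, od, window_h = 10), od[times <= 10][21])
})

test_that("extract_growth_parameters bundles all four parameters", {
  od <- logistic_od(times, K = 2, r = 0.4, N0 = 0.01)
  g <- extract_growth_parameters(times, od)
  expect_equal(g$r_per_h, 0.4, tolerance = 1e-6)
  expect_equal(g$max_od, max(od))
  expect_equal(g$auc_odh, logistic_auc(list(K = 2, r = 0.4, N0 = 0.01), 24),
               tolerance = 1e-5)
  expect_equal(g$latency_h,
               latency(times, od, 0.25), tolerance = 1e-12)

  # non-growing curve: direct measures present, fit-based ones missing
  g2 <- extract_growth_parameters(times, rep(0.06, length(times)))
  expect_true(is.na(g2$r_per_h) && is.na(g2$auc_odh))
  expect_equal(g2$max_od, 0.06)
  expect_true(is.na(g2$latency_h))
  expect_false(g2$converged)

  # curves beyond the window are truncated before everything
  t30 <- seq(0, 30, 0.5)
  od30 <- logistic_od(t30, 2, 0.4, 0.01)
  g3 <- extract_growth_parameters(t30, od30)
  expect_equal(g3$auc_empirical_odh,
               trapz <- sum(diff(times) * (head(od30[t30 <= 24], -1) +
                                             tail(od30[t30 <= 24], -1)) / 2))
})
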