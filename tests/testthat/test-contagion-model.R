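test_that("excitation probability matches the integrated exponential kernel", {
  # independent oracle: numerically integrate the delay density over each day
  oracle <- function(d, t_ex) {
    stats::integrate(function(x) exp(-x / t_ex) / t_ex, d - 1, d,
                     rel.tol = 1e-12)$value
  }
  for (t_ex in c(0.5, 2, 13, 60)) {
    for (d in c(1, 2, 5, 30)) {
      expect_equal(excitation_probability(d, t_ex), oracle(d, t_ex),
                   tolerance = 1e-10)
    }
  }
  expect_equal(excitation_probability(1, 13), 1 - exp(-1 / 13))
})

test_that("excitation kernel is a normalized, decreasing distribution", {
  for (t_ex in c(0.7, 13, 45)) {
    p <- excitation_probability(1:200, t_ex)
    expect_true(all(diff(p) < 0))
    expect_true(all(p > 0 & p < 1))
    # partial sums telescope to 1 - exp(-D/T)
    for (D in c(1, 10, 100)) {
      expect_equal(sum(excitation_probability(1:D, t_ex)),
                   1 - exp(-D / t_ex), tolerance = 1e-12)
    }
  }
  # T -> 0+: all excitation lands on the very next day
  expect_equal(excitation_probability(1, 1e-8), 1, tolerance = 1e-12)
  expect_error(excitation_probability(0, 13), "d must be")
  expect_error(excitation_probability(1, -2), "t_excite")
})

test_that("weekday weights: definition, uniform case, chi-square oracle", {
  # 2007-01-01 is a Monday; 21 days = 3 full weeks
  mon <- as.Date("2007-01-01")
  all_sat <- counts_fixture(rep(c(0, 0, 0, 0, 0, 2, 0), 3), origin = mon)
  w <- weekday_weights(all_sat)
  expect_equal(unname(w$weights["Saturday"]), 7)
  expect_equal(sum(w$weights), 7)

  unif <- counts_fixture(rep(1L, 21), origin = mon)
  wu <- weekday_weights(unif)
  expect_equal(unname(wu$weights), rep(1, 7))
  expect_equal(wu$statistic, 0)
  expect_equal(wu$p_value, 1)

  # counts 10,10,10,10,10,10,24 by weekday; oracle = stats::chisq.test
  skew <- counts_fixture(rep(c(10, 10, 10, 10, 10, 10, 24), 1),
                         origin = mon)
  ws <- weekday_weights(skew)
  ref <- stats::chisq.test(c(10, 10, 10, 10, 10, 10, 24))
  expect_equal(ws$statistic, unname(ref$statistic))
  expect_equal(ws$statistic, 14)
  expect_equal(ws$p_value, ref$p.value)

  expect_error(weekday_weights(counts_fixture(rep(0L, 14), origin = mon)),
               "at least one event")
})

test_that("baseline series: constant, smoother fixed point, edge handling", {
  dc <- counts_fixture(c(1, 0, 0, 2, 0))
  expect_equal(baseline_series(dc, baseline_spec("constant")), rep(0.6, 5))

  flat <- counts_fixture(rep(3L, 20))
  for (w in c(3L, 7L)) {
    expect_equal(baseline_series(flat, baseline_spec("running_mean", w)),
                 rep(3, 20))
  }

  spike <- counts_fixture(c(0, 0, 4, 0, 0))
  expect_equal(baseline_series(spike, baseline_spec("running_mean", 3L)),
               c(0, 4 / 3, 4 / 3, 4 / 3, 0))

  expect_error(baseline_series(spike, baseline_spec("running_mean", 10L)),
               "window")
})

test_that("weekday-adjusted baseline multiplies by the day's weight", {
  mon <- as.Date("2007-01-01")
  dc <- counts_fixture(rep(1L, 14), origin = mon)
  w <- c(2, rep(5 / 6, 6)) # average exactly 1, Monday doubled
  b <- baseline_series(dc, baseline_spec("running_mean_weekday",
                                         window_days = 7L,
                                         weekday_weights = w))
  expect_equal(b[c(1, 8)], c(2, 2))
  expect_equal(b[2], 5 / 6)
})

test_that("expected events follows the conditional-intensity definition", {
  params <- contagion_params(0.4, 13)
  b <- rep(0.1, 10)
  # single event on day 0 (index 1)
  one <- counts_fixture(c(1, rep(0, 9)))
  mu <- intensity_mu(expected_events(one, params, b))
  expect_equal(mu[2], 0.1 + 0.4 * (1 - exp(-1 / 13)))
  expect_equal(mu[5], 0.1 + 0.4 * excitation_probability(4, 13))
  expect_equal(mu[1], 0.1) # nothing before the first event

  # two events on day 0 double the contagion part (linearity)
  two <- counts_fixture(c(2, rep(0, 9)))
  mu2 <- intensity_mu(expected_events(two, params, b))
  expect_equal(mu2 - b, 2 * (mu - b))

  # zero coupling: intensity is exactly the baseline
  mu0 <- intensity_mu(expected_events(one, contagion_params(0, 13), b))
  expect_equal(mu0, b)
})

test_that("recursive evaluation equals the brute-force kernel sum", {
  # independent oracle: direct double sum over event pairs
  set.seed(19)
  k <- rpois(60, 0.3)
  dc <- counts_fixture(k)
  params <- contagion_params(0.35, 6)
  mu <- intensity_mu(expected_events(dc, params, rep(0.05, 60)))
  brute <- sapply(seq_len(60), function(n) {
    if (n == 1) return(0.05)
    prior <- seq_len(n - 1)
    0.05 + 0.35 * sum(k[prior] * excitation_probability(n - prior, 6))
  })
  expect_equal(mu, brute, tolerance = 1e-12)
})

test_that("per-event excitation mass within the span never exceeds n_secondary", {
  k <- c(1, rep(0, 199))
  for (t_ex in c(2, 13, 50)) {
    contag <- intensity_mu(expected_events(
      counts_fixture(k), contagion_params(0.3, t_ex), rep(0, 200)))
    expect_lte(sum(contag), 0.3 + 1e-12)
    # approaches n_secondary as the span extends past the event
    expect_equal(sum(contag), 0.3 * (1 - exp(-199 / t_ex)),
                 tolerance = 1e-10)
  }
})

test_that("rescale_to_total enforces the total-expected constraint", {
  dc <- counts_fixture(c(1, 1, 0, 0))
  it <- expected_events(dc, contagion_params(0.5, 3), rep(0.25, 4))
  sc <- sum(it$contagion)
  out <- rescale_to_total(it, 2)
  expect_equal(sum(intensity_mu(out)), 2, tolerance = 1e-12)
  expect_equal(out$contagion, it$contagion) # contagion untouched
  expect_equal(sum(out$baseline), 2 - sc, tolerance = 1e-12)

  # n_secondary = 0: pure baseline scaling
  it0 <- expected_events(dc, contagion_params(0, 3), rep(0.25, 4))
  expect_equal(rescale_to_total(it0, 2)$baseline, rep(0.5, 4))

  # infeasible point signals a typed condition
  big <- expected_events(counts_fixture(c(5, 5, 0, 0)),
                         contagion_params(0.9, 1), rep(0.1, 4))
  expect_error(rescale_to_total(big, 1), class = "selfexcite_infeasible")

  set.seed(5)
  for (i in 1:10) {
    k <- rpois(50, 0.5)
    if (sum(k) < 2) next
    it <- expected_events(counts_fixture(k), contagion_params(0.3, 8),
                          rep(0.2, 50))
    expect_equal(sum(intensity_mu(rescale_to_total(it, sum(k)))), sum(k),
                 tolerance = 1e-9 * sum(k))
  }
})

test_that("intensity is invariant to splitting a day's events into units", {
  # k events on one day contribute exactly k unit kernel terms; compare a
  # 3-event day against the same history built as three 1-event entries
  params <- contagion_params(0.5, 5)
  b <- rep(0.1, 15)
  mu_multi <- intensity_mu(expected_events(
    counts_fixture(c(0, 3, rep(0, 13))), params, b))
  unit_sum <- sapply(seq_len(15), function(n) {
    if (n <= 2) return(b[n])
    b[n] + 0.5 * 3 * excitation_probability(n - 2, 5)
  })
  expect_equal(mu_multi, unit_sum, tolerance = 1e-12)
})
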