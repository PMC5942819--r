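test_that("null fit: constant baseline rescales to the observed rate", {
  set.seed(11)
  k <- rpois(400, 0.08)
  dc <- counts_fixture(k)
  f <- fit_null(dc)
  expect_equal(f$n_params, 0L)
  expect_true(f$converged)
  # mu constant at total/M: negll has closed form
  mu <- sum(k) / 400
  expect_equal(f$negloglik, sum(mu - ifelse(k > 0, k * log(mu), 0)),
               tolerance = 1e-10)
  expect_error(fit_null(counts_fixture(rep(0L, 10))), "zero events")
})

test_that("contagion fit nests the null and recovers a planted signal", {
  cfg <- sim_config(seed = 202)
  es <- simulate_contagion(cfg, seed = 202)
  dc <- to_daily_counts(es)
  null_fit <- fit_null(dc)
  alt_fit <- fit_contagion(dc)
  expect_true(alt_fit$converged)
  expect_lte(alt_fit$negloglik, null_fit$negloglik + 1e-6)
  expect_gte(alt_fit$params$n_secondary, 0)
  expect_gt(alt_fit$params$t_excite, 0)
  expect_equal(alt_fit$n_params, 2L)
})

test_that("fitting null data pushes n_secondary to the boundary region", {
  # median over a few null datasets sits at/near zero coupling
  est <- sapply(1:5, function(i) {
    es <- simulate_null_uniform(150, 2000, seed = 400 + i)
    fit_contagion(to_daily_counts(es))$params$n_secondary
  })
  expect_lte(median(est), 0.06)
})

test_that("negbin contagion fit runs and degenerates towards Poisson", {
  cfg <- sim_config(span_days = 1500L, n_events_null = 150L, seed = 77)
  es <- simulate_contagion(cfg, seed = 77)
  dc <- to_daily_counts(es)
  f <- fit_contagion(dc, likelihood = "negbin")
  expect_true(f$converged)
  expect_equal(f$n_params, 3L)
  # Poisson-generated daily counts: fitted NB2 dispersion should be small
  expect_lt(f$dispersion, 0.5)
})

test_that("likelihood ratio test: algebra and chi-square reference", {
  mk <- function(negll, n_params, model) {
    structure(list(negloglik = negll, n_params = n_params,
                   likelihood = "poisson", model = model,
                   converged = TRUE, params = NULL, dispersion = NULL),
              class = "fit_result")
  }
  eq <- lrt(mk(100, 0, "null"), mk(100, 2, "contagion"))
  expect_equal(eq$lrt_stat, 0)
  expect_equal(eq$p_value, 1)

  cmp <- lrt(mk(103, 0, "null"), mk(100, 2, "contagion"))
  expect_equal(cmp$lrt_stat, 6)
  expect_equal(cmp$df, 2L)
  expect_equal(cmp$p_value, exp(-3), tolerance = 1e-12) # chisq_2 survival
  expect_equal(cmp$aic_null, 206)
  expect_equal(cmp$aic_alt, 204)

  # tiny negative slack is clamped, larger warns
  expect_equal(lrt(mk(100 - 1e-9, 0, "null"),
                   mk(100, 2, "contagion"))$lrt_stat, 0)
  nb <- mk(100, 1, "null"); nb$likelihood <- "negbin"
  expect_error(lrt(nb, mk(99, 2, "contagion")), "same likelihood")
})

test_that("AIC counts every fitted parameter", {
  f <- structure(list(negloglik = 100, n_params = 2L), class = "fit_result")
  expect_equal(aic(f), 204)
  f$n_params <- 3L
  expect_equal(aic(f), 206)
})

test_that("profile CI brackets the estimate and widens with the level", {
  cfg <- sim_config(seed = 55)
  es <- simulate_contagion(cfg, seed = 55)
  dc <- to_daily_counts(es)
  spec <- baseline_spec("constant")
  f <- fit_contagion(dc, spec)
  ci95 <- profile_ci(dc, spec, f, "n_secondary", 0.95)
  expect_lte(ci95$lower, f$params$n_secondary)
  expect_gte(ci95$upper, f$params$n_secondary)
  ci99 <- profile_ci(dc, spec, f, "n_secondary", 0.99)
  expect_lte(ci99$lower, ci95$lower + 1e-6)
  expect_gte(ci99$upper, ci95$upper - 1e-6)
})

test_that("gap-histogram AIC: scaling, dispersion tally, shape ordering", {
  obs <- gap_histogram(c(rep(0L, 12), rep(1L, 6), rep(2L, 2), rep(9L, 4)),
                       d_max = 4)
  n_bins <- length(obs$counts) + 1L
  match_p <- c(obs$counts, obs$overflow) / obs$total
  res <- gap_histogram_aic(obs, match_p, n_params = 2)
  expect_equal(sum(res$expected), obs$total, tolerance = 1e-12)
  expect_equal(res$n_params, 3L) # dispersion tallied on top
  # saturated prediction with alpha -> 0: multinomial-Poisson bound
  expect_equal(res$aic,
               2 * 3 + 2 * negbin_negloglik(res$expected,
                                            c(obs$counts, obs$overflow), 0),
               tolerance = 1e-6)

  # a prediction matching the observed shape never scores worse
  off_p <- rev(match_p)
  res_off <- gap_histogram_aic(obs, off_p, n_params = 2)
  expect_lte(res$negloglik, res_off$negloglik)

  # zero predicted mass under observed counts is an infinite penalty
  zero_p <- c(0, match_p[-1] / sum(match_p[-1]))
  expect_identical(gap_histogram_aic(obs, zero_p, n_params = 2)$aic, Inf)

  expect_error(gap_histogram_aic(obs, match_p[-1], n_params = 2), "overflow")
  expect_error(gap_histogram_aic(obs, match_p * 2, n_params = 2),
               "normalized")
})

test_that("brute-force check: better-matching prediction has lower negloglik", {
  # exhaustive small 3-bin cases
  obs_counts <- c(10L, 6L, 4L)
  obs <- gap_histogram(rep(0:2, obs_counts), d_max = 1)
  truth <- c(obs$counts, obs$overflow) / obs$total
  set.seed(9)
  for (i in 1:20) {
    p <- as.numeric(stats::rmultinom(1, 60, truth) + 1)
    p <- p / sum(p)
    a <- gap_histogram_aic(obs, truth, 1)
    b <- gap_histogram_aic(obs, p, 1)
    expect_lte(a$negloglik, b$negloglik + 1e-9)
  }
})

test_that("the total-expected constraint holds at arbitrary parameter points", {
  set.seed(91)
  k <- rpois(300, 0.1)
  dc <- counts_fixture(k)
  b <- baseline_series(dc, baseline_spec("constant"))
  for (i in 1:10) {
    ns <- runif(1, 0, 0.9); te <- runif(1, 1, 40)
    it <- expected_events(dc, contagion_params(ns, te), b)
    mu <- intensity_mu(rescale_to_total(it, sum(k)))
    expect_equal(sum(mu), sum(k), tolerance = 1e-9 * max(sum(k), 1))
  }
})
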