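#' Simulation configuration
#'
#' Defaults describe the study conditions the toolkit is calibrated around:
#' 232 events over an eight-year (2,922-day) span, contagion parameters
#' `n_secondary = 0.28`, `t_excite = 13` days, and 1,000 Monte Carlo
#' replicates. The contagion simulator's constant baseline rate defaults to
#' `(n_events_null / span_days) * (1 - n_secondary)`: under a subcritical
#' branching process each baseline event generates on average
#' `1 / (1 - n_secondary)` events in total, so this calibration makes the
#' expected total event count match the null target.
#'
#' @param span_days length of the simulated span in days.
#' @param n_events_null number of events for the null simulators, and the
#'   expected total for the calibrated contagion simulator.
#' @param params a [contagion_params()] for the contagion simulator.
#' @param baseline_rate constant baseline events/day for the contagion
#'   simulator; `NULL` (default) applies the branching calibration above.
#' @param n_reps Monte Carlo replicates for ensemble summaries.
#' @param seed master seed; per-replicate seeds are derived from it by a
#'   counter scheme so ensembles are reproducible and order-independent.
#' @param origin calendar date of day 0 for simulated series.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(span_days = 2922L, n_events_null = 232L,
                       params = contagion_params(0.28, 13),
                       baseline_rate = NULL, n_reps = 1000L, seed = 1L,
                       origin = as.Date("2006-01-01")) {
  span_days <- as.integer(span_days)
  n_events_null <- as.integer(n_events_null)
  stopifnot(span_days >= 1L, n_events_null >= 1L, n_reps >= 1L,
            inherits(params, "contagion_params"))
  if (is.null(baseline_rate))
    baseline_rate <- n_events_null / span_days * (1 - params$n_secondary)
  stopifnot(baseline_rate > 0)
  structure(list(span_days = span_days, n_events_null = n_events_null,
                 params = params, baseline_rate = baseline_rate,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 origin = as.Date(origin)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: span %d days, %d null events, n_secondary %.3g, ",
    "t_excite %.3g d,\n  baseline %.5g events/day, %d reps, seed %d\n"),
    x$span_days, x$n_events_null, x$params$n_secondary, x$params$t_excite,
    x$baseline_rate, x$n_reps, x$seed))
  invisible(x)
}

# counter-based per-replicate seed; stays below 2^31
derive_seed <- function(seed, rep) {
  as.integer(((seed %% 100003) * 20011 + rep * 7919) %% 2147483647)
}

#' Simulate the uniform-in-time null model
#'
#' Places `n_events` continuous event times uniformly on `[0, span_days)`,
#' floors them to integer days and sorts them — the null in which events
#' carry no memory of each other, conditioned on the observed event count.
#'
#' @param n_events number of events (`>= 1`).
#' @param span_days span length in days (`>= 1`).
#' @param seed optional integer seed (set just before drawing).
#' @param origin calendar date of day 0.
#' @return an `event_series`.
#' @export
simulate_null_uniform <- function(n_events, span_days, seed = NULL,
                                  origin = as.Date("2006-01-01")) {
  stopifnot(n_events >= 1, span_days >= 1)
  if (!is.null(seed)) set.seed(seed)
  days <- sort(floor(stats::runif(n_events, 0, span_days)))
  event_series(origin + days, span_start = origin,
               span_end = origin + span_days - 1L)
}

#' Simulate the null model by exponential inter-event draws
#'
#' Draws the time between successive events from an Exponential distribution
#' — the equivalent statement of the uniform-in-time null — then bins the
#' event times into integer days. Unlike [simulate_null_uniform()] the span
#' is not held fixed, so the sampling variability of per-realization gap
#' statistics (in particular the spread of the sample variance across
#' replicates) is that of an unconstrained renewal process; this is the
#' generator ensemble summaries use for the null.
#'
#' @param n_events number of events (`>= 2` for non-empty gaps).
#' @param span_days nominal span; sets the mean gap via `mean_gap`.
#' @param mean_gap mean of the exponential inter-event time in days; default
#'   `span_days / (n_events + 1)`, the expected spacing of `n_events` uniform
#'   points on the span.
#' @param seed optional integer seed.
#' @param origin calendar date of day 0.
#' @return an `event_series` (its span stretches to the last event when the
#'   drawn gaps overrun the nominal span).
#' @export
simulate_null_exponential <- function(n_events, span_days,
                                      mean_gap = span_days / (n_events + 1),
                                      seed = NULL,
                                      origin = as.Date("2006-01-01")) {
  stopifnot(n_events >= 1, mean_gap > 0)
  if (!is.null(seed)) set.seed(seed)
  t <- cumsum(c(stats::runif(1), stats::rexp(n_events - 1, 1 / mean_gap)))
  days <- floor(t)
  event_series(origin + days, span_start = origin,
               span_end = origin + max(span_days, max(days) + 1) - 1L)
}

#' Forward simulation of the self-excitation contagion process
#'
#' Day-by-day Monte Carlo: starting from an empty history, each day's
#' expected count is the conditional intensity (baseline plus the excitation
#' contributed by all previously simulated events through the day-binned
#' exponential kernel), and the day's event count is drawn from a Poisson
#' distribution with that mean. The excitation state is carried by the exact
#' kernel recursion, so the cost is linear in the span.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (overrides `config$seed`).
#' @param baseline optional numeric baseline vector of length
#'   `config$span_days`; default a constant at `config$baseline_rate`.
#' @return an `event_series`, or `NULL` when the realization contains no
#'   events.
#' @export
simulate_contagion <- function(config = sim_config(), seed = NULL,
                               baseline = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  m <- config$span_days
  if (is.null(baseline)) baseline <- rep(config$baseline_rate, m)
  if (length(baseline) != m) stop("baseline length must equal span_days")
  ns <- config$params$n_secondary
  if (ns >= 1)
    warning("n_secondary >= 1: supercritical regime, expected counts grow ",
            "without bound")
  q <- exp(-1 / config$params$t_excite)
  w <- ns * (1 - q)
  k <- integer(m)
  s <- 0
  for (t in seq_len(m)) {
    k[t] <- stats::rpois(1L, baseline[t] + w * s)
    s <- q * s + k[t]
  }
  if (sum(k) == 0L) return(NULL)
  event_series(config$origin + rep(seq_len(m) - 1L, k),
               span_start = config$origin,
               span_end = config$origin + m - 1L)
}

#' Ensemble summary of inter-event gap statistics
#'
#' Runs a simulator `n_reps` times with per-replicate seeds derived from the
#' master seed, computes each realization's gap mean, gap variance and
#' fraction of gaps within `cutoff_days`, and reports ensemble averages with
#' empirical 2.5th/97.5th percentile bands, plus the pooled
#' fraction-within-cutoff across all replicates. Replicates with fewer than
#' two events have no gaps and are skipped (and counted).
#'
#' @param generator `"null"` (exponential inter-event draws, see
#'   [simulate_null_exponential()]), `"null_uniform"`, `"contagion"`, or a
#'   function of one argument (the per-replicate seed) returning an
#'   `event_series` (or `NULL`).
#' @param config a [sim_config()].
#' @param cutoff_days cutoff for the fraction-within statistic (default 14).
#' @return an object of class `ensemble_summary`: per-replicate vectors
#'   `gap_mean`, `gap_var`, `frac_within`; their means `mean_gap_mean`,
#'   `mean_gap_var`, `mean_frac_within`; percentile bands `band_*`
#'   (2.5%/97.5%); `pooled_frac_within`; `n_reps`, `n_skipped`, `seed`,
#'   `cutoff_days`.
#' @export
ensemble_gap_summary <- function(generator = c("null", "null_uniform",
                                               "contagion"),
                                 config = sim_config(), cutoff_days = 14L) {
  stopifnot(inherits(config, "sim_config"), config$n_reps >= 2L)
  gen <- if (is.function(generator)) {
    generator
  } else {
    switch(match.arg(generator),
      null = function(s) simulate_null_exponential(
        config$n_events_null, config$span_days, seed = s,
        origin = config$origin),
      null_uniform = function(s) simulate_null_uniform(
        config$n_events_null, config$span_days, seed = s,
        origin = config$origin),
      contagion = function(s) simulate_contagion(config, seed = s))
  }
  n <- config$n_reps
  gap_mean <- gap_var <- frac <- rep(NA_real_, n)
  n_le <- n_gap <- 0
  for (r in seq_len(n)) {
    es <- gen(derive_seed(config$seed, r))
    if (is.null(es) || n_events(es) < 2L) next
    g <- gaps_from_events(es)
    gap_mean[r] <- mean(g)
    gap_var[r] <- stats::var(g)
    frac[r] <- mean(g <= cutoff_days)
    n_le <- n_le + sum(g <= cutoff_days)
    n_gap <- n_gap + length(g)
  }
  ok <- !is.na(gap_mean)
  if (!any(ok)) stop("every replicate was degenerate (fewer than 2 events)")
  band <- function(x) unname(stats::quantile(x[ok], c(0.025, 0.975)))
  structure(list(
    gap_mean = gap_mean, gap_var = gap_var, frac_within = frac,
    mean_gap_mean = mean(gap_mean[ok]),
    mean_gap_var = mean(gap_var[ok], na.rm = TRUE),
    mean_frac_within = mean(frac[ok]),
    band_gap_mean = band(gap_mean),
    band_gap_var = band(gap_var),
    band_frac_within = band(frac),
    pooled_frac_within = n_le / n_gap,
    n_reps = n, n_skipped = sum(!ok), seed = config$seed,
    cutoff_days = as.integer(cutoff_days)),
    class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble_summary: %d replicates (%d skipped), seed %d\n",
              x$n_reps, x$n_skipped, x$seed))
  cat(sprintf("  gap mean: %.2f days  [%.2f, %.2f]\n",
              x$mean_gap_mean, x$band_gap_mean[1], x$band_gap_mean[2]))
  cat(sprintf("  gap variance: %.1f  [%.1f, %.1f]\n",
              x$mean_gap_var, x$band_gap_var[1], x$band_gap_var[2]))
  cat(sprintf("  fraction of gaps <= %d days: %.1f%% (pooled %.1f%%)\n",
              x$cutoff_days, 100 * x$mean_frac_within,
              100 * x$pooled_frac_within))
  invisible(x)
}

#' Model-predicted gap distribution by simulation
#'
#' Pools inter-event gaps across Monte Carlo replicates of the null or
#' contagion model and normalizes the integer-day histogram (bins
#' `0..d_max` plus overflow) to probabilities — the predicted gap
#' distribution that [gap_histogram_aic()] scores against an observed one.
#'
#' @param model `"null"` or `"contagion"`.
#' @param config a [sim_config()].
#' @param d_max largest explicit bin.
#' @return numeric probability vector of length `d_max + 2` (the last entry
#'   the overflow bin), summing to 1.
#' @export
predicted_gap_distribution <- function(model = c("null", "contagion"),
                                       config = sim_config(), d_max = 30L) {
  model <- match.arg(model)
  n <- config$n_reps
  tally <- numeric(d_max + 2L)
  for (r in seq_len(n)) {
    es <- if (model == "null") {
      simulate_null_exponential(config$n_events_null, config$span_days,
                                seed = derive_seed(config$seed, r),
                                origin = config$origin)
    } else {
      simulate_contagion(config, seed = derive_seed(config$seed, r))
    }
    if (is.null(es) || n_events(es) < 2L) next
    h <- gap_histogram(gaps_from_events(es), d_max)
    tally <- tally + c(h$counts, h$overflow)
  }
  if (sum(tally) == 0) stop("no gaps simulated")
  tally / sum(tally)
}
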