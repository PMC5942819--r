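#' Contagion (self-excitation) parameters
#'
#' The two parameters of the self-excitation model: the branching ratio
#' `n_secondary` (mean number of secondary events incited by one event,
#' dimensionless; the process is subcritical when below 1) and the mean decay
#' time `t_excite` of the excitation, in days.
#'
#' @param n_secondary expected secondary events per event, `>= 0`.
#' @param t_excite mean excitation decay time in days, `> 0`.
#' @return an object of class `contagion_params`.
#' @export
contagion_params <- function(n_secondary, t_excite) {
  if (!is.finite(n_secondary) || n_secondary < 0)
    stop("n_secondary must be finite and >= 0")
  if (!is.finite(t_excite) || t_excite <= 0)
    stop("t_excite must be finite and > 0")
  structure(list(n_secondary = n_secondary, t_excite = t_excite),
            class = "contagion_params")
}

#' @export
print.contagion_params <- function(x, ...) {
  cat(sprintf("contagion_params: n_secondary = %.4g, t_excite = %.4g days\n",
              x$n_secondary, x$t_excite))
  invisible(x)
}

#' Day-binned excitation probability
#'
#' Probability that a secondary event incited by an event on day `t_i` falls
#' during the 24 hours of day `t_i + d`, under an exponential delay density
#' with mean `t_excite` integrated over whole days:
#' `P(d) = exp(-(d - 1)/T) - exp(-d/T)`.
#' The kernel sums to 1 over `d = 1, 2, ...` (telescoping) and is strictly
#' decreasing in `d`. Same-day excitation (`d = 0`) is excluded: the
#' conditional intensity sums over strictly prior days only.
#'
#' @param d integer day gap(s), `>= 1`.
#' @param t_excite mean decay time in days, `> 0`.
#' @return probabilities in `(0, 1)`, same length as `d`.
#' @examples
#' excitation_probability(1, 13) # 1 - exp(-1/13)
#' @export
excitation_probability <- function(d, t_excite) {
  if (any(d < 1)) stop("d must be >= 1: excitation acts on later days only")
  if (!is.finite(t_excite) || t_excite <= 0) stop("t_excite must be > 0")
  exp(-(d - 1) / t_excite) - exp(-d / t_excite)
}

#' Day-of-week weights and uniformity test
#'
#' Estimates a multiplicative weight per weekday, `7 * (share of events on
#' that weekday)`, so the weights average exactly 1, together with a Pearson
#' chi-square test of weekday uniformity. The weights are estimated from the
#' data once and then held fixed inside any fit; day-of-week is treated as a
#' fixed adjustment, not a free parameter.
#'
#' @param counts a `daily_counts` with at least one event.
#' @return a list with `weights` (length 7, named Monday..Sunday),
#'   `statistic` (Pearson chi-square, df 6), and `p_value`.
#' @export
weekday_weights <- function(counts) {
  stopifnot(inherits(counts, "daily_counts"))
  total <- sum(counts$counts)
  if (total == 0L) stop("weekday weights need at least one event")
  m <- length(counts$counts)
  wd <- weekday_index(counts$origin, m)
  by_day <- vapply(1:7, function(w) sum(counts$counts[wd == w]), numeric(1))
  names(by_day) <- c("Monday", "Tuesday", "Wednesday", "Thursday",
                     "Friday", "Saturday", "Sunday")
  # small per-weekday counts only degrade the asymptotic p-value, which
  # callers interpret themselves; silence the approximation warning
  test <- suppressWarnings(stats::chisq.test(by_day))
  list(weights = 7 * by_day / total,
       statistic = unname(test$statistic),
       p_value = test$p.value)
}

# 1 = Monday .. 7 = Sunday for each day of a span starting at `origin`
weekday_index <- function(origin, m) {
  first <- as.integer(format(origin, "%u"))
  ((first - 1L + seq_len(m) - 1L) %% 7L) + 1L
}

#' Baseline-rate specification
#'
#' Describes the non-contagion component `N0(t)` of the daily rate: a
#' constant, a centered running mean of the daily counts (which absorbs
#' long-term trends), or the running mean multiplied by fixed day-of-week
#' weights.
#'
#' @param kind one of `"constant"`, `"running_mean"`, `"running_mean_weekday"`.
#' @param window_days width of the running-mean window in days (default 365,
#'   long enough to smooth over weekly and seasonal structure while tracking
#'   year-scale trends).
#' @param weekday_weights optional length-7 non-negative weights averaging 1
#'   (Monday first); when omitted for the weekday kind they are estimated
#'   from the data by [weekday_weights()].
#' @return an object of class `baseline_spec`.
#' @export
baseline_spec <- function(kind = c("constant", "running_mean",
                                   "running_mean_weekday"),
                          window_days = 365L, weekday_weights = NULL) {
  kind <- match.arg(kind)
  window_days <- as.integer(window_days)
  if (is.na(window_days) || window_days < 1L)
    stop("window_days must be a positive integer")
  if (!is.null(weekday_weights)) {
    if (length(weekday_weights) != 7L || any(weekday_weights < 0))
      stop("weekday_weights must be 7 non-negative values")
    if (abs(mean(weekday_weights) - 1) > 1e-8)
      stop("weekday_weights must average exactly 1")
  }
  structure(list(kind = kind, window_days = window_days,
                 weekday_weights = weekday_weights),
            class = "baseline_spec")
}

#' Baseline rate series
#'
#' Builds the baseline expected-events-per-day vector `N0(t)` from daily
#' counts under a [baseline_spec()]. The running mean is a centered boxcar;
#' at the span edges the average is renormalized by the number of days the
#' window actually covers (no padding), so the baseline is not deflated there.
#'
#' @param counts a `daily_counts`.
#' @param spec a `baseline_spec`.
#' @return numeric vector of length `M` (days in span), all entries `>= 0`.
#' @export
baseline_series <- function(counts, spec = baseline_spec("constant")) {
  stopifnot(inherits(counts, "daily_counts"), inherits(spec, "baseline_spec"))
  k <- counts$counts
  m <- length(k)
  if (spec$kind == "constant") return(rep(sum(k) / m, m))
  w <- spec$window_days
  if (w > m) stop("running-mean window (", w, ") exceeds the span (", m, ")")
  b <- running_mean(k, w)
  if (spec$kind == "running_mean_weekday") {
    ww <- spec$weekday_weights
    if (is.null(ww)) ww <- weekday_weights(counts)$weights
    b <- b * ww[weekday_index(counts$origin, m)]
  }
  b
}

# centered boxcar mean with edge renormalization by actual coverage;
# window offsets -floor((w-1)/2) .. +floor(w/2)
running_mean <- function(k, w) {
  m <- length(k)
  left <- (w - 1L) %/% 2L
  right <- w %/% 2L
  cs <- c(0, cumsum(k))
  lo <- pmax(seq_len(m) - left, 1L)
  hi <- pmin(seq_len(m) + right, m)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Conditional expected-events series
#'
#' The conditional intensity of the self-excitation model: for each day `n`,
#' `mu[n] = baseline[n] + n_secondary * sum over prior events on days i < n of
#' P(n - i | t_excite)`, where `P` is [excitation_probability()]. A day with
#' `k` prior events contributes `k` kernel terms. Same-day events do not
#' excite each other.
#'
#' The sum is evaluated exactly in `O(M)` through the kernel's recursive
#' form: with `q = exp(-1/t_excite)`, `P(d) = (1 - q) q^(d-1)`, so the
#' excitation state `S[n] = q S[n-1] + k[n]` carries the whole history.
#'
#' @param history a `daily_counts` (the realized event history).
#' @param params a `contagion_params`.
#' @param baseline numeric baseline vector of matching length (see
#'   [baseline_series()]).
#' @return an object of class `intensity_series`: list with `baseline` and
#'   `contagion` component vectors; `mu = baseline + contagion`.
#' @export
expected_events <- function(history, params, baseline) {
  stopifnot(inherits(history, "daily_counts"),
            inherits(params, "contagion_params"))
  k <- history$counts
  m <- length(k)
  if (length(baseline) != m)
    stop("baseline length must match the daily count vector")
  if (any(baseline < 0)) stop("baseline entries must be >= 0")
  contagion <- contagion_component(k, params$n_secondary, params$t_excite)
  structure(list(baseline = baseline, contagion = contagion),
            class = "intensity_series")
}

# exact O(M) evaluation of the excitation sum via its linear recursion
contagion_component <- function(k, n_secondary, t_excite) {
  m <- length(k)
  if (n_secondary == 0 || m == 1L) return(numeric(m))
  q <- exp(-1 / t_excite)
  s <- stats::filter(k, q, method = "recursive") # s[n] = sum_{i<=n} k_i q^(n-i)
  n_secondary * (1 - q) * c(0, as.numeric(s)[-m])
}

#' @export
print.intensity_series <- function(x, ...) {
  cat(sprintf(
    "intensity_series: %d days, total mu %.3f (baseline %.3f + contagion %.3f)\n",
    length(x$baseline), sum(x$baseline) + sum(x$contagion),
    sum(x$baseline), sum(x$contagion)))
  invisible(x)
}

#' @rdname expected_events
#' @param intensity an `intensity_series`.
#' @export
intensity_mu <- function(intensity) intensity$baseline + intensity$contagion

#' Rescale an intensity series to a fixed total
#'
#' Enforces the likelihood constraint that the total expected number of
#' events equals the total observed: the baseline component is multiplied by
#' `(total - sum(contagion)) / sum(baseline)` while the contagion component
#' is left unchanged. When the contagion component alone already meets or
#' exceeds `total`, no positive baseline scale exists and an error of class
#' `selfexcite_infeasible` is signalled; the fitter converts it into a
#' penalty rather than aborting.
#'
#' @param intensity an `intensity_series`.
#' @param total the target total (the observed event count).
#' @return the rescaled `intensity_series`, with `sum(mu) == total`.
#' @export
rescale_to_total <- function(intensity, total) {
  stopifnot(inherits(intensity, "intensity_series"))
  sc <- sum(intensity$contagion)
  sb <- sum(intensity$baseline)
  if (sc >= total) {
    stop(structure(class = c("selfexcite_infeasible", "error", "condition"),
                   list(message = sprintf(
                          "contagion total %.4g >= target total %.4g: no positive baseline scale",
                          sc, total),
                        call = sys.call(-1), excess = sc - total)))
  }
  if (sb <= 0) stop("baseline sums to zero; cannot rescale")
  intensity$baseline <- intensity$baseline * (total - sc) / sb
  intensity
}
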