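#' Unbinned Poisson negative log-likelihood
#'
#' `sum_i (mu[i] - k[i] * log mu[i])` over every day of the span, zero-count
#' days included. The `log k!` term depends on the data only and is dropped,
#' as is conventional; it is an additive constant for fixed data, so model
#' comparisons are unaffected. A day with `mu = 0` but `k > 0` is an
#' impossible observation; the function returns `+Inf` (a penalty value, not
#' an error) so optimizers can back away from such points.
#'
#' @param intensity an `intensity_series`, or a positive numeric vector of
#'   daily means.
#' @param counts a `daily_counts`, or an integer vector of daily counts.
#' @return the negative log-likelihood (up to the dropped `log k!` constant).
#' @examples
#' poisson_negloglik(c(1, 1), c(1, 0)) # 2
#' @export
poisson_negloglik <- function(intensity, counts) {
  mu <- if (inherits(intensity, "intensity_series")) intensity_mu(intensity)
        else as.numeric(intensity)
  k <- if (inherits(counts, "daily_counts")) counts$counts
       else as.numeric(counts)
  if (length(mu) != length(k)) stop("intensity and counts lengths differ")
  if (any(mu < 0)) stop("intensity must be non-negative")
  if (any(mu == 0 & k > 0)) return(Inf)
  pos <- k > 0
  sum(mu) - sum(k[pos] * log(mu[pos]))
}

#' Negative Binomial negative log-likelihood (NB2)
#'
#' Full negative log-likelihood under the NB2 parameterization, in which the
#' variance is `mu + alpha * mu^2`; `alpha = 0` recovers the Poisson model.
#' Unlike [poisson_negloglik()], the full log-pmf is used (no dropped terms),
#' so at `alpha = 0` this equals the Poisson negative log-likelihood
#' including its `log k!` term.
#'
#' @param mu positive numeric vector of daily (or per-bin) means.
#' @param counts non-negative integer vector, same length.
#' @param dispersion NB2 dispersion `alpha >= 0`.
#' @return the negative log-likelihood.
#' @export
negbin_negloglik <- function(mu, counts, dispersion) {
  mu <- if (inherits(mu, "intensity_series")) intensity_mu(mu) else
    as.numeric(mu)
  k <- if (inherits(counts, "daily_counts")) counts$counts else
    as.numeric(counts)
  if (length(mu) != length(k)) stop("mu and counts lengths differ")
  if (length(dispersion) != 1L || is.na(dispersion) || dispersion < 0)
    stop("dispersion must be a single value >= 0")
  if (any(mu == 0 & k > 0)) return(Inf)
  pos <- mu > 0
  if (dispersion == 0)
    return(-sum(stats::dpois(k[pos], mu[pos], log = TRUE)))
  -sum(stats::dnbinom(k[pos], size = 1 / dispersion, mu = mu[pos],
                      log = TRUE))
}
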