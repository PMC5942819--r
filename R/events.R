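#' Event-date series
#'
#' Construct an ordered series of calendar event dates within a study span.
#' Duplicate dates are legal and meaningful: several events may occur on the
#' same day, and the daily-count model treats them as a count of 2 or more.
#'
#' @param dates a `Date` vector (or ISO-8601 strings) of event dates.
#' @param span_start,span_end optional `Date` bounds of the study period.
#'   Default to the tight span `[min(dates), max(dates)]`. The span may be
#'   wider than the data (a study-period choice) but must contain every event.
#' @return an object of class `event_series`: a list with elements `dates`
#'   (sorted `Date` vector), `span_start` and `span_end`.
#' @examples
#' es <- event_series(c("2006-01-01", "2006-01-04", "2006-01-04"))
#' n_events(es)
#' @export
event_series <- function(dates, span_start = NULL, span_end = NULL) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("event dates contain unparseable or missing values")
  if (length(dates) == 0L) stop("an event series needs at least one event")
  dates <- sort(dates)
  span_start <- if (is.null(span_start)) min(dates) else as.Date(span_start)
  span_end <- if (is.null(span_end)) max(dates) else as.Date(span_end)
  if (is.na(span_start) || is.na(span_end)) stop("unparseable span bound")
  if (span_end < span_start) stop("span_end must not precede span_start")
  if (min(dates) < span_start || max(dates) > span_end)
    stop("all event dates must lie within [span_start, span_end]")
  structure(list(dates = dates, span_start = span_start, span_end = span_end),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("event_series: %d events, span %s .. %s (%d days)\n",
              length(x$dates), format(x$span_start), format(x$span_end),
              span_days(x)))
  invisible(x)
}

#' @rdname event_series
#' @param x an `event_series`.
#' @export
n_events <- function(x) length(x$dates)

#' @rdname event_series
#' @export
span_days <- function(x) as.integer(x$span_end - x$span_start) + 1L

#' Read an event series from a CSV of dates
#'
#' @param path path to a CSV file with a header row.
#' @param column name of the ISO-8601 (`YYYY-MM-DD`) date column.
#' @param span_start,span_end optional study-span override (see
#'   [event_series()]).
#' @return an `event_series`.
#' @export
read_events <- function(path, column = "date",
                        span_start = NULL, span_end = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no event rows in ", path)
  if (!column %in% names(df))
    stop("column '", column, "' not found in ", path)
  raw <- df[[column]]
  dates <- as.Date(raw, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1L]
    stop(sprintf("unparseable date '%s' at data row %d of %s",
                 raw[bad], bad, path))
  }
  event_series(dates, span_start = span_start, span_end = span_end)
}

#' Write an event series to CSV
#'
#' @param events an `event_series`.
#' @param path output file path.
#' @param column date column name to use in the header.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, column = "date") {
  df <- stats::setNames(data.frame(format(events$dates, "%Y-%m-%d")), column)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Daily event counts over a study span
#'
#' Convert an event series to the integer vector of events per day over the
#' full span, retaining zero-count days: the unbinned likelihood is informed
#' by every day, including the days on which nothing happened.
#'
#' @param events an `event_series`.
#' @return an object of class `daily_counts`: a list with `counts` (integer
#'   vector, one entry per day of the span, index 0 = `span_start`) and
#'   `origin` (the calendar date of index 0).
#' @examples
#' es <- event_series(as.Date("2006-01-01") + c(0, 3, 3),
#'                    span_end = as.Date("2006-01-05"))
#' to_daily_counts(es)$counts # 1 0 0 2 0
#' @export
to_daily_counts <- function(events) {
  stopifnot(inherits(events, "event_series"))
  m <- span_days(events)
  day <- as.integer(events$dates - events$span_start)
  counts <- tabulate(day + 1L, nbins = m)
  structure(list(counts = counts, origin = events$span_start),
            class = "daily_counts")
}

#' @export
print.daily_counts <- function(x, ...) {
  cat(sprintf("daily_counts: %d events over %d days from %s\n",
              sum(x$counts), length(x$counts), format(x$origin)))
  invisible(x)
}

#' Rebuild the event series implied by a daily count vector
#'
#' Inverse of [to_daily_counts()] up to the multiset of event days.
#'
#' @param counts a `daily_counts`.
#' @return an `event_series` with the same span.
#' @export
from_daily_counts <- function(counts) {
  stopifnot(inherits(counts, "daily_counts"))
  m <- length(counts$counts)
  days <- rep(seq_len(m) - 1L, counts$counts)
  event_series(counts$origin + days,
               span_start = counts$origin,
               span_end = counts$origin + m - 1L)
}

#' Write daily counts as a two-column CSV (date, count)
#'
#' @param counts a `daily_counts`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_daily_counts <- function(counts, path) {
  m <- length(counts$counts)
  df <- data.frame(date = format(counts$origin + seq_len(m) - 1L, "%Y-%m-%d"),
                   count = counts$counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Integer-day gaps between successive events
#'
#' Events on the same day yield a gap of zero. A series with fewer than two
#' events yields an empty gap sample (not an error).
#'
#' @param events an `event_series`, or an integer vector of event day indices.
#' @return an object of class `gap_sample`: integer vector of day differences
#'   with attribute `n_events`.
#' @examples
#' gaps_from_events(c(0, 3, 3, 23)) # 3 0 20
#' @export
gaps_from_events <- function(events) {
  day <- if (inherits(events, "event_series")) {
    as.integer(events$dates - events$span_start)
  } else {
    sort(as.integer(events))
  }
  g <- if (length(day) < 2L) integer(0) else diff(day)
  structure(g, n_events = length(day), class = "gap_sample")
}

#' @export
print.gap_sample <- function(x, ...) {
  cat(sprintf("gap_sample: %d gaps from %d events\n",
              length(x), attr(x, "n_events")))
  if (length(x)) {
    cat(sprintf("  mean %.2f, var %.2f, max %d\n",
                mean(x), stats::var(x), max(x)))
  }
  invisible(x)
}

#' Histogram of integer-day gaps
#'
#' Bins gaps at integer days `0..d_max`; gaps exceeding `d_max` are collected
#' in an overflow bin so the total is always preserved.
#'
#' @param gaps a `gap_sample` or integer vector of gaps.
#' @param d_max largest explicit integer-day bin (>= 0).
#' @return an object of class `gap_histogram`: list with `counts` (named
#'   vector over bins `0..d_max`), `overflow` and `total`.
#' @export
gap_histogram <- function(gaps, d_max) {
  if (length(d_max) != 1L || is.na(d_max) || d_max < 0)
    stop("d_max must be a single non-negative integer")
  d_max <- as.integer(d_max)
  g <- as.integer(gaps)
  if (any(g < 0)) stop("gaps must be non-negative")
  counts <- tabulate(g[g <= d_max] + 1L, nbins = d_max + 1L)
  names(counts) <- as.character(0:d_max)
  structure(list(counts = counts, overflow = sum(g > d_max),
                 total = length(g), d_max = d_max),
            class = "gap_histogram")
}

#' @export
print.gap_histogram <- function(x, ...) {
  cat(sprintf("gap_histogram: %d gaps in bins 0..%d (+%d overflow)\n",
              x$total, x$d_max, x$overflow))
  invisible(x)
}
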