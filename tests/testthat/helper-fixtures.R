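# shared fixtures: all built in code at test time

# a tiny event series on known day offsets within a fixed span
tiny_series <- function(days = c(0L, 3L, 3L, 23L),
                        origin = as.Date("2006-01-01"), span = 30L) {
  event_series(origin + days, span_start = origin,
               span_end = origin + span - 1L)
}

# write an event CSV and return its path
write_event_csv <- function(dates, path = tempfile(fileext = ".csv"),
                            column = "date") {
  df <- stats::setNames(data.frame(dates), column)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# daily_counts built directly from a count vector
counts_fixture <- function(counts, origin = as.Date("2006-01-01")) {
  structure(list(counts = as.integer(counts), origin = origin),
            class = "daily_counts")
}
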