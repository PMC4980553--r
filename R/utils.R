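# Time handling: all timestamps are POSIXct in UTC at minute resolution.
# Instruments share the participant's clock, so no timezone arithmetic is
# performed; UTC is used as a fixed, DST-free calendar.

.TS_FMT <- "%Y-%m-%dT%H:%M:%S"

parse_ts <- function(x) {
  as.POSIXct(x, format = .TS_FMT, tz = "UTC")
}

format_ts <- function(t) {
  format(t, .TS_FMT, tz = "UTC")
}

# combine a Date and "HH:MM" clock time into POSIXct (UTC)
make_ts <- function(date, clock) {
  as.POSIXct(paste(as.character(date), clock), format = "%Y-%m-%d %H:%M",
             tz = "UTC")
}

ts_date <- function(t) as.Date(t, tz = "UTC")

# minutes between two POSIXct vectors (t2 - t1)
mins_between <- function(t1, t2) {
  as.numeric(difftime(t2, t1, units = "mins"))
}

# round POSIXct down to the whole minute
floor_minute <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

clock_to_min <- function(clock) {
  p <- strsplit(clock, ":", fixed = TRUE)
  vapply(p, function(v) as.numeric(v[1]) * 60 + as.numeric(v[2]), numeric(1))
}

min_to_clock <- function(m) {
  m <- pmin(pmax(round(m), 0), 1439)
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

# simple structured log: a character vector of "LEVEL message" lines
log_line <- function(log, level, msg) {
  c(log, paste0("[", level, "] ", msg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
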