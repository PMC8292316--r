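# Locale-independent weekday handling and small shared helpers.

DAY_NAMES <- c("Sunday", "Monday", "Tuesday", "Wednesday", "Thursday",
               "Friday", "Saturday")

# 0 = Sunday .. 6 = Saturday, independent of locale
day_index <- function(date) as.POSIXlt(date, tz = "UTC")$wday

day_name <- function(date) DAY_NAMES[day_index(date) + 1L]

# Timestamps are local wall-clock times with no zone attached; we parse them
# in UTC so R never applies its own DST rules -- the clock change is handled
# explicitly by the generator and classifier.
parse_ts <- function(x) {
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
}

format_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

# fractional clock hours of a timestamp
time_of_day <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

# von Mises sampler (Best & Fisher 1979 rejection algorithm); used by the
# simulation-based tests and the power/calibration experiments.
rvm <- function(n, mu, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
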