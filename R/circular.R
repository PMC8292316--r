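#' Convert clock hours to angles on the 24-h circle
#'
#' Projects a time of day onto the unit circle: midnight maps to 0 and noon to
#' pi. Values outside `[0, 24)` are reduced modulo 24 first, so `25` and `1`
#' give the same angle.
#'
#' @param t Numeric vector of clock hours.
#' @return Numeric vector of angles in radians, in `[0, 2*pi)`.
#' @seealso [angle_to_hours()] for the inverse projection.
#' @export
#' @examples
#' hours_to_angle(c(0, 12, 25))
hours_to_angle <- function(t) {
  stopifnot(is.numeric(t), all(is.finite(t)))
  (t %% 24) * pi / 12
}

#' Convert angles back to clock hours
#'
#' Inverse of [hours_to_angle()]: divides by 2*pi and multiplies by 24.
#' Angles outside `[0, 2*pi)` are wrapped, so `-pi/12` gives 23.
#'
#' @param theta Numeric vector of angles in radians.
#' @return Numeric vector of clock hours in `[0, 24)`.
#' @export
angle_to_hours <- function(theta) {
  stopifnot(is.numeric(theta), all(is.finite(theta)))
  (theta %% (2 * pi)) * 12 / pi
}

#' Circular mean direction and resultant length
#'
#' Computes the mean direction of a set of angles by vector averaging:
#' the mean of the sines and cosines gives a resultant vector whose direction
#' is the circular mean and whose length (between 0 and 1) measures how
#' concentrated the sample is. Times of day must always be averaged this way;
#' the arithmetic mean of clock hours is meaningless for samples straddling
#' midnight.
#'
#' @param theta Numeric vector of angles in radians (any values; wrapped).
#' @return An object of class `"circular_summary"`: a list with
#'   `mean_direction` (radians in `[0, 2*pi)`, `NA` if the resultant length is
#'   numerically zero), `mean_hours` (the same direction as clock hours),
#'   `resultant_length` and `n`.
#' @export
#' @examples
#' circular_mean(hours_to_angle(c(23, 1)))  # mean at midnight, not noon
circular_mean <- function(theta) {
  stopifnot(is.numeric(theta))
  theta <- theta[!is.na(theta)]
  n <- length(theta)
  if (n == 0L) stop("circular_mean: empty series")
  s <- mean(sin(theta))
  c_ <- mean(cos(theta))
  r <- sqrt(s^2 + c_^2)
  if (r < 1e-12) {
    warning("circular_mean: resultant length ~ 0, mean direction undefined")
    mu <- NA_real_
  } else {
    mu <- atan2(s, c_) %% (2 * pi)
  }
  structure(
    list(
      mean_direction = mu,
      mean_hours = if (is.na(mu)) NA_real_ else angle_to_hours(mu),
      resultant_length = min(r, 1),
      n = n
    ),
    class = "circular_summary"
  )
}

#' @export
print.circular_summary <- function(x, ...) {
  cat("Circular summary (n = ", x$n, ")\n", sep = "")
  cat("  mean direction: ",
      if (is.na(x$mean_direction)) "undefined" else
        sprintf("%.4f rad = %s", x$mean_direction, format_clock(x$mean_hours)),
      "\n", sep = "")
  cat(sprintf("  resultant length: %.4f\n", x$resultant_length))
  invisible(x)
}

#' Midpoint of a sleep bout on the 24-h circle
#'
#' The sleep midpoint is the clock time halfway between sleep onset and
#' offset, computed along the bout (onset forward to offset), so a bout from
#' 23:00 to 07:00 has midpoint 03:00, not 15:00.
#'
#' @param onset,offset Clock hours of bout start and end.
#' @return Clock hours of the midpoint, in `[0, 24)`.
#' @export
circular_midpoint <- function(onset, offset) {
  stopifnot(is.numeric(onset), is.numeric(offset))
  dur <- (offset - onset) %% 24
  if (any(dur == 0)) stop("circular_midpoint: zero-duration bout")
  (onset + dur / 2) %% 24
}

#' Estimate the von Mises concentration parameter
#'
#' Closed-form approximation to the maximum-likelihood inverse of the mean
#' resultant length function A(kappa) = I1(kappa)/I0(kappa), using the
#' standard three-regime formulas:
#' below r = 0.5, `2r + r^3 + 5 r^5 / 6`;
#' from 0.5 to below 0.85, `-0.4 + 1.39 r + 0.43 / (1 - r)`;
#' from 0.85 up, `1 / (r^3 - 4 r^2 + 3 r)`.
#' Published regime cut-points vary around 0.5 by a few hundredths; the two
#' adjacent formulas differ by under 0.5% there, well below the sampling
#' error of any resultant the test consumes. No small-sample correction is
#' applied.
#'
#' @param r Mean resultant length in `[0, 1)`.
#' @param n Sample size the resultant was computed from (recorded for the
#'   caller's bookkeeping; does not alter the estimate).
#' @return Estimated concentration `kappa >= 0`.
#' @export
estimate_kappa <- function(r, n = NULL) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r), r >= 0)
  if (r >= 1) stop("estimate_kappa: resultant length 1 implies infinite concentration")
  if (r < 0.5) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Parametric Watson-Williams multisample test for equal mean directions
#'
#' Tests whether k samples of angles share a common mean direction, assuming
#' each sample follows a von Mises distribution with common concentration.
#' With per-group un-normalized resultants `R_i = n_i * r_i` and pooled
#' resultant `R`, the statistic is
#' \deqn{F = K \frac{(N-k)(\sum R_i - R)}{(k-1)(N - \sum R_i)}}
#' where the correction factor `K = 1 + 3/(8 kappa)` uses the concentration
#' estimated from the pooled weighted mean resultant length. The p-value comes
#' from the F distribution with `(k - 1, N - k)` degrees of freedom.
#'
#' The test assumes reasonably concentrated data; when the pooled mean
#' resultant length falls below 0.45 a warning is issued (the F approximation
#' is doubtful there) but the result is still returned.
#'
#' @param groups List of two or more numeric vectors of angles in radians,
#'   each of length at least 2. Names, if present, are kept in the output.
#' @return An object of classes `"watson_williams"` and `"htest"` with
#'   `statistic` (F), `parameter` (df1, df2), `p.value`, `estimate` (per-group
#'   mean directions in clock hours), plus fields `kappa_hat`,
#'   `correction_factor` and `pooled_r`.
#' @export
#' @examples
#' set.seed(1)
#' a <- hours_to_angle(rnorm(40, 23.5, 0.5) %% 24)
#' b <- hours_to_angle(rnorm(40, 0.8, 0.5) %% 24)
#' watson_williams(list(early = a, late = b))
watson_williams <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("watson_williams: need a list of at least two groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L))
    stop("watson_williams: every group needs at least 2 observations")
  k <- length(groups)
  N <- sum(ns)

  # per-group and pooled un-normalized resultants
  S_i <- vapply(groups, function(g) sum(sin(g)), numeric(1))
  C_i <- vapply(groups, function(g) sum(cos(g)), numeric(1))
  R_i <- sqrt(S_i^2 + C_i^2)
  R_pooled <- sqrt(sum(S_i)^2 + sum(C_i)^2)

  rw <- sum(R_i) / N  # pooled weighted mean resultant length
  if (rw < 0.45)
    warning("watson_williams: pooled mean resultant length < 0.45; ",
            "test assumptions doubtful")
  kappa_hat <- estimate_kappa(rw, n = N)
  correction <- 1 + 3 / (8 * kappa_hat)

  df1 <- k - 1L
  df2 <- N - k
  denom <- N - sum(R_i)
  f_stat <- if (denom <= 0) Inf else
    correction * (df2 * (sum(R_i) - R_pooled)) / (df1 * denom)
  f_stat <- max(f_stat, 0)
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)

  means <- vapply(seq_len(k), function(i)
    angle_to_hours(atan2(S_i[i], C_i[i]) %% (2 * pi)), numeric(1))
  names(means) <- if (!is.null(names(groups))) names(groups) else
    paste0("group", seq_len(k))

  structure(
    list(
      statistic = c(F = f_stat),
      parameter = c(df1 = df1, df2 = df2),
      p.value = p,
      estimate = means,
      kappa_hat = kappa_hat,
      correction_factor = correction,
      pooled_r = rw,
      n = ns,
      method = "Parametric Watson-Williams multisample test for equal means",
      data.name = paste(k, "groups,", N, "angles")
    ),
    class = c("watson_williams", "htest")
  )
}

#' Signed wrapped difference between two clock times, in minutes
#'
#' Difference `b - a` taken on the 24-h circle and mapped to the signed
#' interval `(-720, 720]` minutes, so 23:30 to 00:30 is +60 min, not -1380.
#'
#' @param a,b Clock hours.
#' @return Signed minutes in `(-720, 720]`.
#' @export
wrapped_diff_minutes <- function(a, b) {
  m <- ((b - a) * 60) %% 1440
  ifelse(m > 720, m - 1440, m)
}

# hh:mm formatting for clock-hour values
format_clock <- function(h) {
  h <- h %% 24
  hh <- floor(h)
  mm <- round((h - hh) * 60)
  hh <- ifelse(mm == 60, (hh + 1) %% 24, hh)
  mm <- ifelse(mm == 60, 0, mm)
  sprintf("%02d:%02d", as.integer(hh), as.integer(mm))
}
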