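#' Low-pass filter specification
#'
#' Marker-derived kinematics are conditioned with a 4th-order low-pass
#' Butterworth filter at 6 Hz; ground reaction forces at 20 Hz. Filtering is
#' zero-phase (forward-backward) by default so that event-anchored windows
#' are not shifted by phase lag; the effective magnitude response is then the
#' squared single-pass magnitude.
#'
#' @param order Filter order, even (default 4).
#' @param cutoff Cutoff frequency in Hz (6 kinematics, 20 GRF).
#' @param zero_phase Apply forward and backward (default \code{TRUE}).
#' @return Object of class \code{filter_spec}.
#' @export
filter_spec <- function(order = 4L, cutoff = 6, zero_phase = TRUE) {
  if (order < 2L || order %% 2L != 0L) stop("filter order must be even")
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(order = as.integer(order), cutoff = cutoff,
                 zero_phase = isTRUE(zero_phase)), class = "filter_spec")
}

# Butterworth low-pass as cascaded second-order sections (bilinear transform
# of the analog prototype with cutoff prewarping). The cascade form keeps the
# realized deep-stopband response on the analytic curve, which a single
# expanded transfer function does not at this order.
butter_sections <- function(order, cutoff_hz, sample_rate) {
  if (cutoff_hz >= sample_rate / 2) {
    stop("cutoff (", cutoff_hz, " Hz) must be below the Nyquist frequency (",
         sample_rate / 2, " Hz)")
  }
  wc <- tan(pi * cutoff_hz / sample_rate)
  lapply(seq_len(order %/% 2L), function(k) {
    th <- pi * (2 * k - 1) / (2 * order)   # prototype pole-pair angle
    a0 <- 1 + 2 * wc * sin(th) + wc^2
    list(b = (wc^2 / a0) * c(1, 2, 1),
         a = c(1, 2 * (wc^2 - 1) / a0, (1 - 2 * wc * sin(th) + wc^2) / a0))
  })
}

# steady-state initial filter state for a unit step (direct form II
# transposed), so edge transients vanish for locally constant signals
iir_steady_state <- function(b, a) {
  n <- length(a) - 1L
  A <- rbind(-a[-1L], cbind(diag(1, n - 1L), 0))
  solve(diag(n) - t(A), b[-1L] - b[1L] * a[-1L])
}

iir_apply <- function(b, a, x, zi) {
  z <- zi
  y <- numeric(length(x))
  nb <- length(b)
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    for (k in seq_len(nb - 2L)) {
      z[k] <- b[k + 1L] * xi + z[k + 1L] - a[k + 1L] * yi
    }
    z[nb - 1L] <- b[nb] * xi - a[nb] * yi
    y[i] <- yi
  }
  y
}

single_pass <- function(sections, x) {
  for (s in sections) {
    x <- iir_apply(s$b, s$a, x, iir_steady_state(s$b, s$a) * x[1L])
  }
  x
}

#' Zero-phase Butterworth low-pass filter
#'
#' Filters a uniformly sampled series with a Butterworth low-pass filter.
#' With \code{zero_phase = TRUE} the filter is applied forward and backward,
#' cancelling phase; edge effects are controlled by odd-reflection padding
#' and steady-state filter initialization, so a constant series passes
#' through unchanged (unit DC gain).
#'
#' @param x Numeric series.
#' @param sample_rate Sampling frequency in Hz.
#' @param spec A \code{\link{filter_spec}}.
#' @return Filtered series, same length as \code{x}.
#' @export
#' @examples
#' x <- sin(2 * pi * 1 * (0:239) / 120) + sin(2 * pi * 45 * (0:239) / 120)
#' y <- butterworth_lowpass(x, 120, filter_spec(cutoff = 6))
butterworth_lowpass <- function(x, sample_rate, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  n <- length(x)
  if (n <= 3L * spec$order) {
    stop("series too short for order-", spec$order, " filtering (need > ",
         3L * spec$order, " samples, got ", n, ")")
  }
  sections <- butter_sections(spec$order, spec$cutoff, sample_rate)
  pad <- min(n - 1L, 3L * spec$order)
  pre <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xx <- c(pre, x, post)
  y <- single_pass(sections, xx)
  if (spec$zero_phase) y <- rev(single_pass(sections, rev(y)))
  y[seq(pad + 1L, pad + n)]
}

#' Analytic Butterworth magnitude response
#'
#' Magnitude of the digital Butterworth low-pass (bilinear transform with
#' cutoff prewarping) at frequency \code{f}, squared when \code{zero_phase}
#' (two passes). Useful as a closed-form reference for the attenuation the
#' filter applies at any frequency.
#'
#' @param f Frequency in Hz (vectorized).
#' @param sample_rate Sampling frequency in Hz.
#' @param spec A \code{\link{filter_spec}}.
#' @return Gain in (0, 1].
#' @export
butterworth_gain <- function(f, sample_rate, spec = filter_spec()) {
  ratio <- tan(pi * f / sample_rate) / tan(pi * spec$cutoff / sample_rate)
  g <- 1 / sqrt(1 + ratio^(2 * spec$order))
  if (spec$zero_phase) g^2 else g
}

#' Normalize forces and moments to body weight
#'
#' Divides a force or moment series by the subject's body weight
#' (mass times g, g = 9.81 m/s^2), making it dimensionless in body weights
#' (forces) or expressed per body weight (moments).
#'
#' @param x Numeric series (N or N m).
#' @param body_mass Body mass in kg.
#' @return Normalized series.
#' @export
normalize_to_bodyweight <- function(x, body_mass) {
  if (is.null(body_mass) || !is.numeric(body_mass) || length(body_mass) != 1 ||
      is.na(body_mass) || body_mass <= 0) {
    stop("body_mass must be a positive scalar (kg); it is required for ",
         "body-weight normalization")
  }
  x / (body_mass * 9.81)
}

#' Swing reference interval
#'
#' Interval of late swing, relative to heel strike, over which the prosthesis
#' is taken to be in its unloaded configuration. The mean ankle angle over
#' this interval defines the zero reference, removing alignment bias between
#' subjects and sessions.
#'
#' @param start_ms,end_ms Interval bounds in ms relative to heel strike; both
#'   must be negative (before heel strike) with \code{end_ms > start_ms}.
#' @return Object of class \code{swing_reference}.
#' @export
swing_reference <- function(start_ms = -400, end_ms = -250) {
  if (end_ms <= start_ms) stop("end_ms must exceed start_ms")
  if (end_ms >= 0) stop("swing reference must lie strictly before heel strike")
  structure(list(start_ms = start_ms, end_ms = end_ms),
            class = "swing_reference")
}

#' Reference ankle angles to their unloaded swing value
#'
#' Subtracts from an ankle angle series its mean over the swing reference
#' interval, so that the unloaded prosthesis reads zero degrees. Idempotent;
#' constant alignment offsets vanish.
#'
#' @param x Angle series in degrees.
#' @param sample_rate Sampling frequency in Hz.
#' @param heel_strike_time Heel-strike time in seconds (time 0 = first
#'   sample).
#' @param ref A \code{\link{swing_reference}}.
#' @return Referenced angle series, same length.
#' @export
normalize_ankle_to_swing <- function(x, sample_rate, heel_strike_time,
                                     ref = swing_reference()) {
  stopifnot(inherits(ref, "swing_reference"))
  hs_idx <- round(heel_strike_time * sample_rate) + 1
  i0 <- hs_idx + round(ref$start_ms * sample_rate / 1000)
  i1 <- hs_idx + round(ref$end_ms * sample_rate / 1000)
  if (i0 < 1 || i1 > length(x)) {
    stop("swing reference interval [", ref$start_ms, ", ", ref$end_ms,
         "] ms lies outside the recording")
  }
  x - mean(x[i0:i1])
}

#' Numerical time derivative
#'
#' First or second time derivative of a uniformly sampled series. Angular
#' velocity and acceleration of the ankle are obtained as the first and
#' second derivatives of the ankle angle. Interior samples use central
#' differences; the end points use one-sided second-order stencils so the
#' output keeps the input length.
#'
#' @param x Numeric series, length >= 3.
#' @param sample_rate Sampling frequency in Hz.
#' @param order 1 (velocity) or 2 (acceleration).
#' @return Derivative series, same length as \code{x}.
#' @export
differentiate <- function(x, sample_rate, order = 1L) {
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to differentiate")
  h <- 1 / sample_rate
  if (order == 1L) {
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * h)
    d[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (2 * h)
    d[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (2 * h)
    d
  } else {
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / h^2
    if (n >= 4L) {
      d[1] <- (2 * x[1] - 5 * x[2] + 4 * x[3] - x[4]) / h^2
      d[n] <- (2 * x[n] - 5 * x[n - 1] + 4 * x[n - 2] - x[n - 3]) / h^2
    } else {
      d[1] <- d[2]
      d[n] <- d[2]
    }
    d
  }
}
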