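#' Analysis window specification
#'
#' Analysis windows are 150 ms long and advance by one sample (8.33 ms at
#' 120 Hz). A window is categorized as mid-swing when at least half of its
#' data come from mid-swing and less than half come from after residual-limb
#' heel strike. Two readings of that rule are provided:
#' \describe{
#'   \item{\code{span_rule} (default)}{mid-swing iff the window starts no
#'     earlier than \code{midswing_earliest_start_ms} before heel strike and
#'     ends no later than \code{latest_end_after_hs_ms} after it, i.e. window
#'     starts in [-250, -75] ms with the defaults. This matches the
#'     description of the classification region as running from mid-swing up
#'     to 75 ms after heel strike (22 windows per stride at 120 Hz).}
#'   \item{\code{strict_rule}}{additionally requires the window to
#'     \emph{begin} between \code{midswing_earliest_start_ms} and
#'     \code{midswing_latest_start_ms} before heel strike, i.e. starts in
#'     [-250, -192] ms (7 windows per stride at 120 Hz).}
#' }
#'
#' @param length_ms Window length in ms (default 150).
#' @param step_ms Step between consecutive window starts in ms (default
#'   1000/120, exactly one sample at 120 Hz).
#' @param midswing_earliest_start_ms Earliest mid-swing window start, ms
#'   before heel strike (default 250).
#' @param midswing_latest_start_ms Latest mid-swing window start under the
#'   strict rule, ms before heel strike (default 192).
#' @param latest_end_after_hs_ms Latest mid-swing window end, ms after heel
#'   strike (default 75).
#' @param rule \code{"span_rule"} or \code{"strict_rule"}.
#' @return Object of class \code{window_spec}.
#' @export
window_spec <- function(length_ms = 150, step_ms = 1000 / 120,
                        midswing_earliest_start_ms = 250,
                        midswing_latest_start_ms = 192,
                        latest_end_after_hs_ms = 75,
                        rule = c("span_rule", "strict_rule")) {
  rule <- match.arg(rule)
  if (length_ms <= 0 || step_ms <= 0) stop("length and step must be positive")
  if (midswing_earliest_start_ms <= midswing_latest_start_ms ||
      midswing_latest_start_ms < 0 || latest_end_after_hs_ms < 0) {
    stop("need earliest_start > latest_start >= 0 and latest_end >= 0")
  }
  structure(list(length_ms = length_ms, step_ms = step_ms,
                 midswing_earliest_start_ms = midswing_earliest_start_ms,
                 midswing_latest_start_ms = midswing_latest_start_ms,
                 latest_end_after_hs_ms = latest_end_after_hs_ms,
                 rule = rule),
            class = "window_spec")
}

window_samples <- function(spec, sample_rate) {
  max(1L, as.integer(round(spec$length_ms * sample_rate / 1000)))
}

step_samples <- function(spec, sample_rate) {
  max(1L, as.integer(round(spec$step_ms * sample_rate / 1000)))
}

#' Categorize a window by gait region
#'
#' Pure function of the window start time relative to heel strike (ms) and
#' the window spec; see \code{\link{window_spec}} for the two rules.
#'
#' @param start_time_rel_hs Window start in ms relative to heel strike
#'   (negative = before). Vectorized.
#' @param spec A \code{window_spec}.
#' @return Character vector, \code{"mid_swing"} or \code{"other"}.
#' @export
classify_window_region <- function(start_time_rel_hs, spec = window_spec()) {
  eps <- 1e-9
  starts_ok <- start_time_rel_hs >= -spec$midswing_earliest_start_ms - eps
  ends_ok <- start_time_rel_hs + spec$length_ms <=
    spec$latest_end_after_hs_ms + eps
  mid <- starts_ok & ends_ok
  if (spec$rule == "strict_rule") {
    mid <- mid & start_time_rel_hs <= -spec$midswing_latest_start_ms + eps
  }
  ifelse(mid, "mid_swing", "other")
}

#' Enumerate analysis windows over a trial
#'
#' Slides a window of \code{spec$length_ms} over the sample grid from the
#' first sample, advancing by \code{spec$step_ms} (snapped to whole samples),
#' and categorizes each window relative to the heel-strike sample.
#'
#' @param trial A \code{trial_recording}.
#' @param spec A \code{window_spec}.
#' @return Data frame with one row per window: \code{start_sample} and
#'   \code{end_sample} (half-open, 1-based), \code{start_ms} relative to heel
#'   strike, and \code{region}.
#' @export
enumerate_windows <- function(trial, spec = window_spec()) {
  stopifnot(inherits(trial, "trial_recording"), inherits(spec, "window_spec"))
  fs <- trial$sample_rate
  wlen <- window_samples(spec, fs)
  step <- step_samples(spec, fs)
  n <- nrow(trial$series)
  if (n < wlen) {
    stop("trial '", trial$trial_id, "' (", n,
         " samples) is shorter than one window (", wlen, " samples)")
  }
  hs_idx <- round(trial$heel_strike_time * fs) + 1  # snapped to grid
  starts <- seq.int(1L, n - wlen + 1L, by = step)
  start_ms <- (starts - hs_idx) * 1000 / fs
  data.frame(
    start_sample = starts,
    end_sample = starts + wlen,
    start_ms = start_ms,
    region = classify_window_region(start_ms, spec),
    stringsAsFactors = FALSE
  )
}

#' Closed-form mid-swing window count
#'
#' Number of mid-swing windows per stride on a sample grid anchored at the
#' heel-strike sample (window starts at integer multiples of the step).
#' Equals brute-force enumeration of the grid for any valid spec.
#'
#' @param spec A \code{window_spec}.
#' @param sample_rate Sampling frequency in Hz.
#' @return Integer count (22 for the default span rule at 120 Hz, 7 for the
#'   strict rule).
#' @export
midswing_window_count <- function(spec = window_spec(), sample_rate = 120) {
  eps <- 1e-9
  k <- step_samples(spec, sample_rate)
  lo <- ceiling(-spec$midswing_earliest_start_ms * sample_rate / 1000 - eps)
  hi <- floor((spec$latest_end_after_hs_ms - spec$length_ms) *
                sample_rate / 1000 + eps)
  if (spec$rule == "strict_rule") {
    hi <- min(hi, floor(-spec$midswing_latest_start_ms * sample_rate / 1000 +
                          eps))
  }
  if (hi < lo) return(0L)
  max(0L, as.integer(floor(hi / k) - ceiling(lo / k) + 1L))
}
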