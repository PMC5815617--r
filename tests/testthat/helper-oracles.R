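# Independent oracles and small fixture builders used across the suite.

# Pooled-covariance discriminant computed the long way: explicit per-class
# scatter accumulation and per-row score evaluation with solve(). Kept free
# of any package internals so it can stand against fit_lda/predict.
oracle_lda_predict <- function(x_train, y_train, x_test,
                               class_order = sort(unique(y_train))) {
  n <- nrow(x_train)
  k <- length(class_order)
  p <- ncol(x_train)
  mus <- list()
  scatter <- matrix(0, p, p)
  for (cl in class_order) {
    rows <- x_train[y_train == cl, , drop = FALSE]
    mu <- colMeans(rows)
    mus[[cl]] <- mu
    for (i in seq_len(nrow(rows))) {
      d <- rows[i, ] - mu
      scatter <- scatter + tcrossprod(d)
    }
  }
  sigma <- scatter / (n - k)
  sigma_inv <- solve(sigma)
  priors <- vapply(class_order, function(cl) mean(y_train == cl), numeric(1))
  apply(x_test, 1L, function(x) {
    scores <- vapply(seq_len(k), function(ci) {
      mu <- mus[[class_order[ci]]]
      drop(x %*% sigma_inv %*% mu) -
        0.5 * drop(mu %*% sigma_inv %*% mu) + log(priors[ci])
    }, numeric(1))
    class_order[which.max(scores)]
  })
}

# Draw a random 3-class Gaussian instance with shared covariance.
random_lda_instance <- function(p = sample(2:5, 1), n_per = sample(10:60, 1)) {
  classes <- terrain_levels()
  a <- matrix(stats::rnorm(p * p), p)
  sigma_chol <- chol(crossprod(a) / p + diag(0.5, p))
  mus <- lapply(seq_along(classes), function(i) stats::rnorm(p, sd = 2))
  draw <- function(mu, n) {
    sweep(matrix(stats::rnorm(n * p), n) %*% sigma_chol, 2L, mu, "+")
  }
  x_train <- do.call(rbind, lapply(mus, draw, n = n_per))
  y_train <- rep(classes, each = n_per)
  x_test <- do.call(rbind, lapply(mus, draw, n = 10))
  y_test <- rep(classes, each = 10)
  colnames(x_train) <- colnames(x_test) <- paste0("f", seq_len(p))
  list(x_train = x_train, y_train = y_train, x_test = x_test, y_test = y_test)
}

# Brute-force mid-swing window count: walk the heel-strike-anchored sample
# grid and classify each start with the region rule, written out directly.
brute_force_midswing_count <- function(spec, sample_rate) {
  eps <- 1e-9
  k <- max(1L, as.integer(round(spec$step_ms * sample_rate / 1000)))
  span <- ceiling((spec$midswing_earliest_start_ms + spec$length_ms +
                     spec$latest_end_after_hs_ms) * sample_rate / 1000) + 2L
  count <- 0L
  for (s in seq(-span, span)) {
    if (s %% k != 0) next
    start_ms <- s * 1000 / sample_rate
    ok <- start_ms >= -spec$midswing_earliest_start_ms - eps &&
      start_ms + spec$length_ms <= spec$latest_end_after_hs_ms + eps
    if (spec$rule == "strict_rule") {
      ok <- ok && start_ms <= -spec$midswing_latest_start_ms + eps
    }
    if (ok) count <- count + 1L
  }
  count
}

random_window_spec <- function() {
  length_ms <- stats::runif(1, 50, 400)
  step_ms <- stats::runif(1, 5, 60)
  latest_start <- stats::runif(1, 0, 300)
  earliest_start <- latest_start + stats::runif(1, 5, 300)
  window_spec(length_ms = length_ms, step_ms = step_ms,
              midswing_earliest_start_ms = earliest_start,
              midswing_latest_start_ms = latest_start,
              latest_end_after_hs_ms = stats::runif(1, 0, 200),
              rule = sample(c("span_rule", "strict_rule"), 1))
}

# Minimal hand-built trial: named deterministic signals, 120 Hz.
tiny_trial <- function(signals = c("a", "b"), n = 144, fs = 120,
                       hs = 0.8, terrain = "flush", subject = "S01",
                       id = "tiny1") {
  series <- sapply(seq_along(signals), function(j) {
    sin(2 * pi * j * (0:(n - 1)) / n) + j
  })
  colnames(series) <- signals
  trial_recording(series, sample_rate = fs, heel_strike_time = hs,
                  terrain = terrain, subject_id = subject, trial_id = id,
                  body_mass = 80)
}

# Amplitude of the f-Hz component over a central, integer-cycle stretch,
# via the discrete Fourier coefficient (rejects edge transients and other
# frequencies).
sinusoid_amplitude <- function(x, f, fs, margin_s) {
  i0 <- round(margin_s * fs) + 1
  i1 <- length(x) - round(margin_s * fs)
  mid <- x[i0:i1]
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  period <- fs / gcd(as.integer(f), as.integer(fs))  # samples per whole cycles
  n <- floor(length(mid) / period) * period
  mid <- mid[seq_len(n)]
  2 * Mod(sum(mid * exp(-2i * pi * f * (seq_len(n) - 1) / fs))) / n
}
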