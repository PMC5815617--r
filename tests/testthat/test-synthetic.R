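test_that("generation is deterministic and seed-sensitive", {
  cfg <- preset_discriminative(seed = 11, n_subjects = 2,
                               trials_per_class = 1)
  t1 <- generate_trial(cfg, 1, "inversion", 1)
  t2 <- generate_trial(cfg, 1, "inversion", 1)
  expect_identical(t1$series, t2$series)
  cfg2 <- preset_discriminative(seed = 12, n_subjects = 2,
                                trials_per_class = 1)
  t3 <- generate_trial(cfg2, 1, "inversion", 1)
  expect_false(identical(t1$series, t3$series))
  # the global RNG stream is left untouched
  set.seed(1)
  before <- .Random.seed
  invisible(generate_trial(cfg, 2, "flush", 1))
  expect_identical(.Random.seed, before)
})

test_that("zero effects, offsets and noise give class-identical trials", {
  cfg <- synthetic_config(inventory = signal_inventory("ips_only"),
                          n_subjects = 1, trials_per_class = 1,
                          subject_sd = 0, noise_sd = 1e-300, seed = 3)
  te <- generate_trial(cfg, 1, "eversion", 1)
  tf <- generate_trial(cfg, 1, "flush", 1)
  ti <- generate_trial(cfg, 1, "inversion", 1)
  expect_equal(te$series, tf$series, tolerance = 1e-12)
  expect_equal(tf$series, ti$series, tolerance = 1e-12)
})

test_that("dataset layout mirrors the study design", {
  cfg <- preset_discriminative(seed = 21)
  ds <- generate_dataset(cfg)
  expect_length(ds$trials, 45L)  # 3 subjects x 3 classes x 5 trials
  counts <- table(terrain_factor(dataset_labels(ds)))
  expect_true(all(counts == 15L))
  subj <- vapply(ds$trials, `[[`, character(1), "subject_id")
  expect_equal(length(unique(subj)), 3L)
  for (trial in ds$trials) validate_trial(trial, cfg$inventory)
  # different seeds give different data
  ds2 <- generate_dataset(preset_discriminative(seed = 22))
  expect_false(identical(ds$trials[[1]]$series, ds2$trials[[1]]$series))
})

test_that("class effects appear where and as configured", {
  delta <- 3
  cfg <- synthetic_config(
    inventory = signal_inventory("ips_only"),
    class_effects = list(ips_ml_acc = c(eversion = -delta,
                                        inversion = delta)),
    n_subjects = 1, trials_per_class = 40, subject_sd = 0, noise_sd = 1,
    seed = 31)
  fs <- cfg$sample_rate
  hs_idx <- round(cfg$heel_strike_time * fs) + 1
  # effect-window center (~ -87.5 ms): ramp is ~1 there
  center <- hs_idx + round(mean(cfg$effect_window_ms) * fs / 1000)
  span <- (center - 2):(center + 2)
  diff_means <- function(terrain) {
    base <- generate_trial(synthetic_config(
      inventory = cfg$inventory, n_subjects = 1, trials_per_class = 1,
      subject_sd = 0, noise_sd = 1e-300, seed = 31), 1, "flush", 1)
    vals <- vapply(seq_len(cfg$trials_per_class), function(k) {
      tr <- generate_trial(cfg, 1, terrain, k)
      mean(tr$series[span, "ips_ml_acc"] - base$series[span, "ips_ml_acc"])
    }, numeric(1))
    mean(vals)
  }
  n_eff <- cfg$trials_per_class * length(span)
  tol <- 3 * cfg$noise_sd / sqrt(n_eff)
  w_center <- mean(0.5 - 0.5 * cos(2 * pi *
    ((span - 1) / fs - cfg$heel_strike_time - cfg$effect_window_ms[1] / 1000) /
    (diff(cfg$effect_window_ms) / 1000)))
  expect_lt(abs(diff_means("inversion") - delta * w_center), tol)
  expect_lt(abs(diff_means("eversion") + delta * w_center), tol)
  expect_lt(abs(diff_means("flush")), tol)
})

test_that("subject offsets are constant within subject and sized by tau", {
  cfg <- synthetic_config(inventory = signal_inventory("ips_only"),
                          n_subjects = 60, trials_per_class = 1,
                          subject_sd = 0.5, noise_sd = 1e-300, seed = 41)
  base <- generate_trial(synthetic_config(
    inventory = cfg$inventory, n_subjects = 1, trials_per_class = 1,
    subject_sd = 0, noise_sd = 1e-300, seed = 41), 1, "flush", 1)
  offsets <- vapply(1:60, function(s) {
    tr <- generate_trial(cfg, s, "flush", 1)
    d <- tr$series[, "ips_cor_angvel"] - base$series[, "ips_cor_angvel"]
    expect_lt(diff(range(d)), 1e-9)  # constant over the stride
    d[1]
  }, numeric(1))
  expect_lt(abs(sd(offsets) - 0.5), 0.5 / sqrt(2 * 59) * 3.5)
})

test_that("discriminative preset separates informative from noise signals", {
  cfg <- preset_discriminative(seed = 51)
  fm <- build_feature_matrix(generate_dataset(cfg), cfg$inventory)
  solo <- function(sig) loocv(fm, signals = sig)$report$overall
  informative <- vapply(names(cfg$class_effects), solo, numeric(1))
  noise <- vapply(c("ankle_flexion_angle", "grf_vert", "ips_ml_acc"), solo,
                  numeric(1))
  expect_gt(min(informative), max(noise) + 0.2)
  # opposite effect signs for the two slopes on the inversion-rate channel
  eff <- cfg$class_effects$ankle_inversion_angvel
  expect_lt(eff[["eversion"]] * eff[["inversion"]], 0)
})

test_that("AR(1) noise matches its nominal marginal variance", {
  cfg <- synthetic_config(inventory = signal_inventory("ips_only"),
                          n_subjects = 1, trials_per_class = 10,
                          subject_sd = 0, noise_sd = 2,
                          noise_model = "ar1", seed = 61)
  base <- generate_trial(synthetic_config(
    inventory = cfg$inventory, n_subjects = 1, trials_per_class = 1,
    subject_sd = 0, noise_sd = 1e-300, seed = 61), 1, "flush", 1)
  resid <- unlist(lapply(1:10, function(k) {
    generate_trial(cfg, 1, "flush", k)$series[, 1] - base$series[, 1]
  }))
  # marginal sd within 15% (AR(1) correlation inflates the estimator's var)
  expect_lt(abs(sd(resid) - 2) / 2, 0.15)
  rho_hat <- cor(resid[-1], resid[-length(resid)])
  expect_gt(rho_hat, 0.8)
})

test_that("invalid configurations are refused", {
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(effect_window_ms = c(100, 800)),
               "outside the stride")
  expect_error(synthetic_config(n_subjects = 0), "at least one")
  expect_error(
    synthetic_config(class_effects = list(bogus = c(eversion = 1,
                                                    inversion = 1))),
    "absent from the inventory")
  expect_error(
    synthetic_config(inventory = signal_inventory("ips_only"),
                     class_effects = list(ips_ml_acc = c(eversion = 1))),
    "inversion")
})
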