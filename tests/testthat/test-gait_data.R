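test_that("inventories have the documented feature counts and policies", {
  for (variant in c("full_with_ips", "full_mc_only")) {
    inv <- signal_inventory(variant)
    expect_equal(n_features(inv), 124L)
    expect_equal(sum(inv$stat_policy == "four_stats"), 28L)
    expect_equal(sum(inv$stat_policy == "two_stats"), 6L)
  }
  ips <- signal_inventory("ips_only")
  expect_equal(n_features(ips), 24L)
  expect_equal(nrow(ips), 6L)
  # GRF/COP are exactly the two-statistic signals
  full <- signal_inventory("full_with_ips")
  two <- full$name[full$stat_policy == "two_stats"]
  expect_setequal(two, c(paste0("grf_", c("ap", "ml", "vert")),
                         paste0("cop_", c("ap", "ml", "vert"))))
  expect_equal(length(feature_keys(full)), 124L)
  expect_false(anyDuplicated(feature_keys(full)) > 0)
})

test_that("terrain labels and slopes are a bijection over three classes", {
  expect_equal(terrain_slope(terrain_levels()), c(-15, 0, 15))
  expect_equal(terrain_from_slope(c(-15, 0, 15)), terrain_levels())
  expect_error(terrain_from_slope(5), "slope")
  expect_error(terrain_slope("uphill"), "unknown")
})

test_that("trial write/read round-trips field-by-field", {
  trial <- tiny_trial(signals = c("grf_vert", "ankle_flexion_angle"))
  trial$units <- c(grf_vert = "N", ankle_flexion_angle = "deg")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial(trial, path)
  back <- read_trial(path)
  expect_equal(back$series, trial$series, tolerance = 1e-12)
  expect_identical(back$terrain, trial$terrain)
  expect_identical(back$subject_id, trial$subject_id)
  expect_identical(back$trial_id, trial$trial_id)
  expect_equal(back$heel_strike_time, trial$heel_strike_time)
  expect_equal(back$sample_rate, trial$sample_rate)
  expect_equal(back$body_mass, trial$body_mass)
  expect_equal(back$units, trial$units)
  # deterministic serialization: identical bytes on rewrite
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_trial(trial, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
  # layout: one header + preamble + one row per sample, time + 2 signals
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  expect_length(body, nrow(trial$series) + 1L)
  expect_equal(strsplit(body[1], "\t")[[1]],
               c("time", "grf_vert", "ankle_flexion_angle"))
})

test_that("reader fails loudly on missing signals and missing events", {
  trial <- tiny_trial(signals = signal_inventory("ips_only")$name[-6])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial(trial, path)
  expect_error(read_trial(path, expect_signals = signal_inventory("ips_only")),
               "ips_tran_angvel")
  # strip the heel-strike line from the preamble
  lines <- readLines(path)
  writeLines(lines[!grepl("heel_strike_time", lines)], path)
  expect_error(read_trial(path), "heel-strike")
})

test_that("reader rejects non-uniform time steps", {
  path <- withr::local_tempfile(fileext = ".tsv")
  n <- 60
  time <- (0:(n - 1)) / 120
  time[30] <- time[30] + 0.004  # a dropped-frame style glitch
  writeLines(c("# terrain: flush", "# heel_strike_time: 0.3",
               "# subject_id: S01", "# trial_id: bad",
               paste("time", "a", sep = "\t"),
               paste(time, seq_len(n), sep = "\t")), path)
  expect_error(read_trial(path), "non-uniform")
})

test_that("dialect reader maps foreign columns onto package signals", {
  path <- withr::local_tempfile(fileext = ".txt")
  n <- 60
  writeLines(c(paste("Frame", "AnkleFlex", "VertGRF", sep = "\t"),
               paste(seq_len(n), sin(seq_len(n) / 10), 800, sep = "\t")),
             path)
  dia <- trial_dialect(
    columns = c(AnkleFlex = "ankle_flexion_angle", VertGRF = "grf_vert"),
    time_col = NULL, sample_rate = 120,
    metadata = list(terrain = "inversion", heel_strike_time = 0.3,
                    subject_id = "S09", trial_id = "foreign1"))
  trial <- read_trial(path, dialect = dia)
  expect_equal(colnames(trial$series),
               c("ankle_flexion_angle", "grf_vert"))
  expect_identical(trial$terrain, "inversion")
  expect_equal(trial$sample_rate, 120)
  # a declared column absent from the file is an error naming it
  dia_bad <- dia
  dia_bad$columns <- c(dia$columns, Missing = "cop_ap")
  expect_error(read_trial(path, dialect = dia_bad), "Missing")
})

test_that("dataset round-trip through manifest preserves counts and labels", {
  cfg <- preset_single_signal(seed = 3, n_subjects = 1, trials_per_class = 3)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  back <- load_dataset(manifest)
  expect_length(back$trials, 9L)
  expect_equal(unname(table(terrain_factor(dataset_labels(back)))),
               rep(3L, 3), ignore_attr = TRUE)
  expect_identical(back$role, "synthetic")
})

test_that("manifest loading rejects empty manifests and mixed inventories", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.tsv")
  writeLines(character(0), empty)
  expect_error(load_dataset(empty), "no trials")

  t1 <- tiny_trial(signals = c("a", "b"), id = "t1")
  t2 <- tiny_trial(signals = c("a", "c"), id = "t2")
  write_trial(t1, file.path(dir, "t1.tsv"))
  write_trial(t2, file.path(dir, "t2.tsv"))
  mixed <- file.path(dir, "mixed.tsv")
  writeLines(c("t1.tsv\ttraining", "t2.tsv\ttraining"), mixed)
  expect_error(load_dataset(mixed), "inconsistent")
})

test_that("trial validation enforces heel-strike margins", {
  series <- matrix(0, 30, 1, dimnames = list(NULL, "a"))
  expect_error(
    trial_recording(series, 120, heel_strike_time = 0.05, terrain = "flush",
                    subject_id = "s", trial_id = "t"),
    "before")
  expect_error(
    trial_recording(series, 120, heel_strike_time = 0.5, terrain = "flush",
                    subject_id = "s", trial_id = "t"),
    "outside")
})
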