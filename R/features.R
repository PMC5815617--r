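#' Per-window summary statistics
#'
#' Statistics computed over one analysis window of one signal: mean, sample
#' standard deviation (n - 1 denominator), maximum and minimum for kinematic,
#' moment and power signals; mean and standard deviation only for GRF and COP
#' signals.
#'
#' @param x Numeric window segment, length >= 2.
#' @param policy \code{"four_stats"} or \code{"two_stats"}.
#' @return Named numeric vector in the fixed order mean, sd, max, min
#'   (first two for \code{two_stats}).
#' @export
#' @examples
#' window_statistics(c(1, 2, 3, 4))
window_statistics <- function(x, policy = c("four_stats", "two_stats")) {
  policy <- match.arg(policy)
  if (length(x) < 2L) stop("window segment must have at least 2 samples")
  out <- c(mean = mean(x), sd = stats::sd(x), max = max(x), min = min(x))
  out[stat_names(policy)]
}

#' Build the feature vector of one window
#'
#' Concatenates the per-window statistics of every inventory signal, in
#' inventory order crossed with statistic order, into a single vector: 124
#' values for the full inventories, 24 for the in-pylon-only inventory.
#'
#' @param trial A \code{trial_recording} providing every inventory signal.
#' @param window One row of \code{\link{enumerate_windows}} (or any list with
#'   \code{start_sample} and \code{end_sample}).
#' @param inventory A \code{signal_inventory}.
#' @return Named numeric vector keyed \code{"<signal>.<stat>"}.
#' @export
build_feature_vector <- function(trial, window, inventory) {
  stopifnot(inherits(trial, "trial_recording"),
            inherits(inventory, "signal_inventory"))
  missing <- setdiff(inventory$name, colnames(trial$series))
  if (length(missing)) {
    stop("trial '", trial$trial_id, "' is missing signal(s): ",
         paste(missing, collapse = ", "))
  }
  i0 <- window$start_sample
  i1 <- window$end_sample - 1L
  if (i0 < 1L || i1 > nrow(trial$series)) {
    stop("window [", i0, ", ", i1, "] outside trial '", trial$trial_id, "'")
  }
  seg <- trial$series[i0:i1, inventory$name, drop = FALSE]
  vals <- unlist(lapply(seq_len(nrow(inventory)), function(j) {
    window_statistics(seg[, j], inventory$stat_policy[j])
  }), use.names = FALSE)
  names(vals) <- feature_keys(inventory)
  vals
}

#' Build the feature matrix of a dataset
#'
#' One row per mid-swing window per trial, with trial, subject and label
#' provenance retained so resampling can be done at the trial level without
#' leaking near-duplicate windows across folds. Trials that yield no
#' mid-swing window are excluded with a warning.
#'
#' @param dataset A \code{gait_dataset}.
#' @param inventory A \code{signal_inventory}.
#' @param spec A \code{window_spec}.
#' @return Object of class \code{feature_matrix}: list with \code{values}
#'   (numeric matrix), \code{info} (data frame: trial_id, subject_id, label,
#'   start_ms) and \code{inventory}.
#' @export
build_feature_matrix <- function(dataset, inventory, spec = window_spec()) {
  stopifnot(inherits(dataset, "gait_dataset"),
            inherits(inventory, "signal_inventory"),
            inherits(spec, "window_spec"))
  rows <- list()
  info <- list()
  for (trial in dataset$trials) {
    win <- enumerate_windows(trial, spec)
    win <- win[win$region == "mid_swing", , drop = FALSE]
    if (!nrow(win)) {
      warning("trial '", trial$trial_id,
              "' yields no mid-swing window; excluded")
      next
    }
    vals <- t(vapply(seq_len(nrow(win)), function(i) {
      build_feature_vector(trial, win[i, ], inventory)
    }, numeric(n_features(inventory))))
    rows[[length(rows) + 1L]] <- vals
    info[[length(info) + 1L]] <- data.frame(
      trial_id = trial$trial_id, subject_id = trial$subject_id,
      label = trial$terrain, start_ms = win$start_ms,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("dataset yields no mid-swing windows")
  values <- do.call(rbind, rows)
  colnames(values) <- feature_keys(inventory)
  structure(list(values = values, info = do.call(rbind, info),
                 inventory = inventory),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " windows x ", ncol(x$values),
      " features (", length(unique(x$info$trial_id)), " trials, ",
      length(unique(x$info$subject_id)), " subjects)\n", sep = "")
  invisible(x)
}

#' Restrict a feature matrix to a signal subset
#'
#' Keeps every statistic column belonging to the chosen signals, preserving
#' inventory order. Selection operates at signal granularity: a signal's 2 or
#' 4 statistics always move together.
#'
#' @param fm A \code{feature_matrix}.
#' @param signals Character vector of signal names, a subset of the
#'   inventory.
#' @return A \code{feature_matrix} over the restricted inventory.
#' @export
restrict_to_signals <- function(fm, signals) {
  stopifnot(inherits(fm, "feature_matrix"))
  unknown <- setdiff(signals, fm$inventory$name)
  if (length(unknown)) {
    stop("unknown signal(s): ", paste(unknown, collapse = ", "))
  }
  keep <- fm$inventory$name %in% signals
  sub_inv <- new_signal_inventory(fm$inventory[keep, , drop = FALSE],
                                  variant = "custom")
  keys <- feature_keys(sub_inv)
  structure(list(values = fm$values[, keys, drop = FALSE],
                 info = fm$info, inventory = sub_inv),
            class = "feature_matrix")
}

#' Subset feature-matrix rows
#'
#' @param fm A \code{feature_matrix}.
#' @param rows Integer or logical row index.
#' @return A \code{feature_matrix} with the selected windows.
#' @export
fm_rows <- function(fm, rows) {
  stopifnot(inherits(fm, "feature_matrix"))
  structure(list(values = fm$values[rows, , drop = FALSE],
                 info = fm$info[rows, , drop = FALSE],
                 inventory = fm$inventory),
            class = "feature_matrix")
}

#' Serialize a feature matrix to TSV
#'
#' @param fm A \code{feature_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- cbind(fm$info[c("trial_id", "subject_id", "label", "start_ms")],
              as.data.frame(fm$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
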