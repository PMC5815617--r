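#' Single-stride trial recording
#'
#' Container for one trial: a multichannel time series sampled on a shared
#' uniform time base, the residual-limb heel-strike event that anchors all
#' analysis windows, the terrain label, and subject/prosthesis metadata. The
#' protocol records one step on the cross-slope per trial, so a trial holds
#' one stride.
#'
#' @param series Numeric matrix, samples in rows, one named column per signal.
#' @param sample_rate Sampling frequency in Hz (default 120).
#' @param heel_strike_time Heel-strike event time in seconds on the trial
#'   time base (time 0 is the first sample).
#' @param terrain Terrain label, one of \code{terrain_levels()}.
#' @param subject_id Subject identifier.
#' @param trial_id Trial identifier; must be unique within a dataset.
#' @param prosthesis \code{"prescribed"} or \code{"prototype"}.
#' @param body_mass Subject body mass in kg, or \code{NULL} if unknown.
#' @param units Optional named character vector mapping signal names to unit
#'   strings.
#' @return An object of class \code{trial_recording}.
#' @export
trial_recording <- function(series, sample_rate = 120, heel_strike_time,
                            terrain, subject_id, trial_id,
                            prosthesis = c("prescribed", "prototype"),
                            body_mass = NULL, units = NULL) {
  prosthesis <- match.arg(prosthesis)
  series <- as.matrix(series)
  storage.mode(series) <- "double"
  if (is.null(colnames(series)) || anyDuplicated(colnames(series))) {
    stop("series must have unique column names (signal names)")
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be positive")
  }
  terrain <- match.arg(terrain, terrain_levels())
  trial <- structure(list(
    series = series,
    sample_rate = sample_rate,
    heel_strike_time = heel_strike_time,
    terrain = terrain,
    subject_id = as.character(subject_id),
    trial_id = as.character(trial_id),
    prosthesis = prosthesis,
    body_mass = body_mass,
    units = units
  ), class = "trial_recording")
  validate_trial(trial)
  trial
}

#' Validate a trial recording
#'
#' Checks the structural invariants a trial must satisfy to be classifiable:
#' uniform shared time base (all series share one length), heel strike inside
#' the recording with at least \code{pre_ms} of signal before it and
#' \code{post_ms} after it (the span the mid-swing windows need).
#'
#' @param trial A \code{trial_recording}.
#' @param inventory Optional \code{signal_inventory}; when given, the trial
#'   must provide every inventory signal.
#' @param pre_ms,post_ms Required margins around heel strike, in ms.
#' @return The trial, invisibly. Errors describe the first violated invariant.
#' @export
validate_trial <- function(trial, inventory = NULL, pre_ms = 250,
                           post_ms = 75) {
  stopifnot(inherits(trial, "trial_recording"))
  n <- nrow(trial$series)
  if (n < 2L) stop("trial '", trial$trial_id, "': series too short")
  duration <- (n - 1L) / trial$sample_rate
  hs <- trial$heel_strike_time
  if (!is.numeric(hs) || length(hs) != 1L || is.na(hs)) {
    stop("trial '", trial$trial_id, "': heel_strike_time missing")
  }
  if (hs < 0 || hs > duration) {
    stop("trial '", trial$trial_id, "': heel strike outside recording")
  }
  if (hs < pre_ms / 1000 || duration - hs < post_ms / 1000) {
    stop("trial '", trial$trial_id, "': need >= ", pre_ms,
         " ms before and >= ", post_ms, " ms after heel strike")
  }
  if (!is.null(inventory)) {
    missing <- setdiff(inventory$name, colnames(trial$series))
    if (length(missing)) {
      stop("trial '", trial$trial_id, "' is missing signal(s): ",
           paste(missing, collapse = ", "))
    }
  }
  invisible(trial)
}

#' @export
print.trial_recording <- function(x, ...) {
  cat("<trial_recording> ", x$trial_id, "\n",
      "  subject: ", x$subject_id, " (", x$prosthesis, ")\n",
      "  terrain: ", x$terrain, " (", terrain_slope(x$terrain), " deg)\n",
      "  ", nrow(x$series), " samples x ", ncol(x$series), " signals @ ",
      x$sample_rate, " Hz, heel strike at ", x$heel_strike_time, " s\n",
      sep = "")
  invisible(x)
}

#' Dataset of trial recordings
#'
#' @param trials List of \code{trial_recording} objects with a consistent
#'   signal set and unique trial ids.
#' @param role Dataset role: \code{"training"}, \code{"test1"},
#'   \code{"test2"} or \code{"synthetic"}.
#' @return Object of class \code{gait_dataset}.
#' @export
gait_dataset <- function(trials, role = c("training", "test1", "test2",
                                          "synthetic")) {
  role <- match.arg(role)
  if (!length(trials)) stop("dataset must contain at least one trial")
  if (!all(vapply(trials, inherits, logical(1), "trial_recording"))) {
    stop("all elements must be trial_recording objects")
  }
  ids <- vapply(trials, `[[`, character(1), "trial_id")
  if (anyDuplicated(ids)) stop("duplicate trial ids in dataset")
  ref <- sort(colnames(trials[[1]]$series))
  for (t in trials) {
    if (!identical(sort(colnames(t$series)), ref)) {
      stop("trial '", t$trial_id,
           "' has a different signal set than the rest of the dataset")
    }
  }
  names(trials) <- ids
  structure(list(trials = trials, role = role), class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  lab <- vapply(x$trials, `[[`, character(1), "terrain")
  cat("<gait_dataset> role=", x$role, ", ", length(x$trials), " trials\n",
      sep = "")
  print(table(factor(lab, levels = terrain_levels())))
  invisible(x)
}

#' Terrain labels of a dataset
#'
#' @param dataset A \code{gait_dataset}.
#' @return Character vector of per-trial terrain labels, named by trial id.
#' @export
dataset_labels <- function(dataset) {
  stopifnot(inherits(dataset, "gait_dataset"))
  vapply(dataset$trials, `[[`, character(1), "terrain")
}
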