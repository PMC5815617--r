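#' Write a trial to a tab-separated text file
#'
#' Serializes a \code{trial_recording} to the package's canonical trial
#' format: a '#'-prefixed metadata preamble (\code{key: value} lines for
#' subject_id, trial_id, prosthesis, terrain, heel_strike_time, sample_rate
#' and optionally body_mass and units), a header row of column names, a time
#' column in seconds, and one tab-separated row per sample. Numbers are
#' written with 15 significant digits so a read/write round trip reproduces
#' the trial to text precision, and serialization is deterministic (identical
#' bytes for identical trials).
#'
#' @param trial A \code{trial_recording}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trial <- function(trial, path) {
  validate_trial(trial)
  meta <- c(
    subject_id = trial$subject_id,
    trial_id = trial$trial_id,
    prosthesis = trial$prosthesis,
    terrain = trial$terrain,
    heel_strike_time = format(trial$heel_strike_time, digits = 15),
    sample_rate = format(trial$sample_rate, digits = 15)
  )
  if (!is.null(trial$body_mass)) {
    meta <- c(meta, body_mass = format(trial$body_mass, digits = 15))
  }
  if (!is.null(trial$units)) {
    meta <- c(meta, units = paste(names(trial$units), trial$units,
                                  sep = "=", collapse = ";"))
  }
  n <- nrow(trial$series)
  time <- (seq_len(n) - 1L) / trial$sample_rate
  body <- cbind(time = time, trial$series)
  lines <- c(
    paste0("# ", names(meta), ": ", meta),
    paste(colnames(body), collapse = "\t"),
    apply(body, 1L, function(r) {
      paste(formatC(r, digits = 15, format = "g"), collapse = "\t")
    })
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Column-mapping dialect for foreign trial files
#'
#' Describes how to read a tab-separated trial file whose layout differs from
#' the canonical format, e.g. the deposited supplementary TXT exports. The
#' reader never sniffs: every signal column must be declared explicitly.
#'
#' @param columns Named character vector mapping file column names to package
#'   signal names.
#' @param time_col Name of the time column (seconds), or \code{NULL} if the
#'   file has none (then \code{sample_rate} must be given).
#' @param sample_rate Sampling rate in Hz, used when \code{time_col} is
#'   \code{NULL} and as a cross-check otherwise.
#' @param metadata Named list of metadata values (\code{terrain},
#'   \code{heel_strike_time}, \code{subject_id}, ...) supplied externally for
#'   files that carry none.
#' @return Object of class \code{trial_dialect}.
#' @export
trial_dialect <- function(columns = NULL, time_col = "time",
                          sample_rate = NULL, metadata = list()) {
  structure(list(columns = columns, time_col = time_col,
                 sample_rate = sample_rate, metadata = metadata),
            class = "trial_dialect")
}

#' Read a trial from a tab-separated text file
#'
#' Reads the canonical trial format written by \code{\link{write_trial}}, or
#' a foreign layout described by an explicit \code{\link{trial_dialect}}.
#' Fails loudly on missing signals, non-uniform sampling or an absent
#' heel-strike event rather than guessing.
#'
#' @param path File path.
#' @param dialect Optional \code{trial_dialect}. When given,
#'   \code{dialect$columns} declares which file columns become which signals
#'   and \code{dialect$metadata} can supply or override preamble metadata.
#' @param expect_signals Optional character vector (or
#'   \code{signal_inventory}) of required signal names; missing ones raise an
#'   error naming them.
#' @param time_tolerance Maximum relative deviation of any time step from the
#'   nominal sampling interval before a sampling error is raised.
#' @return A validated \code{trial_recording}.
#' @export
read_trial <- function(path, dialect = NULL, expect_signals = NULL,
                       time_tolerance = 1e-6) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta_lines <- lines[is_meta & seq_along(lines) < match(FALSE, is_meta)]
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([^:]+):\\s*(.*)$", ml))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  if (!is.null(dialect)) {
    for (k in names(dialect$metadata)) meta[[k]] <- dialect$metadata[[k]]
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 2L) stop("file '", path, "' has no data rows")
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1]]
  dat <- utils::read.table(text = body[-1L], sep = "\t",
                           col.names = header, check.names = FALSE)
  time_col <- if (is.null(dialect)) "time" else dialect$time_col
  if (!is.null(dialect) && !is.null(dialect$columns)) {
    missing_file <- setdiff(names(dialect$columns), header)
    if (length(missing_file)) {
      stop("file '", path, "' is missing declared column(s): ",
           paste(missing_file, collapse = ", "))
    }
    sig <- as.matrix(dat[names(dialect$columns)])
    colnames(sig) <- unname(dialect$columns)
  } else {
    keep <- setdiff(header, time_col)
    sig <- as.matrix(dat[keep])
  }
  # sample rate: from preamble, dialect, or the time column
  sample_rate <- suppressWarnings(as.numeric(meta$sample_rate))
  if (!length(sample_rate) || is.na(sample_rate)) {
    sample_rate <- if (!is.null(dialect)) dialect$sample_rate else NULL
  }
  if (!is.null(time_col) && time_col %in% names(dat)) {
    dt <- diff(dat[[time_col]])
    if (length(dt)) {
      if (any(dt <= 0) || max(abs(dt - mean(dt))) > time_tolerance * mean(dt)) {
        stop("file '", path, "': non-uniform time steps")
      }
      rate_from_time <- 1 / mean(dt)
      if (is.null(sample_rate) || is.na(sample_rate)) {
        sample_rate <- rate_from_time
      } else if (abs(rate_from_time - sample_rate) > 1e-3 * sample_rate) {
        stop("file '", path, "': time column implies ",
             signif(rate_from_time, 6), " Hz but sample_rate is ", sample_rate)
      }
    }
  }
  if (is.null(sample_rate) || is.na(sample_rate)) {
    stop("file '", path, "': sample rate unknown (no time column, ",
         "no preamble, none in dialect)")
  }
  if (is.null(meta$heel_strike_time)) {
    stop("file '", path, "': heel-strike event missing")
  }
  if (!is.null(expect_signals)) {
    want <- if (inherits(expect_signals, "signal_inventory")) {
      expect_signals$name
    } else expect_signals
    missing_sig <- setdiff(want, colnames(sig))
    if (length(missing_sig)) {
      stop("file '", path, "' is missing signal(s): ",
           paste(missing_sig, collapse = ", "))
    }
  }
  units <- NULL
  if (!is.null(meta$units)) {
    kv <- strsplit(strsplit(meta$units, ";", fixed = TRUE)[[1]], "=",
                   fixed = TRUE)
    units <- vapply(kv, `[`, character(1), 2L)
    names(units) <- vapply(kv, `[`, character(1), 1L)
  }
  trial_recording(
    series = sig,
    sample_rate = sample_rate,
    heel_strike_time = as.numeric(meta$heel_strike_time),
    terrain = meta$terrain %||% stop("file '", path, "': terrain missing"),
    subject_id = meta$subject_id %||% "unknown",
    trial_id = meta$trial_id %||% tools::file_path_sans_ext(basename(path)),
    prosthesis = meta$prosthesis %||% "prescribed",
    body_mass = if (!is.null(meta$body_mass)) as.numeric(meta$body_mass),
    units = units
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dataset and its manifest
#'
#' Writes every trial with \code{\link{write_trial}} into \code{dir} and a
#' manifest listing one \code{path<TAB>role} pair per line.
#'
#' @param dataset A \code{gait_dataset}.
#' @param dir Output directory (created if absent).
#' @param manifest Manifest file name within \code{dir}.
#' @return Path of the manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir, manifest = "manifest.tsv") {
  stopifnot(inherits(dataset, "gait_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rel <- paste0(vapply(dataset$trials, `[[`, character(1), "trial_id"), ".tsv")
  for (i in seq_along(dataset$trials)) {
    write_trial(dataset$trials[[i]], file.path(dir, rel[i]))
  }
  mpath <- file.path(dir, manifest)
  con <- file(mpath, open = "wb")
  writeLines(paste(rel, dataset$role, sep = "\t"), con, sep = "\n")
  close(con)
  invisible(mpath)
}

#' Load a dataset from a manifest
#'
#' The manifest lists one trial file per line as \code{path<TAB>role}
#' (paths relative to the manifest). All trials must share one signal set and
#' one role; a mismatch raises a schema error naming the offending trial.
#'
#' @param manifest Manifest file path.
#' @param dialect Optional \code{trial_dialect} applied to every trial file.
#' @return A \code{gait_dataset}.
#' @export
load_dataset <- function(manifest, dialect = NULL) {
  if (!file.exists(manifest)) stop("no such manifest: ", manifest)
  lines <- readLines(manifest)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (!length(lines)) stop("manifest '", manifest, "' lists no trials")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  paths <- vapply(parts, `[`, character(1), 1L)
  roles <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "training",
                  character(1))
  if (length(unique(roles)) != 1L) {
    stop("manifest mixes roles: ", paste(unique(roles), collapse = ", "))
  }
  base <- dirname(manifest)
  trials <- lapply(paths, function(p) {
    read_trial(file.path(base, p), dialect = dialect)
  })
  ref <- sort(colnames(trials[[1]]$series))
  for (i in seq_along(trials)) {
    if (!identical(sort(colnames(trials[[i]]$series)), ref)) {
      stop("trial file '", paths[i],
           "' has a signal set inconsistent with '", paths[1], "'")
    }
  }
  gait_dataset(trials, role = roles[1L])
}
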