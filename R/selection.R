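#' Evaluation protocol for wrapper selection
#'
#' Defines how candidate signal sets are scored while selecting ("Pick"):
#' either leave-one-trial-out cross-validation on the training windows, or
#' accuracy of a single train/test split against a fixed held-out dataset.
#'
#' @param kind \code{"loocv_training"} or \code{"fixed_test"}.
#' @param test A test \code{feature_matrix}, required for
#'   \code{"fixed_test"}.
#' @param unit Cross-validation unit for \code{"loocv_training"}.
#' @return Object of class \code{eval_protocol}.
#' @export
eval_protocol <- function(kind = c("loocv_training", "fixed_test"),
                          test = NULL, unit = "trial") {
  kind <- match.arg(kind)
  if (kind == "fixed_test" && !inherits(test, "feature_matrix")) {
    stop("fixed_test protocol needs a test feature_matrix")
  }
  structure(list(kind = kind, test = test, unit = unit),
            class = "eval_protocol")
}

# score one signal subset under a protocol; returns an accuracy_report
score_signals <- function(train_fm, signals, protocol, lambda,
                          priors = "empirical", scale = FALSE) {
  if (protocol$kind == "loocv_training") {
    loocv(train_fm, signals = signals, lambda = lambda, unit = protocol$unit,
          priors = priors, scale = scale)$report
  } else {
    evaluate_on_test(train_fm, protocol$test, signals = signals,
                     lambda = lambda, priors = priors, scale = scale)$report
  }
}

new_selection_trace <- function(method, steps, ranking, inventory, protocol,
                                lambda) {
  structure(list(method = method, steps = steps, ranking = ranking,
                 inventory = inventory, protocol_kind = protocol$kind,
                 lambda = lambda),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace> ", x$method, " over ", nrow(x$inventory),
      " signals (", x$protocol_kind, ")\n", sep = "")
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Sequential forward selection of input signals
#'
#' Greedy wrapper selection: starting from the empty set, every remaining
#' signal is tried in combination with the signals already chosen, and the
#' one giving the most accurate classifier is added; this repeats until all
#' signals are ranked. Accuracy ties break toward the signal that appears
#' first in the inventory, making the ranking deterministic.
#'
#' @param train Training data: a \code{feature_matrix}, or a
#'   \code{gait_dataset} together with \code{inventory}.
#' @param inventory \code{signal_inventory}, required when \code{train} is a
#'   dataset.
#' @param protocol An \code{\link{eval_protocol}}.
#' @param lambda Shrinkage for every fitted classifier.
#' @param window \code{window_spec} used when featurizing a dataset.
#' @return A \code{selection_trace}: per-step table (signal, accuracy,
#'   per-class accuracy range) and the full ranking.
#' @export
sfs <- function(train, inventory = NULL,
                protocol = eval_protocol("loocv_training"),
                lambda = 1e-4, window = window_spec()) {
  fm <- as_feature_matrix(train, inventory, window)
  sig <- fm$inventory$name
  if (length(sig) < 2L) stop("need at least 2 signals to select among")
  if (length(unique(fm$info$label)) < 2L) {
    stop("training data contain a single terrain class")
  }
  chosen <- character(0)
  steps <- vector("list", length(sig))
  for (step in seq_along(sig)) {
    remaining <- setdiff(sig, chosen)   # inventory order preserved
    reports <- lapply(remaining, function(s) {
      score_signals(fm, c(chosen, s), protocol, lambda)
    })
    acc <- vapply(reports, `[[`, numeric(1), "overall")
    best <- which.max(acc)              # first max = lowest inventory index
    chosen <- c(chosen, remaining[best])
    rng <- reports[[best]]$per_class_range
    steps[[step]] <- data.frame(
      step = step, signal = remaining[best], n_signals = step,
      accuracy = acc[best], per_class_min = rng[["min"]],
      per_class_max = rng[["max"]], stringsAsFactors = FALSE)
  }
  new_selection_trace("SFS", do.call(rbind, steps), chosen, fm$inventory,
                      protocol, lambda)
}

#' Sequential backward selection of input signals
#'
#' Greedy backward elimination: starting from the full signal set, each
#' candidate removal is evaluated and the signal whose removal leaves the
#' most accurate classifier (i.e. the least useful signal) is dropped; this
#' repeats until a single signal survives. The ranking reports the reverse
#' removal order, so the last survivor has rank 1. Ties break toward the
#' lowest inventory index.
#'
#' @inheritParams sfs
#' @return A \code{selection_trace} with one step per removal (evaluated set
#'   sizes N-1 down to 1).
#' @export
sbs <- function(train, inventory = NULL,
                protocol = eval_protocol("loocv_training"),
                lambda = 1e-4, window = window_spec()) {
  fm <- as_feature_matrix(train, inventory, window)
  sig <- fm$inventory$name
  if (length(sig) < 2L) stop("need at least 2 signals to select among")
  if (length(unique(fm$info$label)) < 2L) {
    stop("training data contain a single terrain class")
  }
  current <- sig
  removed <- character(0)
  steps <- vector("list", length(sig) - 1L)
  for (step in seq_len(length(sig) - 1L)) {
    reports <- lapply(current, function(s) {
      score_signals(fm, setdiff(current, s), protocol, lambda)
    })
    acc <- vapply(reports, `[[`, numeric(1), "overall")
    worst <- which.max(acc)             # removing it hurts least
    rng <- reports[[worst]]$per_class_range
    steps[[step]] <- data.frame(
      step = step, signal = current[worst],
      n_signals = length(current) - 1L, accuracy = acc[worst],
      per_class_min = rng[["min"]], per_class_max = rng[["max"]],
      stringsAsFactors = FALSE)
    removed <- c(removed, current[worst])
    current <- setdiff(current, current[worst])
  }
  ranking <- c(current, rev(removed))
  new_selection_trace("SBS", do.call(rbind, steps), ranking, fm$inventory,
                      protocol, lambda)
}

as_feature_matrix <- function(x, inventory = NULL, window = window_spec()) {
  if (inherits(x, "feature_matrix")) return(x)
  if (inherits(x, "gait_dataset")) {
    if (is.null(inventory)) {
      stop("an inventory is required to featurize a dataset")
    }
    return(build_feature_matrix(x, inventory, window))
  }
  stop("expected a feature_matrix or gait_dataset")
}

#' Accuracy as a function of signal count
#'
#' Re-evaluates the nested signal sets along a selection path (prefixes of
#' the final ranking) on one or more measurement datasets, producing the
#' accuracy-versus-signal-count curves and, across pick/measure protocol
#' combinations, the cross-evaluation grid.
#'
#' @param trace A \code{selection_trace}.
#' @param train_fm The training \code{feature_matrix} the trace was built on.
#' @param measure Named list of measurements: each element either the string
#'   \code{"loocv"} (leave-one-trial-out on the training windows) or a test
#'   \code{feature_matrix}.
#' @param lambda Shrinkage; defaults to the trace's value.
#' @return Data frame with one row per signal count (1..N) and one accuracy
#'   column per measure.
#' @export
accuracy_vs_count_curve <- function(trace, train_fm,
                                    measure = list(loocv = "loocv"),
                                    lambda = NULL) {
  stopifnot(inherits(trace, "selection_trace"),
            inherits(train_fm, "feature_matrix"))
  if (is.null(lambda)) lambda <- trace$lambda
  if (is.null(names(measure)) || any(!nzchar(names(measure)))) {
    stop("measure must be a named list")
  }
  ranking <- trace$ranking
  out <- data.frame(n_signals = seq_along(ranking),
                    signal_added = ranking, stringsAsFactors = FALSE)
  for (mname in names(measure)) {
    m <- measure[[mname]]
    accs <- vapply(seq_along(ranking), function(k) {
      signals <- ranking[seq_len(k)]
      if (identical(m, "loocv")) {
        loocv(train_fm, signals = signals, lambda = lambda)$report$overall
      } else if (inherits(m, "feature_matrix")) {
        evaluate_on_test(train_fm, m, signals = signals,
                         lambda = lambda)$report$overall
      } else {
        stop("measure '", mname, "' must be \"loocv\" or a feature_matrix")
      }
    }, numeric(1))
    out[[mname]] <- accs
  }
  out
}

#' Write a selection trace as a ranking table
#'
#' Tab-separated table (rank, signal, accuracy, per-class accuracy range)
#' plus a JSON twin next to it.
#'
#' @param trace A \code{selection_trace}.
#' @param path Output TSV path; the JSON twin replaces the extension with
#'   \code{.json}.
#' @return \code{path}, invisibly.
#' @export
write_selection_trace <- function(trace, path) {
  stopifnot(inherits(trace, "selection_trace"))
  steps <- trace$steps
  rank_of <- match(steps$signal, trace$ranking)
  tab <- data.frame(rank = rank_of, signal = steps$signal,
                    n_signals = steps$n_signals,
                    accuracy = steps$accuracy,
                    per_class_min = steps$per_class_min,
                    per_class_max = steps$per_class_max)
  tab <- tab[order(tab$rank), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(method = trace$method, protocol = trace$protocol_kind,
         lambda = trace$lambda, ranking = trace$ranking, steps = steps),
    sub("\\.[^.]*$", ".json", path), digits = NA, auto_unbox = TRUE)
  invisible(path)
}
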