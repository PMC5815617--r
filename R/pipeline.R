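#' Simulate a dataset to disk
#'
#' Generates a synthetic dataset and writes its trial files and manifest,
#' giving a fully reproducible on-disk input for the pipeline.
#'
#' @param config A \code{synthetic_config}.
#' @param dir Output directory.
#' @param role Dataset role written into the manifest.
#' @return The manifest path, invisibly.
#' @export
simulate_dataset <- function(config, dir, role = "training") {
  ds <- generate_dataset(config, role = role)
  write_dataset(ds, dir)
}

resolve_dataset <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "gait_dataset")) return(x)
  if (is.character(x) && length(x) == 1L) return(load_dataset(x))
  stop(what, " must be a gait_dataset or a manifest path")
}

#' Run the full classification experiment
#'
#' Orchestrates the complete offline analysis: featurize the datasets,
#' run sequential forward and/or backward selection under each requested
#' pick protocol, re-measure every selection path on every evaluation
#' dataset, and write ranking tables, accuracy-versus-signal-count curves,
#' the pick-by-measure grid and a run report (TSV + JSON) into
#' \code{out_dir}.
#'
#' Pick protocols: \code{"loocv"} scores candidate signal sets by
#' leave-one-trial-out cross-validation on the training windows;
#' \code{"test1"} / \code{"test2"} score them against the corresponding
#' held-out dataset. Every curve is additionally measured on all available
#' evaluation datasets, which yields the cross-evaluation grid.
#'
#' @param training Training data: \code{gait_dataset} or manifest path.
#' @param test1,test2 Optional held-out datasets (dataset or manifest path).
#' @param inventory A \code{signal_inventory}.
#' @param window A \code{window_spec}.
#' @param lambda Shrinkage for every classifier fit.
#' @param methods Subset of \code{c("sfs", "sbs")}.
#' @param picks Pick protocols to run; defaults to \code{"loocv"} plus every
#'   supplied test set.
#' @param out_dir Output directory; created if needed.
#' @return Invisibly, a list with the feature matrices, traces, curves and
#'   grid.
#' @export
run_experiment <- function(training, test1 = NULL, test2 = NULL,
                           inventory = signal_inventory("ips_only"),
                           window = window_spec(), lambda = 1e-4,
                           methods = c("sfs", "sbs"), picks = NULL,
                           out_dir = ".") {
  methods <- match.arg(methods, c("sfs", "sbs"), several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  training <- resolve_dataset(training, "training")
  test1 <- resolve_dataset(test1, "test1")
  test2 <- resolve_dataset(test2, "test2")

  message("featurizing training data (", length(training$trials), " trials)")
  train_fm <- build_feature_matrix(training, inventory, window)
  tests <- list()
  for (nm in c("test1", "test2")) {
    ds <- get(nm)
    if (!is.null(ds)) {
      message("featurizing ", nm, " (", length(ds$trials), " trials)")
      tests[[nm]] <- build_feature_matrix(ds, inventory, window)
    }
  }
  if (is.null(picks)) picks <- c("loocv", names(tests))
  measures <- c(list(loocv = "loocv"), tests)

  traces <- list()
  curves <- list()
  grid_rows <- list()
  for (method in methods) {
    sel_fun <- if (method == "sfs") sfs else sbs
    for (pick in picks) {
      protocol <- if (pick == "loocv") {
        eval_protocol("loocv_training")
      } else {
        eval_protocol("fixed_test", test = tests[[pick]])
      }
      key <- paste(method, pick, sep = "_")
      message("selection: ", toupper(method), " picked on ", pick)
      trace <- sel_fun(train_fm, protocol = protocol, lambda = lambda)
      traces[[key]] <- trace
      write_selection_trace(trace,
                            file.path(out_dir, paste0("ranking_", key,
                                                      ".tsv")))
      curve <- accuracy_vs_count_curve(trace, train_fm, measure = measures,
                                       lambda = lambda)
      curves[[key]] <- curve
      utils::write.table(curve,
                         file.path(out_dir, paste0("curve_", key, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      # best classifier under the pick measure: fewest signals at the peak
      pick_acc <- curve[[pick]]
      n_best <- which(pick_acc >= max(pick_acc) - 1e-12)[1L]
      row <- data.frame(method = toupper(method), pick = pick,
                        n_signals = n_best,
                        stringsAsFactors = FALSE)
      for (mname in names(measures)) {
        row[[paste0("accuracy_", mname)]] <- curve[[mname]][n_best]
      }
      grid_rows[[key]] <- row
    }
  }
  grid <- do.call(rbind, grid_rows)
  rownames(grid) <- NULL
  utils::write.table(grid, file.path(out_dir, "pick_measure_grid.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    package_version = as.character(utils::packageVersion("gaitterrain")),
    inventory_variant = inventory_variant(inventory),
    n_features = n_features(inventory),
    lambda = lambda,
    window = unclass(window),
    n_training_trials = length(training$trials),
    n_training_windows = nrow(train_fm$values),
    n_test_windows = lapply(tests, function(x) nrow(x$values)),
    methods = methods, picks = picks,
    grid = grid
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(train_fm = train_fm, tests = tests, traces = traces,
                 curves = curves, grid = grid))
}
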