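#' Confusion matrix over terrain classes
#'
#' Rows are the true terrain, columns the predicted terrain, in the fixed
#' class order eversion / flush / inversion (-15, 0, +15 degrees).
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @return Object of class \code{terrain_confusion}: 3x3 integer matrix.
#' @export
confusion_matrix <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors differ in length (", length(true_labels), " vs ",
         length(predicted_labels), ")")
  }
  counts <- table(true = terrain_factor(true_labels),
                  predicted = terrain_factor(predicted_labels))
  structure(unclass(counts), class = "terrain_confusion")
}

#' @export
print.terrain_confusion <- function(x, ...) {
  cat("confusion matrix (rows = true, cols = predicted):\n")
  print(unclass(x))
  rep <- accuracy_report(x)
  cat(sprintf("overall accuracy %.4f (error %.4f)\n", rep$overall, rep$error))
  invisible(x)
}

#' Accuracy summary of a confusion matrix
#'
#' Overall accuracy is the number of windows whose terrain was predicted
#' correctly divided by the total number of windows. Per-class accuracy is
#' the diagonal rate within each true class; its (min, max) range is the
#' "individual terrain" range reported alongside the overall value.
#'
#' @param cm A \code{terrain_confusion}.
#' @return List with \code{overall}, \code{per_class}, \code{per_class_range}
#'   (min, max over classes present), \code{error} and \code{n}.
#' @export
accuracy_report <- function(cm) {
  stopifnot(inherits(cm, "terrain_confusion"))
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  row_n <- rowSums(m)
  per_class <- ifelse(row_n > 0, diag(m) / row_n, NA_real_)
  names(per_class) <- rownames(m)
  overall <- sum(diag(m)) / total
  rng <- range(per_class, na.rm = TRUE)
  list(overall = overall, per_class = per_class,
       per_class_range = c(min = rng[1], max = rng[2]),
       error = 1 - overall, n = total)
}

#' Leave-one-out cross-validation
#'
#' For each held-out unit, fits the classifier on the remaining windows and
#' predicts the held-out mid-swing windows; predictions are pooled into one
#' confusion matrix. The unit defaults to the trial: overlapping windows
#' within a trial are near-duplicates, so leaving out single windows would
#' leak information between folds. Window-level folds remain available for
#' comparison. Folds whose training part loses a terrain class entirely are
#' skipped and reported, not silently imputed.
#'
#' @param fm A \code{feature_matrix}.
#' @param signals Optional signal subset (see
#'   \code{\link{restrict_to_signals}}).
#' @param lambda Shrinkage passed to \code{\link{fit_lda}}.
#' @param unit \code{"trial"} (default) or \code{"window"}.
#' @param priors,scale Passed to \code{\link{fit_lda}}.
#' @return List with \code{confusion}, \code{report}
#'   (\code{\link{accuracy_report}}), \code{predictions} (data frame) and
#'   \code{skipped_folds}.
#' @export
loocv <- function(fm, signals = NULL, lambda = 1e-4,
                  unit = c("trial", "window"),
                  priors = "empirical", scale = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  unit <- match.arg(unit)
  if (!is.null(signals)) fm <- restrict_to_signals(fm, signals)
  fold_id <- if (unit == "trial") fm$info$trial_id else seq_len(nrow(fm$values))
  folds <- unique(fold_id)
  if (length(folds) < 2L) stop("need at least 2 cross-validation units")
  truth <- character(0)
  pred <- character(0)
  held <- integer(0)
  skipped <- character(0)
  for (f in folds) {
    test_rows <- which(fold_id == f)
    train_rows <- which(fold_id != f)
    train_y <- fm$info$label[train_rows]
    if (!all(unique(fm$info$label) %in% train_y)) {
      skipped <- c(skipped, as.character(f))
      next
    }
    model <- fit_lda(fm$values[train_rows, , drop = FALSE], train_y,
                     lambda = lambda, priors = priors, scale = scale)
    p <- predict(model, fm$values[test_rows, , drop = FALSE])
    truth <- c(truth, fm$info$label[test_rows])
    pred <- c(pred, p$label)
    held <- c(held, test_rows)
  }
  if (length(skipped)) {
    warning(length(skipped), " fold(s) skipped (missing class in training ",
            "part): ", paste(utils::head(skipped, 5L), collapse = ", "))
  }
  if (!length(truth)) stop("all folds skipped; cannot evaluate")
  cm <- confusion_matrix(truth, pred)
  list(confusion = cm, report = accuracy_report(cm),
       predictions = data.frame(row = held, true = truth, predicted = pred,
                                stringsAsFactors = FALSE),
       skipped_folds = skipped)
}

#' Train on one dataset, evaluate on another
#'
#' Fits a single classifier on all training mid-swing windows and predicts
#' every test mid-swing window.
#'
#' @param train_fm,test_fm \code{feature_matrix} objects over the same
#'   inventory.
#' @param signals Optional signal subset applied to both.
#' @param lambda,priors,scale Passed to \code{\link{fit_lda}}.
#' @return List with \code{confusion}, \code{report}, \code{model} and
#'   \code{predictions}.
#' @export
evaluate_on_test <- function(train_fm, test_fm, signals = NULL,
                             lambda = 1e-4, priors = "empirical",
                             scale = FALSE) {
  stopifnot(inherits(train_fm, "feature_matrix"),
            inherits(test_fm, "feature_matrix"))
  if (!is.null(signals)) {
    train_fm <- restrict_to_signals(train_fm, signals)
    test_fm <- restrict_to_signals(test_fm, signals)
  }
  if (!identical(colnames(train_fm$values), colnames(test_fm$values))) {
    stop("training and test feature matrices have different feature keys")
  }
  if (!nrow(test_fm$values)) stop("test feature matrix is empty")
  model <- fit_lda(train_fm, lambda = lambda, priors = priors, scale = scale)
  p <- predict(model, test_fm)
  cm <- confusion_matrix(test_fm$info$label, p$label)
  list(confusion = cm, report = accuracy_report(cm), model = model,
       predictions = data.frame(trial_id = test_fm$info$trial_id,
                                true = test_fm$info$label,
                                predicted = p$label,
                                stringsAsFactors = FALSE))
}
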