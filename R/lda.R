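#' Fit a pooled-covariance linear discriminant classifier
#'
#' Multi-class linear discriminant analysis: class means \eqn{\mu_c}, one
#' pooled within-class covariance \eqn{\Sigma} (divisor n - K), and the
#' linear discriminant score
#' \deqn{\delta_c(x) = x' \Sigma_\lambda^{-1} \mu_c -
#'   \tfrac{1}{2} \mu_c' \Sigma_\lambda^{-1} \mu_c + \log \pi_c,}
#' where \eqn{\Sigma_\lambda = (1 - \lambda)\Sigma +
#' \lambda \, (\mathrm{tr}\,\Sigma / p) I} is the shrunk covariance. A small
#' shrinkage (default \code{1e-4}) keeps \eqn{\Sigma_\lambda} well
#' conditioned when the feature count approaches the per-class window count;
#' set \code{lambda = 0} for the plain estimator.
#'
#' @param x A \code{feature_matrix}, or a numeric matrix (then \code{y} is
#'   required).
#' @param y Terrain labels, one per row of \code{x} (ignored for a
#'   \code{feature_matrix}).
#' @param lambda Shrinkage in [0, 1].
#' @param priors \code{"empirical"} (class proportions) or \code{"uniform"}.
#' @param scale Z-score features before fitting (stored and re-applied at
#'   prediction). Plain LDA is scale-invariant at \code{lambda = 0}; scaling
#'   mainly matters for the conditioning of shrunk fits.
#' @return Object of class \code{terrain_lda}: class order, means, pooled
#'   covariance, shrinkage, priors, discriminant coefficients and fitted
#'   feature keys.
#' @export
fit_lda <- function(x, y = NULL, lambda = 1e-4,
                    priors = c("empirical", "uniform"), scale = FALSE) {
  priors <- match.arg(priors)
  if (inherits(x, "feature_matrix")) {
    y <- x$info$label
    x <- x$values
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(y) || length(y) != nrow(x)) {
    stop("labels must be supplied, one per row")
  }
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  y <- terrain_factor(y)
  y <- droplevels(y)
  counts <- table(y)
  if (length(counts) < 2L) stop("need at least 2 classes to fit")
  if (any(counts < 2L)) {
    stop("class(es) with fewer than 2 windows: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  n <- nrow(x)
  p <- ncol(x)
  k <- length(counts)

  scaling <- NULL
  if (isTRUE(scale)) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl == 0] <- 1
    x <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
    scaling <- list(center = ctr, scale = scl)
  }

  means <- rowsum(x, y) / as.vector(counts)
  centered <- x - means[as.integer(y), , drop = FALSE]
  sigma <- crossprod(centered) / (n - k)
  sigma_l <- (1 - lambda) * sigma
  diag(sigma_l) <- diag(sigma_l) + lambda * sum(diag(sigma)) / p
  ch <- tryCatch(chol(sigma_l), error = function(e) NULL)
  if (!is.null(ch)) {
    piv <- diag(ch)
    if ((min(piv) / max(piv))^2 < 1e-12) ch <- NULL
  }
  if (is.null(ch)) {
    stop("pooled covariance is singular",
         if (lambda == 0) " (lambda = 0); refit with lambda > 0" else "")
  }
  pri <- if (priors == "empirical") as.vector(counts) / n else rep(1 / k, k)
  # discriminant as an affine map: scores = x A + b
  a <- backsolve(ch, forwardsolve(t(ch), t(means)))   # Sigma^-1 mu_c
  b <- -0.5 * colSums(a * t(means)) + log(pri)
  structure(list(
    class_order = levels(y),
    means = means,
    pooled_cov = sigma,
    lambda = lambda,
    priors = stats::setNames(pri, levels(y)),
    scaling = scaling,
    coef = a,
    intercept = b,
    keys = colnames(x),
    n = n
  ), class = "terrain_lda")
}

#' @export
print.terrain_lda <- function(x, ...) {
  cat("<terrain_lda> ", length(x$class_order), " classes, ",
      length(x$keys), " features, lambda=", x$lambda, ", n=", x$n, "\n",
      sep = "")
  invisible(x)
}

#' Predict terrain for feature rows
#'
#' Evaluates the per-class discriminant scores and returns the argmax label
#' per row; exact score ties break toward the earlier class in canonical
#' order. Prediction is deterministic.
#'
#' @param object A \code{terrain_lda}.
#' @param newdata A \code{feature_matrix}, numeric matrix, or single named
#'   vector, with columns matching the fitted feature keys.
#' @param ... Unused.
#' @return List with \code{label} (character vector) and \code{scores}
#'   (matrix of discriminant values, one column per class).
#' @export
predict.terrain_lda <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L,
                                               dimnames = list(NULL,
                                                               names(newdata)))
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    missing <- setdiff(object$keys, colnames(newdata))
    if (length(missing)) {
      stop("newdata is missing feature(s): ",
           paste(utils::head(missing, 5L), collapse = ", "),
           if (length(missing) > 5L) ", ...")
    }
    newdata <- newdata[, object$keys, drop = FALSE]
  } else if (ncol(newdata) != length(object$keys)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$keys))
  }
  if (!is.null(object$scaling)) {
    newdata <- sweep(sweep(newdata, 2L, object$scaling$center), 2L,
                     object$scaling$scale, "/")
  }
  scores <- newdata %*% object$coef
  scores <- sweep(scores, 2L, object$intercept, "+")
  colnames(scores) <- object$class_order
  idx <- max.col(scores, ties.method = "first")
  list(label = object$class_order[idx], scores = scores)
}

#' Majority vote over recent window predictions
#'
#' Aggregates the last \code{k} window-level terrain calls into one stride
#' decision; the modal label wins, and a tie goes to the label seen most
#' recently among those tied.
#'
#' @param labels Character vector of window predictions, oldest first.
#' @param k Number of most recent windows to vote over.
#' @return A single terrain label.
#' @export
#' @examples
#' majority_vote(c("flush", "inversion", "inversion"), k = 3)
majority_vote <- function(labels, k) {
  if (!length(labels)) stop("no labels to vote over")
  if (k < 1L) stop("k must be >= 1")
  if (length(labels) < k) stop("need at least k = ", k, " labels")
  recent <- utils::tail(labels, k)
  counts <- table(recent)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  # tie: the most recently observed among the tied labels
  recent[max(vapply(top, function(l) max(which(recent == l)), integer(1)))]
}

#' Serialize a fitted classifier to JSON
#'
#' @param model A \code{terrain_lda}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_lda <- function(model, path) {
  stopifnot(inherits(model, "terrain_lda"))
  obj <- list(class_order = model$class_order,
              means = as.data.frame(model$means),
              pooled_cov = as.data.frame(model$pooled_cov),
              lambda = model$lambda,
              priors = as.list(model$priors),
              scaling = model$scaling,
              keys = model$keys, n = model$n)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized classifier
#'
#' @param path JSON path written by \code{\link{write_lda}}.
#' @return A \code{terrain_lda}.
#' @export
read_lda <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!length(obj$scaling)) {
    obj$scaling <- NULL
  } else {
    obj$scaling <- list(center = unlist(obj$scaling$center),
                        scale = unlist(obj$scaling$scale))
  }
  means <- as.matrix(obj$means)
  rownames(means) <- obj$class_order
  sigma <- as.matrix(obj$pooled_cov)
  p <- ncol(sigma)
  sigma_l <- (1 - obj$lambda) * sigma
  diag(sigma_l) <- diag(sigma_l) + obj$lambda * sum(diag(sigma)) / p
  ch <- chol(sigma_l)
  a <- backsolve(ch, forwardsolve(t(ch), t(means)))
  pri <- unlist(obj$priors)
  b <- -0.5 * colSums(a * t(means)) + log(pri[obj$class_order])
  structure(list(class_order = obj$class_order, means = means,
                 pooled_cov = sigma, lambda = obj$lambda,
                 priors = pri[obj$class_order],
                 scaling = obj$scaling, coef = a, intercept = b,
                 keys = obj$keys, n = obj$n),
            class = "terrain_lda")
}
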