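# Gaussian-process ddG regressor.
#
# Thin, contract-enforcing wrapper around kernlab::gausspr: features are
# standardised with training-set statistics inside the wrapper, the RBF
# bandwidth defaults to the deterministic median-pairwise-distance
# heuristic, the target is centred and restored, and the feature manifest
# plus a training fingerprint travel with the fitted model so predictions
# on a mismatched feature layout are refused rather than silently wrong.

MODEL_FORMAT_VERSION <- "nabind-model-1"

#' Train the ddG regressor
#'
#' Fits a Gaussian-process regressor (RBF kernel plus a white-noise term)
#' on a signature matrix. Features are standardised internally (zero
#' mean, unit variance; constant columns pass through unscaled) and the
#' statistics are stored in the model. The RBF bandwidth `sigma` defaults
#' to the median heuristic, computed deterministically. A constant target
#' collapses to a constant model. Training is deterministic given the
#' data and `seed` (the seed enters only the fingerprint and any
#' subsampling of the bandwidth heuristic).
#'
#' @param X numeric feature matrix with column names (the manifest).
#' @param y numeric ddG vector, kcal/mol.
#' @param noise_var white-noise variance of the GP (kernlab floor 1e-3).
#' @param sigma RBF inverse-bandwidth; `NULL` for the median heuristic.
#' @param regressor `"gaussian_process"` (default) or `"random_forest"`
#'   (comparison alternative, via randomForest if installed).
#' @param seed integer seed recorded in the fingerprint.
#' @return a `na_model` object.
#' @export
na_train <- function(X, y, noise_var = 0.01, sigma = NULL,
                     regressor = c("gaussian_process", "random_forest"),
                     seed = 1) {
  regressor <- match.arg(regressor)
  X <- as.matrix(X)
  if (is.null(colnames(X))) stopf("feature matrix must carry a manifest (column names)")
  if (nrow(X) != length(y)) stopf("rows(X) = %d but length(y) = %d", nrow(X), length(y))
  if (nrow(X) < 20) stopf("need at least 20 training rows, got %d", nrow(X))
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("non-finite feature at row %d, column '%s'", bad[1, 1],
          colnames(X)[bad[1, 2]])
  if (any(!is.finite(y))) stopf("non-finite target value")
  noise_var <- max(noise_var, 1e-3)

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  ymean <- mean(y)
  yc <- y - ymean

  fingerprint <- content_checksum(dim(X), colnames(X), colSums(Xs), y, seed)

  if (stats::sd(y) < 1e-12) {
    fit <- NULL; kind <- "constant"; sigma <- NA_real_
  } else if (regressor == "gaussian_process") {
    if (is.null(sigma)) sigma <- median_sigma(Xs)
    fit <- kernlab::gausspr(Xs, yc, type = "regression", kernel = "rbfdot",
                            kpar = list(sigma = sigma), var = noise_var,
                            scaled = FALSE, fit = FALSE)
    kind <- "gaussian_process"
  } else {
    if (!requireNamespace("randomForest", quietly = TRUE))
      stopf("regressor 'random_forest' needs the randomForest package")
    fit <- with_seed(seed, randomForest::randomForest(Xs, yc))
    kind <- "random_forest"
  }

  structure(list(kind = kind, fit = fit, center = ctr, scale = scl,
                 ymean = ymean,
                 hyperparameters = list(sigma = sigma, noise_var = noise_var),
                 manifest = colnames(X), fingerprint = fingerprint,
                 seed = seed, version = MODEL_FORMAT_VERSION),
            class = "na_model")
}

# deterministic median heuristic: 1 / (2 * median squared pairwise
# distance), on an evenly strided subsample when n is large
median_sigma <- function(Xs, max_n = 400) {
  n <- nrow(Xs)
  idx <- if (n > max_n) round(seq(1, n, length.out = max_n)) else seq_len(n)
  d2 <- as.numeric(stats::dist(Xs[idx, , drop = FALSE]))^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) return(1)
  1 / (2 * m)
}

#' Predict ddG for new signatures
#'
#' @param model a `na_model`.
#' @param X feature matrix whose column names must equal the model's
#'   manifest (same names, same order); otherwise prediction is refused
#'   and the discrepant names are listed.
#' @return data frame with `ddg_pred` (kcal/mol) and `classification`
#'   (`"reducing"` if `ddg_pred < 0`, else `"increasing"`).
#' @export
na_predict <- function(model, X) {
  stopifnot(inherits(model, "na_model"))
  X <- as.matrix(X)
  if (!identical(colnames(X), model$manifest)) {
    extra <- setdiff(colnames(X), model$manifest)
    miss <- setdiff(model$manifest, colnames(X))
    moved <- if (length(extra) == 0 && length(miss) == 0) "feature order differs"
             else sprintf("unexpected: [%s]; missing: [%s]",
                          paste(utils::head(extra, 5), collapse = ", "),
                          paste(utils::head(miss, 5), collapse = ", "))
    stopf("feature manifest mismatch: %s", moved)
  }
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  pred <- switch(model$kind,
    constant = rep(0, nrow(Xs)),
    gaussian_process = as.numeric(kernlab::predict(model$fit, Xs)),
    random_forest = as.numeric(stats::predict(model$fit, Xs)))
  ddg <- pred + model$ymean
  data.frame(ddg_pred = ddg,
             classification = ifelse(ddg < 0, "reducing", "increasing"),
             stringsAsFactors = FALSE)
}

#' Save / load a trained model
#'
#' The serialized artifact embeds the feature manifest, the training
#' fingerprint and a format version tag; loading a file with a different
#' tag, or a file that is not a model, fails with an explicit error.
#'
#' @param model a `na_model`.
#' @param path file path.
#' @return `load_model` returns the `na_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "na_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stopf("cannot read model file '%s': %s",
                                            path, conditionMessage(e)))
  if (!inherits(obj, "na_model"))
    stopf("'%s' is not a nabind model file", path)
  if (!identical(obj$version, MODEL_FORMAT_VERSION))
    stopf("model format version mismatch: file has '%s', this build expects '%s'",
          obj$version %||% "<none>", MODEL_FORMAT_VERSION)
  obj
}

#' @export
print.na_model <- function(x, ...) {
  cat(sprintf("<na_model %s> %d features, fingerprint %s\n", x$kind,
              length(x$manifest), x$fingerprint))
  invisible(x)
}

#' Cross-validated predictions
#'
#' Trains one model per fold on the complementary records and predicts
#' the held-out fold; rows failing featurization (NA rows in `X`) are
#' skipped and reported.
#'
#' @param X feature matrix.
#' @param y target vector.
#' @param folds integer fold index per row (from [make_folds()]).
#' @param ... passed to [na_train()].
#' @return numeric vector of out-of-fold predictions (`NA` for skipped
#'   rows).
#' @export
cross_validate <- function(X, y, folds, ...) {
  stopifnot(nrow(X) == length(y), length(folds) == length(y))
  ok <- stats::complete.cases(X) & is.finite(y)
  pred <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- ok & folds != f
    te <- ok & folds == f
    if (!any(te)) next
    m <- na_train(X[tr, , drop = FALSE], y[tr], ...)
    pred[te] <- na_predict(m, X[te, , drop = FALSE])$ddg_pred
  }
  pred
}
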