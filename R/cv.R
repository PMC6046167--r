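#' Stratified k-fold assignment
#'
#' Shuffles each class separately and deals trials round-robin, so fold
#' class counts differ by at most one. Deterministic given `seed`; the
#' caller's RNG state is preserved.
#'
#' @param labels Class label per trial.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.character(labels)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Precompute per-fold one-vs-one CSP features
#'
#' CSP filters do not depend on the classifier hyperparameters, so for a
#' fixed fold assignment the fold features can be computed once and reused
#' for every hyperparameter evaluation. Filters are fit on each fold's
#' training partition only; test trials are projected through the
#' train-fitted filters (no label leakage).
#'
#' @param afmats List of `af_matrix` for all trials.
#' @param labels Class label per trial.
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @param m CSP filters per side.
#' @param classes Class order.
#' @return Object of class `cv_features`: per-fold `train` (training
#'   layout), `test` (prediction layout), `test_labels`, plus `folds`,
#'   `labels`, `classes`, `seed`.
#' @export
prepare_cv_features <- function(afmats, labels, k = 5L, seed = 1L, m = 2L,
                                classes = c("flexion", "extension",
                                            "abduction")) {
  labels <- as.character(labels)
  folds <- stratified_folds(labels, k, seed)
  fold_data <- lapply(seq_len(k), function(f) {
    tr <- which(folds != f)
    te <- which(folds == f)
    filters <- fit_ovo_csp(afmats[tr], labels[tr], m = m, classes = classes)
    list(train = ovo_features(filters, afmats[tr], labels[tr]),
         test = ovo_features(filters, afmats[te], restrict = FALSE),
         test_labels = labels[te],
         filters = filters)
  })
  structure(list(fold_data = fold_data, folds = folds, labels = labels,
                 classes = classes, k = as.integer(k), seed = seed),
            class = "cv_features")
}

#' Cross-validated objectives for one hyperparameter setting
#'
#' Trains the one-vs-one twin SVM on each fold's training features,
#' predicts the held-out trials, pools the confusion counts over folds, and
#' returns the per-class and total correct rates of the pooled matrix.
#'
#' @param cvdata A [prepare_cv_features()] object.
#' @param c1,c2 Shared twin-SVM penalties.
#' @param kernel A [kernel_spec()].
#' @param test_labels Optional replacement test labels per fold (list of
#'   length k) — used for label-permutation controls.
#' @param return_predictions Also return the pooled truth/prediction
#'   vectors?
#' @return List: `CRF`, `CRE`, `CRA`, `CR` (percent), `cm` (pooled counts),
#'   and with `return_predictions` also `truth` and `pred`.
#' @export
cv_objectives <- function(cvdata, c1, c2, kernel = kernel_spec("rbf", 1),
                          test_labels = NULL, return_predictions = FALSE) {
  truth <- character(0)
  pred <- character(0)
  for (f in seq_len(cvdata$k)) {
    fd <- cvdata$fold_data[[f]]
    res <- tryCatch({
      model <- ovo_twsvm(fd$train, c1, c2, kernel)
      predict(model, fd$test)
    }, afcsp_error = function(e)
      stop_afcsp("fold ", f, ": ", conditionMessage(e),
                 class = "afcsp_fold_failure"))
    truth <- c(truth,
               if (is.null(test_labels)) fd$test_labels
               else test_labels[[f]])
    pred <- c(pred, as.character(res$class))
  }
  cr <- confusion_and_rates(truth, pred, cvdata$classes)
  out <- list(CRF = cr$CRF, CRE = cr$CRE, CRA = cr$CRA, CR = cr$CR,
              cm = cr$cm)
  if (return_predictions) {
    out$truth <- truth
    out$pred <- pred
  }
  out
}
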