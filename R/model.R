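#' Fit the full AF-CSP + one-vs-one twin SVM decoder
#'
#' Fits the three pairwise CSP filters on the supplied AF matrices, extracts
#' 4-D log-variance features per pair, and trains the one-vs-one twin SVM on
#' them. The returned object carries everything needed to classify new
#' trials (filters + planes), and serializes to JSON.
#'
#' @param afmats List of `af_matrix` (training trials).
#' @param labels Class label per trial.
#' @param c1,c2 Shared twin-SVM penalties.
#' @param kernel A [kernel_spec()].
#' @param m CSP filters per side.
#' @param classes Class order.
#' @return Object of class `afcsp_model`.
#' @export
fit_afcsp_model <- function(afmats, labels, c1, c2,
                            kernel = kernel_spec("rbf", 1), m = 2L,
                            classes = c("flexion", "extension",
                                        "abduction")) {
  of <- build_ovo_features(afmats, labels, m = m, classes = classes)
  model <- ovo_twsvm(of$features, c1, c2, kernel)
  structure(list(filters = of$filters, twsvm = model, m = as.integer(m),
                 classes = classes),
            class = "afcsp_model")
}

#' @export
print.afcsp_model <- function(x, ...) {
  cat("AF-CSP one-vs-one twin SVM decoder\n")
  print(x$twsvm)
  invisible(x)
}

#' @export
coef.afcsp_model <- function(object, ...) {
  list(c1 = object$twsvm$c1, c2 = object$twsvm$c2,
       kernel = object$twsvm$kernel)
}

#' Classify trials with a fitted AF-CSP decoder
#'
#' @param object A fitted [fit_afcsp_model()].
#' @param newdata List of `af_matrix` for the trials to classify.
#' @param ... Ignored.
#' @return List: `class` (factor), `votes` (trials x classes).
#' @export
predict.afcsp_model <- function(object, newdata, ...) {
  feats <- ovo_features(object$filters, newdata, restrict = FALSE)
  predict(object$twsvm, feats)
}

#' Serialize a fitted AF-CSP decoder to versioned JSON
#'
#' @param model A fitted [fit_afcsp_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_afcsp_model <- function(model, path) {
  tmp_tw <- tempfile(fileext = ".json")
  on.exit(unlink(tmp_tw))
  write_ovo_twsvm(model$twsvm, tmp_tw)
  payload <- list(
    format = "afcsp-model", version = 1L,
    m = model$m, classes = model$classes,
    filters = lapply(model$filters, function(f)
      list(W = f$W, m = f$m, selected_rows = f$selected_rows,
           eigenvalues = f$eigenvalues, pair = f$pair,
           degenerate = f$degenerate)),
    twsvm = jsonlite::read_json(tmp_tw, simplifyVector = FALSE))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a serialized AF-CSP decoder
#'
#' @param path File written by [write_afcsp_model()].
#' @return An `afcsp_model`.
#' @export
read_afcsp_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "afcsp-model"))
    stop_afcsp("not an afcsp model file", class = "afcsp_parse_error")
  num <- function(v) as.numeric(unlist(v))
  filters <- lapply(p$filters, function(f) {
    W <- do.call(rbind, lapply(f$W, num))
    rownames(W) <- paste0("csp", seq_len(nrow(W)))
    structure(list(W = W, m = as.integer(f$m),
                   selected_rows = as.integer(unlist(f$selected_rows)),
                   eigenvalues = num(f$eigenvalues),
                   pair = unlist(f$pair),
                   degenerate = isTRUE(f$degenerate)),
              class = "csp")
  })
  names(filters) <- names(p$filters)
  tmp_tw <- tempfile(fileext = ".json")
  on.exit(unlink(tmp_tw))
  jsonlite::write_json(p$twsvm, tmp_tw, auto_unbox = TRUE, digits = NA)
  structure(list(filters = filters, twsvm = read_ovo_twsvm(tmp_tw),
                 m = as.integer(p$m), classes = unlist(p$classes)),
            class = "afcsp_model")
}
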