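#' Confusion matrix and per-class correct rates
#'
#' Builds the 3 x 3 confusion matrix (true class x predicted class, order
#' flexion/extension/abduction) and the correct rates
#' `CRF = CNF/TNF x 100`, `CRE`, `CRA`, plus the total rate
#' `CR = (CNF + CNE + CNA) / (TNF + TNE + TNA) x 100`.
#'
#' @param truth,pred Equal-length label vectors over the three classes.
#' @param classes Class order.
#' @return List: `cm` (counts), `CRF`, `CRE`, `CRA`, `CR` (percent),
#'   `per_class` (named vector), `n`.
#' @export
confusion_and_rates <- function(truth, pred,
                                classes = c("flexion", "extension",
                                            "abduction")) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred))
    stop_afcsp("label vectors differ in length", class = "afcsp_bad_input")
  bad <- setdiff(unique(c(truth, pred)), classes)
  if (length(bad))
    stop_afcsp("labels outside the class set: ", paste(bad, collapse = ", "),
               class = "afcsp_bad_label")
  cm <- table(factor(truth, levels = classes),
              factor(pred, levels = classes))
  cm <- matrix(as.integer(cm), 3, 3, dimnames = dimnames(cm))
  totals <- rowSums(cm)
  per_class <- ifelse(totals > 0, 100 * diag(cm) / totals, NA_real_)
  names(per_class) <- classes
  list(cm = cm,
       CRF = per_class[[1]], CRE = per_class[[2]], CRA = per_class[[3]],
       CR = 100 * sum(diag(cm)) / sum(cm),
       per_class = per_class, n = length(truth))
}

#' Cohen's kappa from a 3 x 3 confusion matrix
#'
#' `kappa = (P_o - P_e) / (1 - P_e)` with `P_o` the diagonal proportion and
#' `P_e` the chance agreement from row/column marginal products. Accepts
#' counts or percentage matrices (percentages are treated as weights).
#'
#' @param cm Square numeric matrix, true x predicted.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n <= 0)
    stop_afcsp("empty confusion matrix", class = "afcsp_bad_input")
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (1 - p_e < .Machine$double.eps)
    stop_afcsp("degenerate marginals: chance agreement is 1",
               class = "afcsp_degenerate")
  (p_o - p_e) / (1 - p_e)
}

#' Aggregate per-subject accuracies as mean +/- population SD
#'
#' The spread is the population standard deviation (divisor n, not n - 1):
#' the subjects summarized are the whole group under study, not a sample
#' from a larger pool, and only this convention is consistent with the
#' package's reporting of group summaries.
#'
#' @param accuracies Nonempty numeric vector of percentages.
#' @return Object of class `subject_summary`: `accuracies`, `mean`, `sd`
#'   (population), plus 2-decimal `mean_2dp` / `sd_2dp`.
#' @export
aggregate_subjects <- function(accuracies) {
  if (length(accuracies) == 0)
    stop_afcsp("no accuracies to aggregate", class = "afcsp_bad_input")
  m <- mean(accuracies)
  s <- sqrt(mean((accuracies - m)^2))
  structure(list(accuracies = accuracies, mean = m, sd = s,
                 mean_2dp = round(m, 2), sd_2dp = round(s, 2)),
            class = "subject_summary")
}

#' @export
print.subject_summary <- function(x, ...) {
  cat(sprintf("%d subjects: %.2f%% +/- %.2f%% (population SD)\n",
              length(x$accuracies), x$mean, x$sd))
  invisible(x)
}

#' Full evaluation report for a set of predictions
#'
#' @param truth,pred Label vectors.
#' @param classes Class order.
#' @return List: confusion matrix (counts and row-normalized percent),
#'   per-class rates, total CR, Cohen's kappa.
#' @export
evaluation_report <- function(truth, pred,
                              classes = c("flexion", "extension",
                                          "abduction")) {
  cr <- confusion_and_rates(truth, pred, classes)
  cm_pct <- 100 * sweep(cr$cm, 1, pmax(rowSums(cr$cm), 1), "/")
  list(confusion_counts = cr$cm,
       confusion_percent = round(cm_pct, 2),
       per_class_rates = cr$per_class,
       CR = cr$CR,
       kappa = cohen_kappa(cr$cm),
       n = cr$n)
}
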