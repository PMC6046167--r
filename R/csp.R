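#' Trace-normalized covariance of an AF matrix
#'
#' `R = X X^T / trace(X X^T)`: symmetric, positive semi-definite, unit
#' trace, so trials contribute equally regardless of overall amplitude.
#'
#' @param X An `af_matrix` or a plain N x M numeric matrix.
#' @return N x N matrix with trace 1.
#' @export
normalized_covariance <- function(X) {
  if (inherits(X, "af_matrix")) X <- X$values
  S <- tcrossprod(X)
  tr <- sum(diag(S))
  if (tr <= 0)
    stop_afcsp("zero matrix has no normalized covariance",
               class = "afcsp_bad_input")
  S / tr
}

#' Class-average normalized covariance
#'
#' Arithmetic mean of the per-trial normalized covariances of all trials
#' carrying `label`.
#'
#' @param afmats List of `af_matrix` (or plain matrices).
#' @param labels Class label per entry of `afmats`.
#' @param label The class to average.
#' @return N x N matrix with trace 1.
#' @export
class_covariance <- function(afmats, labels, label) {
  idx <- which(as.character(labels) == label)
  if (length(idx) == 0)
    stop_afcsp("no trials with label '", label, "'",
               class = "afcsp_bad_label")
  covs <- lapply(afmats[idx], normalized_covariance)
  Reduce(`+`, covs) / length(covs)
}

#' Fit a pairwise common spatial pattern filter
#'
#' Whitens the composite covariance `R_C = R_l + R_r` via its
#' eigendecomposition (`P = A_C^{-1/2} U_C^T`), eigendecomposes the
#' whitened left-class covariance `S_j = P R_l P^T`, and returns the filter
#' matrix `W = B^T P` with rows ordered by descending eigenvalue of `S_j`.
#' Because `S_j + S_k = I` after whitening, the eigenvalues for the two
#' classes are complementary (`lambda_j + lambda_k = 1`); the first rows
#' maximize left-class variance, the last rows right-class variance, and
#' the retained set is the first `m` plus last `m` rows.
#'
#' A ridge `eps * I` with `eps = ridge * trace(R_C) / N` regularizes
#' rank-deficient inputs. Row signs are canonicalized so each row's
#' largest-magnitude entry is positive.
#'
#' @param R_l,R_r Class covariance matrices (trace-normalized).
#' @param m Filters retained per side (default 2, so 2m = 4 features).
#' @param pair Optional `c(classA, classB)` annotation.
#' @param ridge Relative ridge regularization.
#' @return Object of class `csp`: `W` (N x N), `m`, `selected_rows`,
#'   `eigenvalues` (of `S_j`, descending), `pair`, `degenerate`.
#' @export
fit_csp <- function(R_l, R_r, m = 2L, pair = c("left", "right"),
                    ridge = 1e-8) {
  N <- nrow(R_l)
  stopifnot(nrow(R_r) == N, ncol(R_l) == N, ncol(R_r) == N)
  if (2 * m > N)
    stop_afcsp("2m exceeds matrix order N", class = "afcsp_bad_config")
  # the ridge is split across the two class covariances so that the
  # complementarity identity S_j + S_k = I holds exactly after whitening
  eps <- ridge * sum(diag(R_l + R_r)) / N
  R_l <- (R_l + t(R_l)) / 2 + diag(eps / 2, N)
  R_r <- (R_r + t(R_r)) / 2 + diag(eps / 2, N)
  R_c <- R_l + R_r
  ec <- eigen(R_c, symmetric = TRUE)
  if (any(ec$values <= 0))
    stop_afcsp("composite covariance is not positive definite after ridge",
               class = "afcsp_not_pd")
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  S_j <- P %*% R_l %*% t(P)
  S_j <- (S_j + t(S_j)) / 2
  es <- eigen(S_j, symmetric = TRUE)   # descending eigenvalues
  B <- es$vectors
  W <- t(B) %*% P
  for (i in seq_len(N)) {
    j <- which.max(abs(W[i, ]))
    if (W[i, j] < 0) W[i, ] <- -W[i, ]
  }
  rownames(W) <- paste0("csp", seq_len(N))
  structure(list(W = W, m = as.integer(m),
                 selected_rows = c(seq_len(m), (N - m + 1):N),
                 eigenvalues = es$values,
                 pair = pair, ridge_eps = eps,
                 degenerate = max(abs(es$values - 0.5)) < 1e-6),
            class = "csp")
}

#' @export
print.csp <- function(x, ...) {
  cat(sprintf("CSP filter (%s vs %s): N = %d, m = %d%s\n",
              x$pair[1], x$pair[2], nrow(x$W), x$m,
              if (x$degenerate) " [degenerate: classes indistinguishable]"
              else ""))
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues),
                              collapse = " "), "\n")
  invisible(x)
}

#' Log-variance CSP features of one trial
#'
#' Projects the AF matrix through the filter (`Z = W X`) and returns
#' `f_p = log(var(Z_p) / sum_i var(Z_i))` over the 2m retained rows, so
#' `sum(exp(f)) == 1`.
#'
#' @param X An `af_matrix` or N x M matrix.
#' @param filt A fitted [fit_csp()] object.
#' @return Numeric vector of length 2m.
#' @export
extract_features <- function(X, filt) {
  if (inherits(X, "af_matrix")) X <- X$values
  Z <- filt$W[filt$selected_rows, , drop = FALSE] %*% X
  v <- apply(Z, 1, stats::var)
  if (any(v <= 0))
    stop_afcsp("zero-variance projected row; cannot take log-variance",
               class = "afcsp_bad_input")
  log(v / sum(v))
}

ovo_pairs <- function(classes = c("flexion", "extension", "abduction")) {
  list(f1 = classes[c(1, 2)], f2 = classes[c(1, 3)], f3 = classes[c(2, 3)])
}

#' Fit the three one-vs-one CSP filters
#'
#' @param afmats List of `af_matrix` (training partition only).
#' @param labels Class label per trial.
#' @param m Filters retained per side.
#' @param classes Class order; pairs are (1,2), (1,3), (2,3).
#' @param ridge Passed to [fit_csp()].
#' @return Named list (`f1`, `f2`, `f3`) of `csp` objects.
#' @export
fit_ovo_csp <- function(afmats, labels, m = 2L,
                        classes = c("flexion", "extension", "abduction"),
                        ridge = 1e-8) {
  labels <- as.character(labels)
  missing_cl <- setdiff(classes, unique(labels))
  if (length(missing_cl))
    stop_afcsp("class missing from training data: ",
               paste(missing_cl, collapse = ", "),
               class = "afcsp_bad_label")
  lapply(ovo_pairs(classes), function(pr) {
    fit_csp(class_covariance(afmats, labels, pr[1]),
            class_covariance(afmats, labels, pr[2]),
            m = m, pair = pr, ridge = ridge)
  })
}

#' Per-pair feature sets for a collection of trials
#'
#' For each pair filter, extracts features for the trials belonging to that
#' pair's two classes (training layout) or, with `restrict = FALSE`, for
#' every trial (prediction layout, where each trial needs coordinates in
#' all three pair spaces).
#'
#' @param filters Output of [fit_ovo_csp()].
#' @param afmats List of `af_matrix`.
#' @param labels Class label per trial (may be `NULL` when
#'   `restrict = FALSE`).
#' @param restrict Keep only the pair's own classes?
#' @return Named list per pair: `x` (trials x 2m feature matrix), `labels`,
#'   `pair`, `trial_index` (indices into `afmats`).
#' @export
ovo_features <- function(filters, afmats, labels = NULL, restrict = TRUE) {
  labels <- if (is.null(labels)) rep(NA_character_, length(afmats))
            else as.character(labels)
  lapply(filters, function(filt) {
    idx <- if (restrict) which(labels %in% filt$pair)
           else seq_along(afmats)
    x <- t(vapply(afmats[idx], extract_features, filt = filt,
                  numeric(2 * filt$m)))
    list(x = x, labels = labels[idx], pair = filt$pair, trial_index = idx)
  })
}

#' Fit pairwise CSP and extract one-vs-one features in one step
#'
#' Filters are fit on exactly the trials passed in, so passing the training
#' partition guarantees no test-label leakage.
#'
#' @inheritParams fit_ovo_csp
#' @return List with `features` (as [ovo_features()]) and `filters`.
#' @export
build_ovo_features <- function(afmats, labels, m = 2L,
                               classes = c("flexion", "extension",
                                           "abduction"),
                               ridge = 1e-8) {
  filters <- fit_ovo_csp(afmats, labels, m = m, classes = classes,
                         ridge = ridge)
  list(features = ovo_features(filters, afmats, labels), filters = filters)
}
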