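#' Kernel specification for the twin SVM
#'
#' @param kind `"linear"` or `"rbf"`. The RBF kernel is
#'   `exp(-||u - v||^2 / (2 lambda^2))` with `lambda` the kernel width
#'   (searched over `[2^-20, 2^3]` by the optimizer).
#' @param lambda RBF width; required positive when `kind = "rbf"`.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("linear", "rbf"), lambda = 1) {
  kind <- match.arg(kind)
  if (kind == "rbf" && (!is.finite(lambda) || lambda <= 0))
    stop_afcsp("rbf kernel needs lambda > 0", class = "afcsp_bad_config")
  structure(list(kind = kind, lambda = lambda), class = "kernel_spec")
}

kernel_matrix <- function(U, V, kernel) {
  U <- as.matrix(U); V <- as.matrix(V)
  if (kernel$kind == "linear") return(U %*% t(V))
  d2 <- outer(rowSums(U^2), rowSums(V^2), "+") - 2 * U %*% t(V)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * kernel$lambda^2))
}

# Box-constrained QP: min 1/2 a' Q a - e' a, 0 <= a <= cmax, via the
# interior-point solver kernlab::ipop. Q is PSD by construction; a tiny
# diagonal load keeps the solver well-posed when Q is near-singular.
solve_box_qp <- function(Q, cmax) {
  n <- nrow(Q)
  Q <- Q + diag(max(sum(diag(Q)) / n, 1) * 1e-10, n)
  # vacuous inequality 0 <= sum(alpha) <= n * cmax keeps the KKT system
  # nonsingular (an all-zero constraint row would make it singular)
  sol <- tryCatch(
    kernlab::ipop(c = rep(-1, n), H = Q, A = matrix(1, 1, n), b = 0,
                  l = rep(0, n), u = rep(cmax, n), r = n * cmax,
                  maxiter = 200),
    error = function(e)
      stop_afcsp("QP solver failed: ", conditionMessage(e),
                 class = "afcsp_qp_failure"))
  how <- kernlab::how(sol)
  if (!how %in% c("converged", "relative convergence"))
    stop_afcsp("QP solver did not converge (status: ", how, ")",
               class = "afcsp_qp_failure")
  pmin(pmax(kernlab::primal(sol), 0), cmax)
}

#' Fit a binary twin support vector machine
#'
#' Learns two nonparallel hyperplanes: plane 1 minimizes the squared
#' distance to class i while class j lies at unit distance on the negative
#' side (slack penalty `c1`); plane 2 symmetrically fits class j against
#' class i (penalty `c2`). Each plane is obtained from the convex dual QP
#' with box constraints `0 <= alpha <= c`, using a ridge
#' `eps = 1e-7 trace` on the Gram matrix inverse. With an RBF kernel the
#' surfaces are `K(x, C^T) w + b = 0`, `C` stacking both classes' training
#' samples.
#'
#' @param A_i,A_j Samples x dims matrices for class i and class j.
#' @param c1,c2 Positive penalty parameters for planes 1 and 2.
#' @param kernel A [kernel_spec()].
#' @return Object of class `twin_svm` with components `w_i, b_i`
#'   (plane of class i), `w_j, b_j`, `alpha`, `gamma`, `C` (training stack,
#'   kernel case), `norm_i`, `norm_j` (feature-space plane norms),
#'   `kernel`, `degenerate`.
#' @export
twin_svm <- function(A_i, A_j, c1, c2, kernel = kernel_spec("linear")) {
  A_i <- as.matrix(A_i); A_j <- as.matrix(A_j)
  if (nrow(A_i) == 0 || nrow(A_j) == 0)
    stop_afcsp("both classes need at least one sample",
               class = "afcsp_bad_input")
  if (c1 <= 0 || c2 <= 0)
    stop_afcsp("penalties must be positive", class = "afcsp_bad_config")
  C <- rbind(A_i, A_j)
  Phi_i <- if (kernel$kind == "linear") A_i else kernel_matrix(A_i, C, kernel)
  Phi_j <- if (kernel$kind == "linear") A_j else kernel_matrix(A_j, C, kernel)
  H <- cbind(Phi_i, 1)
  G <- cbind(Phi_j, 1)
  reg_inv <- function(M) {
    eps <- 1e-7 * sum(diag(M))
    solve(M + diag(eps, nrow(M)))
  }
  HtHinv <- reg_inv(crossprod(H))
  GtGinv <- reg_inv(crossprod(G))
  alpha <- solve_box_qp(G %*% HtHinv %*% t(G), c1)
  gamma <- solve_box_qp(H %*% GtGinv %*% t(H), c2)
  u1 <- -HtHinv %*% t(G) %*% alpha     # (w_i, b_i)
  u2 <- GtGinv %*% t(H) %*% gamma      # (w_j, b_j)
  d <- length(u1) - 1L
  w_i <- u1[seq_len(d)]; b_i <- u1[d + 1L]
  w_j <- u2[seq_len(d)]; b_j <- u2[d + 1L]
  plane_norm <- function(w) {
    n2 <- if (kernel$kind == "linear") sum(w^2)
          else drop(t(w) %*% kernel_matrix(C, C, kernel) %*% w)
    sqrt(max(n2, 0))
  }
  dup <- nrow(A_i) == nrow(A_j) &&
    isTRUE(all.equal(A_i[do.call(order, as.data.frame(A_i)), , drop = FALSE],
                     A_j[do.call(order, as.data.frame(A_j)), , drop = FALSE],
                     check.attributes = FALSE))
  structure(list(w_i = w_i, b_i = b_i, w_j = w_j, b_j = b_j,
                 alpha = alpha, gamma = gamma,
                 C = if (kernel$kind == "rbf") C else NULL,
                 norm_i = plane_norm(w_i), norm_j = plane_norm(w_j),
                 c1 = c1, c2 = c2, kernel = kernel,
                 degenerate = dup),
            class = "twin_svm")
}

#' @export
print.twin_svm <- function(x, ...) {
  cat(sprintf("twin SVM (%s kernel%s): c1 = %.4g, c2 = %.4g%s\n",
              x$kernel$kind,
              if (x$kernel$kind == "rbf")
                sprintf(", lambda = %.4g", x$kernel$lambda) else "",
              x$c1, x$c2,
              if (x$degenerate) " [degenerate: identical classes]" else ""))
  invisible(x)
}

#' Perpendicular distance from a point to one twin hyperplane
#'
#' `|w . phi(x) + b| / ||w||` in the kernel feature space; invariant to
#' rescaling of `(w, b)`.
#'
#' @param x Feature vector (or matrix of rows).
#' @param pair A fitted [twin_svm()].
#' @param side `"i"` (plane of the first class) or `"j"`.
#' @return Nonnegative distance(s).
#' @export
plane_distance <- function(x, pair, side = c("i", "j")) {
  side <- match.arg(side)
  w <- if (side == "i") pair$w_i else pair$w_j
  b <- if (side == "i") pair$b_i else pair$b_j
  nrm <- if (side == "i") pair$norm_i else pair$norm_j
  if (nrm <= .Machine$double.eps^0.5)
    stop_afcsp("zero-norm plane normal", class = "afcsp_degenerate_plane")
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  phi <- if (pair$kernel$kind == "linear") x
         else kernel_matrix(x, pair$C, pair$kernel)
  as.numeric(abs(phi %*% w + b)) / nrm
}

#' Predict the binary class of feature vectors with a twin SVM
#'
#' @param object A [twin_svm()].
#' @param newdata Feature matrix (rows = samples).
#' @param ... Ignored.
#' @return Integer vector: 1 for the first class (nearer plane i), 2 for
#'   the second.
#' @export
predict.twin_svm <- function(object, newdata, ...) {
  di <- plane_distance(newdata, object, "i")
  dj <- plane_distance(newdata, object, "j")
  ifelse(di <= dj, 1L, 2L)
}

# Primal objective of plane 1 (and symmetrically plane 2): used by the
# tests' brute-force oracle comparison.
twsvm_primal_objective <- function(pair, A_i, A_j, which = c("i", "j")) {
  which <- match.arg(which)
  phi <- function(X) if (pair$kernel$kind == "linear") as.matrix(X)
                     else kernel_matrix(X, pair$C, pair$kernel)
  if (which == "i") {
    fit <- phi(A_i) %*% pair$w_i + pair$b_i
    viol <- pmax(0, 1 + (phi(A_j) %*% pair$w_i + pair$b_i))
    0.5 * sum(fit^2) + pair$c1 * sum(viol)
  } else {
    fit <- phi(A_j) %*% pair$w_j + pair$b_j
    viol <- pmax(0, 1 - (phi(A_i) %*% pair$w_j + pair$b_j))
    0.5 * sum(fit^2) + pair$c2 * sum(viol)
  }
}

#' Fit the one-vs-one three-class twin SVM
#'
#' One binary twin SVM per class pair, each trained only on its two
#' classes' samples, sharing the penalties `c1` (all first planes) and `c2`
#' (all second planes).
#'
#' @param features Per-pair training features as produced by
#'   [ovo_features()] / [build_ovo_features()] (training layout).
#' @param c1,c2 Shared penalties.
#' @param kernel A [kernel_spec()].
#' @return Object of class `ovo_twsvm`: `pairs` (3 `twin_svm`), `classes`,
#'   `c1`, `c2`, `kernel`.
#' @export
ovo_twsvm <- function(features, c1, c2, kernel = kernel_spec("linear")) {
  if (length(features) != 3)
    stop_afcsp("need the three pair feature sets", class = "afcsp_bad_input")
  classes <- unique(unlist(lapply(features, `[[`, "pair")))
  pairs <- lapply(features, function(fs) {
    twin_svm(fs$x[fs$labels == fs$pair[1], , drop = FALSE],
             fs$x[fs$labels == fs$pair[2], , drop = FALSE],
             c1, c2, kernel)
  })
  pair_names <- lapply(features, `[[`, "pair")
  structure(list(pairs = pairs, pair_classes = pair_names,
                 classes = classes, c1 = c1, c2 = c2, kernel = kernel),
            class = "ovo_twsvm")
}

#' @export
print.ovo_twsvm <- function(x, ...) {
  cat(sprintf("one-vs-one twin SVM: %d sub-classifiers over {%s}\n",
              length(x$pairs), paste(x$classes, collapse = ", ")))
  cat(sprintf("  %s kernel%s, c1 = %.4g, c2 = %.4g\n", x$kernel$kind,
              if (x$kernel$kind == "rbf")
                sprintf(" (lambda = %.4g)", x$kernel$lambda) else "",
              x$c1, x$c2))
  invisible(x)
}

#' Predict classes by one-vs-one distance voting
#'
#' Each sub-classifier votes for the class whose hyperplane is nearer; the
#' majority wins. A three-way tie (1,1,1) is broken by the smallest sum of
#' normalized distances to the candidate class's own planes across the two
#' pairs involving it; any remaining tie falls to the lowest class index.
#'
#' @param object A fitted [ovo_twsvm()].
#' @param newdata Per-pair feature sets in prediction layout
#'   ([ovo_features()] with `restrict = FALSE`): every trial must have
#'   coordinates in each pair's feature space.
#' @param ... Ignored.
#' @return List: `class` (factor over the model's classes), `votes`
#'   (trials x classes matrix).
#' @export
predict.ovo_twsvm <- function(object, newdata, ...) {
  n <- nrow(newdata[[1]]$x)
  classes <- object$classes
  votes <- matrix(0L, n, length(classes),
                  dimnames = list(NULL, classes))
  dist_own <- matrix(0, n, length(classes),
                     dimnames = list(NULL, classes))
  for (k in seq_along(object$pairs)) {
    pr <- object$pair_classes[[k]]
    tw <- object$pairs[[k]]
    di <- plane_distance(newdata[[k]]$x, tw, "i")
    dj <- plane_distance(newdata[[k]]$x, tw, "j")
    win <- ifelse(di <= dj, pr[1], pr[2])
    for (cl in pr) votes[, cl] <- votes[, cl] + (win == cl)
    dist_own[, pr[1]] <- dist_own[, pr[1]] + di
    dist_own[, pr[2]] <- dist_own[, pr[2]] + dj
  }
  pick <- integer(n)
  for (t in seq_len(n)) {
    top <- which(votes[t, ] == max(votes[t, ]))
    if (length(top) > 1) {
      best <- top[dist_own[t, top] == min(dist_own[t, top])]
      top <- best[1]
    }
    pick[t] <- top[1]
  }
  list(class = factor(classes[pick], levels = classes), votes = votes)
}

#' Serialize a fitted one-vs-one twin SVM to versioned JSON
#'
#' @param model A fitted [ovo_twsvm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ovo_twsvm <- function(model, path) {
  payload <- list(
    format = "afcsp-ovo-twsvm", version = 1L,
    c1 = model$c1, c2 = model$c2,
    kernel = unclass(model$kernel),
    classes = model$classes,
    pairs = lapply(seq_along(model$pairs), function(k) {
      tw <- model$pairs[[k]]
      list(classes = model$pair_classes[[k]],
           w_i = tw$w_i, b_i = tw$b_i, w_j = tw$w_j, b_j = tw$b_j,
           norm_i = tw$norm_i, norm_j = tw$norm_j,
           C = tw$C, degenerate = tw$degenerate)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a serialized one-vs-one twin SVM
#'
#' @param path File written by [write_ovo_twsvm()].
#' @return An `ovo_twsvm` usable with [predict.ovo_twsvm()].
#' @export
read_ovo_twsvm <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "afcsp-ovo-twsvm"))
    stop_afcsp("not an afcsp model file", class = "afcsp_parse_error")
  kernel <- kernel_spec(p$kernel$kind, as.numeric(p$kernel$lambda))
  num <- function(v) as.numeric(unlist(v))
  pairs <- lapply(p$pairs, function(q) {
    C <- NULL
    if (!is.null(q$C))
      C <- do.call(rbind, lapply(q$C, num))
    structure(list(w_i = num(q$w_i), b_i = num(q$b_i),
                   w_j = num(q$w_j), b_j = num(q$b_j),
                   alpha = NULL, gamma = NULL, C = C,
                   norm_i = num(q$norm_i), norm_j = num(q$norm_j),
                   c1 = num(p$c1), c2 = num(p$c2), kernel = kernel,
                   degenerate = isTRUE(q$degenerate)),
              class = "twin_svm")
  })
  pair_classes <- lapply(p$pairs, function(q) unlist(q$classes))
  structure(list(pairs = pairs, pair_classes = pair_classes,
                 classes = unlist(p$classes),
                 c1 = num(p$c1), c2 = num(p$c2), kernel = kernel),
            class = "ovo_twsvm")
}
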