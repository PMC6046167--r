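test_that("normalized covariance has unit trace, symmetry and the right
           rank", {
  R <- normalized_covariance(diag(8))
  expect_equal(R, diag(8) / 8)
  expect_equal(sum(diag(R)), 1, tolerance = 1e-12)

  set.seed(3)
  X <- matrix(rnorm(8 * 30), 8, 30)
  R2 <- normalized_covariance(X)
  expect_equal(sum(diag(R2)), 1, tolerance = 1e-12)
  expect_equal(R2, t(R2))

  one_row <- matrix(0, 8, 30); one_row[3, ] <- rnorm(30)
  expect_equal(qr(normalized_covariance(one_row))$rank, 1)
  expect_error(normalized_covariance(matrix(0, 8, 8)),
               class = "afcsp_bad_input")
})

test_that("class covariance averages per-trial covariances", {
  set.seed(4)
  X1 <- matrix(rnorm(8 * 30), 8, 30)
  X2 <- matrix(rnorm(8 * 30), 8, 30)
  same <- class_covariance(list(X1, X1), c("a", "a"), "a")
  expect_equal(same, normalized_covariance(X1))
  two <- class_covariance(list(X1, X2), c("a", "a"), "a")
  expect_equal(two,
               (normalized_covariance(X1) + normalized_covariance(X2)) / 2)
  expect_error(class_covariance(list(X1), c("a"), "b"),
               class = "afcsp_bad_label")

  af <- demo_af()
  Rf <- class_covariance(af$afmats, af$labels, "flexion")
  expect_equal(sum(diag(Rf)), 1, tolerance = 1e-12)
  expect_gte(min(eigen(Rf, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)
})

test_that("CSP whitening and eigenvalue complementarity hold to 1e-8", {
  R_l <- random_spd(8, seed = 101)
  R_r <- random_spd(8, seed = 202)
  filt <- fit_csp(R_l, R_r)
  # reconstruct the (ridge-regularized) covariances the filter whitened
  Rl_r <- R_l + diag(filt$ridge_eps / 2, 8)
  Rr_r <- R_r + diag(filt$ridge_eps / 2, 8)
  # whitening: W R_C W^T = I
  W <- filt$W
  I_hat <- W %*% (Rl_r + Rr_r) %*% t(W)
  expect_lt(max(abs(I_hat - diag(8))), 1e-8)
  # complementarity: W R_l W^T and W R_r W^T are diagonal with sum 1
  D_l <- W %*% Rl_r %*% t(W)
  D_r <- W %*% Rr_r %*% t(W)
  expect_lt(max(abs(D_l - diag(diag(D_l)))), 1e-8)
  expect_lt(max(abs(diag(D_l) + diag(D_r) - 1)), 1e-8)
  expect_equal(unname(diag(D_l)), filt$eigenvalues, tolerance = 1e-8)
  # descending order, full rank, selected rows
  expect_true(all(diff(filt$eigenvalues) <= 1e-12))
  expect_equal(qr(filt$W)$rank, 8)
  expect_identical(filt$selected_rows, c(1L, 2L, 7L, 8L))
})

test_that("CSP matches a direct generalized-eigenvector solve", {
  R_l <- random_spd(8, seed = 7)
  R_r <- random_spd(8, seed = 8)
  filt <- fit_csp(R_l, R_r)
  R_c <- R_l + R_r
  for (i in seq_len(8)) {
    w <- filt$W[i, ]
    lam <- filt$eigenvalues[i]
    expect_lt(max(abs(R_l %*% w - lam * R_c %*% w)), 1e-6)
  }
  # eigenvalues agree with an independent generalized solver
  ref <- sort(Re(eigen(solve(R_c, R_l))$values), decreasing = TRUE)
  expect_equal(filt$eigenvalues, ref, tolerance = 1e-6)
})

test_that("equal class covariances are flagged degenerate", {
  R <- random_spd(8, seed = 9)
  filt <- fit_csp(R, R)
  expect_true(filt$degenerate)
  expect_equal(filt$eigenvalues, rep(0.5, 8), tolerance = 1e-8)
})

test_that("block-structured classes produce strongly discriminative filters
           and separable features", {
  blocks <- block_af_matrices()
  R_a <- class_covariance(blocks$A, rep("A", 10), "A")
  R_b <- class_covariance(blocks$B, rep("B", 10), "B")
  filt <- fit_csp(R_a, R_b, pair = c("A", "B"))
  top <- filt$W[1, , drop = FALSE]
  var_ratio <- function(X) stats::var(as.numeric(top %*% X))
  v_a <- mean(vapply(blocks$A, var_ratio, numeric(1)))
  v_b <- mean(vapply(blocks$B, var_ratio, numeric(1)))
  expect_gt(v_a / v_b, 10)

  f_a <- t(vapply(blocks$A, extract_features, filt = filt, numeric(4)))
  f_b <- t(vapply(blocks$B, extract_features, filt = filt, numeric(4)))
  pooled_sd <- sqrt((stats::var(f_a[, 1]) + stats::var(f_b[, 1])) / 2)
  expect_gt(abs(mean(f_a[, 1]) - mean(f_b[, 1])) / pooled_sd, 2)
})

test_that("log-variance features are normalized (sum exp f = 1)", {
  filt <- structure(list(W = diag(8), m = 2L,
                         selected_rows = c(1L, 2L, 7L, 8L)),
                    class = "csp")
  # equal-variance projections give the uniform feature log(1/4)
  set.seed(12)
  base <- rnorm(50)
  X <- matrix(0, 8, 50)
  for (i in c(1, 2, 7, 8)) X[i, ] <- base
  expect_equal(extract_features(X, filt), rep(log(0.25), 4))

  af <- demo_af()
  filters <- fit_ovo_csp(af$afmats[1:30], af$labels[1:30])
  for (i in c(1, 15, 30)) {
    f <- extract_features(af$afmats[[i]], filters$f1)
    expect_length(f, 4)
    expect_equal(sum(exp(f)), 1, tolerance = 1e-9)
  }
  X0 <- matrix(0, 8, 50); X0[1, ] <- 1  # zero-variance projections
  expect_error(extract_features(X0, filt), class = "afcsp_bad_input")
})

test_that("one-vs-one feature construction pairs the right classes and sees
           only the trials passed in", {
  af <- demo_af()
  of <- build_ovo_features(af$afmats, af$labels)
  expect_named(of$features, c("f1", "f2", "f3"))
  expect_identical(of$filters$f1$pair, c("flexion", "extension"))
  expect_identical(of$filters$f2$pair, c("flexion", "abduction"))
  expect_identical(of$filters$f3$pair, c("extension", "abduction"))
  for (fs in of$features) {
    expect_equal(nrow(fs$x), 40)
    expect_equal(ncol(fs$x), 4)
  }
  expect_error(fit_ovo_csp(af$afmats[af$labels == "flexion"],
                           af$labels[af$labels == "flexion"]),
               class = "afcsp_bad_label")

  # filters depend only on the training partition
  tr <- 1:45
  f1 <- fit_ovo_csp(af$afmats[tr], af$labels[tr])
  f2 <- fit_ovo_csp(af$afmats[tr], af$labels[tr])
  expect_identical(f1$f1$W, f2$f1$W)
  feats_a <- ovo_features(f1, af$afmats[46:60], restrict = FALSE)
  feats_b <- ovo_features(f1, af$afmats[c(50:60, 46:49)], restrict = FALSE)
  expect_equal(feats_a$f1$x[1, ], feats_b$f1$x[12, ])
})
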