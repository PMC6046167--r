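toy_i <- matrix(c(0, 0, 0, 1), 2, 2, byrow = TRUE)
toy_j <- matrix(c(2, 0, 2, 1), 2, 2, byrow = TRUE)

test_that("the linear twin SVM recovers the two class planes on the axis
           toy", {
  tw <- twin_svm(toy_i, toy_j, 1, 1)
  # plane i hugs class i (x = 0), plane j hugs class j (x = 2)
  expect_lt(max(plane_distance(toy_i, tw, "i")), 1e-3)
  expect_lt(max(plane_distance(toy_j, tw, "j")), 1e-3)
  expect_equal(plane_distance(toy_i, tw, "j"), c(2, 2), tolerance = 1e-2)
  expect_equal(plane_distance(toy_j, tw, "i"), c(2, 2), tolerance = 1e-2)
  expect_identical(predict(tw, rbind(c(0.2, 0.5), c(1.8, 0.5))), c(1L, 2L))
})

test_that("the solved primal objective matches exhaustive brute force on
           non-separable 2-D toys", {
  A_i <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  A_j <- matrix(c(0.5, 0.5, 2, 0, 1, 1.5), 3, 2, byrow = TRUE)
  for (cost in c(0.5, 2)) {
    tw <- twin_svm(A_i, A_j, cost, cost)
    obj_i <- twsvm_primal_objective(tw, A_i, A_j, "i")
    obj_j <- twsvm_primal_objective(tw, A_i, A_j, "j")
    brute_i <- brute_force_plane(A_i, A_j, cost, "i")
    brute_j <- brute_force_plane(A_j, A_i, cost, "j")
    expect_lt(abs(obj_i - brute_i), 0.01 * brute_i + 1e-6)
    expect_lt(abs(obj_j - brute_j), 0.01 * brute_j + 1e-6)
  }
})

test_that("duplicating every sample leaves the planes unchanged", {
  tw1 <- twin_svm(toy_i, toy_j, 1, 1)
  tw2 <- twin_svm(rbind(toy_i, toy_i), rbind(toy_j, toy_j), 1, 1)
  unit <- function(w, b) { s <- sqrt(sum(w^2)); c(w, b) / s }
  expect_equal(unit(tw1$w_i, tw1$b_i), unit(tw2$w_i, tw2$b_i),
               tolerance = 1e-3)
  expect_equal(unit(tw1$w_j, tw1$b_j), unit(tw2$w_j, tw2$b_j),
               tolerance = 1e-3)
})

test_that("in the identity-kernel limit (RBF width -> 0 on distinct points)
           the toy stays separable", {
  tw <- twin_svm(toy_i, toy_j, 1, 1, kernel_spec("rbf", 2^-10))
  expect_identical(predict(tw, toy_i), c(1L, 1L))
  expect_identical(predict(tw, toy_j), c(2L, 2L))
  # and a moderate-width RBF also classifies the training points
  tw2 <- twin_svm(toy_i, toy_j, 1, 1, kernel_spec("rbf", 1))
  expect_identical(predict(tw2, rbind(toy_i, toy_j)), c(1L, 1L, 2L, 2L))
})

test_that("plane distances are exact and scale-invariant", {
  lin <- kernel_spec("linear")
  pair <- structure(list(w_i = c(1, 0), b_i = 0, w_j = c(2, 0), b_j = -4,
                         norm_i = 1, norm_j = 2, kernel = lin, C = NULL),
                    class = "twin_svm")
  expect_equal(plane_distance(c(0, 5), pair, "i"), 0)
  expect_equal(plane_distance(c(3, 0), pair, "i"), 3)
  # (w, b) scaled by 5 leaves the distance unchanged
  scaled <- pair
  scaled$w_i <- 5 * pair$w_i; scaled$b_i <- 5 * pair$b_i; scaled$norm_i <- 5
  expect_equal(plane_distance(c(3, 2), scaled, "i"),
               plane_distance(c(3, 2), pair, "i"))
  degen <- pair; degen$norm_i <- 0
  expect_error(plane_distance(c(1, 1), degen, "i"),
               class = "afcsp_degenerate_plane")
})

test_that("dual variables respect their box constraints", {
  A_i <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  A_j <- matrix(c(0.5, 0.5, 2, 0, 1, 1.5), 3, 2, byrow = TRUE)
  for (cost in c(0.25, 1, 4)) {
    tw <- twin_svm(A_i, A_j, cost, cost, kernel_spec("rbf", 0.8))
    expect_true(all(tw$alpha >= -1e-6 & tw$alpha <= cost + 1e-6))
    expect_true(all(tw$gamma >= -1e-6 & tw$gamma <= cost + 1e-6))
  }
})

test_that("raising c1 never increases the margin-violation sum of plane 1", {
  A_i <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  A_j <- matrix(c(0.5, 0.5, 1, 1, 0.2, 0.8), 3, 2, byrow = TRUE)
  viol <- vapply(c(0.1, 0.5, 1, 2, 5, 10), function(cost) {
    tw <- twin_svm(A_i, A_j, cost, 1)
    sum(pmax(0, 1 + (A_j %*% tw$w_i + tw$b_i)))
  }, numeric(1))
  expect_true(all(diff(viol) <= 1e-6))
})

test_that("twin SVM input validation works", {
  expect_error(twin_svm(toy_i, toy_j, -1, 1), class = "afcsp_bad_config")
  expect_error(twin_svm(toy_i[0, , drop = FALSE], toy_j, 1, 1),
               class = "afcsp_bad_input")
  expect_error(kernel_spec("rbf", 0), class = "afcsp_bad_config")
  tw <- twin_svm(toy_i, toy_i, 1, 1)  # duplicate classes
  expect_true(tw$degenerate)
})

make_ovo_features <- function(centers, n = 10, sd = 0.15, seed = 2,
                              classes = c("flexion", "extension",
                                          "abduction")) {
  set.seed(seed)
  pts <- lapply(classes, function(cl)
    cbind(rnorm(n, centers[[cl]][1], sd), rnorm(n, centers[[cl]][2], sd)))
  names(pts) <- classes
  pairs <- list(f1 = classes[1:2], f2 = classes[c(1, 3)], f3 = classes[2:3])
  feats <- lapply(pairs, function(pr)
    list(x = rbind(pts[[pr[1]]], pts[[pr[2]]]),
         labels = rep(pr, each = n), pair = pr,
         trial_index = seq_len(2 * n)))
  list(features = feats, points = pts)
}

test_that("one-vs-one voting classifies a separable 3-class toy perfectly
           and reproduces the 2-votes-wins walkthrough", {
  toy <- make_ovo_features(list(flexion = c(0, 0), extension = c(3, 0),
                                abduction = c(1.5, 3)))
  model <- ovo_twsvm(toy$features, 1, 1)
  expect_length(model$pairs, 3)
  # prediction layout: the same query point in every pair space
  query <- function(p) lapply(toy$features, function(f)
    list(x = matrix(p, 1, 2), pair = f$pair))
  pred <- predict(model, query(c(0.1, -0.1)))  # deep in class 1 territory
  expect_identical(as.character(pred$class), "flexion")
  # Fig-6-style vote pattern: class 1 beats 2 and 3, class 2 beats 3
  expect_equal(unname(pred$votes[1, ]), c(2, 1, 0))
  # training accuracy 100%
  all_feats <- lapply(toy$features, function(f)
    list(x = do.call(rbind, toy$points), pair = f$pair))
  truth <- rep(c("flexion", "extension", "abduction"), each = 10)
  acc <- mean(as.character(predict(model, all_feats)$class) == truth)
  expect_equal(acc, 1)
})

test_that("three-way vote ties break by summed plane distance, then lowest
           class index", {
  lin <- kernel_spec("linear")
  plane <- function(w_i, b_i, w_j, b_j)
    structure(list(w_i = w_i, b_i = b_i, w_j = w_j, b_j = b_j,
                   norm_i = sqrt(sum(w_i^2)), norm_j = sqrt(sum(w_j^2)),
                   kernel = lin, C = NULL),
              class = "twin_svm")
  classes <- c("flexion", "extension", "abduction")
  # cyclic pair winners: f1 -> flexion, f2 -> abduction, f3 -> extension
  model <- structure(list(
    pairs = list(plane(c(1, 0), -1, c(1, 0), -9),     # flexion nearer
                 plane(c(1, 0), -9, c(1, 0), -2),     # abduction nearer
                 plane(c(1, 0), -3.5, c(1, 0), -9)),  # extension nearer
    pair_classes = list(classes[1:2], classes[c(1, 3)], classes[2:3]),
    classes = classes, c1 = 1, c2 = 1, kernel = lin),
    class = "ovo_twsvm")
  newdata <- lapply(1:3, function(k) list(x = matrix(c(4, 0), 1, 2)))
  pred <- predict(model, newdata)
  expect_equal(unname(pred$votes[1, ]), c(1, 1, 1))
  # summed own-plane distances: flexion 3+5, extension 0.5+5, abduction 5+2
  expect_identical(as.character(pred$class), "extension")

  # a strict vote cycle with equal summed distances falls back to the
  # lowest class index
  sym <- structure(list(
    pairs = list(plane(c(1, 0), -3, c(1, 0), -6),   # flexion 1, extension 2
                 plane(c(1, 0), -6, c(1, 0), -3),   # abduction 1, flexion 2
                 plane(c(1, 0), -3, c(1, 0), -6)),  # extension 1, abduction 2
    pair_classes = list(classes[1:2], classes[c(1, 3)], classes[2:3]),
    classes = classes, c1 = 1, c2 = 1, kernel = lin),
    class = "ovo_twsvm")
  pred2 <- predict(sym, newdata)
  expect_equal(unname(pred2$votes[1, ]), c(1, 1, 1))
  expect_identical(as.character(pred2$class), "flexion")
})

test_that("a fitted RBF model serializes to JSON and back without changing
           its predictions", {
  toy <- make_ovo_features(list(flexion = c(0, 0), extension = c(2, 0),
                                abduction = c(1, 2)), seed = 4)
  model <- ovo_twsvm(toy$features, 1.5, 0.7, kernel_spec("rbf", 0.9))
  path <- withr::local_tempfile(fileext = ".json")
  write_ovo_twsvm(model, path)
  model2 <- read_ovo_twsvm(path)
  grid <- as.matrix(expand.grid(seq(-0.5, 2.5, 0.5), seq(-0.5, 2.5, 0.5)))
  nd <- lapply(toy$features, function(f) list(x = grid, pair = f$pair))
  expect_identical(as.character(predict(model, nd)$class),
                   as.character(predict(model2, nd)$class))
  expect_equal(model2$c1, 1.5)
  expect_equal(model2$kernel$lambda, 0.9)
})
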