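# Shared fixtures, computed lazily once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# The standard study-condition dataset: 60 trials, 20/class, erd depth 0.5.
demo_trialset <- function() fixture("demo_trialset", function() {
  generate_trialset(sim_config(seed = 42))
})

demo_af <- function() fixture("demo_af", function() {
  build_af_matrices(preprocess_trialset(demo_trialset()))
})

demo_cv <- function() fixture("demo_cv", function() {
  af <- demo_af()
  prepare_cv_features(af$afmats, af$labels, k = 5, seed = 7)
})

# Block-structured AF-like matrices: class A active on rows 1-2, class B on
# rows 7-8; ideal CSP input with a known discriminative structure.
block_af_matrices <- function(n_per_class = 10, n_rows = 8, n_cols = 30,
                              seed = 5) {
  set.seed(seed)
  make <- function(active) {
    X <- matrix(stats::rnorm(n_rows * n_cols, sd = 0.05), n_rows, n_cols)
    X[active, ] <- X[active, ] + matrix(stats::rnorm(length(active) * n_cols,
                                                     sd = 1),
                                        length(active), n_cols)
    X
  }
  list(A = replicate(n_per_class, make(1:2), simplify = FALSE),
       B = replicate(n_per_class, make(7:8), simplify = FALSE))
}

# Random symmetric positive-definite matrix.
random_spd <- function(n, seed) {
  set.seed(seed)
  M <- matrix(stats::rnorm(n * n), n, n)
  S <- crossprod(M) + diag(0.1, n)
  S / sum(diag(S))
}

# Direct primal minimization of one twin-SVM plane on a 2-D toy,
# independent of the dual QP route: a global grid over plane angle x scale
# x offset locates the basin, then a derivative-free polish refines it.
brute_force_plane <- function(A_own, A_other, cost, side = c("i", "j"),
                              th_grid = seq(0, 2 * pi,
                                            length.out = 145)[-145],
                              s_grid = exp(seq(log(0.05), log(8),
                                               length.out = 40)),
                              b_grid = seq(-6, 6, by = 0.05)) {
  side <- match.arg(side)
  primal <- function(p) {
    margin <- A_other %*% p[1:2] + p[3]
    viol <- if (side == "i") pmax(0, 1 + margin) else pmax(0, 1 - margin)
    0.5 * sum((A_own %*% p[1:2] + p[3])^2) + cost * sum(viol)
  }
  best <- Inf
  best_p <- NULL
  for (th in th_grid) {
    u <- c(cos(th), sin(th))
    po <- as.numeric(A_own %*% u)
    px <- as.numeric(A_other %*% u)
    for (s in s_grid) {
      fit <- 0.5 * colSums(outer(s * po, b_grid, "+")^2)
      margin <- outer(s * px, b_grid, "+")
      viol <- if (side == "i") 1 + margin else 1 - margin
      viol[viol < 0] <- 0
      obj <- fit + cost * colSums(viol)
      k <- which.min(obj)
      if (obj[k] < best) {
        best <- obj[k]
        best_p <- c(s * u, b_grid[k])
      }
    }
  }
  polish <- stats::optim(best_p, primal, method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-12))
  min(best, polish$value)
}

# O(M N^3) reference non-dominated sorting: peel maximal non-dominated sets.
brute_force_fronts <- function(objectives) {
  remaining <- seq_len(nrow(objectives))
  fronts <- list()
  while (length(remaining)) {
    nd <- remaining[vapply(remaining, function(p) {
      !any(vapply(remaining, function(q)
        q != p && dominates(objectives[q, ], objectives[p, ]), logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1L]] <- nd
    remaining <- setdiff(remaining, nd)
  }
  fronts
}

# Band power from the one-sided amplitude spectrum.
band_power <- function(x, fs, band) {
  s <- amplitude_spectrum(x, fs)
  keep <- s$freq >= band[1] & s$freq <= band[2]
  sum(s$mag[keep]^2)
}
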