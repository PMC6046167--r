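#' Hyperparameter search bounds
#'
#' Penalties `c1`, `c2` in `[2^-3, 2^3]` and RBF width `lambda` in
#' `[2^-20, 2^3]`. The genome is encoded in log2 space: lambda's range
#' spans 23 octaves and would be numerically invisible to linear-space
#' operators.
#'
#' @param c1,c2,lambda Length-2 `(lower, upper)` vectors.
#' @return Object of class `param_bounds` with a `log2` matrix attribute.
#' @export
param_bounds <- function(c1 = c(2^-3, 2^3), c2 = c(2^-3, 2^3),
                         lambda = c(2^-20, 2^3)) {
  b <- rbind(c1 = c1, c2 = c2, lambda = lambda)
  colnames(b) <- c("lower", "upper")
  if (any(b[, 1] >= b[, 2]))
    stop_afcsp("each lower bound must be below its upper bound",
               class = "afcsp_bad_config")
  if (any(b <= 0))
    stop_afcsp("bounds must be positive (log2 genome)",
               class = "afcsp_bad_config")
  structure(list(raw = b, log2 = log2(b)), class = "param_bounds")
}

#' NSGA-II configuration
#'
#' Defaults follow the standard presets: population 100, crossover rate
#' 0.9, mutation rate 0.1 (per gene), simulated binary crossover and
#' polynomial mutation with distribution indices 20.
#'
#' @param pop_size Even population size.
#' @param crossover_rate Probability a parent pair is crossed.
#' @param mutation_rate Per-gene polynomial mutation probability.
#' @param generations Number of generations.
#' @param eta_c,eta_m SBX / polynomial mutation distribution indices.
#' @param seed Integer seed for the GA stream.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 100L, crossover_rate = 0.9,
                      mutation_rate = 0.1, generations = 200L,
                      eta_c = 20, eta_m = 20, seed = 1L) {
  if (pop_size %% 2 != 0 || pop_size < 2)
    stop_afcsp("pop_size must be even and >= 2", class = "afcsp_bad_config")
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1)
    stop_afcsp("rates must lie in [0, 1]", class = "afcsp_bad_config")
  structure(list(pop_size = as.integer(pop_size),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 generations = as.integer(generations),
                 eta_c = eta_c, eta_m = eta_m, seed = as.integer(seed)),
            class = "ga_config")
}

#' Strict Pareto dominance (maximization)
#'
#' `a` dominates `b` when `a` is no worse on every objective and strictly
#' better on at least one.
#'
#' @param a,b Numeric objective vectors of equal length.
#' @return Logical.
#' @export
dominates <- function(a, b) all(a >= b) && any(a > b)

#' Fast non-dominated sorting
#'
#' Deb's O(M N^2) bookkeeping sort: front 1 is the maximal non-dominated
#' set; each later front is non-dominated once earlier fronts are removed.
#'
#' @param objectives Individuals x objectives matrix (maximization).
#' @return List: `fronts` (list of index vectors), `rank` (per individual).
#' @export
fast_nondominated_sort <- function(objectives) {
  n <- nrow(objectives)
  dom_count <- integer(n)
  dominated_by <- vector("list", n)
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      if (p == q) next
      if (dominates(objectives[p, ], objectives[q, ]))
        dominated_by[[p]] <- c(dominated_by[[p]], q)
      else if (dominates(objectives[q, ], objectives[p, ]))
        dom_count[p] <- dom_count[p] + 1L
    }
  }
  rank <- integer(n)
  fronts <- list()
  current <- which(dom_count == 0L)
  fi <- 1L
  while (length(current)) {
    fronts[[fi]] <- current
    rank[current] <- fi
    nxt <- integer(0)
    for (p in current) {
      for (q in dominated_by[[p]]) {
        dom_count[q] <- dom_count[q] - 1L
        if (dom_count[q] == 0L) nxt <- c(nxt, q)
      }
    }
    current <- nxt
    fi <- fi + 1L
  }
  list(fronts = fronts, rank = rank)
}

#' Crowding distance within one front
#'
#' Per objective, boundary members get `Inf`; interior members accumulate
#' the neighbor gap normalized by the objective's range (objectives with
#' zero range contribute nothing).
#'
#' @param objectives Members x objectives matrix for one front.
#' @return Numeric distances, `Inf` for boundary members.
#' @export
crowding_distance <- function(objectives) {
  n <- nrow(objectives)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (j in seq_len(ncol(objectives))) {
    o <- order(objectives[, j])
    rng <- objectives[o[n], j] - objectives[o[1], j]
    d[o[c(1, n)]] <- Inf
    if (rng > 0)
      for (i in 2:(n - 1))
        d[o[i]] <- d[o[i]] +
          (objectives[o[i + 1], j] - objectives[o[i - 1], j]) / rng
  }
  d
}

# Simulated binary crossover on one gene pair.
sbx_gene <- function(p1, p2, eta) {
  u <- stats::runif(1)
  beta <- if (u <= 0.5) (2 * u)^(1 / (eta + 1))
          else (1 / (2 * (1 - u)))^(1 / (eta + 1))
  c(0.5 * ((1 + beta) * p1 + (1 - beta) * p2),
    0.5 * ((1 - beta) * p1 + (1 + beta) * p2))
}

# Polynomial mutation on one gene.
poly_mutate_gene <- function(g, lower, upper, eta) {
  u <- stats::runif(1)
  delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1
           else 1 - (2 * (1 - u))^(1 / (eta + 1))
  g + delta * (upper - lower)
}

clip_genes <- function(g, lb) pmin(pmax(g, lb[, 1]), lb[, 2])

decode_genes <- function(genes) {
  v <- 2^genes
  names(v) <- c("c1", "c2", "lambda")
  v
}

#' Evaluate one genome: cross-validated per-class correct rates
#'
#' Decodes `(c1, c2, lambda)` from log2 gene space and runs
#' [cv_objectives()].
#'
#' @param genes Length-3 numeric vector in log2 space.
#' @param cvdata A [prepare_cv_features()] object.
#' @param kernel_kind `"rbf"` or `"linear"`.
#' @return Numeric vector `(CRF, CRE, CRA, CR)` in percent.
#' @export
evaluate_genes <- function(genes, cvdata, kernel_kind = "rbf") {
  p <- decode_genes(genes)
  kern <- if (kernel_kind == "rbf") kernel_spec("rbf", p[["lambda"]])
          else kernel_spec("linear")
  r <- cv_objectives(cvdata, p[["c1"]], p[["c2"]], kern)
  c(CRF = r$CRF, CRE = r$CRE, CRA = r$CRA, CR = r$CR)
}

# Binary tournament under the crowded-comparison operator.
tournament_pick <- function(rank, crowd) {
  cand <- sample.int(length(rank), 2)
  a <- cand[1]; b <- cand[2]
  if (rank[a] < rank[b]) a
  else if (rank[b] < rank[a]) b
  else if (crowd[a] >= crowd[b]) a else b
}

#' NSGA-II hyperparameter optimization of the one-vs-one twin SVM
#'
#' Elitist (mu + lambda) evolution over `(c1, c2, lambda)` in log2 space:
#' binary tournament selection on (rank, crowding), simulated binary
#' crossover, polynomial mutation with bound clipping, parents and
#' offspring pooled and truncated by non-dominated rank then crowding.
#' The three maximized objectives are the cross-validated per-class correct
#' rates (CRF, CRE, CRA); the total rate CR is tracked for model selection
#' but does not enter dominance.
#'
#' @param cvdata A [prepare_cv_features()] object (folds are fixed across
#'   all evaluations, so objective differences reflect parameters only).
#' @param config A [ga_config()].
#' @param bounds A [param_bounds()].
#' @param kernel_kind `"rbf"` (default) or `"linear"` (ignores lambda).
#' @return Object of class `nsga2_fit`: `front` (data frame of the final
#'   non-dominated set: c1, c2, lambda, CRF, CRE, CRA, CR), `best`
#'   (best-CR archive member, as a one-row data frame), `history`
#'   (non-decreasing best archived CR per generation, index 0 = initial
#'   population), `n_evaluations`, `config`, `bounds`, `kernel_kind`.
#' @export
nsga2_optimize <- function(cvdata, config = ga_config(),
                           bounds = param_bounds(), kernel_kind = "rbf") {
  lb <- bounds$log2
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  n <- config$pop_size
  genes <- sapply(seq_len(3), function(j) stats::runif(n, lb[j, 1], lb[j, 2]))
  objs <- t(apply(genes, 1, evaluate_genes, cvdata = cvdata,
                  kernel_kind = kernel_kind))
  n_eval <- n
  archive <- NULL
  update_archive <- function(g, o) {
    cand <- data.frame(t(decode_genes(g)), t(o))
    if (is.null(archive) || o[["CR"]] > archive$CR) archive <<- cand
  }
  for (i in seq_len(n)) update_archive(genes[i, ], objs[i, ])
  history <- archive$CR
  for (gen in seq_len(config$generations)) {
    fs <- fast_nondominated_sort(objs[, 1:3, drop = FALSE])
    crowd <- numeric(n)
    for (fr in fs$fronts)
      crowd[fr] <- crowding_distance(objs[fr, 1:3, drop = FALSE])
    # offspring
    kid_genes <- matrix(0, n, 3)
    i <- 1L
    while (i <= n) {
      p1 <- genes[tournament_pick(fs$rank, crowd), ]
      p2 <- genes[tournament_pick(fs$rank, crowd), ]
      ch <- rbind(p1, p2)
      if (stats::runif(1) < config$crossover_rate)
        for (j in 1:3) {
          g <- sbx_gene(p1[j], p2[j], config$eta_c)
          ch[1, j] <- g[1]; ch[2, j] <- g[2]
        }
      for (r in 1:2) for (j in 1:3)
        if (stats::runif(1) < config$mutation_rate)
          ch[r, j] <- poly_mutate_gene(ch[r, j], lb[j, 1], lb[j, 2],
                                       config$eta_m)
      ch <- t(apply(ch, 1, clip_genes, lb = lb))
      kid_genes[i, ] <- ch[1, ]
      if (i + 1L <= n) kid_genes[i + 1L, ] <- ch[2, ]
      i <- i + 2L
    }
    kid_objs <- t(apply(kid_genes, 1, evaluate_genes, cvdata = cvdata,
                        kernel_kind = kernel_kind))
    n_eval <- n_eval + n
    for (i in seq_len(n)) update_archive(kid_genes[i, ], kid_objs[i, ])
    # (mu + lambda) environmental selection
    all_genes <- rbind(genes, kid_genes)
    all_objs <- rbind(objs, kid_objs)
    fs2 <- fast_nondominated_sort(all_objs[, 1:3, drop = FALSE])
    keep <- integer(0)
    for (fr in fs2$fronts) {
      if (length(keep) + length(fr) <= n) {
        keep <- c(keep, fr)
      } else {
        cd <- crowding_distance(all_objs[fr, 1:3, drop = FALSE])
        keep <- c(keep, fr[order(cd, decreasing = TRUE)][
          seq_len(n - length(keep))])
        break
      }
    }
    genes <- all_genes[keep, , drop = FALSE]
    objs <- all_objs[keep, , drop = FALSE]
    history <- c(history, archive$CR)
  }
  fs <- fast_nondominated_sort(objs[, 1:3, drop = FALSE])
  fr1 <- fs$fronts[[1]]
  front <- data.frame(t(apply(genes[fr1, , drop = FALSE], 1, decode_genes)),
                      objs[fr1, , drop = FALSE])
  rownames(front) <- NULL
  structure(list(front = front, best = archive, history = history,
                 n_evaluations = n_eval, config = config, bounds = bounds,
                 kernel_kind = kernel_kind),
            class = "nsga2_fit")
}

#' @export
print.nsga2_fit <- function(x, ...) {
  cat(sprintf(paste0("NSGA-II fit (%s kernel): %d generations, pop %d, ",
                     "%d evaluations\n"),
              x$kernel_kind, x$config$generations, x$config$pop_size,
              x$n_evaluations))
  cat(sprintf("  Pareto front: %d members; best archived CR = %.2f%%\n",
              nrow(x$front), x$best$CR))
  cat(sprintf("  best parameters: c1 = %.4f, c2 = %.4f, lambda = %.4f\n",
              x$best$c1, x$best$c2, x$best$lambda))
  invisible(x)
}

#' @export
plot.nsga2_fit <- function(x, ...) {
  plot(seq_along(x$history) - 1, x$history, type = "s",
       xlab = "generation", ylab = "best archived CR (%)",
       main = "NSGA-II convergence", ...)
  invisible(x)
}

#' Select the reported model from a Pareto front
#'
#' Maximal total correct rate CR; ties broken by the larger minimum
#' per-class rate, then by the lowest row index.
#'
#' @param front Data frame with columns `CRF`, `CRE`, `CRA`, `CR` (as in
#'   `nsga2_fit$front`).
#' @return The selected row (one-row data frame).
#' @export
select_best <- function(front) {
  if (is.null(front) || nrow(front) == 0)
    stop_afcsp("empty Pareto front", class = "afcsp_bad_input")
  top <- which(front$CR == max(front$CR))
  if (length(top) > 1) {
    mins <- apply(front[top, c("CRF", "CRE", "CRA")], 1, min)
    top <- top[mins == max(mins)]
  }
  front[top[1], , drop = FALSE]
}

#' Random hyperparameter search baseline
#'
#' Uniform draws in log2 gene space under the same bounds and folds; the
#' comparison baseline for the optimizer.
#'
#' @param cvdata A [prepare_cv_features()] object.
#' @param n_draws Number of evaluations.
#' @param bounds A [param_bounds()].
#' @param kernel_kind Kernel kind.
#' @param seed Integer seed.
#' @return List: `best_CR`, `best` (one-row data frame), `draws`
#'   (data frame of all evaluations).
#' @export
random_search <- function(cvdata, n_draws, bounds = param_bounds(),
                          kernel_kind = "rbf", seed = 1L) {
  lb <- bounds$log2
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  genes <- sapply(seq_len(3), function(j)
    stats::runif(n_draws, lb[j, 1], lb[j, 2]))
  rows <- lapply(seq_len(n_draws), function(i) {
    o <- evaluate_genes(genes[i, ], cvdata, kernel_kind)
    data.frame(t(decode_genes(genes[i, ])), t(o))
  })
  draws <- do.call(rbind, rows)
  best <- draws[which.max(draws$CR), , drop = FALSE]
  list(best_CR = best$CR, best = best, draws = draws)
}
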