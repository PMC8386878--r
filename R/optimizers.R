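#' Optimize link selection for a spreader
#'
#' Selects up to `budget` nodes for the spreader to link to, by one of five
#' strategies:
#'
#' * `"glim"` — greedy influence maximization: at each iteration the spread
#'   \eqn{\sigma(S \cup \{v\})} is evaluated for every remaining candidate
#'   (by Monte-Carlo simulation or the exact path-sum oracle) and the argmax
#'   is linked, after which the target's incoming weights renormalize. Because
#'   \eqn{\sigma} is monotone and submodular, with exact evaluation this
#'   greedy achieves at least \eqn{(1 - 1/e) \approx 0.63} of the optimum.
#' * `"outdegree"` — link to the `budget` candidates of highest out-degree;
#'   the ranking is static since adding a link to a node does not change its
#'   out-degree.
#' * `"eigenvector"` — iteratively link to the candidate of highest right
#'   eigenvector centrality of the *current* extended graph, recomputing the
#'   centrality after every addition.
#' * `"random"` — uniform sample of candidates without replacement (baseline).
#' * `"brute"` — exhaustive search over all `budget`-subsets with the exact
#'   oracle (test oracle for the greedy guarantee; capped).
#'
#' Ties are always broken by smallest node identifier, so exact-evaluator
#' runs are fully deterministic. Monte-Carlo evaluation inside GLIM uses
#' common random numbers by default: within one iteration every candidate is
#' scored against the same threshold draws, which removes between-candidate
#' sampling noise from the comparison.
#'
#' @param x A `lim_graph`, edge data frame, or `lim_state` (whose spreader
#'   and already-selected links are then used as the starting point).
#' @param spreader Spreader node identifier (ignored if `x` is a state).
#' @param budget Maximum number of links to add (\eqn{k \ge 1}).
#' @param method One of `"glim"`, `"outdegree"`, `"eigenvector"`, `"random"`,
#'   `"brute"`.
#' @param evaluator `"mc"` (Monte-Carlo) or `"exact"` (path-sum oracle; small
#'   graphs only). For the heuristic methods the evaluator is only used to
#'   report the spread after each addition, never to choose.
#' @param replicates Monte-Carlo replicates per spread evaluation.
#' @param seed Integer root seed controlling all randomness.
#' @param link_weight Raw weight of every added link (default 1, giving new
#'   normalized weight \eqn{1/d^{\mathrm{in}}} on unit-weight graphs).
#' @param common_rn Use common random numbers across candidates within a GLIM
#'   iteration (default `TRUE`).
#' @param subset_cap For `method = "brute"`: refuse when the number of
#'   candidate subsets exceeds this (default 5000).
#' @return A `link_selection` object: the chosen nodes in order, a trace
#'   tibble (`step`, `node`, `spread`, `std_error`, `fraction`), and the
#'   final `lim_state`. `tidy()` returns the trace, `glance()` a one-row
#'   summary, `autoplot()` the spread-versus-budget curve.
#' @examples
#' g <- data.frame(source = c("1", "1", "2"), target = c("2", "3", "3"))
#' optimize_links(g, spreader = "1", budget = 1, method = "glim",
#'                evaluator = "exact")
#' @export
optimize_links <- function(x, spreader = NULL, budget = 1,
                           method = c("glim", "outdegree", "eigenvector",
                                      "random", "brute"),
                           evaluator = c("mc", "exact"), replicates = 1000,
                           seed = NULL, link_weight = 1, common_rn = TRUE,
                           subset_cap = 5000) {
  method <- match.arg(method)
  evaluator <- match.arg(evaluator)
  if (!is.numeric(budget) || budget < 1) abort("`budget` must be >= 1.")
  budget <- as.integer(budget)
  state <- as_lim_state(x, spreader)
  selector <- switch(method,
    glim = select_glim,
    outdegree = select_outdegree,
    eigenvector = select_eigenvector,
    random = select_random,
    brute = select_brute
  )
  res <- selector(state, budget, evaluator, replicates, seed, link_weight,
                  common_rn, subset_cap)
  n <- length(state$graph$nodes)
  trace <- tibble(
    step = seq_along(res$selected),
    node = res$selected,
    spread = res$spread,
    std_error = res$se,
    fraction = res$spread / n
  )
  structure(
    list(method = method, spreader = state$spreader, budget = budget,
         evaluator = evaluator, replicates = replicates, seed = seed,
         selected = res$selected, trace = trace, state = res$state),
    class = "link_selection"
  )
}

# Spread of `state` under the requested evaluator; returns c(mean, se).
eval_spread <- function(state, evaluator, replicates, seed) {
  if (evaluator == "exact") {
    c(exact_spread(state), 0)
  } else {
    est <- estimate_spread(state, replicates = replicates, seed = seed)
    c(est$mean_spread, est$std_error)
  }
}

select_glim <- function(state, budget, evaluator, replicates, seed,
                        link_weight, common_rn, ...) {
  nodes <- state$graph$nodes
  n <- length(nodes)
  selected <- character(0)
  spread <- se <- numeric(0)
  for (step in seq_len(budget)) {
    cands <- candidate_nodes(state)
    if (length(cands) == 0) break
    if (evaluator == "exact") {
      vals <- vapply(cands, function(v) {
        exact_spread(add_spreader_link(state, v, link_weight))
      }, numeric(1))
      ses <- rep(0, length(cands))
    } else {
      iter_seed <- derive_seed(seed, step)
      if (common_rn) {
        Theta <- threshold_matrix(n, replicates, iter_seed)
        scored <- lapply(cands, function(v) {
          st2 <- add_spreader_link(state, v, link_weight)
          Z <- lt_fixed_point(t(weight_matrix(st2)),
                              nodes == state$spreader, Theta)
          counts <- colSums(Z)
          c(mean(counts), sd(counts) / sqrt(length(counts)))
        })
      } else {
        scored <- lapply(seq_along(cands), function(i) {
          st2 <- add_spreader_link(state, cands[i], link_weight)
          est <- estimate_spread(st2, replicates = replicates,
                                 seed = derive_seed(iter_seed, i))
          c(est$mean_spread, est$std_error)
        })
      }
      vals <- vapply(scored, `[`, numeric(1), 1)
      ses <- vapply(scored, `[`, numeric(1), 2)
    }
    best <- node_min(cands[vals == max(vals)])
    state <- add_spreader_link(state, best, link_weight)
    selected <- c(selected, best)
    # the argmax of noisy estimates is upward-biased (winner's curse over
    # ~|candidates| draws), so the reported spread of the enlarged set is
    # re-estimated on an independent stream
    est <- eval_spread(state, evaluator, replicates,
                       derive_seed(seed, 50000 + step))
    spread <- c(spread, est[1])
    se <- c(se, est[2])
  }
  list(selected = selected, spread = spread, se = se, state = state)
}

# Report the spread after each prefix of a fixed ranking (for heuristics).
trace_ranking <- function(state, ranking, evaluator, replicates, seed,
                          link_weight) {
  spread <- se <- numeric(0)
  for (i in seq_along(ranking)) {
    state <- add_spreader_link(state, ranking[i], link_weight)
    est <- eval_spread(state, evaluator, replicates,
                       derive_seed(seed, 100000 + i))
    spread <- c(spread, est[1])
    se <- c(se, est[2])
  }
  list(selected = ranking, spread = spread, se = se, state = state)
}

out_degree <- function(graph) {
  deg <- table(factor(graph$edges$source, levels = graph$nodes))
  setNames(as.integer(deg), graph$nodes)
}

select_outdegree <- function(state, budget, evaluator, replicates, seed,
                             link_weight, ...) {
  cands <- candidate_nodes(state)
  deg <- out_degree(state$graph)[cands]
  # stable: candidates already in identifier order, so ties keep that order
  ranking <- cands[order(-deg)][seq_len(min(budget, length(cands)))]
  trace_ranking(state, ranking, evaluator, replicates, seed, link_weight)
}

# Right eigenvector centrality of the raw-weight adjacency of the extended
# graph: x <- A x by power iteration, so a node scores high when it points at
# high-scoring nodes (out-influence). Returns NULL on non-convergence.
right_eigen_centrality <- function(W, tol = 1e-10, max_iter = 1000) {
  n <- nrow(W)
  x <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    y <- drop(W %*% x)
    norm_y <- sqrt(sum(y^2))
    if (norm_y < .Machine$double.eps) return(NULL)
    y <- y / norm_y
    if (max(abs(y - x)) <= tol * max(abs(x))) return(y)
    x <- y
  }
  NULL
}

select_eigenvector <- function(state, budget, evaluator, replicates, seed,
                               link_weight, ...) {
  selected <- character(0)
  spread <- se <- numeric(0)
  for (step in seq_len(budget)) {
    cands <- candidate_nodes(state)
    if (length(cands) == 0) break
    W <- weight_matrix(state, normalized = FALSE)
    cen <- right_eigen_centrality(W)
    if (is.null(cen)) {
      warn("Eigenvector centrality did not converge; using out-degree ranking for this iteration.")
      cen <- out_degree(state$graph)
    } else {
      cen <- setNames(cen, state$graph$nodes)
    }
    sc <- cen[cands]
    best <- node_min(cands[sc >= max(sc) - 1e-12])
    state <- add_spreader_link(state, best, link_weight)
    selected <- c(selected, best)
    est <- eval_spread(state, evaluator, replicates,
                       derive_seed(seed, 100000 + step))
    spread <- c(spread, est[1])
    se <- c(se, est[2])
  }
  list(selected = selected, spread = spread, se = se, state = state)
}

select_random <- function(state, budget, evaluator, replicates, seed,
                          link_weight, ...) {
  cands <- candidate_nodes(state)
  k <- min(budget, length(cands))
  ranking <- with_rng(derive_seed(seed, 7), sample(cands, k))
  trace_ranking(state, ranking, evaluator, replicates, seed, link_weight)
}

select_brute <- function(state, budget, evaluator, replicates, seed,
                         link_weight, common_rn, subset_cap) {
  cands <- candidate_nodes(state)
  k <- min(budget, length(cands))
  n_subsets <- choose(length(cands), k)
  if (n_subsets > subset_cap) {
    abort(sprintf(
      "Brute-force search over %d subsets exceeds cap %d.",
      n_subsets, subset_cap
    ), class = "limnet_brute_cap")
  }
  subsets <- utils::combn(cands, k, simplify = FALSE)
  vals <- vapply(subsets, function(ss) {
    exact_spread(Reduce(function(st, v) add_spreader_link(st, v, link_weight),
                        ss, state))
  }, numeric(1))
  best_val <- max(vals)
  # lexicographically smallest maximizer under identifier order
  winners <- subsets[vals >= best_val - 1e-12]
  keys <- vapply(winners, function(ss) {
    paste(formatC(match(node_sort(ss), state$graph$nodes), width = 8,
                  flag = "0"), collapse = "")
  }, character(1))
  best_set <- node_sort(winners[[order(keys)[1]]])
  trace_ranking(state, best_set, "exact", replicates, seed, link_weight)
}

#' @export
print.link_selection <- function(x, ...) {
  cat(sprintf("<link_selection> method '%s', spreader '%s', %d link(s)\n",
              x$method, x$spreader, length(x$selected)))
  print(x$trace, n = 20)
  invisible(x)
}

#' @exportS3Method
tidy.link_selection <- function(x, ...) x$trace

#' @exportS3Method
glance.link_selection <- function(x, ...) {
  last <- nrow(x$trace)
  tibble(
    method = x$method, spreader = x$spreader, budget = x$budget,
    links = last,
    final_spread = if (last) x$trace$spread[last] else 1,
    final_fraction = if (last) x$trace$fraction[last] else
      1 / length(x$state$graph$nodes),
    evaluator = x$evaluator
  )
}

#' Classic influence maximization (seed selection) under the linear threshold
#' model
#'
#' The contrast problem to link-based optimization: choose `budget` *seed*
#' nodes that are activated with certainty at time 0 (no links are added and
#' no weights renormalize), maximizing expected spread by greedy marginal
#' gain. Provided to reproduce the qualitative difference between the two
#' problems: seed selection favours the most influential node even when that
#' node is itself heavily influenced, whereas link selection discounts
#' targets whose in-neighbourhood dilutes the new link.
#'
#' With `budget = 0` the seed set is empty and the spread is 0 by convention.
#' The exact evaluator uses the single-seed path-sum oracle and therefore
#' supports `budget = 1` only; Monte-Carlo evaluation supports any budget.
#'
#' @inheritParams optimize_links
#' @return A `seed_selection` object with `selected`, `trace` and the spread
#'   of the final seed set.
#' @export
optimize_seeds <- function(x, budget = 1, evaluator = c("mc", "exact"),
                           replicates = 1000, seed = NULL) {
  evaluator <- match.arg(evaluator)
  graph <- as_lim_graph(x)
  if (!is.numeric(budget) || budget < 0) abort("`budget` must be >= 0.")
  budget <- as.integer(budget)
  if (evaluator == "exact" && budget > 1) {
    abort("The exact evaluator supports budget 1 only; use evaluator = 'mc'.")
  }
  nodes <- graph$nodes
  n <- length(nodes)
  seeds <- character(0)
  spread <- numeric(0)
  for (step in seq_len(budget)) {
    cands <- node_sort(setdiff(nodes, seeds))
    if (length(cands) == 0) break
    vals <- vapply(cands, function(v) {
      imp_spread(graph, c(seeds, v), evaluator, replicates,
                 derive_seed(seed, step))
    }, numeric(1))
    best <- node_min(cands[vals == max(vals)])
    seeds <- c(seeds, best)
    spread <- c(spread, vals[match(best, cands)])
  }
  structure(
    list(method = "imp_greedy", budget = budget, evaluator = evaluator,
         selected = seeds,
         trace = tibble(step = seq_along(seeds), node = seeds,
                        spread = spread, fraction = spread / n),
         final_spread = if (length(spread)) spread[length(spread)] else 0),
    class = "seed_selection"
  )
}

imp_spread <- function(graph, seeds, evaluator, replicates, seed) {
  if (evaluator == "exact") {
    # single seed: expected spread is the path sum from that seed
    return(exact_spread(lim_state(graph, seeds[1])))
  }
  nodes <- graph$nodes
  st <- lim_state(graph, seeds[1])
  Wt <- t(weight_matrix(st))
  Theta <- threshold_matrix(length(nodes), replicates, seed)
  Z <- lt_fixed_point(Wt, nodes %in% seeds, Theta)
  mean(colSums(Z))
}

#' @export
print.seed_selection <- function(x, ...) {
  cat(sprintf("<seed_selection> %d seed(s): %s (final spread %.3f)\n",
              length(x$selected), paste(x$selected, collapse = ", "),
              x$final_spread))
  invisible(x)
}

#' @exportS3Method
tidy.seed_selection <- function(x, ...) x$trace
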