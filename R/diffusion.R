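#' Draw activation thresholds
#'
#' Each node draws an activation threshold \eqn{\theta(v) \in [0, 1]}
#' independently; the default (and the only distribution for which the exact
#' path-sum spread identity holds) is Uniform\[0, 1\]. Draws are reproducible
#' from `seed`.
#'
#' @param nodes Character vector of node identifiers (or a `lim_graph` /
#'   `lim_state`, whose node set is used).
#' @param seed Integer seed, or `NULL` to use the ambient RNG state.
#' @param dist A function `function(n)` returning `n` draws in \[0, 1\];
#'   defaults to [stats::runif()].
#' @return A tibble `node`, `theta`.
#' @export
draw_thresholds <- function(nodes, seed = NULL, dist = stats::runif) {
  if (inherits(nodes, "lim_state")) nodes <- nodes$graph$nodes
  if (inherits(nodes, "lim_graph")) nodes <- nodes$nodes
  nodes <- as.character(nodes)
  if (length(nodes) == 0) abort("`nodes` must be nonempty.")
  th <- with_rng(seed, dist(length(nodes)))
  if (any(th < 0 | th > 1)) abort("Thresholds must lie in [0, 1].")
  tibble(node = nodes, theta = as.numeric(th))
}

as_threshold_vector <- function(thresholds, nodes) {
  if (is.data.frame(thresholds)) {
    th <- setNames(thresholds$theta, thresholds$node)
  } else {
    th <- thresholds
  }
  if (!all(nodes %in% names(th))) {
    abort("`thresholds` must cover every node in the graph.")
  }
  unname(th[nodes])
}

# Synchronous linear-threshold fixed point for a batch of replicates.
# Wt: transposed normalized weight matrix (Wt[v, u] = w_n(u, v)), active0:
# logical start vector, Theta: n x R threshold matrix. Returns the final
# n x R activation indicator matrix. Each sweep evaluates every node against
# the previous indicator, so the process is deterministic given Theta.
lt_fixed_point <- function(Wt, active0, Theta) {
  n <- nrow(Wt)
  R <- ncol(Theta)
  Z <- matrix(active0, n, R)
  n_active <- colSums(Z)
  repeat {
    infl <- Wt %*% Z
    Z <- Z | (infl >= Theta)
    new_active <- colSums(Z)
    if (all(new_active == n_active)) break
    n_active <- new_active
  }
  Z
}

#' Run one linear threshold diffusion
#'
#' Deterministic synchronous fixed-point iteration: the spreader is active at
#' time 0; at each step every inactive node becomes active if the normalized
#' weights of its already-active in-neighbours sum to at least its threshold
#' (the comparison is inclusive, \eqn{\ge}). Stops as soon as an iteration
#' activates no new node.
#'
#' @param state A `lim_state` (or graph/edge table plus `spreader`).
#' @param thresholds A threshold assignment from [draw_thresholds()] (tibble
#'   `node`,`theta` or a named numeric vector covering every node).
#' @param spreader,selected Used to build a state when `state` is a graph.
#' @return An object of class `lim_diffusion` with fields `activated`
#'   (character vector), `activation_time` (tibble `node`, `time`; spreader at
#'   time 0) and `iterations` (the stopping time \eqn{t^*}).
#' @examples
#' g <- data.frame(source = c("s", "a"), target = c("a", "b"))
#' th <- tibble::tibble(node = c("s", "a", "b"), theta = 0.5)
#' simulate_diffusion(g, th, spreader = "s")
#' @export
simulate_diffusion <- function(state, thresholds, spreader = NULL,
                               selected = character(0)) {
  state <- as_lim_state(state, spreader, selected)
  nodes <- state$graph$nodes
  th <- as_threshold_vector(thresholds, nodes)
  Wt <- t(weight_matrix(state))
  n <- length(nodes)
  z <- nodes == state$spreader
  time <- rep(NA_integer_, n)
  time[z] <- 0L
  t_star <- 0L
  repeat {
    infl <- drop(Wt %*% z)
    z_new <- z | (infl >= th)
    if (all(z_new == z)) break
    t_star <- t_star + 1L
    time[z_new & !z] <- t_star
    z <- z_new
  }
  structure(
    list(
      activated = nodes[z],
      activation_time = tibble(node = nodes[z], time = time[z]),
      iterations = t_star
    ),
    class = "lim_diffusion"
  )
}

#' @export
print.lim_diffusion <- function(x, ...) {
  cat(sprintf("<lim_diffusion> %d node(s) activated in %d iteration(s)\n",
              length(x$activated), x$iterations))
  invisible(x)
}

#' @exportS3Method
tidy.lim_diffusion <- function(x, ...) x$activation_time

# n x R threshold matrix; column r is drawn from its own derived seed so any
# single replicate is reproducible in isolation.
threshold_matrix <- function(n, replicates, seed) {
  if (is.null(seed)) {
    return(matrix(runif(n * replicates), n, replicates))
  }
  vapply(seq_len(replicates), function(r) {
    with_rng(derive_seed(seed, r), runif(n))
  }, numeric(n))
}

# Mean/SE/fraction summary from a vector of per-replicate activation counts.
spread_from_counts <- function(counts, n_nodes) {
  m <- mean(counts)
  se <- if (length(counts) > 1) sd(counts) / sqrt(length(counts)) else 0
  structure(
    list(mean_spread = m, std_error = se, replicates = length(counts),
         as_fraction = m / n_nodes, n_nodes = n_nodes),
    class = "spread_estimate"
  )
}

#' Monte-Carlo spread estimate
#'
#' Estimates the spread \eqn{\sigma(S)} — the expected number of nodes active
#' at the diffusion fixed point, spreader included — by averaging independent
#' linear-threshold runs, each with fresh Uniform\[0, 1\] thresholds. With a
#' fixed seed the estimate is bit-reproducible, and replicate \eqn{r} uses its
#' own derived RNG stream.
#'
#' @inheritParams simulate_diffusion
#' @param replicates Number of Monte-Carlo runs (at least 1).
#' @param seed Integer root seed, or `NULL`.
#' @return A `spread_estimate`: `mean_spread`, `std_error`, `replicates`,
#'   `as_fraction` (mean divided by the total node count), `n_nodes`.
#' @examples
#' g <- data.frame(source = "s", target = c("a", "b"))
#' estimate_spread(g, spreader = "s", replicates = 100, seed = 1)
#' @export
estimate_spread <- function(state, spreader = NULL, selected = character(0),
                            replicates = 1000, seed = NULL) {
  state <- as_lim_state(state, spreader, selected)
  if (!is.numeric(replicates) || replicates < 1) {
    abort("`replicates` must be at least 1.")
  }
  replicates <- as.integer(replicates)
  nodes <- state$graph$nodes
  n <- length(nodes)
  Wt <- t(weight_matrix(state))
  Theta <- threshold_matrix(n, replicates, seed)
  Z <- lt_fixed_point(Wt, nodes == state$spreader, Theta)
  spread_from_counts(colSums(Z), n)
}

#' @export
print.spread_estimate <- function(x, ...) {
  cat(sprintf(
    "<spread_estimate> mean %.4f (se %.4f, %d replicates), fraction %.4f\n",
    x$mean_spread, x$std_error, x$replicates, x$as_fraction))
  invisible(x)
}

#' @exportS3Method
tidy.spread_estimate <- function(x, ...) {
  tibble(mean_spread = x$mean_spread, std_error = x$std_error,
         replicates = x$replicates, as_fraction = x$as_fraction,
         n_nodes = x$n_nodes)
}
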