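#' @name spread_oracle
#' @title Exact spread oracle on small graphs
#'
#' @description Under Uniform\[0, 1\] thresholds, the expected linear threshold
#' spread from a spreader \eqn{s} equals the sum, over all simple paths
#' starting at \eqn{s}, of the product of normalized edge weights along the
#' path (the empty path contributing 1, the spreader itself). Simple-path
#' enumeration is exponential — counting simple paths is #P-hard — so these
#' functions are an oracle for validation and brute-force optimization on
#' small graphs, guarded by a node-count cap. Inside the oracle the
#' spreader's in-edges are ignored: a simple path can never re-enter \eqn{s},
#' so such edges carry no influence from \eqn{s}, and dropping them realises
#' the convention \eqn{N^S_{\mathrm{in}}(s) = \emptyset} used by the
#' closed-form marginal gain.
NULL

ORACLE_NODE_CAP <- 20L

check_oracle_cap <- function(state, node_cap, max_len = NULL) {
  n <- length(state$graph$nodes)
  if (is.null(max_len) && n > node_cap) {
    abort(sprintf(
      "Oracle scope exceeded: %d nodes > cap %d. %s", n, node_cap,
      "Simple-path enumeration is exponential; use Monte-Carlo estimation."
    ), class = "limnet_oracle_cap")
  }
  invisible(TRUE)
}

# Normalized weight matrix of the extended graph with the spreader's in-edges
# removed (renormalizing the remaining columns is NOT done: the spreader's
# in-edges never contribute to any simple path from s, and other nodes'
# denominators do not involve edges into s).
oracle_matrix <- function(state) {
  Wn <- weight_matrix(state, normalized = TRUE)
  Wn[, state$spreader] <- 0
  Wn
}

out_neighbours <- function(W) {
  lapply(seq_len(nrow(W)), function(u) which(W[u, ] > 0))
}

#' Enumerate simple paths from the spreader
#'
#' Depth-first enumeration of every simple path starting at the spreader in
#' the extended graph, including the empty path (the spreader alone). Paths
#' never revisit a node and never re-enter the spreader.
#'
#' @inheritParams estimate_spread
#' @param max_len Optional maximum number of edges per path; when set, the
#'   node-count cap is not enforced.
#' @param node_cap Refuse graphs with more nodes than this unless `max_len`
#'   is given (default 20).
#' @return A list of character vectors, each a node sequence beginning with
#'   the spreader; the first element is the length-1 empty path.
#' @examples
#' g <- data.frame(source = c("s", "a"), target = c("a", "b"))
#' enumerate_simple_paths(lim_state(g, "s"))
#' @export
enumerate_simple_paths <- function(state, spreader = NULL,
                                   selected = character(0), max_len = NULL,
                                   node_cap = ORACLE_NODE_CAP) {
  state <- as_lim_state(state, spreader, selected)
  check_oracle_cap(state, node_cap, max_len)
  nodes <- state$graph$nodes
  W <- oracle_matrix(state)
  out <- out_neighbours(W)
  s_idx <- match(state$spreader, nodes)
  max_edges <- max_len %||% Inf
  paths <- list()
  visited <- logical(length(nodes))
  path <- integer(0)
  rec <- function(u, depth) {
    path[depth] <<- u
    paths[[length(paths) + 1L]] <<- nodes[path[seq_len(depth)]]
    if (depth - 1L >= max_edges) return(invisible())
    visited[u] <<- TRUE
    for (v in out[[u]]) {
      if (!visited[v]) rec(v, depth + 1L)
    }
    visited[u] <<- FALSE
  }
  rec(s_idx, 1L)
  paths
}

# Sum over simple paths from s_idx of the product of W entries along the path,
# including the empty path (term 1). `visited` marks blocked nodes.
path_sum <- function(W, out, s_idx, visited = logical(nrow(W))) {
  total <- 0
  rec <- function(u, prod) {
    total <<- total + prod
    visited[u] <<- TRUE
    for (v in out[[u]]) {
      if (!visited[v]) rec(v, prod * W[u, v])
    }
    visited[u] <<- FALSE
  }
  rec(s_idx, 1)
  total
}

#' Exact expected spread via the simple-path identity
#'
#' Computes \eqn{\sigma(S) = \sum_{\pi} \prod_{e \in \pi} w_n^S(e)} over all
#' simple paths \eqn{\pi} starting at the spreader in the extended graph —
#' the exact expected number of activated nodes under Uniform\[0, 1\]
#' thresholds (empty path = the spreader itself, so the value is always in
#' \eqn{[1, |V|]}).
#'
#' @inheritParams enumerate_simple_paths
#' @return A single number.
#' @examples
#' g <- data.frame(source = c("s", "a"), target = c("a", "b"))
#' exact_spread(g, spreader = "s")  # 3: both weights normalize to 1
#' @export
exact_spread <- function(state, spreader = NULL, selected = character(0),
                         node_cap = ORACLE_NODE_CAP) {
  state <- as_lim_state(state, spreader, selected)
  check_oracle_cap(state, node_cap)
  nodes <- state$graph$nodes
  W <- oracle_matrix(state)
  path_sum(W, out_neighbours(W), match(state$spreader, nodes))
}

#' Closed-form marginal gain of one additional link
#'
#' Evaluates the increase \eqn{\sigma(S \cup \{x\}) - \sigma(S)} without
#' recomputing either spread, as
#' \eqn{w_n^{S\cup\{x\}}(s, x) \sum_{\rho} (1 - I^S(\rho))\, U^S(\rho)},
#' where the sum runs over simple paths \eqn{\rho} out of \eqn{x} (including
#' the empty path), \eqn{U^S(\rho)} is the product of normalized weights
#' along \eqn{\rho}, and \eqn{I^S(\rho)} sums the weight products of all
#' simple paths from \eqn{s} ending at \eqn{x} that can be prepended to
#' \eqn{\rho}. Every term is nonnegative because \eqn{I^S(\rho) \le 1}, which
#' is how monotonicity of \eqn{\sigma} follows.
#'
#' @inheritParams enumerate_simple_paths
#' @param x Candidate node: in the graph, not the spreader, not already
#'   linked from it.
#' @param link_weight Raw weight of the prospective link (default 1).
#' @return A single nonnegative number, equal (to numerical precision) to
#'   `exact_spread` after the link minus `exact_spread` before it.
#' @export
marginal_gain <- function(state, x, spreader = NULL,
                          selected = character(0), link_weight = 1,
                          node_cap = ORACLE_NODE_CAP) {
  state <- as_lim_state(state, spreader, selected)
  check_oracle_cap(state, node_cap)
  x <- as.character(x)
  if (!x %in% candidate_nodes(state)) {
    abort(sprintf("'%s' is not a valid candidate for the spreader.", x))
  }
  nodes <- state$graph$nodes
  W <- oracle_matrix(state)
  out <- out_neighbours(W)
  s_idx <- match(state$spreader, nodes)
  x_idx <- match(x, nodes)

  # normalized weight the new link will carry: lw / (lw + raw in-weight of x)
  ee <- extended_edges(state)
  raw_in <- sum(ee$weight[ee$target == x & ee$source != state$spreader])
  w_new <- link_weight / (link_weight + raw_in)

  # DFS over paths rho out of x; for each rho accumulate (1 - I(rho)) U(rho).
  # I(rho): sum of weight products over simple paths s -> x avoiding rho's
  # interior nodes (paths end on first arrival at x).
  input_sum <- function(blocked) {
    total <- 0
    visited <- blocked
    visited[x_idx] <- FALSE
    rec <- function(u, prod) {
      visited[u] <<- TRUE
      for (v in out[[u]]) {
        if (v == x_idx) {
          total <<- total + prod * W[u, v]
        } else if (!visited[v]) {
          rec(v, prod * W[u, v])
        }
      }
      visited[u] <<- FALSE
    }
    if (s_idx == x_idx) return(0)
    rec(s_idx, 1)
    total
  }

  gain_sum <- 0
  on_rho <- logical(length(nodes))
  rec_rho <- function(u, prod_u) {
    on_rho[u] <<- TRUE
    i_rho <- input_sum(on_rho)
    gain_sum <<- gain_sum + (1 - i_rho) * prod_u
    for (v in out[[u]]) {
      if (!on_rho[v] && v != s_idx) rec_rho(v, prod_u * W[u, v])
    }
    on_rho[u] <<- FALSE
  }
  rec_rho(x_idx, 1)
  w_new * gain_sum
}
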