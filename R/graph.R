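#' Construct a weighted directed graph
#'
#' The base data structure of the package: a directed graph \eqn{G = (V, E, w)}
#' with a strictly positive weight on every edge. Weights model how strongly
#' one node influences another; only *relative* incoming influence matters for
#' diffusion, so they are normalized per target node (see
#' [normalize_incoming()]). Self-loops and duplicate ordered pairs are
#' rejected.
#'
#' @param edges A data frame with columns `source`, `target` and optionally
#'   `weight` (default 1). Node identifiers are coerced to character.
#' @param nodes Optional character vector of additional (possibly isolated)
#'   node identifiers.
#' @return An object of class `lim_graph` with fields `nodes` (sorted
#'   identifiers) and `edges` (a tibble `source`, `target`, `weight`).
#' @examples
#' g <- lim_graph(data.frame(source = c("s", "a"), target = c("a", "b")))
#' g
#' @export
lim_graph <- function(edges, nodes = NULL) {
  if (inherits(edges, "lim_graph")) return(edges)
  stopifnot(is.data.frame(edges))
  if (!all(c("source", "target") %in% names(edges))) {
    abort("`edges` must have columns `source` and `target`.")
  }
  edges <- as_tibble(edges)
  if (!"weight" %in% names(edges)) edges$weight <- 1
  edges <- edges[c("source", "target", "weight")]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$weight <- as.numeric(edges$weight)
  if (anyNA(edges)) abort("`edges` contains missing values.")
  if (any(edges$weight <= 0)) {
    abort(paste0(
      "All edge weights must be strictly positive: incoming weights are ",
      "normalized to sum to 1, which requires a nonzero denominator."
    ))
  }
  if (any(edges$source == edges$target)) {
    abort("Self-loops are not allowed.")
  }
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- edges[duplicated(key), , drop = FALSE]
    abort(sprintf(
      "Duplicate edge(s): %s.",
      paste0(dup$source, "->", dup$target, collapse = ", ")
    ))
  }
  all_nodes <- node_sort(unique(c(edges$source, edges$target,
                                  as.character(nodes %||% character(0)))))
  if (length(all_nodes) == 0) abort("Graph must contain at least one node.")
  ord <- order(match(edges$source, all_nodes), match(edges$target, all_nodes))
  structure(
    list(nodes = all_nodes, edges = edges[ord, , drop = FALSE]),
    class = "lim_graph"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.lim_graph <- function(x, ...) {
  cat(sprintf("<lim_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  print(x$edges, n = 6)
  invisible(x)
}

#' @export
format.lim_graph <- function(x, ...) {
  sprintf("<lim_graph> %d nodes, %d edges", length(x$nodes), nrow(x$edges))
}

as_lim_graph <- function(x) {
  if (inherits(x, "lim_graph")) x else lim_graph(x)
}

#' Create a link-selection state for a spreader
#'
#' A `lim_state` couples a base graph with a fixed spreader node \eqn{s} and an
#' ordered set \eqn{S} of link targets. The extended edge set is
#' \eqn{E^S = E \cup \{(s, v) : v \in S\}}; each added link carries a strictly
#' positive raw weight (default 1). The base graph is never modified: adding a
#' link returns a new state, which is what greedy lookahead requires.
#'
#' @param graph A `lim_graph` or an edge data frame.
#' @param spreader Node identifier of the spreader (seed) \eqn{s}.
#' @param selected Character vector of already-selected targets, in order.
#' @param link_weight Raw weight(s) for the added links (recycled).
#' @return An object of class `lim_state`.
#' @examples
#' g <- lim_graph(data.frame(source = "a", target = "b"))
#' st <- lim_state(g, spreader = "a")
#' candidate_nodes(st)
#' @export
lim_state <- function(graph, spreader, selected = character(0),
                      link_weight = 1) {
  graph <- as_lim_graph(graph)
  spreader <- as.character(spreader)
  if (!spreader %in% graph$nodes) {
    abort(sprintf("Unknown spreader node '%s'.", spreader))
  }
  selected <- as.character(selected)
  lw <- rep_len(as.numeric(link_weight), length(selected))
  st <- structure(
    list(graph = graph, spreader = spreader,
         selected = character(0), link_weights = numeric(0)),
    class = "lim_state"
  )
  for (i in seq_along(selected)) {
    st <- add_spreader_link(st, selected[i], lw[i])
  }
  st
}

#' @export
print.lim_state <- function(x, ...) {
  cat(sprintf("<lim_state> spreader '%s', %d selected link(s) of %d nodes\n",
              x$spreader, length(x$selected), length(x$graph$nodes)))
  if (length(x$selected)) {
    cat("  S =", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}

as_lim_state <- function(x, spreader = NULL, selected = character(0),
                         link_weight = 1) {
  if (inherits(x, "lim_state")) return(x)
  if (is.null(spreader)) abort("`spreader` must be supplied.")
  lim_state(x, spreader, selected, link_weight)
}

#' Extended edge table of a state
#'
#' Base edges plus the spreader links added so far (\eqn{E^S} with raw
#' weights \eqn{w^S}).
#'
#' @param state A `lim_state`.
#' @return A tibble `source`, `target`, `weight`.
#' @export
extended_edges <- function(state) {
  stopifnot(inherits(state, "lim_state"))
  out <- state$graph$edges
  if (length(state$selected)) {
    out <- bind_rows(out, tibble(
      source = state$spreader,
      target = state$selected,
      weight = state$link_weights
    ))
  }
  out
}

#' Normalize incoming influence weights
#'
#' For every edge \eqn{(u, v)}, divides its raw weight by the total raw weight
#' entering \eqn{v}, so that the incoming weights of any node with in-degree
#' at least 1 sum to exactly 1. This is the relative-influence view used by
#' the linear threshold model. Nodes with in-degree 0 contribute no rows.
#'
#' @param x A `lim_state`, `lim_graph`, or edge data frame.
#' @param ... Passed to [lim_state()] when `x` is not already a state
#'   (e.g. `spreader`).
#' @return A tibble `source`, `target`, `weight`, `weight_norm`.
#' @examples
#' g <- data.frame(source = c("a", "b"), target = c("v", "v"),
#'                 weight = c(2, 1))
#' normalize_incoming(lim_graph(g))
#' @export
normalize_incoming <- function(x, ...) {
  edges <- if (inherits(x, "lim_state")) {
    extended_edges(x)
  } else if (inherits(x, "lim_graph")) {
    x$edges
  } else if (is.data.frame(x)) {
    lim_graph(x)$edges
  } else {
    abort("`x` must be a lim_state, lim_graph or edge data frame.")
  }
  edges |>
    group_by(.data$target) |>
    mutate(weight_norm = .data$weight / sum(.data$weight)) |>
    ungroup()
}

#' Add a spreader link to a state
#'
#' Adds the edge \eqn{(s, v)} with raw weight `link_weight` and returns a new
#' state; the input state and the base graph are untouched. Because incoming
#' weights are renormalized, the relative influence of the target's other
#' in-neighbours shrinks by the factor
#' \eqn{\sum w / (w_{\mathrm{link}} + \sum w)}, where \eqn{\sum w} is the raw
#' incoming weight of the target before the link.
#'
#' @param state A `lim_state`.
#' @param target Node to link to; must be in the graph, differ from the
#'   spreader, and not already receive an edge from the spreader.
#' @param link_weight Strictly positive raw weight of the new link. The
#'   default 1 matches the unit-weight convention in which the new normalized
#'   weight is \eqn{1/d^{\mathrm{in}}}.
#' @return A new `lim_state`.
#' @export
add_spreader_link <- function(state, target, link_weight = 1) {
  stopifnot(inherits(state, "lim_state"))
  target <- as.character(target)
  link_weight <- as.numeric(link_weight)
  if (length(target) != 1) abort("`target` must be a single node.")
  if (!target %in% state$graph$nodes) {
    abort(sprintf("Unknown node '%s'.", target))
  }
  if (target == state$spreader) {
    abort("Cannot link the spreader to itself.")
  }
  if (!is.finite(link_weight) || link_weight <= 0) {
    abort("`link_weight` must be strictly positive.")
  }
  ee <- extended_edges(state)
  if (any(ee$source == state$spreader & ee$target == target)) {
    abort(sprintf("Edge from spreader to '%s' already exists.", target))
  }
  structure(
    list(
      graph = state$graph,
      spreader = state$spreader,
      selected = c(state$selected, target),
      link_weights = c(state$link_weights, link_weight)
    ),
    class = "lim_state"
  )
}

#' Candidate link targets
#'
#' Nodes the spreader can still link to: every node other than the spreader
#' that does not already receive an edge from it (in the extended edge set).
#' Returned in deterministic identifier order.
#'
#' @param state A `lim_state`.
#' @return Character vector of candidate node identifiers.
#' @export
candidate_nodes <- function(state) {
  stopifnot(inherits(state, "lim_state"))
  ee <- extended_edges(state)
  linked <- ee$target[ee$source == state$spreader]
  node_sort(setdiff(state$graph$nodes, c(state$spreader, linked)))
}

# Dense weight matrix of the extended graph; W[u, v] = weight of edge u -> v
# (normalized per column when normalized = TRUE). dimnames are node ids.
weight_matrix <- function(state, normalized = TRUE) {
  state <- if (inherits(state, "lim_state")) state else
    lim_state(as_lim_graph(state), as_lim_graph(state)$nodes[1])
  nodes <- state$graph$nodes
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ee <- extended_edges(state)
  W[cbind(match(ee$source, nodes), match(ee$target, nodes))] <- ee$weight
  if (normalized) {
    cs <- colSums(W)
    pos <- cs > 0
    W[, pos] <- sweep(W[, pos, drop = FALSE], 2, cs[pos], "/")
  }
  W
}

#' @exportS3Method
tidy.lim_graph <- function(x, ...) x$edges

#' @exportS3Method
tidy.lim_state <- function(x, ...) normalize_incoming(x)

#' @exportS3Method
glance.lim_graph <- function(x, ...) {
  tibble(nodes = length(x$nodes), edges = nrow(x$edges),
         mean_out_degree = nrow(x$edges) / length(x$nodes))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
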