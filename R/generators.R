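#' @name generators
#' @title Synthetic network generators
#'
#' @description Six generators spanning the structural range relevant to
#' small-network diffusion studies: three growing-network models producing
#' directed acyclic graphs of increasing connectivity (plain GN, GNR with
#' redirection probability `p`, GNC with copying), the random-k-out digraph
#' (every node gets exactly `k` out-edges; cycles allowed), and two
#' undirected models converted to bidirected digraphs (a power-law-degree
#' tree and the Barabasi-Albert preferential attachment network).
#'
#' All generators emit unit edge weights, label nodes `"0"` to `"n-1"` by
#' arrival order, and are reproducible from `seed`. The growing networks use
#' the citation convention: edges point newcomer to ancestor, so a node's
#' in-degree is its attachment count and the preferential kernel
#' (in-degree + 1) is well defined. Under this orientation the spreader
#' starts with no reach of its own in GN/GNR trees — all spread must be
#' bought through links, whose normalized weight is diluted by the target's
#' attachment popularity, which is exactly the trade-off the link-selection
#' problem studies.
NULL

new_generated_graph <- function(from, to, n) {
  nodes <- as.character(0:(n - 1))
  lim_graph(
    tibble(source = as.character(from), target = as.character(to), weight = 1),
    nodes = nodes
  )
}

# Grow a recursive tree: each newcomer i picks a parent among 0..i-1 with
# probability proportional to (in-degree + 1), where in-degree counts the
# attachments already received; with probability `redirect_p` the attachment
# is redirected to the picked node's own parent (the root redirects to
# itself). Returns the parent vector (0-based).
grow_tree <- function(n, redirect_p, seed) {
  with_rng(seed, {
    parent <- rep(NA_integer_, n)
    children <- rep(0L, n) # attachment counts
    redirects <- 0L
    for (i in seq_len(n - 1)) {
      w <- children[seq_len(i)] + 1
      j <- sample.int(i, 1, prob = w) - 1L # candidate parent, 0-based
      if (redirect_p > 0 && runif(1) < redirect_p) {
        redirects <- redirects + 1L
        if (!is.na(parent[j + 1])) j <- parent[j + 1]
      }
      parent[i + 1] <- j
      children[j + 1] <- children[j + 1] + 1L
    }
    attr(parent, "redirects") <- redirects
    parent
  })
}

#' @rdname generators
#' @param n Number of nodes (at least 2).
#' @param seed Integer seed.
#' @return A `lim_graph` with unit weights and nodes `"0"..."n-1"`.
#' @examples
#' generate_gn(10, seed = 1)
#' @export
generate_gn <- function(n, seed = NULL) {
  check_n(n)
  parent <- grow_tree(n, 0, seed)
  new_generated_graph(1:(n - 1), parent[-1], n)
}

#' @rdname generators
#' @param p Redirection probability in \[0, 1\] (default 0.3).
#' @export
generate_gnr <- function(n, p = 0.3, seed = NULL) {
  check_n(n)
  if (p < 0 || p > 1) abort("`p` must lie in [0, 1].")
  parent <- grow_tree(n, p, seed)
  new_generated_graph(1:(n - 1), parent[-1], n)
}

#' @rdname generators
#' @export
generate_gnc <- function(n, seed = NULL) {
  check_n(n)
  with_rng(seed, {
    # newcomer i points at a uniform target and at all of the target's own
    # attachment targets
    targets <- vector("list", n) # out-neighbourhoods, 0-based
    for (i in seq_len(n - 1)) {
      j <- sample.int(i, 1) - 1L
      targets[[i + 1]] <- unique(c(j, targets[[j + 1]]))
    }
    from <- rep(1:(n - 1), lengths(targets)[-1])
    to <- unlist(targets[-1])
    new_generated_graph(from, to, n)
  })
}

#' @rdname generators
#' @param k Out-degree of every node in the random-k-out graph
#'   (`1 <= k <= n - 1`).
#' @export
generate_random_k_out <- function(n, k = 5, seed = NULL) {
  check_n(n)
  if (k < 1 || k > n - 1) abort("`k` must lie in [1, n - 1].")
  with_rng(seed, {
    from <- rep(0:(n - 1), each = k)
    to <- unlist(lapply(0:(n - 1), function(i) {
      others <- (0:(n - 1))[-(i + 1)]
      others[sample.int(n - 1, k)]
    }))
    new_generated_graph(from, to, n)
  })
}

#' @rdname generators
#' @param exponent Power-law exponent of the tree degree distribution
#'   (default 3).
#' @export
generate_pl_tree <- function(n, exponent = 3, seed = NULL) {
  check_n(n)
  if (n == 2) {
    return(new_generated_graph(c(0, 1), c(1, 0), 2))
  }
  with_rng(seed, {
    # Degree sequence: iid rounded continuous power law (Pareto tail
    # x^{-exponent}, minimum 1), rejection-sampled until it is exactly
    # tree-feasible (sum 2(n-1)); conditioning keeps the tail undistorted.
    dmax <- n - 1
    target <- 2L * (n - 1L)
    deg <- NULL
    for (try in seq_len(2000)) {
      z <- pmin(round(runif(n)^(-1 / (exponent - 1))), dmax)
      if (sum(z) == target) {
        deg <- as.integer(z)
        break
      }
    }
    if (is.null(deg)) {
      # pathological parameters: fall back to minimal repair of the last draw
      deg <- as.integer(pmax(pmin(round(runif(n)^(-1 / (exponent - 1))),
                                  dmax), 1))
      while (sum(deg) > target) {
        i <- resample(which(deg > 1), 1)
        deg[i] <- deg[i] - 1L
      }
      while (sum(deg) < target) {
        i <- resample(which(deg < dmax), 1)
        deg[i] <- deg[i] + 1L
      }
    }
    # random labelled tree with this degree sequence via a Pruefer sequence:
    # node i appears deg[i] - 1 times, in random order
    prufer <- resample(rep.int(seq_len(n), deg - 1L))
    edges <- decode_prufer(prufer, n)
    bidirect(edges[, 1] - 1L, edges[, 2] - 1L, n)
  })
}

# Decode a Pruefer sequence (values in 1..n, length n-2) into the n-1 edges
# of the corresponding labelled tree.
decode_prufer <- function(prufer, n) {
  deg <- rep(1L, n)
  for (p in prufer) deg[p] <- deg[p] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (i in seq_along(prufer)) {
    leaf <- which.max(deg == 1L)
    edges[i, ] <- c(leaf, prufer[i])
    deg[leaf] <- 0L
    deg[prufer[i]] <- deg[prufer[i]] - 1L
  }
  edges[n - 1L, ] <- which(deg == 1L)
  edges
}

bidirect <- function(a, b, n) {
  new_generated_graph(c(a, b), c(b, a), n)
}

#' @rdname generators
#' @param m Number of edges each incoming node attaches with in the
#'   Barabasi-Albert model (default 5; must satisfy `m < n`).
#' @export
generate_ba_bidirected <- function(n, m = 5, seed = NULL) {
  check_n(n)
  if (m < 1 || m >= n) abort("`m` must satisfy 1 <= m < n.")
  g <- with_rng(seed, igraph::sample_pa(n, power = 1, m = m, directed = FALSE))
  el <- igraph::as_edgelist(g, names = FALSE)
  bidirect(el[, 1] - 1L, el[, 2] - 1L, n)
}

check_n <- function(n) {
  if (!is.numeric(n) || n < 2) abort("`n` must be at least 2.")
}

#' Generate a synthetic network by type name
#'
#' Dispatcher over the six generators, with the study's default parameters
#' (`p = 0.3`, random-out-degree `k = 5`, `m = 5`, power-law exponent 3).
#'
#' @param type One of `"gn"`, `"gnr"`, `"gnc"`, `"random_k_out"`,
#'   `"pl_tree"`, `"ba"`.
#' @param n Number of nodes.
#' @param seed Integer seed.
#' @param p,k,m,exponent Type-specific parameters (see [generators]).
#' @return A `lim_graph`.
#' @export
generate_network <- function(type = c("gn", "gnr", "gnc", "random_k_out",
                                      "pl_tree", "ba"),
                             n = 50, seed = NULL, p = 0.3, k = 5, m = 5,
                             exponent = 3) {
  type <- match.arg(type)
  switch(type,
    gn = generate_gn(n, seed),
    gnr = generate_gnr(n, p, seed),
    gnc = generate_gnc(n, seed),
    random_k_out = generate_random_k_out(n, k, seed),
    pl_tree = generate_pl_tree(n, exponent, seed),
    ba = generate_ba_bidirected(n, m, seed)
  )
}
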