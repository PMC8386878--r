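# Random unit-weight digraph on nodes "0".."n-1" with edge probability p and
# node "0" as the conventional spreader. Regenerates deterministically from
# `seed`.
random_digraph <- function(n, seed, p = 0.35) {
  withr::with_seed(seed, {
    nodes <- as.character(0:(n - 1))
    pairs <- expand.grid(source = nodes, target = nodes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    pairs <- pairs[stats::runif(nrow(pairs)) < p, ]
    lim_graph(pairs, nodes = nodes)
  })
}

# Independent reference implementation of one synchronous linear-threshold
# run, written over the tidy edge table with explicit loops (deliberately a
# different code path from the package's matrix fixed point). Returns the
# activated node set.
naive_lt_run <- function(graph, spreader, thresholds, selected = character(0)) {
  st <- lim_state(graph, spreader, selected)
  en <- normalize_incoming(st)
  theta <- stats::setNames(thresholds$theta, thresholds$node)
  nodes <- st$graph$nodes
  active <- spreader
  repeat {
    newly <- character(0)
    for (v in setdiff(nodes, active)) {
      w_in <- en$weight_norm[en$target == v & en$source %in% active]
      if (sum(w_in) >= theta[[v]]) newly <- c(newly, v)
    }
    if (length(newly) == 0) break
    active <- c(active, newly)
  }
  sort(active)
}

# Expected spread by plain Monte-Carlo over the naive simulator (independent
# oracle for the exact path-sum spread; slow, tiny n only).
naive_mc_spread <- function(graph, spreader, selected = character(0),
                            reps = 2000, seed = 1) {
  sizes <- vapply(seq_len(reps), function(r) {
    th <- draw_thresholds(lim_state(graph, spreader, selected),
                          seed = seed + r)
    length(naive_lt_run(graph, spreader, th, selected))
  }, numeric(1))
  c(mean = mean(sizes), se = stats::sd(sizes) / sqrt(reps))
}

# All-subset exact spread table for a small instance: named numeric vector,
# names are comma-joined sorted subsets ("(empty)" for the empty set).
subset_spread_table <- function(graph, spreader, candidates) {
  subsets <- unlist(lapply(0:length(candidates), function(k) {
    utils::combn(candidates, k, simplify = FALSE)
  }), recursive = FALSE)
  vals <- vapply(subsets, function(ss) {
    exact_spread(lim_state(graph, spreader, ss))
  }, numeric(1))
  stats::setNames(vals, vapply(subsets, subset_key, character(1)))
}

subset_key <- function(ss) {
  if (length(ss) == 0) "(empty)" else paste(sort(ss), collapse = ",")
}

subset_unkey <- function(key) {
  if (key == "(empty)") character(0) else strsplit(key, ",")[[1]]
}
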