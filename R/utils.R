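#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data
#' @importFrom dplyr arrange bind_rows group_by mutate summarise ungroup
#' @importFrom tibble tibble as_tibble
#' @importFrom stats runif sd setNames
NULL

# Deterministic ordering of node identifiers: numeric when every id looks like
# an integer, otherwise locale-independent radix sort. Ties throughout the
# package (argmax selection, ranking heuristics) are broken by this order.
node_sort <- function(ids) {
  ids <- as.character(ids)
  if (length(ids) == 0) return(character(0))
  if (all(grepl("^-?[0-9]+$", ids))) {
    ids[order(as.numeric(ids), method = "radix")]
  } else {
    ids[order(ids, method = "radix")]
  }
}

# First element of `ids` under node_sort ordering (tie-break helper).
node_min <- function(ids) node_sort(ids)[1]

# sample() that never falls into the 1:x convenience trap for length-1 input
resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

# Derive a child seed from a root seed and a stream counter. Keeps results
# below 2^31 so set.seed() accepts them; exact in double arithmetic.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  s <- (as.numeric(seed) %% 2147483647) * 69069 + as.numeric(stream) * 1234567
  as.integer(s %% 2147483629) + 1L
}

# Evaluate `expr` under a local RNG state seeded with `seed` (NULL = use the
# ambient RNG without touching it).
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
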