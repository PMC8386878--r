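test_that("incoming weights normalize to relative influence shares", {
  g <- lim_graph(data.frame(source = c("a", "b"), target = c("v", "v")))
  nw <- normalize_incoming(g)
  expect_equal(nw$weight_norm, c(0.5, 0.5))

  g1 <- lim_graph(data.frame(source = "a", target = "v"))
  expect_equal(normalize_incoming(g1)$weight_norm, 1.0)

  g2 <- lim_graph(data.frame(source = c("a", "b"), target = c("v", "v"),
                             weight = c(2, 1)))
  nw2 <- normalize_incoming(g2)
  expect_equal(nw2$weight_norm[nw2$source == "a"], 2 / 3)
  expect_equal(nw2$weight_norm[nw2$source == "b"], 1 / 3)
})

test_that("graph construction enforces the data-model invariants", {
  expect_error(lim_graph(data.frame(source = "a", target = "b", weight = 0)),
               "positive")
  expect_error(lim_graph(data.frame(source = "a", target = "b", weight = -1)),
               "positive")
  expect_error(lim_graph(data.frame(source = "a", target = "a")),
               "Self-loop")
  expect_error(
    lim_graph(data.frame(source = c("a", "a"), target = c("b", "b"))),
    "Duplicate")
  expect_error(lim_graph(data.frame(x = 1)), "source")
})

test_that("adding a spreader link dilutes the target's other in-edges", {
  # target with two unit-weight in-neighbours: 1/2 shares become 1/3
  g <- lim_graph(data.frame(source = c("a", "b"), target = c("v", "v")),
                 nodes = "s")
  st <- add_spreader_link(lim_state(g, "s"), "v")
  nw <- normalize_incoming(st)
  expect_equal(nw$weight_norm[nw$target == "v"], rep(1 / 3, 3))

  # target with no in-neighbours: the new link takes the whole share
  g2 <- lim_graph(data.frame(source = "a", target = "b"), nodes = "s")
  st2 <- add_spreader_link(lim_state(g2, "s"), "a")
  nw2 <- normalize_incoming(st2)
  expect_equal(nw2$weight_norm[nw2$target == "a"], 1.0)
})

test_that("link addition validates its preconditions", {
  g <- lim_graph(data.frame(source = "s", target = "a"), nodes = "b")
  st <- lim_state(g, "s")
  expect_error(add_spreader_link(st, "a"), "already exists")
  expect_error(add_spreader_link(st, "s"), "itself")
  expect_error(add_spreader_link(st, "zzz"), "Unknown")
  expect_error(add_spreader_link(st, "b", link_weight = 0), "positive")
  st2 <- add_spreader_link(st, "b")
  expect_error(add_spreader_link(st2, "b"), "already exists")
  # value semantics: the original state is untouched
  expect_identical(st$selected, character(0))
  expect_identical(nrow(st$graph$edges), 1L)
})

test_that("closed-form dilution factor matches fresh renormalization", {
  # adding (s, x) shrinks each prior share by sum_w / (lw + sum_w)
  for (seed in 1:100) {
    g <- random_digraph(sample(4:7, 1), seed = seed)
    st <- lim_state(g, "0")
    cands <- candidate_nodes(st)
    if (length(cands) == 0) next
    x <- cands[1]
    lw <- withr::with_seed(seed, stats::runif(1, 0.2, 3))
    before <- normalize_incoming(st)
    ee <- extended_edges(st)
    sum_w <- sum(ee$weight[ee$target == x])
    shrink <- sum_w / (lw + sum_w)
    after <- normalize_incoming(add_spreader_link(st, x, lw))
    old_rows <- before[before$target == x, ]
    for (i in seq_len(nrow(old_rows))) {
      got <- after$weight_norm[after$target == x &
                                after$source == old_rows$source[i]]
      expect_equal(got, old_rows$weight_norm[i] * shrink, tolerance = 1e-12)
    }
    expect_equal(after$weight_norm[after$target == x & after$source == "0"],
                 lw / (lw + sum_w), tolerance = 1e-12)
  }
})

test_that("normalized in-weights sum to one after any link sequence", {
  g <- random_digraph(7, seed = 11)
  st <- lim_state(g, "0")
  picks <- utils::head(candidate_nodes(st), 4)
  for (x in picks) {
    st <- add_spreader_link(
      st, x, withr::with_seed(100 + match(x, picks), stats::runif(1, 0.5, 2)))
    sums <- normalize_incoming(st) |>
      dplyr::group_by(target) |>
      dplyr::summarise(s = sum(weight_norm))
    expect_true(all(abs(sums$s - 1) < 1e-12))
  }
})

test_that("final weights do not depend on link insertion order", {
  g <- random_digraph(6, seed = 3)
  st <- lim_state(g, "0")
  picks <- candidate_nodes(st)[1:3]
  a <- normalize_incoming(lim_state(g, "0", picks))
  b <- normalize_incoming(lim_state(g, "0", rev(picks)))
  merged <- dplyr::inner_join(a, b, by = c("source", "target"))
  expect_equal(nrow(merged), nrow(a))
  expect_equal(merged$weight_norm.x, merged$weight_norm.y, tolerance = 1e-14)
})

test_that("candidate set excludes the spreader and already-linked nodes", {
  # spreader already points everywhere: nothing left
  g <- lim_graph(data.frame(source = "s", target = c("a", "b", "c")))
  expect_identical(candidate_nodes(lim_state(g, "s")), character(0))

  # isolated spreader in a 5-node graph: all four others
  g2 <- lim_graph(data.frame(source = c("1", "2"), target = c("2", "3")),
                  nodes = c("s", "4"))
  expect_identical(candidate_nodes(lim_state(g2, "s")),
                   c("1", "2", "3", "4"))

  # linked target drops out
  st <- add_spreader_link(lim_state(g2, "s"), "2")
  expect_identical(candidate_nodes(st), c("1", "3", "4"))
})

test_that("numeric-looking identifiers order numerically", {
  g <- lim_graph(data.frame(source = c("10", "2"), target = c("2", "10")),
                 nodes = "1")
  expect_identical(g$nodes, c("1", "2", "10"))
})
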