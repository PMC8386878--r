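#' Compare optimization strategies on a network type
#'
#' The experiment harness: for each of `realizations` freshly generated
#' networks (or repeated runs on a supplied graph), every requested method
#' selects links up to `budget` and the fraction of activated nodes after
#' each addition is recorded; curves are aggregated across realizations as
#' mean and standard deviation per step. The whole run is reproducible from
#' `seed`: realization \eqn{r} generates its network from a seed derived from
#' the root, and each method within a realization runs on its own derived
#' stream.
#'
#' @param type Generator type (see [generate_network()]), or `NULL` when
#'   `graph` is supplied.
#' @param graph Optional fixed `lim_graph`/edge data frame to use for every
#'   realization instead of generating.
#' @param methods Character vector of method names accepted by
#'   [optimize_links()].
#' @param n,p,k,m,exponent Generator parameters.
#' @param budget Number of links each method may add (default 15).
#' @param replicates Monte-Carlo replicates per spread evaluation
#'   (default 1000).
#' @param realizations Number of network realizations (default 10).
#' @param spreader Spreader rule: `"random"` (default; a node drawn
#'   uniformly per realization from a seeded stream, the practice for
#'   studies on generated networks), `"first"` (node `"0"` of generated
#'   networks), or an explicit node identifier.
#' @param seed Integer root seed.
#' @return A `lim_comparison`: `curves` (tibble `method`, `step`,
#'   `mean_fraction`, `sd_fraction`), `traces` (per-realization
#'   `link_selection` objects) and the configuration. `tidy()` returns the
#'   curves; `autoplot()` draws them.
#' @examples
#' cmp <- run_comparison("gn", n = 12, methods = c("glim", "random"),
#'                       budget = 2, replicates = 50, realizations = 2,
#'                       seed = 1)
#' tidy(cmp)
#' @export
run_comparison <- function(type = NULL, graph = NULL,
                           methods = c("glim", "eigenvector", "outdegree",
                                       "random"),
                           n = 50, budget = 15, replicates = 1000,
                           realizations = 10, spreader = "random", seed = NULL,
                           p = 0.3, k = 5, m = 5, exponent = 3) {
  if (is.null(type) && is.null(graph)) {
    abort("Supply either `type` or `graph`.")
  }
  known <- c("glim", "eigenvector", "outdegree", "random", "brute")
  if (!all(methods %in% known)) {
    abort(sprintf("Unknown method(s): %s.",
                  paste(setdiff(methods, known), collapse = ", ")))
  }
  traces <- list()
  rows <- list()
  for (r in seq_len(realizations)) {
    g <- if (is.null(graph)) {
      generate_network(type, n = n, seed = derive_seed(seed, 1000 + r),
                       p = p, k = k, m = m, exponent = exponent)
    } else {
      as_lim_graph(graph)
    }
    s <- pick_spreader(g, spreader, derive_seed(seed, 2000 + r))
    for (mi in seq_along(methods)) {
      sel <- optimize_links(
        g, spreader = s, budget = budget, method = methods[mi],
        replicates = replicates,
        seed = derive_seed(seed, 3000 + r * 100 + mi)
      )
      traces[[sprintf("%s_r%d", methods[mi], r)]] <- sel
      rows[[length(rows) + 1L]] <- mutate(
        sel$trace, method = methods[mi], realization = r)
    }
  }
  per_run <- bind_rows(rows)
  curves <- per_run |>
    group_by(.data$method, .data$step) |>
    summarise(mean_fraction = mean(.data$fraction),
              sd_fraction = if (dplyr::n() > 1) sd(.data$fraction) else 0,
              .groups = "drop") |>
    arrange(match(.data$method, methods), .data$step)
  structure(
    list(curves = curves, per_run = per_run, traces = traces,
         config = list(type = type, methods = methods, n = n, budget = budget,
                       replicates = replicates, realizations = realizations,
                       spreader = spreader, seed = seed,
                       p = p, k = k, m = m, exponent = exponent)),
    class = "lim_comparison"
  )
}

pick_spreader <- function(graph, spreader, seed) {
  if (identical(spreader, "first")) return(graph$nodes[1])
  if (identical(spreader, "random")) {
    return(with_rng(seed, resample(graph$nodes, 1)))
  }
  spreader <- as.character(spreader)
  if (!spreader %in% graph$nodes) {
    abort(sprintf("Spreader '%s' is not in the graph.", spreader))
  }
  spreader
}

#' @export
print.lim_comparison <- function(x, ...) {
  cat(sprintf(
    "<lim_comparison> %s: %d realization(s), budget %d, methods: %s\n",
    x$config$type %||% "user graph", x$config$realizations, x$config$budget,
    paste(x$config$methods, collapse = ", ")))
  print(x$curves |> group_by(.data$method) |>
          dplyr::slice_tail(n = 1) |> ungroup(), n = 10)
  invisible(x)
}

#' @exportS3Method
tidy.lim_comparison <- function(x, ...) x$curves

#' @exportS3Method
glance.lim_comparison <- function(x, ...) {
  x$curves |>
    group_by(.data$method) |>
    summarise(final_fraction = .data$mean_fraction[which.max(.data$step)],
              sd = .data$sd_fraction[which.max(.data$step)],
              .groups = "drop")
}

#' Export comparison curves
#'
#' Writes the aggregated curves as a tidy CSV (`method`, `step`,
#' `mean_fraction`, `sd_fraction`); output is byte-stable for fixed inputs.
#' Optionally also writes the curve plot.
#'
#' @param result A `lim_comparison`.
#' @param path Output CSV path.
#' @param plot_path Optional path for a PNG/PDF of `autoplot(result)`.
#' @return `path`, invisibly.
#' @export
export_curves <- function(result, path, plot_path = NULL) {
  stopifnot(inherits(result, "lim_comparison"))
  readr::write_csv(result$curves, path, progress = FALSE)
  if (!is.null(plot_path)) {
    ggplot2::ggsave(plot_path, autoplot(result), width = 6, height = 4,
                    dpi = 150)
  }
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method
autoplot.lim_comparison <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$step, y = .data$mean_fraction,
                               colour = .data$method)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_fraction - .data$sd_fraction,
                   ymax = .data$mean_fraction + .data$sd_fraction,
                   fill = .data$method),
      alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "links selected", y = "fraction of activated nodes",
                  colour = "method", fill = "method") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.link_selection <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$step, y = .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "links selected", y = "fraction of activated nodes",
                  title = sprintf("%s (spreader %s)", object$method,
                                  object$spreader)) +
    ggplot2::theme_minimal()
}

#' Curve plot shorthand
#'
#' @param result A `lim_comparison`.
#' @param ... Passed to `autoplot`.
#' @return A ggplot object.
#' @export
plot_comparison <- function(result, ...) autoplot(result, ...)
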