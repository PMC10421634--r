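#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a timescale fit
#'
#' @param x a `timescale_fit` from [fit_half_life()].
#' @param ... unused.
#' @return One row per parameter (`a`, `b`, `c`).
#' @export
tidy.timescale_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"),
                 estimate = c(x$a, x$b, x$c))
}

#' @rdname tidy.timescale_fit
#' @export
glance.timescale_fit <- function(x, ...) {
  tibble::tibble(half_life = x$half_life,
                 adj.r.squared = x$adj_r_squared,
                 degenerate = x$degenerate,
                 n = nrow(x$curve))
}

#' Tidy a module assignment
#'
#' @param x a `module_assignment` from [best_cut()].
#' @param ... unused.
#' @return A tibble with `posture` and `module` columns.
#' @export
tidy.module_assignment <- function(x, ...) {
  tibble::tibble(posture = names(x$membership),
                 module = unname(x$membership))
}

#' @rdname tidy.module_assignment
#' @export
glance.module_assignment <- function(x, ...) {
  tibble::tibble(n_modules = x$n_modules, modularity = x$Q,
                 cut_height = x$cut_height)
}

#' Tidy a shuffle-null distribution
#'
#' @param x a `null_distribution` from [shuffle_null()].
#' @param ... unused.
#' @return One row per permutation draw.
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$null), value = x$null)
}

#' @rdname tidy.null_distribution
#' @export
glance.null_distribution <- function(x, ...) {
  tibble::tibble(metric = x$metric, observed = x$observed,
                 null_mean = mean(x$null), null_sd = sd(x$null),
                 n = x$n, p.value = x$p_value)
}

#' Tidy a transition graph into an edge table
#'
#' @param x a `transition_graph`.
#' @param ... unused.
#' @return A tibble with `from`, `to`, `probability`, `count`.
#' @export
tidy.transition_graph <- function(x, ...) {
  df <- expand.grid(to = x$postures, from = x$postures,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$probability <- as.vector(x$M)
  df$count <- as.vector(x$counts)
  tibble::as_tibble(df[, c("from", "to", "probability", "count")])
}
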