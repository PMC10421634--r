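#' Modularity or stability curve across transition lags
#'
#' For each lag T, builds the lag-T transition graph and either (a)
#' `metric = "modularity"`: the modularity Q of the modularity-maximizing
#' dendrogram cut, or (b) `metric = "stability"`: the adjusted mutual
#' information between the best-cut partitions at lags T and T + 1.
#'
#' @param runs a `posture_runs` tibble (or list of them).
#' @param lags integer vector of lags (run units).
#' @param metric `"modularity"` or `"stability"`.
#' @param heights cut heights passed to [best_cut()].
#' @return A tibble of class `metric_curve` with columns `lag`, `value`;
#'   attribute `metric`.
#' @export
metric_curve <- function(runs, lags = 1:30,
                         metric = c("modularity", "stability"),
                         heights = seq(0.4, 1.4, length.out = 51)) {
  metric <- match.arg(metric)
  lags <- sort(unique(as.integer(lags)))
  need <- if (metric == "stability") sort(unique(c(lags, lags + 1L))) else lags
  parts <- new.env(parent = emptyenv())
  part_at <- function(T) {
    key <- as.character(T)
    if (!is.null(parts[[key]])) return(parts[[key]])
    g <- transition_matrix(runs, lag = T)
    bc <- suppressWarnings(best_cut(paris_dendrogram(g), g, heights = heights))
    parts[[key]] <- bc
    bc
  }
  vals <- vapply(lags, function(T) {
    if (metric == "modularity") part_at(T)$Q
    else ami(part_at(T), part_at(T + 1L))
  }, 0)
  out <- tibble::tibble(lag = lags, value = vals)
  attr(out, "metric") <- metric
  class(out) <- c("metric_curve", class(out))
  out
}

#' Exponential timescale fit of a metric curve
#'
#' Fits `M = a * exp(b * T) + c` by trust-region nonlinear least squares
#' with the decay rate constrained to `b < 0`, initialized from a
#' log-linear regression, and reports the half-life `H = -log(2) / b`
#' together with the adjusted R-squared. Flat curves are flagged degenerate
#' and get no half-life.
#'
#' @param curve a `metric_curve`, or any data frame with `lag` and `value`.
#' @return A list of class `timescale_fit`: `a`, `b`, `c`, `half_life`,
#'   `adj_r_squared`, `degenerate`, `fitted`, `curve`.
#' @export
fit_half_life <- function(curve) {
  lag <- curve$lag; value <- curve$value
  if (length(unique(lag)) < 4) stopf("need at least 4 distinct lags")
  if (sd(value) < 1e-12)
    return(structure(list(a = 0, b = NA_real_, c = mean(value),
                          half_life = NA_real_, adj_r_squared = NA_real_,
                          degenerate = TRUE, fitted = value, curve = curve),
                     class = "timescale_fit"))
  c0 <- min(value) - 1e-6
  y0 <- pmax(value - c0, 1e-12)
  ll <- lm(log(y0) ~ lag)
  b0 <- unname(min(max(stats::coef(ll)[2], -10), -1e-6))
  a0 <- unname(exp(stats::coef(ll)[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(value ~ a * exp(b * lag) + c,
                      start = list(a = a0, b = b0, c = c0),
                      lower = c(a = -Inf, b = -10, c = -Inf),
                      upper = c(a = Inf, b = -1e-6, c = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    obj <- function(p) sum((value - (p[1] * exp(p[2] * lag) + p[3]))^2)
    op <- stats::optim(c(a0, b0, c0), obj, method = "L-BFGS-B",
                       lower = c(-Inf, -10, -Inf), upper = c(Inf, -1e-6, Inf))
    co <- setNames(op$par, c("a", "b", "c"))
  } else co <- stats::coef(fit)
  pred <- co["a"] * exp(co["b"] * lag) + co["c"]
  ssr <- sum((value - pred)^2); sst <- sum((value - mean(value))^2)
  nn <- length(value); p <- 3
  adj <- 1 - (ssr / max(nn - p, 1)) / (sst / (nn - 1))
  degenerate <- abs(co["a"]) < 1e-10
  structure(list(a = unname(co["a"]), b = unname(co["b"]), c = unname(co["c"]),
                 half_life = if (degenerate) NA_real_ else unname(-log(2) / co["b"]),
                 adj_r_squared = unname(adj), degenerate = degenerate,
                 fitted = unname(pred), curve = tibble::tibble(lag = lag, value = value)),
            class = "timescale_fit")
}

#' @export
print.timescale_fit <- function(x, ...) {
  cat(sprintf("<timescale_fit: a=%.4g b=%.4g c=%.4g, half-life %s lags, adj R2 %.3f>\n",
              x$a, x$b, x$c,
              if (is.na(x$half_life)) "NA" else sprintf("%.3g", x$half_life),
              x$adj_r_squared))
  invisible(x)
}

#' Label-shuffle null distribution for graph organization metrics
#'
#' Shuffles posture labels, rebuilds the lag-T transition matrix, re-runs
#' the hierarchical clustering and recomputes the metric (modularity of the
#' best cut, or the Dasgupta score of the Paris tree), `n` times. By
#' default the shuffle permutes run-level labels, preserving run count and
#' label frequencies; `unit = "frames"` permutes frame labels instead and
#' re-compresses. The p-value uses the add-one permutation convention
#' `p = (1 + #{null >= observed}) / (1 + n)`.
#'
#' @param runs a `posture_runs` tibble.
#' @param metric `"modularity"` or `"dasgupta"`.
#' @param n number of shuffles (default 100).
#' @param lag transition lag.
#' @param unit `"runs"` or `"frames"`.
#' @param seed integer seed.
#' @param heights cut heights for [best_cut()].
#' @return A list of class `null_distribution`: `observed`, `null`
#'   (length-n numeric), `p_value`, `metric`, `n`.
#' @export
shuffle_null <- function(runs, metric = c("modularity", "dasgupta"),
                         n = 100, lag = 1, unit = c("runs", "frames"),
                         seed = NULL, heights = seq(0.4, 1.4, length.out = 51)) {
  metric <- match.arg(metric); unit <- match.arg(unit)
  if (n < 1) stopf("n must be >= 1")
  fps <- attr(runs, "fps") %||% 30
  eval_metric <- function(r) {
    g <- transition_matrix(r, lag = lag)
    d <- paris_dendrogram(g)
    if (metric == "modularity")
      suppressWarnings(best_cut(d, g, heights = heights))$Q
    else dasgupta_score(d, g)
  }
  observed <- eval_metric(runs)
  null <- local_seed(seed, vapply(seq_len(n), function(i) {
    r2 <- runs
    if (unit == "runs") {
      r2$posture <- sample(r2$posture)
    } else {
      fl <- rep(runs$posture, runs$length)
      r2 <- compress_runs(sample(fl), fps = fps)
    }
    eval_metric(r2)
  }, 0))
  structure(list(observed = observed, null = null,
                 p_value = (1 + sum(null >= observed)) / (1 + n),
                 metric = metric, n = n, lag = lag, unit = unit),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution: %s observed %.4f vs %d shuffles (mean %.4f), p = %.4g>\n",
              x$metric, x$observed, x$n, mean(x$null), x$p_value))
  invisible(x)
}

#' Compare behavioral organization across sessions
#'
#' Three comparison families over a table of per-session results:
#'
#' * `"anova"`: two-way type-II ANOVA (no interaction) of a per-session
#'   metric on the crossed `subject` and `task` factors. `data` needs
#'   columns `subject`, `task` and the metric named by `value`.
#' * `"paired_ami"`: AMI between the module assignments of all unique
#'   session pairs, each with a label-randomization p-value (shuffle one
#'   side's module labels, `n_permutations` times, add-one convention) and
#'   Benjamini-Hochberg correction across pairs. `data` needs `session`,
#'   `subject`, `task` and a list-column `modules` of named membership
#'   vectors (or `module_assignment` objects).
#' * `"partialled_ttest"`: from the pairwise AMI table, compares
#'   within-subject against between-subject pairs after subtracting the
#'   mean AMI of each task-pair group (and the symmetric task comparison
#'   partialling out subject pairing), with unpaired t-tests.
#'
#' @param data a tibble; see above per comparison.
#' @param comparison one of `"anova"`, `"paired_ami"`, `"partialled_ttest"`.
#' @param value for `"anova"`: name of the metric column.
#' @param n_permutations shuffles per pair for `"paired_ami"`.
#' @param seed integer seed for the permutation draws.
#' @return A tibble of results (test statistics and p-values); for
#'   `"paired_ami"` one row per session pair.
#' @export
compare_sessions <- function(data,
                             comparison = c("anova", "paired_ami", "partialled_ttest"),
                             value = "value", n_permutations = 100, seed = NULL) {
  comparison <- match.arg(comparison)
  switch(comparison,
         anova = session_anova(data, value),
         paired_ami = session_pairwise_ami(data, n_permutations, seed),
         partialled_ttest = session_partialled_ttest(data, n_permutations, seed))
}

session_anova <- function(data, value) {
  stopifnot(all(c("subject", "task") %in% names(data)), value %in% names(data))
  data$subject <- factor(data$subject); data$task <- factor(data$task)
  if (nlevels(data$subject) < 2 || nlevels(data$task) < 2)
    stopf("two-way ANOVA needs at least 2 levels per factor")
  tab <- table(data$subject, data$task)
  if (any(tab == 0)) stopf("ANOVA design has empty subject x task cells")
  fit <- lm(stats::reformulate(c("subject", "task"), response = value), data = data)
  an <- car::Anova(fit, type = 2)
  tibble::tibble(term = rownames(an),
                 sumsq = an[["Sum Sq"]], df = an[["Df"]],
                 statistic = an[["F value"]], p.value = an[["Pr(>F)"]]) |>
    dplyr::filter(.data$term != "Residuals")
}

session_pairwise_ami <- function(data, n_permutations = 100, seed = NULL) {
  stopifnot(all(c("session", "subject", "task", "modules") %in% names(data)))
  memb <- lapply(data$modules, function(m)
    if (inherits(m, "module_assignment")) m$membership else m)
  ns <- nrow(data)
  rows <- list()
  local_seed(seed, {
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
      if (j <= i) next
      obs <- ami(memb[[i]], memb[[j]])
      null <- vapply(seq_len(n_permutations), function(k) {
        shuf <- memb[[j]]
        perm <- sample(unname(shuf))
        names(perm) <- names(shuf)
        ami(memb[[i]], perm)
      }, 0)
      tk <- sort(c(data$task[i], data$task[j]))
      rows[[length(rows) + 1]] <- tibble::tibble(
        session_a = data$session[i], session_b = data$session[j],
        subject_pair = if (data$subject[i] == data$subject[j]) "within" else "between",
        task_a = tk[1], task_b = tk[2],
        task_pair = paste(tk, collapse = "|"),
        ami = obs,
        p.value = (1 + sum(null >= obs)) / (1 + n_permutations))
    }
  })
  out <- dplyr::bind_rows(rows)
  out$p.adj <- p.adjust(out$p.value, method = "BH")
  out
}

session_partialled_ttest <- function(data, n_permutations = 100, seed = NULL) {
  pairs <- if (all(c("ami", "subject_pair", "task_pair") %in% names(data))) data
  else session_pairwise_ami(data, n_permutations, seed)
  res <- list()
  # subject effect, task partialled out
  x <- dplyr::mutate(dplyr::group_by(pairs, .data$task_pair),
                     adj = .data$ami - mean(.data$ami))
  x <- dplyr::ungroup(x)
  if (length(unique(x$subject_pair)) == 2 &&
      all(table(x$subject_pair) >= 2)) {
    tt <- t.test(adj ~ subject_pair, data = x)
    res$subject <- tibble::tibble(
      comparison = "within_vs_between_subject", partialled = "task",
      estimate = diff(rev(tt$estimate)), statistic = unname(tt$statistic),
      df = unname(tt$parameter), p.value = tt$p.value)
  }
  # task effect, subject pairing partialled out (same-task pairs only)
  y <- dplyr::mutate(dplyr::group_by(pairs, .data$subject_pair),
                     adj = .data$ami - mean(.data$ami))
  y <- dplyr::ungroup(y)
  y <- dplyr::filter(y, .data$task_a == .data$task_b)
  if (length(unique(y$task_pair)) == 2 && all(table(y$task_pair) >= 2)) {
    tt <- t.test(adj ~ task_pair, data = y)
    res$task <- tibble::tibble(
      comparison = paste(levels(factor(y$task_pair)), collapse = "_vs_"),
      partialled = "subject",
      estimate = diff(rev(tt$estimate)), statistic = unname(tt$statistic),
      df = unname(tt$parameter), p.value = tt$p.value)
  }
  dplyr::bind_rows(res)
}
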