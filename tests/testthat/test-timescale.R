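test_that("half-life is exact on noiseless exponentials and scale-free in a", {
  lags <- 1:200
  curve <- tibble::tibble(lag = lags, value = 1 * exp(-log(2) / 30 * lags) + 0.05)
  fit <- fit_half_life(curve)
  expect_equal(fit$half_life, 30, tolerance = 1e-6)
  expect_equal(fit$a, 1, tolerance = 1e-6)
  expect_equal(fit$c, 0.05, tolerance = 1e-6)
  expect_gt(fit$adj_r_squared, 0.999999)
  # doubling the amplitude leaves the half-life unchanged
  curve2 <- dplyr::mutate(curve, value = 2 * exp(-log(2) / 30 * lag) + 0.05)
  expect_equal(fit_half_life(curve2)$half_life, 30, tolerance = 1e-6)
})

test_that("half-life recovery tolerates noise across planted decay rates", {
  set.seed(1)
  for (H in c(10, 30, 100)) {
    errs <- replicate(60, {
      lags <- 1:200
      v <- exp(-log(2) / H * lags) + 0.05 + rnorm(200, sd = 0.01)
      abs(fit_half_life(tibble::tibble(lag = lags, value = v))$half_life - H) / H
    })
    expect_lte(median(errs), 0.10)
  }
})

test_that("flat curves are flagged degenerate with no half-life", {
  flat <- tibble::tibble(lag = 1:20, value = rep(0.3, 20))
  fit <- fit_half_life(flat)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$half_life))
  expect_error(fit_half_life(tibble::tibble(lag = 1:3, value = 1:3)),
               "4 distinct lags")
  gl <- glance(fit)
  expect_true(gl$degenerate)
})

test_that("modularity curves decay with lag for planted chains", {
  rep <- behavior_repertoire(n_postures = 8, n_modules = 2,
                             within_module_prob = 0.85, seed = 2)
  lab <- generate_markov_labels(rep, 60000, seed = 3)
  runs <- compress_runs(lab$labels)
  mc <- metric_curve(runs, lags = c(1:10, seq(15, 60, by = 5)))
  expect_true(all(is.finite(mc$value)))
  expect_lt(cor(mc$lag, mc$value, method = "spearman"), 0)
  fit <- fit_half_life(mc)
  expect_lt(fit$b, 0)
  # stability mode: partitions are consistent across adjacent small lags
  st <- metric_curve(runs, lags = 1:3, metric = "stability")
  expect_gt(mean(st$value), 0.8)
})

test_that("iid label sequences produce modularity inside the null band", {
  set.seed(4)
  fl <- sample(8, 3000, replace = TRUE)
  runs <- compress_runs(fl)
  nd <- shuffle_null(runs, "modularity", n = 100, seed = 5)
  expect_gt(nd$p_value, 0.05)
  band <- range(nd$null)
  expect_gte(nd$observed, band[1] - 0.02)
  expect_lte(nd$observed, band[2] + 0.02)
})

test_that("shuffle nulls are deterministic given a seed and detect structure", {
  rep <- behavior_repertoire(seed = 6)
  lab <- generate_markov_labels(rep, 40000, seed = 7)
  runs <- compress_runs(lab$labels)
  n1 <- shuffle_null(runs, "modularity", n = 30, seed = 8)
  n2 <- shuffle_null(runs, "modularity", n = 30, seed = 8)
  expect_identical(n1$null, n2$null)
  expect_equal(n1$p_value, 1 / 31)
  nd <- shuffle_null(runs, "dasgupta", n = 30, seed = 9)
  expect_equal(nd$p_value, 1 / 31)
  nf <- shuffle_null(runs, "modularity", n = 10, unit = "frames", seed = 10)
  expect_equal(nf$p_value, 1 / 11)
  expect_error(shuffle_null(runs, "modularity", n = 0), "n must be")
})

test_that("two-way ANOVA on session metrics reports both factors", {
  set.seed(14)
  df <- tidyr::expand_grid(subject = c("a", "b"), task = c("t1", "t2", "t3"),
                           rep = 1:3)
  df$value <- 0.5 + 0.2 * (df$subject == "b") + rnorm(nrow(df), sd = 0.02)
  out <- compare_sessions(df, "anova")
  expect_setequal(out$term, c("subject", "task"))
  expect_lt(out$p.value[out$term == "subject"], 0.001)
  expect_gt(out$p.value[out$term == "task"], 0.05)
  expect_error(compare_sessions(df[df$subject == "a", ], "anova"), "2 levels")
})

test_that("pairwise session AMI separates shared from distinct repertoires", {
  m1 <- setNames(rep(1:3, each = 4), paste0("p", 1:12))
  m2 <- m1; m2[1] <- 2L                     # nearly identical
  m3 <- setNames(rep(1:3, times = 4), paste0("p", 1:12))  # scrambled
  data <- tibble::tibble(
    session = c("s1", "s2", "s3", "s4"),
    subject = c("a", "a", "b", "b"),
    task = c("t1", "t2", "t1", "t2"),
    modules = list(m1, m2, m1, m3))
  out <- compare_sessions(data, "paired_ami", n_permutations = 50, seed = 12)
  expect_equal(nrow(out), 6)
  expect_equal(out$ami[out$session_a == "s1" & out$session_b == "s3"], 1)
  expect_true(all(out$p.adj >= out$p.value - 1e-12))
  d13 <- out[out$session_a == "s1" & out$session_b == "s3", ]
  expect_lt(d13$p.value, 0.05)
  tt <- compare_sessions(out, "partialled_ttest")
  expect_true(all(c("statistic", "p.value") %in% names(tt)))
})

test_that("subject-specific repertoires drive the individual factor", {
  # power check at planted effect size: two subjects with different
  # repertoires, tasks identical in distribution
  set.seed(13)
  hits <- 0
  for (r in 1:10) {
    sessions <- list()
    for (s in c("a", "b")) {
      rep_s <- behavior_repertoire(n_postures = 10, n_modules = 3,
                                   within_module_prob = if (s == "a") 0.92 else 0.7,
                                   seed = 100 + r + as.integer(s == "b"))
      for (tk in c("t1", "t2")) for (k in 1:2) {
        lab <- generate_markov_labels(rep_s, 12000,
                                      seed = 1000 * r + k + 7 * (tk == "t2") +
                                        13 * (s == "b"))
        g <- transition_matrix(compress_runs(lab$labels), lag = 1)
        bc <- suppressWarnings(best_cut(paris_dendrogram(g), g))
        sessions[[length(sessions) + 1]] <-
          tibble::tibble(subject = s, task = tk, value = bc$Q)
      }
    }
    out <- compare_sessions(dplyr::bind_rows(sessions), "anova")
    if (out$p.value[out$term == "subject"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
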