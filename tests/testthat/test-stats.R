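# Paired inference: test gate, signed-rank internals, FDR, comparison maps.

test_that("identical conditions give the degenerate unit p-value", {
  r <- paired_compare(rep(1:6, 3), rep(1:6, 3))
  expect_equal(r$test_used, "degenerate")
  expect_equal(r$p_value, 1)
  expect_equal(r$statistic, 0)
})

test_that("the normality gate picks t for normal and wilcoxon for heavy tails", {
  set.seed(15)
  picks_t <- replicate(200, {
    d <- rnorm(18, 0.5, 1)
    paired_compare(rep(0, 18), d)$test_used
  })
  expect_gt(mean(picks_t == "paired_t"), 0.9)
  picks_w <- replicate(200, {
    d <- rcauchy(18) + 0.5
    paired_compare(rep(0, 18), d)$test_used
  })
  expect_gt(mean(picks_w == "wilcoxon"), 0.5)
})

test_that("descriptives follow the chosen test's format", {
  set.seed(16)
  a <- rnorm(18); b <- a + rnorm(18, 0.5)
  r <- paired_compare(a, b, gate = FALSE)
  expect_equal(r$descriptives$format, "mean_sd")
  heavy <- rcauchy(18)
  r2 <- paired_compare(rep(0, 18), heavy * 10 + 0.2)
  if (r2$test_used == "wilcoxon") {
    expect_equal(r2$descriptives$format, "median_q1q3")
  }
  expect_error(paired_compare(1:2, 2:3), "n >= 3")
  expect_error(paired_compare(c(1, NA, 3), c(1, 2, 3)), "NA")
})

test_that("one-tailed test targets the fatigue > comfort direction", {
  set.seed(17)
  a <- rnorm(18)
  b <- a + 0.8
  r1 <- paired_compare(a, b, tail = "one", gate = FALSE)
  r2 <- paired_compare(b, a, tail = "one", gate = FALSE)
  expect_lt(r1$p_value, 0.05)
  expect_gt(r2$p_value, 0.5)
})

test_that("signed-rank agrees with stats::wilcox.test when zeros/ties absent", {
  set.seed(18)
  for (i in 1:5) {
    d <- round(rnorm(8, 0.3), 3)
    d <- d[d != 0]
    if (anyDuplicated(abs(d))) next
    ours <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  # large-sample normal approximation tracks wilcox.test's
  d <- rnorm(30, 0.4)
  ours <- wilcoxon_signed_rank(d)
  ref <- stats::wilcox.test(d, exact = FALSE, correct = FALSE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 0.02)
  expect_error(wilcoxon_signed_rank(rep(0, 5)), "all differences zero")
})

test_that("Benjamini-Hochberg matches the hand-applied step-up rule", {
  res <- fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(res$adjusted, rep(0.04, 4))
  expect_true(all(res$reject))
  expect_false(any(fdr_adjust(rep(1, 5))$reject))
  expect_equal(fdr_adjust(0.03)$adjusted, 0.03)
  expect_error(fdr_adjust(numeric(0)), "empty")
  expect_error(fdr_adjust(c(0.5, 1.2)), "outside")
  # monotone in raw p and order-invariant
  set.seed(19)
  p <- runif(40)
  adj <- fdr_adjust(p)$adjusted
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
  perm <- sample(40)
  expect_equal(fdr_adjust(p[perm])$adjusted, adj[perm])
})

test_that("compare_edges finds nothing under identical data and the right
           direction under effect", {
  sims <- simulate_plv_study(0.8, n_participants = 6, n_epochs = 10,
                             n_samples = 100, n_channels = 8, seed = 20)
  same <- compare_edges(sims$comfort, sims$comfort)
  expect_equal(same$summary$n_significant, 0)
  eff <- simulate_plv_study(0.9, 0.5, n_participants = 12, n_epochs = 20,
                            n_samples = 200, n_channels = 8, seed = 21)
  em <- compare_edges(eff$comfort, eff$fatigue)
  expect_gt(mean(em$edges$significant), 0.5)
  sig <- em$edges[em$edges$significant, ]
  expect_true(all(sig$fatigue_mean > sig$comfort_mean))
  expect_equal(nrow(em$edges), choose(8, 2))
  expect_error(compare_edges(eff$comfort[1:3], eff$fatigue), "aligned")
})

test_that("threshold-grid table has the contracted shape and star codes", {
  sims <- simulate_plv_study(0.62, 0.5, n_participants = 6, n_epochs = 10,
                             n_samples = 150, n_channels = 10, seed = 22)
  grid <- c(0.6, 0.7)
  tabs <- list()
  for (cond in c("comfort", "fatigue")) {
    for (p in seq_along(sims[[cond]])) {
      pm <- sims[[cond]][[p]]
      pm$band <- "alpha"
      for (Ti in grid) {
        tabs[[length(tabs) + 1]] <-
          metrics_for_graph(build_graph(pm, threshold = Ti, montage = NULL))
      }
    }
  }
  tt <- compare_global_across_thresholds(tabs, grid = grid)
  expect_equal(nrow(tt), length(grid) * 4 * 1)
  expect_setequal(unique(tt$metric), c("bc", "ne", "cc", "cpl"))
  expect_true(all(tt$stars %in% c("", "*", "**", "***")))
  expect_true(all(tt$stars[tt$p < 0.001] == "***"))
  expect_error(compare_global_across_thresholds(tabs, grid = c(0.6, 0.65)),
               "missing metric table")
})

test_that("node difference maps cover all channels with region roll-up", {
  sims <- simulate_plv_study(0.75, 0.6, n_participants = 6, n_epochs = 10,
                             n_samples = 150,
                             labels = default_montage()$label, seed = 23)
  tabs <- list()
  for (cond in c("comfort", "fatigue")) {
    for (p in seq_along(sims[[cond]])) {
      pm <- sims[[cond]][[p]]
      pm$band <- "alpha"
      tabs[[length(tabs) + 1]] <-
        metrics_for_graph(build_graph(pm, threshold = 0.6))
    }
  }
  nm <- node_difference_map(tabs, "ne", "alpha", 0.6)
  expect_equal(nrow(nm$channels), 24)
  expect_setequal(nm$regions$region,
                  c("frontal", "temporal", "central", "parietal",
                    "occipital"))
  expect_equal(sum(nm$regions$n_channels), 24)
  # fatigue (lower jitter) should raise nodal efficiency everywhere
  expect_true(all(nm$channels$diff > 0))
  # identical conditions: all differences zero
  comfort_tabs <- Filter(function(mt) mt$condition == "comfort", tabs)
  mirrored <- lapply(comfort_tabs, function(mt) {
    mt$condition <- "fatigue"
    mt
  })
  nm0 <- node_difference_map(c(comfort_tabs, mirrored), "ne", "alpha", 0.6)
  expect_true(all(abs(nm0$channels$diff) < 1e-15))
})
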