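test_that("singlet gating retains singlets and rejects doublets", {
  pure <- simulate_flow_events(20000, 0.3, seed = 1, doublet_fraction = 0)
  g <- gate_singlets(pure)
  expect_gte(nrow(g) / nrow(pure), 0.99)
  mixed <- simulate_flow_events(20000, 0.3, seed = 2,
                                doublet_fraction = 0.1)
  gm <- gate_singlets(mixed)
  doublet_retention <- sum(gm$true_doublet) / sum(mixed$true_doublet)
  expect_lt(doublet_retention, 0.05)
})

test_that("singlet gating is idempotent", {
  ev <- simulate_flow_events(10000, 0.3, seed = 3)
  once <- gate_singlets(ev)
  twice <- gate_singlets(once)
  expect_identical(as.data.frame(once), as.data.frame(twice))
})

test_that("percent positive matches the gate quantile on the control itself", {
  ctl <- gate_singlets(simulate_flow_events(50000, 0, seed = 4,
                                            condition = "uninfected"))
  r <- percent_positive(ctl, ctl, gate_quantile = 0.999)
  expect_lt(abs(r$percent_positive - 0.1), 0.05)
})

test_that("an uninfected (raltegravir-like) condition reads near zero", {
  rtg <- gate_singlets(simulate_flow_events(30000, 0, seed = 5,
                                            condition = "RTG"))
  ctl <- gate_singlets(simulate_flow_events(30000, 0, seed = 6,
                                            condition = "uninfected"))
  r <- percent_positive(rtg, ctl)
  expect_lte(r$percent_positive, 0.2)
})

test_that("percent positive recovers a 70% infected fraction within 1 point", {
  pcts <- vapply(1:20, function(s) {
    ev <- gate_singlets(simulate_flow_events(20000, 0.70, separation = 4,
                                             seed = 100 + s))
    ctl <- gate_singlets(simulate_flow_events(20000, 0, separation = 4,
                                              seed = 200 + s,
                                              condition = "uninfected"))
    percent_positive(ev, ctl)$percent_positive
  }, 0)
  expect_lt(abs(mean(pcts) - 70), 1)
})

test_that("percent positive is non-increasing in the gate quantile", {
  ev <- gate_singlets(simulate_flow_events(20000, 0.5, seed = 7))
  ctl <- gate_singlets(simulate_flow_events(20000, 0, seed = 8,
                                            condition = "uninfected"))
  p <- vapply(c(0.9, 0.99, 0.999, 0.9999), function(q)
    percent_positive(ev, ctl, gate_quantile = q)$percent_positive, 0)
  expect_true(all(diff(p) <= 0))
})

test_that("Kruskal-Wallis H matches hand-ranked and degenerate cases", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0)
  expect_equal(kruskal_wallis(list(c(5, 5, 5), c(5, 5)))$p_value, 1)
  # ranks 1..3 vs 4..6: H = 12/(6*7) * (3*(2-3.5)^2 + 3*(5-3.5)^2) = 3.857
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 3.857, tolerance = 1e-3)
})

test_that("chi-square p agrees with the exhaustive permutation oracle", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(4.8, 6.3, 7.0, 5.9)
  kw <- kruskal_wallis(list(x, y))
  pool <- c(x, y)
  combos <- utils::combn(8, 4)
  hs <- vapply(seq_len(ncol(combos)), function(i) {
    a <- pool[combos[, i]]
    kruskal_wallis(list(a, pool[-combos[, i]]))$H
  }, 0)
  p_perm <- mean(hs >= kw$H - 1e-12)
  expect_lt(abs(kw$p_value - p_perm), 0.05)
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(9)
  g <- list(rnorm(12), rnorm(12, 1), rnorm(12, 2))
  expect_equal(kruskal_wallis(g)$H,
               kruskal_wallis(lapply(g, exp))$H, tolerance = 1e-12)
})

test_that("Dunn comparisons flag only the shifted group", {
  expect_equal(dunn_test(list(a = c(1, 2, 3), b = c(1, 2, 3)))$pairwise$z, 0)
  expect_equal(dunn_test(list(a = c(1, 2, 3), b = c(1, 2, 3)))$pairwise$p_adj, 1)
  set.seed(10)
  g <- list(a = rnorm(15), b = rnorm(15), c = rnorm(15) + 10)
  d <- dunn_test(g)$pairwise
  sig <- d$p_adj < 0.05
  expect_equal(sig[d$group1 == "a" & d$group2 == "b"], FALSE)
  expect_true(all(sig[d$group2 == "c"]))
})

test_that("adjusted p never drops below raw p", {
  for (s in 1:20) {
    set.seed(s)
    g <- list(rnorm(8), rnorm(8, 0.5), rnorm(8, 1))
    d <- dunn_test(g)$pairwise
    expect_true(all(d$p_adj >= d$p_raw - 1e-12))
  }
  expect_error(dunn_test(list(a = 1:3, b = numeric(0))), "non-empty")
})

test_that("equally infected conditions are rarely called different", {
  # five-condition design, two replicates each: the three labeled-IN
  # conditions share a true infected fraction; Dunn comparisons among them
  # should be non-significant in >= 90% of simulations
  n_sig <- 0
  for (s in 1:100) {
    pcts <- lapply(1:3, function(cnd) vapply(1:2, function(rep) {
      ev <- gate_singlets(simulate_flow_events(
        2000, 0.7, seed = s * 100 + cnd * 10 + rep))
      ctl <- gate_singlets(simulate_flow_events(
        2000, 0, seed = s * 100 + cnd * 10 + rep + 5000,
        condition = "uninfected"))
      percent_positive(ev, ctl)$percent_positive
    }, 0))
    d <- dunn_test(pcts)$pairwise
    if (any(d$p_adj < 0.05)) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 10)
})

test_that("luciferase normalization is linear and flags missing p24", {
  conds <- data.frame(condition = c("A", "B", "RTG", "uninfected"),
                      rlu_per_p24 = c(2000, 500, 0, 0),
                      p24_ng = c(10, 10, 10, 1))
  tab <- simulate_rlu_table(conds, seed = 11, n_replicates = 6)
  p24 <- data.frame(condition = c("A", "B", "RTG"),
                    p24_ng = c(10, 10, 10))
  norm <- rlu_normalize(tab, p24, background_condition = "uninfected")
  # equal p24: normalization preserves ordering
  expect_gt(norm$mean_rlu_per_p24[norm$condition == "A"],
            norm$mean_rlu_per_p24[norm$condition == "B"])
  # halving p24 doubles the normalized value
  p24_half <- p24; p24_half$p24_ng[1] <- 5
  norm2 <- rlu_normalize(tab, p24_half, background_condition = "uninfected")
  expect_equal(norm2$mean_rlu_per_p24[norm2$condition == "A"],
               2 * norm$mean_rlu_per_p24[norm$condition == "A"])
  # raltegravir-like condition sits within noise of background
  bg_sd <- sd(tab$rlu[tab$condition == "uninfected"])
  expect_lte(abs(norm$mean_rlu_per_p24[norm$condition == "RTG"]) * 10,
             2 * max(bg_sd, 1))
  expect_error(rlu_normalize(tab, p24[1:2, ],
                             background_condition = "uninfected"),
               "missing p24")
})
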