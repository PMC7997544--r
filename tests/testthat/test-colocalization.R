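rand_points <- function(n, w = 10, h = 10)
  data.frame(x_um = runif(n, 0, w), y_um = runif(n, 0, h))

test_that("identical point sets are fully colocalized at distance zero", {
  set.seed(1)
  ref <- rand_points(50)
  pr <- pair_to_reference(ref, ref, threshold_um = 0.5)
  expect_equal(nrow(pr$pairs), 50)
  expect_true(all(pr$pairs$distance_um == 0))
  expect_equal(colocalized_fraction(pr)$fraction, 1)
})

test_that("a 1 um shift abolishes colocalization at the 0.5 um rule", {
  # points on a 3 um lattice: after a 1 um shift no query point can lie
  # within 0.5 um of any reference
  g <- expand.grid(x_um = seq(1, 28, 3), y_um = seq(1, 28, 3))
  ref <- data.frame(x_um = g$x_um, y_um = g$y_um)
  q <- ref; q$x_um <- q$x_um + 1
  pr <- pair_to_reference(ref, q, threshold_um = 0.5)
  expect_equal(nrow(pr$pairs), 0)
  expect_equal(colocalized_fraction(pr)$fraction, 0)
})

test_that("ties at exactly the threshold are excluded (strict inequality)", {
  ref <- data.frame(x_um = 5, y_um = 5)
  q <- data.frame(x_um = 5.5, y_um = 5)
  expect_equal(nrow(pair_to_reference(ref, q, 0.5)$pairs), 0)
  expect_equal(nrow(pair_to_reference(ref, q, 0.5 + 1e-9)$pairs), 1)
})

test_that("grid pairing equals the exhaustive O(n^2) oracle over 50 seeds", {
  for (s in 1:50) {
    set.seed(s)
    ref <- rand_points(200)
    q <- rand_points(200)
    got <- pair_to_reference(ref, q, 0.5, edge_exclude = FALSE)$pairs
    want <- exhaustive_pairs(ref, q, 0.5)
    got <- got[order(got$ref_id), ]
    expect_equal(got$ref_id, want$ref_id)
    expect_equal(got$query_id, want$query_id)
    expect_equal(got$distance_um, want$distance_um, tolerance = 1e-12)
  }
})

test_that("pairing is invariant to row order in either table", {
  set.seed(3)
  ref <- rand_points(80); q <- rand_points(80)
  base <- pair_to_reference(ref, q, 0.5, edge_exclude = FALSE)$pairs
  perm_q <- sample(nrow(q))
  pr2 <- pair_to_reference(ref, q[perm_q, ], 0.5, edge_exclude = FALSE)$pairs
  # map permuted query ids back
  pr2$query_id <- perm_q[pr2$query_id]
  expect_equal(pr2[order(pr2$ref_id), c("ref_id", "query_id")],
               base[order(base$ref_id), c("ref_id", "query_id")],
               ignore_attr = TRUE)
})

test_that("fraction is non-decreasing in the distance threshold", {
  set.seed(4)
  ref <- rand_points(100); q <- rand_points(100)
  fr <- vapply(c(0.1, 0.25, 0.5, 1, 2), function(th)
    colocalized_fraction(pair_to_reference(ref, q, th,
                                           edge_exclude = FALSE))$fraction,
    0)
  expect_true(all(diff(fr) >= 0))
})

test_that("degenerate tables are handled per contract", {
  ref <- rand_points(10)
  expect_error(pair_to_reference(ref[0, ], ref, 0.5), "empty reference")
  pr <- pair_to_reference(ref, ref[0, ], 0.5)
  expect_equal(nrow(pr$pairs), 0)
})

test_that("one-to-one mode never reuses a query detection", {
  ref <- data.frame(x_um = c(5, 5.1), y_um = c(5, 5))
  q <- data.frame(x_um = 5.04, y_um = 5)
  many <- pair_to_reference(ref, q, 0.5)
  one <- pair_to_reference(ref, q, 0.5, mode = "one_to_one")
  expect_equal(nrow(many$pairs), 2)
  expect_equal(nrow(one$pairs), 1)
  expect_equal(one$pairs$ref_id, 1)  # closer reference wins
})

test_that("edge exclusion removes border references from the denominator", {
  ref <- data.frame(x_um = c(0.1, 5), y_um = c(0.1, 5))
  q <- data.frame(x_um = 5, y_um = 5.2)
  pr <- pair_to_reference(ref, q, 0.5, field_bounds = c(10, 10))
  expect_equal(pr$n_reference, 1)
  expect_equal(pr$n_excluded_edge, 1)
})

test_that("chance colocalization matches the Poisson void-probability form", {
  set.seed(5)
  bounds <- c(50, 50)
  lam <- 0.4
  ref <- data.frame(x_um = runif(300, 0, 50), y_um = runif(300, 0, 50))
  q <- data.frame(x_um = runif(lam * 2500, 0, 50),
                  y_um = runif(lam * 2500, 0, 50))
  cc <- chance_colocalization(ref, q, bounds, n_shuffles = 60, seed = 6)
  closed <- 1 - exp(-lam * pi * 0.5^2)
  se <- sd(cc$null_fractions) / sqrt(length(cc$null_fractions))
  expect_lt(abs(cc$null_mean - closed), 3 * max(se, 0.004))
  # vanishing query density gives a vanishing null
  cc0 <- chance_colocalization(ref, q[0, ], bounds, n_shuffles = 5,
                               seed = 7)
  expect_equal(cc0$null_mean, 0)
})

test_that("a truly colocalized field exceeds the null's 97.5th percentile", {
  set.seed(8)
  ref <- rand_points(200, 30, 30)
  q <- ref
  q$x_um <- q$x_um + rnorm(200, 0, 0.05)
  q$y_um <- q$y_um + rnorm(200, 0, 0.05)
  obs <- colocalized_fraction(
    pair_to_reference(ref, q, 0.5, edge_exclude = FALSE))$fraction
  cc <- chance_colocalization(ref, q, c(30, 30), n_shuffles = 100,
                              seed = 9)
  expect_gt(obs, cc$null_q975)
})

test_that("pairing estimator recovers the dual-label fraction", {
  # detection-free: synthetic detections at known efficiency and 0.02 um
  # localization noise; measured fraction ~ truth x query efficiency
  eff <- 0.97
  for (truth_frac in c(0.25, 0.5, 0.75, 0.95)) {
    set.seed(round(1000 * truth_frac))
    n <- 2000
    pos <- rand_points(n, 300, 300)  # VOG-like sub-confluent density
    dual <- runif(n) < truth_frac
    ref_det <- pos[runif(n) < eff, ]
    qpos <- pos[dual, ]
    q_det <- qpos[runif(nrow(qpos)) < eff, ]
    q_det$x_um <- q_det$x_um + rnorm(nrow(q_det), 0, 0.02)
    q_det$y_um <- q_det$y_um + rnorm(nrow(q_det), 0, 0.02)
    fr <- colocalized_fraction(
      pair_to_reference(ref_det, q_det, 0.5, field_bounds = c(300, 300)))
    expect_lt(abs(fr$fraction - truth_frac * eff), 0.03)
  }
})

test_that("intensity summaries report unit ratio for identical tables", {
  set.seed(10)
  masses <- data.frame(channel = "red", x_um = runif(50), y_um = runif(50),
                       mass = rlnorm(50, log(2000), 0.25), size_um = 0.15,
                       ecc = 0.02, raw_peak = 100)
  tab <- structure(masses, class = c("detection_table", "data.frame"))
  s <- intensity_summary(list(a = tab, b = tab), n_boot = 200, seed = 1)
  expect_equal(s$ratios$ratio, 1)
  expect_equal(s$summary$median_mass[1], s$summary$median_mass[2])
})

test_that("bootstrap interval covers the true 20-fold median ratio", {
  # 50 replicate simulations of two constructs at 20:1 median stoichiometry
  cover <- 0
  for (s in 1:50) {
    set.seed(s)
    a <- rlnorm(120, log(4000), 0.25)
    b <- rlnorm(120, log(200), 0.25)
    mk <- function(m) structure(
      data.frame(channel = "x", x_um = 0, y_um = 0, mass = m,
                 size_um = 0.15, ecc = 0, raw_peak = 1),
      class = c("detection_table", "data.frame"))
    r <- intensity_summary(list(gag = mk(a), pol = mk(b)), n_boot = 300,
                           seed = s)$ratios
    if (r$ci_lo <= 20 && 20 <= r$ci_hi) cover <- cover + 1
  }
  expect_gte(cover, 45)  # >= 90% coverage
})
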