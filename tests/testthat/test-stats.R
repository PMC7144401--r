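test_that("Kruskal-Wallis matches the hand rank-sum formula", {
  # identical groups: no location difference at all
  same <- data.frame(y = rep(c(1, 2, 3), 4),
                     g = rep(c("a", "b", "c", "d"), each = 3))
  res0 <- kruskal_wallis(same, y, g)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # {1,2,3} vs {4,5,6}: ranks 1..6, R1 = 6, R2 = 15 ->
  # H = 12/(6*7) * (36/3 + 225/3) - 3*7 = 27/7
  res <- kruskal_wallis(data.frame(y = 1:6,
                                   g = rep(c("a", "b"), each = 3)), y, g)
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-10)
  expect_error(kruskal_wallis(data.frame(y = 1:5, g = "a"), y, g),
               "two non-empty groups")
})

test_that("Kruskal-Wallis p-values are uniform under label permutation", {
  set.seed(31)
  y <- rnorm(24)
  g <- rep(c("a", "b", "c"), each = 8)
  p <- vapply(1:400, function(i) {
    kruskal_wallis(data.frame(y = y, g = sample(g)), y, g)$p_value
  }, 0)
  # discrete rank-test p-values tie; the KS approximation is still adequate
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("Spearman correlation handles monotone and reversed pairs", {
  d <- data.frame(x = 1:10, y = (1:10)^3)
  expect_equal(spearman_with_p(d, x, y)$estimate, 1)
  d2 <- data.frame(x = 1:10, y = -(1:10)^3)
  expect_equal(spearman_with_p(d2, x, y)$estimate, -1)
  expect_error(spearman_with_p(data.frame(x = 1:9, y = rep(1, 9)), x, y),
               "constant")
})

test_that("small-sample Spearman p agrees with a permutation oracle", {
  set.seed(33)
  x <- rnorm(10)
  y <- 0.5 * x + rnorm(10)
  obs <- spearman_with_p(data.frame(x = x, y = y), x, y)
  r_obs <- abs(cor(x, y, method = "spearman"))
  perm <- vapply(1:9999, function(i) {
    abs(cor(x, sample(y), method = "spearman"))
  }, 0)
  p_perm <- mean(perm >= r_obs - 1e-12)
  expect_lt(abs(obs$p_value - p_perm), 0.01)
})

test_that("the Fisher-z correlation difference matches hand computation", {
  eq <- correlation_difference_test(0.4, 40, 0.4, 40)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  hand_z <- (atanh(0.5) - atanh(0)) / sqrt(1 / 47 + 1 / 47)
  res <- correlation_difference_test(0.5, 50, 0.0, 50)
  expect_equal(res$statistic, hand_z, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pnorm(-abs(hand_z)), tolerance = 1e-12)
  expect_error(correlation_difference_test(1, 30, 0.2, 30), "< 1")
})

test_that("rank-sum test gives the exact enumeration for tiny groups", {
  d <- data.frame(v = c(1, 2, 3, 4), g = c("a", "a", "b", "b"))
  expect_equal(rank_sum_test(d, v, g)$p_value, 1 / 3, tolerance = 1e-12)
  same <- data.frame(v = c(5, 5), g = c("a", "b"))
  expect_equal(rank_sum_test(same, v, g)$p_value, 1)
})

test_that("rank-sum test has high power for a one-SD location shift", {
  set.seed(35)
  rej <- vapply(1:200, function(i) {
    d <- data.frame(v = c(rnorm(30), rnorm(30, 1)),
                    g = rep(c("a", "b"), each = 30))
    rank_sum_test(d, v, g)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
})

test_that("rank statistics are invariant under monotone transformations", {
  set.seed(37)
  d <- data.frame(x = rexp(30), y = rnorm(30),
                  g = rep(c("a", "b", "c"), 10))
  d2 <- within(d, { x <- log(x); y <- exp(y / 3) })
  expect_equal(spearman_with_p(d, x, y)$estimate,
               spearman_with_p(d2, x, y)$estimate)
  expect_equal(kruskal_wallis(d, x, g)$statistic,
               kruskal_wallis(d2, x, g)$statistic)
})

test_that("canonical correlations agree with the base cancor oracle", {
  set.seed(39)
  x <- matrix(rnorm(80 * 4), 80)
  y <- matrix(rnorm(80 * 3), 80)
  y[, 1] <- y[, 1] + 0.8 * x[, 1]
  d <- as.data.frame(cbind(x, y))
  names(d) <- c(paste0("x", 1:4), paste0("y", 1:3))
  res <- cca_pillai_bootstrap(d, paste0("x", 1:4), paste0("y", 1:3),
                              replications = 99, seed = 1)
  oracle <- stats::cancor(scale(x), scale(y))$cor
  expect_equal(res$canonical_correlations, oracle, tolerance = 1e-8)
  expect_equal(res$pillai, sum(oracle^2), tolerance = 1e-8)
})

test_that("a duplicated block attains perfect canonical correlation", {
  set.seed(43)
  x <- matrix(rnorm(60 * 3), 60)
  d <- as.data.frame(cbind(x, x))
  names(d) <- c(paste0("x", 1:3), paste0("y", 1:3))
  res <- cca_pillai_bootstrap(d, paste0("x", 1:3), paste0("y", 1:3),
                              replications = 199, seed = 2)
  expect_equal(res$canonical_correlations, rep(1, 3), tolerance = 1e-8)
  expect_equal(res$p_value, 1 / 200)   # smallest attainable add-one p
})

test_that("orthogonalized blocks have zero Pillai trace", {
  set.seed(45)
  x <- matrix(rnorm(100 * 3), 100)
  y <- matrix(rnorm(100 * 2), 100)
  y <- stats::resid(lm(y ~ x))          # orthogonal to x by construction
  d <- as.data.frame(cbind(x, y))
  names(d) <- c(paste0("x", 1:3), paste0("y", 1:2))
  res <- cca_pillai_bootstrap(d, paste0("x", 1:3), paste0("y", 1:2),
                              replications = 99, seed = 3)
  expect_lt(res$pillai, 1e-12)
})

test_that("the collinear canonical subjective set is projected, not fatal", {
  sim <- simulate_cohort(sim_config(group_sizes = c(HC = 30, OB = 30,
                                                    DEP = 30, OBDEP = 30),
                                    duration = 60, seed = 47))
  res <- cca_pillai_bootstrap(sim$cohort, replications = 199, seed = 4)
  expect_lte(length(res$canonical_correlations), 6)
  expect_true(all(res$canonical_correlations >= 0 &
                    res$canonical_correlations <= 1))
  expect_error(
    cca_pillai_bootstrap(sim$cohort, replications = 199, seed = 4,
                         on_rank_deficiency = "error"),
    "subjective")
})

test_that("CCA permutation p-values are reproducible under a fixed seed", {
  set.seed(49)
  d <- as.data.frame(matrix(rnorm(50 * 5), 50))
  names(d) <- c(paste0("x", 1:3), paste0("y", 1:2))
  a <- cca_pillai_bootstrap(d, paste0("x", 1:3), paste0("y", 1:2),
                            replications = 499, seed = 7)
  b <- cca_pillai_bootstrap(d, paste0("x", 1:3), paste0("y", 1:2),
                            replications = 499, seed = 7)
  expect_identical(a$null_trace, b$null_trace)
  expect_identical(a$p_value, b$p_value)
})

test_that("CCA rejects a shared latent factor with high power", {
  set.seed(51)
  rej <- vapply(1:60, function(i) {
    f <- rnorm(150)
    x <- sapply(1:4, function(j) 0.8 * f + 0.6 * rnorm(150))
    y <- sapply(1:3, function(j) 0.8 * f + 0.6 * rnorm(150))
    d <- as.data.frame(cbind(x, y))
    names(d) <- c(paste0("x", 1:4), paste0("y", 1:3))
    cca_pillai_bootstrap(d, paste0("x", 1:4), paste0("y", 1:3),
                         replications = 199, seed = i)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)
})
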