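test_that("simulation config validates its invariants", {
  m <- default_transition_matrix()
  expect_true(all(abs(rowSums(m) - 1) < 1e-12))
  bad <- m
  bad[1, 1] <- bad[1, 1] + 0.01
  expect_error(sim_config(transition_matrix = bad), "summing to 1")
  expect_error(sim_config(coupling = 1.2), "\\[-1, 1\\]")
  expect_error(sim_config(duration = 0), "positive")
  expect_error(sim_config(group_sizes = c(HC = -1, OB = 0, DEP = 0,
                                          OBDEP = 0)), ">= 0")
})

test_that("an absorbing A1 transition model yields an all-A1 trajectory", {
  m <- matrix(0, 7, 7, dimnames = list(vigilance_stages(),
                                       vigilance_stages()))
  m[, "A1"] <- 1
  p0 <- setNames(c(0, 1, 0, 0, 0, 0, 0), vigilance_stages())
  cfg <- sim_config(duration = 120, transition_matrix = m,
                    initial_probs = p0)
  traj <- simulate_vigilance_trajectory(cfg, trait = 0, seed = 3)
  expect_true(all(traj$stage == "A1"))
})

test_that("trajectories are bitwise reproducible given the seed", {
  cfg <- sim_config(duration = 180)
  expect_identical(simulate_vigilance_trajectory(cfg, 0.5, seed = 11),
                   simulate_vigilance_trajectory(cfg, 0.5, seed = 11))
  expect_false(identical(simulate_vigilance_trajectory(cfg, 0.5, seed = 11),
                         simulate_vigilance_trajectory(cfg, 0.5, seed = 12)))
})

test_that("with zero coupling the trait leaves the stage marginals unchanged", {
  cfg <- sim_config(duration = 60, coupling = 0)
  prop_b <- function(trait, seeds) {
    vapply(seeds, function(s) {
      tr <- simulate_vigilance_trajectory(cfg, trait, seed = s)
      mean(tr$stage %in% c("B1", "B2/3"))
    }, 0)
  }
  a <- prop_b(-2, 1:200)
  b <- prop_b(+2, 201:400)
  se <- sqrt(var(a) / 200 + var(b) / 200)
  expect_lt(abs(mean(a) - mean(b)), 3 * se + 1e-9)
})

test_that("a sleepier trait drifts the trajectory toward lower stages", {
  cfg <- sim_config(duration = 120)
  mvv_at <- function(trait, seeds) {
    mean(vapply(seeds, function(s) {
      mean_vigilance_value(simulate_vigilance_trajectory(cfg, trait,
                                                         seed = s))
    }, 0))
  }
  expect_lt(mvv_at(+2, 1:100), mvv_at(-2, 101:200))
})

test_that("cohort sizes, labels and reproducibility match the configuration", {
  cfg <- sim_config(duration = 60, seed = 5)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$cohort), 193)
  expect_equal(as.vector(table(sim$cohort$group)), c(66, 68, 16, 43))
  # group label recomputable from BMI / BDI-II
  expect_identical(as.character(classify_group(sim$cohort$bmi,
                                               sim$cohort$bdi)),
                   as.character(sim$cohort$group))
  expect_identical(simulate_cohort(cfg)$cohort, sim$cohort)
  # ground truth is stored alongside, one trajectory per subject
  expect_equal(nrow(sim$ground_truth), 193)
  expect_equal(nrow(sim$ground_truth$trajectory[[1]]), 60)

  empty <- simulate_cohort(sim_config(group_sizes = c(HC = 0, OB = 0,
                                                      DEP = 0, OBDEP = 0)))
  expect_equal(nrow(empty$cohort), 0)
})

test_that("the trait-questionnaire coupling recovers its Monte-Carlo target", {
  cfg <- sim_config(group_sizes = c(HC = 200, OB = 200, DEP = 200,
                                    OBDEP = 200),
                    duration = 60, coupling = 0.8, seed = 17)
  sim <- simulate_cohort(cfg)
  got <- cor(sim$ground_truth$trait, sim$cohort$kss_pre,
             method = "spearman")

  # independent oracle: the generator's marginal response model simulated
  # directly from its definition (latent = 0.8 t + 0.6 e, discretized)
  set.seed(99)
  t_mc <- rnorm(40000)
  z <- 0.8 * t_mc + sqrt(1 - 0.8^2) * rnorm(40000)
  kss_mc <- pmin(pmax(round(3.4 + 1.6 * z), 1), 10)
  target <- cor(t_mc, kss_mc, method = "spearman")
  expect_lt(abs(got - target), 0.1)
})

test_that("group questionnaire shifts order the simulated medians", {
  cfg0 <- sim_config(group_sizes = c(HC = 30, OB = 30, DEP = 30, OBDEP = 30),
                     duration = 60)
  ok <- vapply(1:50, function(r) {
    cfg <- sim_config(group_sizes = cfg0$group_sizes, duration = 60,
                      seed = 1000 + r)
    co <- simulate_cohort(cfg)$cohort
    med <- vapply(split(co, co$group),
                  function(df) c(median(df$kss_pre), median(df$sss_pre)),
                  numeric(2))
    all(pmin(med[, "DEP"], med[, "OBDEP"]) >=
          pmax(med[, "HC"], med[, "OB"]))
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
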