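test_that("stage proportions aggregate A and B families over unmasked time", {
  expect_stage_props(stage_sequence(rep("A1", 1200)), c(0, 1, 0, 0))
  expect_stage_props(stage_sequence(c(rep("0", 600), rep("C", 600))),
                     c(0.5, 0, 0, 0.5))
  s <- stage_sequence(rep("B1", 1200), artifact = c(rep(TRUE, 300),
                                                    rep(FALSE, 900)))
  expect_stage_props(s, c(0, 0, 1, 0))
  expect_error(stage_proportions(stage_sequence(rep("A1", 5), TRUE)),
               "masked")
})

test_that("mean vigilance value reproduces the stage score column", {
  expect_equal(mean_vigilance_value(stage_sequence(rep("A2", 1200))), 5)
  expect_equal(mean_vigilance_value(stage_sequence(rep("A1", 1200))), 6)
  expect_equal(mean_vigilance_value(stage_sequence(rep("C", 1200))), 1)
  expect_equal(mean_vigilance_value(
    stage_sequence(c(rep("0", 600), rep("C", 600)))), 4)
  expect_error(mean_vigilance_value(stage_sequence(rep("C", 9), TRUE)),
               "masked")
})

test_that("MVV lies between the extreme stage scores of any sequence", {
  set.seed(41)
  for (i in 1:25) {
    s <- stage_sequence(sample(vigilance_stages(), 300, replace = TRUE))
    scores <- stage_score(unique(s$stage))
    m <- mean_vigilance_value(s)
    expect_gte(m, min(scores))
    expect_lte(m, max(scores))
  }
})

test_that("arousal stability cascade reproduces the published criteria", {
  # rigidity: only 0/A stages with at least one A2 -> 10
  s10 <- minutes_sequence(c(rep("0", 5), rep("A1", 10), rep("A2", 5)))
  expect_equal(as.integer(arousal_stability_score(s10)), 10)
  # only 0 and A1 -> 11
  s11 <- minutes_sequence(rep(c("0", "A1"), 10))
  expect_equal(as.integer(arousal_stability_score(s11)), 11)

  # 40% B1, first B in minute 7, no B2/3 third, no C -> 8
  s8 <- stage_sequence(c(rep("A1", 360), rep("B1", 480), rep("A1", 360)))
  expect_equal(as.integer(arousal_stability_score(s8)), 8)

  # 35% B2/3 first emerging in minute 8, rest A stages, no C -> 5
  s5 <- stage_sequence(c(rep("A1", 420), rep("B2/3", 420), rep("A2", 360)))
  expect_equal(as.integer(arousal_stability_score(s5)), 5)

  # adding a single C second in minute 9 overrides to 2
  st <- c(rep("A1", 420), rep("B2/3", 420), rep("A2", 360))
  st[8 * 60 + 30] <- "C"
  expect_equal(as.integer(arousal_stability_score(stage_sequence(st))), 2)
})

test_that("ASS depends only on per-minute counts and emergence minutes", {
  set.seed(7)
  for (i in 1:20) {
    st <- sample(vigilance_stages(), 1200, replace = TRUE,
                 prob = c(2, 4, 2, 1, 3, 2, 0.2))
    base <- as.integer(arousal_stability_score(stage_sequence(st)))
    shuffled <- as.vector(vapply(split(st, ceiling(seq_len(1200) / 60)),
                                 sample, character(60)))
    expect_equal(as.integer(arousal_stability_score(
      stage_sequence(shuffled))), base)
  }
})

test_that("adding a C second never increases ASS; removing B/C restores rigidity", {
  set.seed(8)
  for (i in 1:20) {
    st <- sample(c("0", "A1", "A2", "B1", "B2/3"), 1200, replace = TRUE)
    base <- as.integer(arousal_stability_score(stage_sequence(st)))
    st_c <- st
    st_c[sample(1200, 1)] <- "C"
    expect_lte(as.integer(arousal_stability_score(stage_sequence(st_c))),
               base)
    st_a <- ifelse(st %in% c("B1", "B2/3", "C"), "A2", st)
    expect_gte(as.integer(arousal_stability_score(stage_sequence(st_a))), 10)
  }
})

test_that("cascade matches the brute-force rule table on all 7^4 sequences", {
  st <- vigilance_stages()
  grid <- expand.grid(m1 = st, m2 = st, m3 = st, m4 = st,
                      stringsAsFactors = FALSE)
  got <- integer(nrow(grid))
  want <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    by_minute <- unlist(grid[i, ], use.names = FALSE)
    got[i] <- as.integer(arousal_stability_score(
      stage_sequence(by_minute), bin_breaks = c(1, 2, 3),
      seconds_per_minute = 1))
    want[i] <- oracle_ass(by_minute)
  }
  expect_identical(got, want)
})

test_that("arousal_summary binds the three objective parameters", {
  s <- stage_sequence(c(rep("A1", 600), rep("B1", 600)))
  out <- arousal_summary(s)
  expect_named(out, c("prop_0", "prop_a", "prop_b", "prop_c", "mvv", "ass",
                      "n_artifact"))
  expect_equal(out$mvv, 4.5)
  expect_equal(out$ass, 9)  # half B, first B in minute 11 -> bin 11-15
})
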