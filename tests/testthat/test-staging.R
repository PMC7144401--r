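fs <- 200

test_that("a pure occipital 10 Hz tone yields occipital-dominant alpha", {
  tt <- (0:(fs * 2 - 1)) / fs
  tone <- 30 * sin(2 * pi * 10 * tt)
  rec <- tone_recording(fs, 2, list(O1 = tone, O2 = tone))
  f <- extract_segment_features(rec, 1)
  expect_equal(f$alpha_topography, "occipital")
  expect_gt(f$alpha_share, 0.5)
  expect_false(f$sem)
})

test_that("an all-zero second has zero band powers and no flags", {
  rec <- tone_recording(fs, 2)
  f <- extract_segment_features(rec, 2)
  expect_equal(f$total_power, 0)
  expect_equal(f$delta_theta, 0)
  expect_equal(f$alpha_share, 0)
  expect_false(any(f$sem, f$spindle, f$kcomplex))
  expect_equal(f$peak_amplitude, 0)
})

test_that("white noise gives an alpha share near the bandwidth ratio", {
  # flat spectrum: alpha(8-12) over total(1-30) at 1 Hz resolution = 4/29
  set.seed(23)
  rec <- tone_recording(fs, 200)
  rec$signal[] <- rnorm(length(rec$signal), sd = 5)
  shares <- vapply(1:200, function(s) {
    extract_segment_features(rec, s)$alpha_share
  }, 0)
  expect_lt(abs(mean(shares) - 4 / 29), 0.02)
})

test_that("slow eye movement detection passes 0.3 Hz and rejects 10 Hz", {
  tt <- (0:(fs - 1)) / fs
  expect_false(detect_sem(rep(0, fs), fs))
  expect_true(detect_sem(120 * sin(2 * pi * 0.3 * tt), fs))
  # the 0.4 s boxcar response sin(pi f T)/(pi f T) has a null at 10 Hz:
  # a large fast oscillation must not masquerade as a slow deflection
  expect_false(detect_sem(120 * sin(2 * pi * 10 * tt), fs))
  att <- abs(sin(pi * 10 * 0.4) / (pi * 10 * 0.4))
  expect_lt(120 * att, 1)  # analytic filter response oracle
})

test_that("artifact masking flags exactly the contaminated seconds", {
  cfg <- sim_config(duration = 60)
  rec <- synthesize_recording(stage_sequence(rep("A1", 60)), cfg, seed = 9)
  expect_equal(sum(mask_artifacts(rec)), 0)
  spiked <- rec
  spiked$signal["Cz", (2 * fs + 1):(3 * fs)] <- 500   # second 3
  m <- mask_artifacts(spiked)
  expect_identical(which(m), 3L)
  expect_true(all(mask_artifacts(rec, amplitude_threshold = 1e-9)))
  expect_error(mask_artifacts(rec, 0), "> 0")
})

test_that("the classification cascade honours its precedence order", {
  feats <- extract_segment_features(
    tone_recording(fs, 1, list(Cz = rnorm(fs, sd = 5))), 1)
  feats$spindle <- TRUE
  feats$delta_theta <- 1e6
  feats$alpha_share <- 0.9
  expect_equal(classify_segment(feats, baseline = 1), "C")
  feats$spindle <- FALSE
  expect_equal(classify_segment(feats, baseline = 1), "B2/3")
  feats$delta_theta <- 0.5
  feats$alpha_share <- 0.05
  feats$sem <- FALSE
  expect_equal(classify_segment(feats, baseline = 1), "0")
  feats$sem <- TRUE
  expect_equal(classify_segment(feats, baseline = 1), "B1")
})

test_that("noiseless single-characteristic seconds reproduce all seven stages", {
  cfg <- sim_config(duration = 70,
                    noise_scales = list(background = 0, alpha = 30,
                                        alpha_other = 6, delta = 20,
                                        theta = 20, spindle = 25,
                                        kcomplex = 45, sem = 100))
  truth <- stage_sequence(rep(vigilance_stages(), each = 10))
  rec <- synthesize_recording(truth, cfg, seed = 10)
  staged <- stage_recording(rec)
  expect_equal(staging_agreement(truth, staged), 1)
})

test_that("full default-SNR recordings recover the generator labels", {
  cfg <- sim_config(duration = 300)
  for (trait in c(0, 1.5)) {
    truth <- simulate_vigilance_trajectory(cfg, trait,
                                           seed = 30 + round(trait))
    rec <- synthesize_recording(truth, cfg, seed = 40 + round(trait))
    staged <- stage_recording(rec)
    expect_gte(staging_agreement(truth, staged), 0.9)
  }
})

test_that("staging is deterministic and preserves artifact seconds", {
  cfg <- sim_config(duration = 90)
  truth <- simulate_vigilance_trajectory(cfg, 0.5, seed = 12)
  rec <- synthesize_recording(truth, cfg, seed = 13)
  spike_secs <- c(5L, 20L, 41L, 60L, 77L)
  for (s in spike_secs) {
    rec$signal["Pz", ((s - 1) * fs + 20)] <- 500
  }
  st <- stage_recording(rec)
  expect_equal(nrow(st), 90)
  expect_identical(which(st$artifact), spike_secs)
  expect_identical(sum(st$stage == "ARTIFACT"), 5L)
  expect_identical(stage_recording(rec), st)
  expect_error(stage_recording(synthesize_recording(
    stage_sequence(rep("A1", 59)), sim_config(duration = 59), seed = 1)),
    "60 seconds")
})

test_that("stronger slow-wave amplitude monotonically raises B2/3 detection", {
  truth <- stage_sequence(rep(c("A1", "B2/3"), 150))
  frac <- vapply(c(1, 2, 4, 8, 16), function(amp) {
    cfg <- sim_config(duration = 300,
                      noise_scales = list(background = 5, alpha = 30,
                                          alpha_other = 6, delta = amp,
                                          theta = amp, spindle = 25,
                                          kcomplex = 45, sem = 100))
    rec <- synthesize_recording(truth, cfg, seed = 14)
    st <- stage_recording(rec)
    mean(st$stage == "B2/3")
  }, 0)
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[5], frac[1])
})
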