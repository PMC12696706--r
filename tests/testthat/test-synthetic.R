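test_that("cohort generation enforces counts, ranges and effect signs", {
  co <- make_cohort(12, 19, seed = 1)
  expect_length(co, 31)
  groups <- vapply(co, `[[`, "", "group")
  expect_equal(sum(groups == "UWS"), 12)
  expect_equal(sum(groups == "MCS"), 19)
  for (p in co) {
    expect_true(p$crs_r >= 0 && p$crs_r <= 23)
    expect_equal(unname(rowSums(p$rest_band_weights)), rep(1, 4),
                 tolerance = 1e-9)
    expect_true(all(p$task_modulation > 0))
    expect_true(p$attention_gain >= 0 && p$attention_gain <= 1)
    if (p$group == "MCS") {
      m <- p$task_modulation
      expect_true(all(m[c("frontal", "parietal"), c("delta", "theta")] > 1))
      expect_true(all(m[c("frontal", "parietal"), c("alpha", "beta")] < 1))
    } else {
      expect_gt(p$task_modulation["parietal", "gamma"], 1)
      expect_true(all(p$task_modulation[, c("delta", "theta", "alpha",
                                            "beta")] == 1))
    }
  }
  expect_error(make_cohort(0, 5), "positive")
})

test_that("cohort draws are seed-deterministic and seed-sensitive", {
  a <- make_cohort(3, 4, seed = 7)
  b <- make_cohort(3, 4, seed = 7)
  expect_identical(a, b)
  c <- make_cohort(3, 4, seed = 8)
  expect_false(identical(a, c))
})

test_that("attention gain rises with CRS-R when profile noise is off", {
  ec <- default_effect_config()
  ec$attention$noise_sd <- 0
  co <- make_cohort(10, 10, ec, seed = 2)
  meta <- cohort_metadata(co)
  ord <- order(meta$crs_r)
  expect_true(all(diff(meta$attention_gain[ord]) >= -1e-12))
  # with noise: still positively rank-correlated across a larger cohort
  co2 <- make_cohort(20, 30, seed = 3)
  meta2 <- cohort_metadata(co2)
  expect_gt(cor(meta2$crs_r, meta2$attention_gain, method = "spearman"), 0.2)
})

test_that("null-effect configuration removes every group difference", {
  ec <- default_effect_config(null_effects = TRUE)
  expect_true(all(ec$task_modulation$UWS == 1))
  expect_true(all(ec$task_modulation$MCS == 1))
  expect_identical(ec$rest_weights$UWS, ec$rest_weights$MCS)
  expect_equal(ec$attention$noise_sd, 0)
})

test_that("synthesized recordings are deterministic and well-formed", {
  plan <- plan_tiny()
  p <- make_cohort(1, 1, seed = 1)[[2]]
  r1 <- synthesize_recording(p, plan, "task", artifact_rate = 2, seed = 5)
  r2 <- synthesize_recording(p, plan, "task", artifact_rate = 2, seed = 5)
  expect_identical(r1$data, r2$data)
  expect_identical(attr(r1, "artifacts"), attr(r2, "artifacts"))
  r3 <- synthesize_recording(p, plan, "task", artifact_rate = 2, seed = 6)
  expect_false(identical(r1$data, r3$data))

  expect_equal(nrow(r1$data), 31)
  expect_equal(ncol(r1$data), plan$fs_task * session_length_s(plan))
  expect_true(all(c("cue_on", "cue_off") %in% r1$events$label))
  rms <- sqrt(rowMeans(scalp_data(r1)^2))
  expect_true(all(rms > 5 & rms < 40)) # background stays in EEG range
  expect_error(synthesize_recording(p, plan, "sleep"), "arg")
})

test_that("a delta-only profile concentrates Welch power in 1-4 Hz", {
  p <- make_cohort(1, 1, seed = 4)[[1]]
  w <- p$rest_band_weights
  w[] <- 0
  w[, "delta"] <- 1
  p$rest_band_weights <- w
  rec <- synthesize_recording(p, plan_tiny(fs = 125, rest_s = 40), "rest",
                              artifact_rate = 0, seed = 9)
  pp <- preprocess_recording(rec, ica = FALSE)
  # 4 s analysis windows: enough frequency resolution that window leakage
  # does not smear the narrow delta band into its neighbours
  psd <- welch_psd(pp$epochs, window_s = 4, overlap_s = 2)
  bp <- docbci:::band_power_matrix(psd, analysis_bands())
  rel_delta <- bp[, "delta"] / rowSums(bp)
  expect_true(all(rel_delta > 0.9))
  expect_gt(mean(rel_delta), 0.95)
})

test_that("rest spectra reproduce the profile's band weights regionally", {
  plan <- session_plan(rest_s = 200, fs_rest = 125)
  p <- make_cohort(1, 1, seed = 1)[[2]]
  rec <- synthesize_recording(p, plan, "rest", artifact_rate = 0, seed = 11)
  pp <- preprocess_recording(rec, ica = FALSE)
  rp <- relative_power(welch_psd(pp$epochs))
  for (rg in names(brain_regions())) {
    meas <- rp$rel_power[rp$region == rg]
    expect_equal(meas, unname(p$rest_band_weights[rg, ]), tolerance = 0.025)
  }
})

test_that("injected spikes are caught by the 75 uV epoch screen", {
  p <- make_cohort(1, 1, seed = 6)[[1]]
  plan <- session_plan(rest_s = 300, fs_rest = 125)
  rec <- synthesize_recording(p, plan, "rest", artifact_rate = 6,
                              blink_rate = 0, seed = 13)
  log <- attr(rec, "artifacts")
  expect_gt(nrow(log), 20) # ~30 expected at 6/min over 5 min
  expect_lt(abs(nrow(log) - 30), 15)
  ep <- epoch_and_reject(rereference_car(bandpass_and_notch(rec)))
  # every injected transient falls in a rejected epoch
  spike_epochs <- unique(ceiling(log$sample / (5 * rec$fs)))
  expect_true(all(!ep$keep[spike_epochs]))
})

test_that("attention trace peaks follow the configured gain and latency", {
  plan <- plan_bci(n_trials = 4)
  p <- make_cohort(1, 1, seed = 2)[[2]]

  p$attention_gain <- 0
  tr0 <- simulate_attention_trace(p, plan, seed = 1, noise_sd = 0)
  expect_true(all(tr0$attention == 0))

  p$attention_gain <- 1
  tr1 <- simulate_attention_trace(p, plan, seed = 1, noise_sd = 0)
  expect_equal(max(tr1$attention), 1, tolerance = 1e-6)
  onsets <- attr(tr1, "cue_onsets")
  for (t0 in onsets) {
    sel <- tr1$time >= t0 - 2 & tr1$time <= t0 + 10
    tpk <- tr1$time[sel][which.max(tr1$attention[sel])]
    expect_equal(tpk - t0, 4, tolerance = 0.51) # latency 4 s +/- one hop
  }

  tr4 <- simulate_attention_trace(p, plan, seed = 1, noise_sd = 0,
                                  latency_s = 2)
  sel <- tr4$time >= onsets[1] - 2 & tr4$time <= onsets[1] + 8
  tpk <- tr4$time[sel][which.max(tr4$attention[sel])]
  expect_equal(tpk - onsets[1], 2, tolerance = 0.51)
})
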