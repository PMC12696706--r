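test_that("common average reference zeroes the scalp mean at every sample", {
  rec <- white_recording(fs = 125, dur_s = 5, seed = 21)
  out <- rereference_car(rec)
  expect_lt(max(abs(colMeans(scalp_data(out)))), 1e-9)
  # idempotent
  out2 <- rereference_car(out)
  expect_equal(out$data, out2$data, tolerance = 1e-12)
  # EOG untouched
  expect_identical(out$data["EOG", ], rec$data["EOG", ])
  # +10 uV offset on one channel redistributes as -10/30 on the others
  rec2 <- rec
  rec2$data["Cz", ] <- rec2$data["Cz", ] + 10
  d <- rereference_car(rec2)$data - out$data
  expect_equal(unname(d["Cz", 1]), 10 - 10 / 30, tolerance = 1e-9)
  expect_equal(unname(d["O1", 1]), -10 / 30, tolerance = 1e-9)
})

test_that("bad-channel detection flags gross outliers only", {
  rec <- white_recording(fs = 125, dur_s = 10, sd_uv = 15, seed = 3)
  expect_length(detect_bad_channels(rec), 0)
  rec$data["T3", ] <- 0 # dead channel
  rec$data["F7", ] <- rec$data["F7", ] * 8 # huge gain fault
  expect_setequal(detect_bad_channels(rec), c("T3", "F7"))
})

test_that("interpolation rebuilds bad channels from good neighbours", {
  rec <- white_recording(fs = 125, dur_s = 10, sd_uv = 15, seed = 4)
  # identity on empty set
  same <- interpolate_bad_channels(rec, bad = character(0))
  expect_identical(same$data, rec$data)

  rec$data["C3", ] <- 0
  fixed <- interpolate_bad_channels(rec)
  expect_equal(attr(fixed, "interpolated"), "C3")
  rms_all <- sqrt(rowMeans(scalp_data(rec)^2))
  expect_lt(sqrt(mean(fixed$data["C3", ]^2)), 3 * median(rms_all))
  expect_gt(sd(fixed$data["C3", ]), 0)
  # untouched elsewhere
  expect_identical(fixed$data["Pz", ], rec$data["Pz", ])

  # two adjacent bad channels are rebuilt from good channels only:
  # interpolated values must not depend on the other bad channel
  rec2 <- white_recording(fs = 125, dur_s = 10, sd_uv = 15, seed = 5)
  rec2$data["C3", ] <- 0
  rec2$data["FC3", ] <- 0
  fix2 <- interpolate_bad_channels(rec2, bad = c("C3", "FC3"))
  rec3 <- rec2
  rec3$data["FC3", ] <- 1000 # corrupt differently; C3 result must not move
  fix3 <- interpolate_bad_channels(rec3, bad = c("C3", "FC3"))
  expect_identical(fix2$data["C3", ], fix3$data["C3", ])

  expect_error(interpolate_bad_channels(rec, bad = montage_channels()[1:10]),
               "too many")
})

test_that("epoching splits into 5-s windows and rejects over-amplitude", {
  fs <- 125
  rec <- white_recording(fs = fs, dur_s = 300, sd_uv = 5, seed = 6)
  ep <- epoch_and_reject(rec)
  expect_equal(length(ep$keep), 60) # 300 s / 5 s
  expect_true(all(ep$keep))

  # one +100 uV spike at t = 12 s: exactly the 10-15 s epoch is rejected
  rec$data["P3", 12 * fs] <- 100
  ep2 <- epoch_and_reject(rec)
  expect_false(ep2$keep[3])
  expect_equal(sum(!ep2$keep), 1)
  expect_equal(ep2$reason[3], "amplitude")

  # boundary: max exactly 74.9 -> nothing rejected
  rec3 <- white_recording(fs = fs, dur_s = 50, sd_uv = 5, seed = 7)
  rec3$data <- rec3$data / max(abs(scalp_data(rec3))) * 74.9
  expect_true(all(epoch_and_reject(rec3)$keep))

  # rejection is idempotent: re-screening kept epochs rejects nothing
  kept <- ep2$data[, , ep2$keep, drop = FALSE]
  rec4 <- eeg_recording(matrix(kept, nrow = 30,
                               dimnames = list(ep2$channel_names, NULL)),
                        fs, condition = "rest")
  expect_true(all(epoch_and_reject(rec4)$keep))
})

test_that("ICA removes an injected ocular source and spares clean data", {
  plan <- session_plan(n_trials = 4, cue_s = 5, iti_s = 3, pre_s = 4,
                       calibration_s = 22, fs_task = 125, rest_s = 60,
                       fs_rest = 125)
  p <- make_cohort(1, 1, seed = 7)[[2]]

  clean <- bandpass_and_notch(
    synthesize_recording(p, plan, "task", artifact_rate = 0,
                         blink_rate = 0, seed = 9))
  out <- attenuate_artifacts_ica(clean, seed = 3)
  expect_equal(attr(out, "ica_removed"), 0L)
  cors <- vapply(seq_len(30), function(i)
    cor(scalp_data(out)[i, ], scalp_data(clean)[i, ]), numeric(1))
  expect_true(all(cors > 0.99))

  # same seed as the clean recording: identical background, blinks only
  dirty <- bandpass_and_notch(
    synthesize_recording(p, plan, "task", artifact_rate = 0,
                         blink_rate = 10, seed = 9))
  out2 <- attenuate_artifacts_ica(dirty, seed = 3)
  expect_equal(attr(out2, "ica_removed"), 1L)
  # frontal delta-range artifact power reduced by at least 70%
  art <- scalp_data(dirty) - scalp_data(clean)
  resid <- scalp_data(out2) - scalp_data(clean)
  sos_d <- butter_bandpass_sos(1, 4, 125)
  front <- brain_regions()$frontal
  pow <- function(m) mean(sos_filtfilt(t(m[front, ]), sos_d, fs = 125)^2)
  expect_lt(pow(resid), 0.3 * pow(art))

  # determinism under a fixed seed
  out3 <- attenuate_artifacts_ica(dirty, seed = 3)
  expect_identical(out2$data, out3$data)
})

test_that("SNR gauge matches closed forms and error conditions", {
  fs <- 125
  n <- 60 * fs
  base <- white_recording(fs = fs, dur_s = 60, sd_uv = 10, seed = 12)
  ev <- data.frame(sample = c(10, 25, 40) * fs, label = "cue_on")
  rec <- eeg_recording(base$data, fs, base$channel_names, "task", ev)
  r0 <- compute_snr(rec)
  expect_equal(r0$snr_db, 0, tolerance = 0.35) # identical distributions

  # task windows with doubled 8-30 Hz power -> ~3.01 dB
  sos <- butter_bandpass_sos(8, 30, fs)
  extra <- t(sos_filtfilt(t(base$data), sos, fs = fs))
  dat2 <- base$data
  for (s in ev$sample) {
    idx <- s:(s + 5 * fs - 1)
    # add an independent same-power 8-30 component: doubles band power
    shift <- extra[, idx - 7 * fs]
    dat2[, idx] <- dat2[, idx] + shift
  }
  rec2 <- eeg_recording(dat2, fs, base$channel_names, "task", ev)
  r2 <- compute_snr(rec2)
  expect_equal(r2$snr_db, 3.01, tolerance = 0.6)
  expect_gt(r2$snr_db, r0$snr_db)

  expect_error(compute_snr(base), "cue_on")
})

test_that("artifact cleaning raises the task/baseline SNR across subjects", {
  plan <- session_plan(n_trials = 6, cue_s = 5, iti_s = 3, pre_s = 4,
                       calibration_s = 22, fs_task = 125, rest_s = 10,
                       fs_rest = 125)
  co <- make_cohort(3, 3, seed = 7)
  pre <- post <- c()
  for (i in seq_along(co)) {
    rec <- synthesize_recording(co[[i]], plan, "task", artifact_rate = 12,
                                blink_rate = 4, seed = 60 + i)
    pp <- preprocess_recording(rec, ica = TRUE, ica_seed = 3)
    pre <- c(pre, pp$qc$snr_pre_db)
    post <- c(post, pp$qc$snr_post_db)
  }
  expect_gt(mean(post, na.rm = TRUE), mean(pre, na.rm = TRUE))
})

test_that("the preprocessing chain reports its fixed stage order", {
  rec <- white_recording(fs = 125, dur_s = 10, seed = 30)
  pp <- preprocess_recording(rec, ica = FALSE)
  expect_match(pp$qc$stage_order, "filter.*interpolate.*ica.*car.*epoch")
  # CAR property survives epoching
  means <- apply(pp$epochs$data, c(2, 3), mean)
  expect_lt(max(abs(means)), 1e-9)
})
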