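# Shared fixtures and simulation harnesses. Monte-Carlo checks run on
# scaled-down recordings (short durations, 100-125 Hz); the generator's
# effect defaults are never altered.

# short plans used across files
plan_tiny <- function(fs = 125, rest_s = 10)
  session_plan(n_trials = 1, cue_s = 3, iti_s = 2, pre_s = 3,
               calibration_s = 2, rest_s = rest_s, fs_rest = fs,
               fs_task = fs)

plan_spec <- function(fs = 125, rest_s = 10) # spectral-contrast plan
  session_plan(n_trials = 1, cue_s = 5, iti_s = 2, pre_s = 3,
               calibration_s = 5, rest_s = rest_s, fs_rest = fs,
               fs_task = fs)

plan_bci <- function(n_trials = 3, fs = 100)
  session_plan(n_trials = n_trials, cue_s = 5, iti_s = 3, pre_s = 4,
               calibration_s = 21, rest_s = 10, fs_rest = fs, fs_task = fs)

# rest+task relative-power table for a whole cohort (no artifacts, no ICA)
cohort_relative_power <- function(cohort, plan, seed, nfft_factor = 4) {
  rpt <- NULL
  for (p in cohort) {
    for (cond in c("rest", "task")) {
      rec <- synthesize_recording(p, plan, cond, artifact_rate = 0,
                                  seed = derive_seed(seed, p$subject_id,
                                                     cond))
      pp <- preprocess_recording(rec, ica = FALSE, snr = FALSE)
      rp <- relative_power(welch_psd(pp$epochs, nfft_factor = nfft_factor))
      rp$subject_id <- p$subject_id
      rp$group <- p$group
      rp$condition <- cond
      rpt <- rbind(rpt, rp[, c("subject_id", "group", "condition",
                               "region", "band", "rel_power")])
    }
  }
  rpt
}

# within-group effect directions of the synthetic cohort defaults:
# region, band, group, expected sign of (task - rest) relative power
effect_sign_targets <- function() {
  data.frame(
    region = c("frontal", "frontal", "parietal", "frontal", "parietal",
               "frontal", "parietal", "parietal", "parietal"),
    band = c("delta", "theta", "theta", "alpha", "alpha",
             "beta", "beta", "gamma", "gamma"),
    group = c(rep("MCS", 8), "UWS"),
    sign = c(1, 1, 1, -1, -1, -1, -1, -1, 1),
    stringsAsFactors = FALSE)
}

# single-channel epoch set wrapper so Welch can be driven with raw vectors
vector_epochs <- function(x, fs, channel = "X") {
  structure(list(data = array(x, c(1, length(x), 1)),
                 fs = fs, keep = TRUE, reason = "",
                 condition = "rest", window_s = length(x) / fs,
                 threshold_uv = Inf, channel_names = channel),
            class = "epoch_set")
}

# deterministic multichannel test recording: independent white noise
white_recording <- function(fs = 250, dur_s = 10, sd_uv = 10, seed = 1,
                            condition = "rest") {
  n <- round(fs * dur_s)
  x <- docbci:::gauss_matrix(n, 31L, seed) * sd_uv
  eeg_recording(t(x), fs, channel_names = c(montage_channels(), "EOG"),
                condition = condition)
}

# sum of sinusoids on every channel
sine_recording <- function(freqs, amps, fs = 250, dur_s = 10) {
  tt <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  sig <- rowSums(mapply(function(f, a) a * sin(2 * pi * f * tt),
                        freqs, amps))
  data <- matrix(rep(sig, each = 31), 31)
  eeg_recording(data, fs, channel_names = c(montage_channels(), "EOG"),
                condition = "rest")
}
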