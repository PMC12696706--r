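# Synthetic-EEG cohort generator: virtual UWS-like and MCS-like subjects
# with controllable resting band-power composition, task modulation,
# artifacts, and CRS-R-linked attention responsiveness.

#' Session and recording plan
#'
#' Timing and sampling parameters for one subject's recordings: a 5-min
#' resting recording at 500 Hz and a motor-imagery session at 250 Hz made of
#' a calibration baseline followed by `n_trials` trials (pre-cue baseline,
#' imagery cue window, inter-trial interval).
#'
#' @param n_trials number of scored trials (study default 15).
#' @param cue_s imagery cue window, seconds.
#' @param iti_s inter-trial interval, seconds.
#' @param pre_s pre-cue baseline per trial, seconds.
#' @param calibration_s pre-session baseline used to fit the attention-index
#'   normalization, seconds.
#' @param fs_task,fs_rest sampling rates in Hz (must exceed twice the 45 Hz
#'   top analysis frequency).
#' @param rest_s resting-state recording duration, seconds.
#' @return a `session_plan` list.
#' @export
session_plan <- function(n_trials = 15, cue_s = 5, iti_s = 3, pre_s = 4,
                         calibration_s = 30, fs_task = 250, fs_rest = 500,
                         rest_s = 300) {
  stopifnot(n_trials >= 1, cue_s > 0, iti_s > 0, pre_s > 0,
            calibration_s > 0, rest_s > 0)
  if (fs_task <= 90 || fs_rest <= 90)
    stop("sampling rates must exceed twice the 45 Hz analysis limit")
  structure(list(n_trials = as.integer(n_trials), cue_s = cue_s,
                 iti_s = iti_s, pre_s = pre_s, calibration_s = calibration_s,
                 fs_task = fs_task, fs_rest = fs_rest, rest_s = rest_s),
            class = "session_plan")
}

#' Session timing helpers
#'
#' Seconds per trial, total session length, and the cue onset times of a
#' [session_plan()].
#'
#' @param plan a [session_plan()].
#' @return seconds (scalar) or a vector of cue-onset times in seconds.
#' @export
trial_length_s <- function(plan) plan$pre_s + plan$cue_s + plan$iti_s

#' @rdname trial_length_s
#' @export
session_length_s <- function(plan) {
  plan$calibration_s + plan$n_trials * trial_length_s(plan)
}

#' @rdname trial_length_s
#' @export
cue_onsets_s <- function(plan) {
  plan$calibration_s + (seq_len(plan$n_trials) - 1) * trial_length_s(plan) +
    plan$pre_s
}

#' Default effect configuration for the synthetic cohort
#'
#' Group-level spectral structure of the virtual cohort: resting relative
#' band-power compositions per region (UWS delta-dominant; MCS with more
#' beta and less delta), multiplicative task-modulation factors (MCS:
#' delta/theta enhancement with alpha/beta/gamma suppression over
#' frontal-parietal cortex; UWS: localized parietal gamma enhancement only),
#' between-subject variability, and the CRS-R-to-attention-gain linkage.
#'
#' @param null_effects if `TRUE`, all task-modulation factors are 1 and the
#'   two groups share one spectral profile and attention gain (used for
#'   type-I-error calibration).
#' @return an `effect_config` list with elements `rest_weights` and
#'   `task_modulation` (per group: regions x bands matrices),
#'   `weight_jitter_sd`, `modulation_jitter_sd` (log-scale between-subject
#'   SDs), `crs_range` (per group), `attention` (logistic map coefficients
#'   and noise), `target_rho`, `rms_uv` (background RMS per channel),
#'   `attention_shift_max` (peak beta/alpha ratio multiplier at Fp1).
#' @export
default_effect_config <- function(null_effects = FALSE) {
  regions <- names(brain_regions())
  bands <- analysis_bands()$band
  w <- function(...) {
    m <- matrix(c(...), nrow = 4, byrow = TRUE,
                dimnames = list(regions, bands))
    sweep(m, 1, rowSums(m), "/")
  }
  uws_w <- w(0.44, 0.25, 0.18, 0.09, 0.01,
             0.43, 0.25, 0.20, 0.12, 0.01,
             0.42, 0.26, 0.20, 0.10, 0.02,
             0.40, 0.25, 0.22, 0.11, 0.02)
  mcs_w <- w(0.35, 0.28, 0.22, 0.10, 0.01,
             0.36, 0.24, 0.24, 0.15, 0.01,
             0.34, 0.27, 0.24, 0.13, 0.02,
             0.32, 0.26, 0.26, 0.14, 0.02)
  one <- matrix(1, 4, 5, dimnames = list(regions, bands))
  uws_m <- one
  uws_m["parietal", "gamma"] <- 3.0
  mcs_m <- one
  mcs_m["frontal", ] <- c(1.25, 1.30, 0.55, 0.40, 0.90)
  mcs_m["parietal", ] <- c(1.05, 1.50, 0.67, 0.33, 0.50)
  if (null_effects) {
    uws_m <- mcs_m <- one
    mcs_w <- uws_w
  }
  list(
    rest_weights = list(UWS = uws_w, MCS = mcs_w),
    task_modulation = list(UWS = uws_m, MCS = mcs_m),
    weight_jitter_sd = if (null_effects) 0.15 else 0.15,
    modulation_jitter_sd = 0.25,
    crs_range = list(UWS = c(4L, 9L), MCS = c(10L, 20L)),
    # attention_gain = plogis(a + b * crs + noise); calibrated so the
    # recoverable rank correlation with CRS-R is ~ target_rho
    attention = list(a = -3.2, b = 0.2,
                     noise_sd = if (null_effects) 0 else 1.55,
                     equalize = null_effects),
    target_rho = 0.43,
    rms_uv = 15,
    attention_shift_max = 1.2)
}

# run expr with a temporary R RNG seed, restoring prior state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a cohort of virtual subject profiles
#'
#' Draws per-subject spectral profiles and metadata for `n_uws` UWS-like and
#' `n_mcs` MCS-like subjects. Resting band weights and task-modulation
#' factors are jittered on the log scale around the group-level values in
#' `effect_config` (then renormalized), CRS-R totals are drawn uniformly
#' from the group's range, and the attention gain follows a noisy logistic
#' map of CRS-R so that responsiveness increases with the behavioural score.
#'
#' @param n_uws,n_mcs group sizes (study cohort: 12 and 19).
#' @param effect_config see [default_effect_config()].
#' @param seed integer seed; the draw is fully deterministic given the seed.
#' @return a `doc_cohort`: list of `subject_profile` objects.
#' @export
#' @examples
#' cohort <- make_cohort(2, 3, seed = 1)
#' cohort[[1]]$group
make_cohort <- function(n_uws = 12, n_mcs = 19,
                        effect_config = default_effect_config(), seed = 1) {
  if (n_uws < 1 || n_mcs < 1) stop("group counts must be positive")
  groups <- c(rep("UWS", n_uws), rep("MCS", n_mcs))
  n <- length(groups)
  ec <- effect_config
  with_seed(derive_seed(seed, "cohort"), {
    profiles <- vector("list", n)
    for (i in seq_len(n)) {
      g <- groups[i]
      cr <- ec$crs_range[[g]]
      crs <- sample(seq(cr[1], cr[2]), 1)
      w <- ec$rest_weights[[g]] *
        exp(matrix(rnorm(20, 0, ec$weight_jitter_sd), 4, 5))
      w <- sweep(w, 1, rowSums(w), "/")
      m <- ec$task_modulation[[g]]
      # between-subject variation scales each configured effect's log
      # magnitude, never its direction; null factors (1) stay exactly 1
      jit <- exp(matrix(rnorm(20, 0, ec$modulation_jitter_sd), 4, 5))
      m <- exp(log(m) * jit)
      att <- ec$attention
      eta <- if (isTRUE(att$equalize)) att$a + att$b * 12
             else att$a + att$b * crs
      gain <- stats::plogis(eta + rnorm(1, 0, att$noise_sd))
      profiles[[i]] <- validate_profile(structure(list(
        subject_id = sprintf("S%02d", i),
        group = g,
        crs_r = as.integer(crs),
        age = round(rnorm(1, if (g == "UWS") 45.6 else 48.2, 11)),
        sex = sample(c("male", "female"), 1,
                     prob = if (g == "UWS") c(8, 4) / 12 else c(16, 3) / 19),
        duration_months = round(max(1, rnorm(1,
                     if (g == "UWS") 6.1 else 8.6, 4))),
        rest_band_weights = w,
        task_modulation = m,
        attention_gain = gain), class = "subject_profile"))
    }
    structure(profiles, class = "doc_cohort")
  })
}

validate_profile <- function(p) {
  stopifnot(p$group %in% c("UWS", "MCS"),
            p$crs_r >= 0, p$crs_r <= 23,
            all(p$task_modulation > 0),
            p$attention_gain >= 0, p$attention_gain <= 1,
            all(abs(rowSums(p$rest_band_weights) - 1) < 1e-9))
  p
}

#' @export
print.doc_cohort <- function(x, ...) {
  tab <- table(vapply(x, `[[`, "", "group"))
  cat(sprintf("<doc_cohort> %d subjects (%s)\n", length(x),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Cohort metadata as a data.frame
#' @param cohort a `doc_cohort`.
#' @return data.frame with one row per subject.
#' @export
cohort_metadata <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p)
    data.frame(subject_id = p$subject_id, group = p$group, crs_r = p$crs_r,
               age = p$age, sex = p$sex,
               duration_months = p$duration_months,
               attention_gain = p$attention_gain,
               stringsAsFactors = FALSE)))
}

#' Simulate the latent attention time course of a session
#'
#' Each trial contributes a smooth attention bump peaking `latency_s`
#' seconds after cue onset with height equal to the subject's attention
#' gain; smoothed Gaussian noise is superimposed and the series is clipped
#' to \[0, 1\]. The series is defined on the attention-index hop grid and
#' drives the Fp1 beta/alpha ratio shift during task synthesis.
#'
#' @param profile a `subject_profile`.
#' @param plan a [session_plan()].
#' @param seed integer seed.
#' @param latency_s cue-onset-to-peak latency in seconds (delayed responses
#'   in this population motivate the 4 s default).
#' @param width_s Gaussian bump SD in seconds.
#' @param noise_sd SD of the additive smoothed noise.
#' @param hop_s time step of the returned grid.
#' @return data.frame with columns `time` (s) and `attention` in \[0, 1\];
#'   attribute `cue_onsets` gives the cue times in seconds.
#' @export
simulate_attention_trace <- function(profile, plan, seed = 1,
                                     latency_s = 4, width_s = 1.5,
                                     noise_sd = 0.05, hop_s = 0.5) {
  stopifnot(plan$n_trials >= 1)
  tt <- seq(0, session_length_s(plan), by = hop_s)
  onsets <- cue_onsets_s(plan)
  a <- numeric(length(tt))
  for (t0 in onsets)
    a <- a + profile$attention_gain *
      exp(-(tt - (t0 + latency_s))^2 / (2 * width_s^2))
  if (noise_sd > 0) {
    eps <- with_seed(derive_seed(seed, profile$subject_id, "atttrace"), {
      e <- rnorm(length(tt))
      as.numeric(stats::filter(e, rep(1 / 3, 3), sides = 2, circular = TRUE))
    })
    a <- a + noise_sd * eps
  }
  out <- data.frame(time = tt, attention = pmin(1, pmax(0, a)))
  attr(out, "cue_onsets") <- onsets
  out
}

# Cross-talk matrix of the full measurement chain: E[b, b'] = fraction of a
# band-b noise component's measured in-range Welch power that lands in
# band-b' bins. The chain (forward-backward band filter, broadband
# analysis filter, Hamming-window leakage, per-segment mean removal) is
# characterized empirically by pushing a long fixed-seed unit noise
# component through the package's own filters and Welch estimator, so the
# generator's variance allocation and the analyser agree by construction.
# Cached per sampling rate.
.crosstalk_cache <- new.env(parent = emptyenv())

band_crosstalk <- function(fs, bands = analysis_bands(), order = 6,
                           calib_s = 200) {
  key <- paste(fs, order, calib_s, paste(bands$f_low, collapse = ","),
               paste(bands$f_high, collapse = ","), sep = "|")
  if (!is.null(.crosstalk_cache[[key]])) return(.crosstalk_cache[[key]])
  fr <- attr(bands, "f_range")
  n <- as.integer(calib_s * fs)
  sos_bb <- butter_bandpass_sos(fr[1], fr[2], fs, order)
  nb <- nrow(bands)
  E <- matrix(0, nb, nb, dimnames = list(bands$band, bands$band))
  for (i in seq_len(nb)) {
    sos <- butter_bandpass_sos(bands$f_low[i], bands$f_high[i], fs, order)
    x <- .sosfiltfilt_mat(gauss_matrix(n, 1L, 770100 + i), sos,
                          as.integer(3 * fs))
    v1 <- mean(x^2) # component variance as scaled by the generator
    x <- .sosfiltfilt_mat(x, sos_bb, as.integer(3 * fs))
    r <- welch_psd_matrix(t(x), fs)
    psd <- structure(list(psd = r$psd, freq = r$freq,
                          channel_names = "calib"), class = "psd_result")
    bp <- band_power_matrix(psd, bands)
    # rows are measured in-range band powers per unit component variance,
    # so out-of-range leakage differences between bands are accounted for
    E[i, ] <- bp / v1
  }
  .crosstalk_cache[[key]] <- E
  E
}

# solve for per-component variances so measured band fractions match target
component_variances <- function(weights, E) {
  v <- try(solve(t(E), weights), silent = TRUE)
  if (inherits(v, "try-error") || any(v <= 0)) v <- weights
  v / sum(v)
}

#' Synthesize one multichannel EEG recording
#'
#' The signal is a sum of five band-limited noise components (white noise
#' shaped with the same Butterworth sections used by the preprocessing
#' stage) whose variances are chosen so the measured Welch relative power
#' per region matches the subject's resting weights; under the task
#' condition the weights switch to the renormalized product with the
#' task-modulation factors during cue windows, and the Fp1 beta/alpha
#' ratio is additionally shifted upward in proportion to the latent
#' attention trace. Ocular artifacts (frontal-dominant slow waves mirrored
#' on the EOG channel) and transient high-amplitude spikes are injected at
#' the requested rate.
#'
#' @param profile a `subject_profile`.
#' @param plan a [session_plan()].
#' @param condition `"rest"` or `"task"`.
#' @param artifact_rate transient spike events per minute (blinks occur at
#'   `blink_rate`).
#' @param seed integer seed; synthesis is bitwise deterministic given
#'   (profile, plan, seed).
#' @param blink_rate ocular artifact events per minute.
#' @param attention_args list of overrides passed to
#'   [simulate_attention_trace()].
#' @param rms_uv background per-channel RMS amplitude in microvolts (kept in
#'   the 10-30 range so the 75 uV screen is meaningful).
#' @param shift_max peak multiplicative shift of the Fp1 beta/alpha power
#'   ratio at full attention.
#' @return an [eeg_recording()] with cue events (task) and an `artifacts`
#'   attribute (data.frame: sample, type, channel, amplitude).
#' @export
synthesize_recording <- function(profile, plan, condition = c("rest", "task"),
                                 artifact_rate = 2, seed = 1,
                                 blink_rate = artifact_rate,
                                 attention_args = list(),
                                 rms_uv = 15, shift_max = 1.2) {
  condition <- match.arg(condition)
  bands <- analysis_bands()
  regions <- brain_regions()
  chans <- montage_channels()
  fs <- if (condition == "rest") plan$fs_rest else plan$fs_task
  dur <- if (condition == "rest") plan$rest_s else session_length_s(plan)
  n <- as.integer(round(dur * fs))

  region_of <- rep(names(regions), lengths(regions))
  names(region_of) <- unlist(regions, use.names = FALSE)
  region_of <- region_of[chans]

  E <- band_crosstalk(fs, bands)
  w_rest <- profile$rest_band_weights            # regions x bands
  v_rest <- t(apply(w_rest, 1, component_variances, E = E))
  w_task <- w_rest * profile$task_modulation
  w_task <- sweep(w_task, 1, rowSums(w_task), "/")
  v_task <- t(apply(w_task, 1, component_variances, E = E))

  # cue-window indicator on the sample grid
  cue_ind <- rep(FALSE, n)
  events <- NULL
  att <- NULL
  if (condition == "task") {
    onsets <- cue_onsets_s(plan)
    on_i <- pmin(n, as.integer(round(onsets * fs)) + 1L)
    off_i <- pmin(n, as.integer(round((onsets + plan$cue_s) * fs)))
    for (k in seq_along(on_i)) cue_ind[on_i[k]:off_i[k]] <- TRUE
    events <- data.frame(
      sample = c(on_i, off_i),
      label = rep(c("cue_on", "cue_off"), each = length(on_i)),
      stringsAsFactors = FALSE)
    events <- events[order(events$sample), , drop = FALSE]
    att <- do.call(simulate_attention_trace,
                   c(list(profile = profile, plan = plan, seed = seed),
                     attention_args))
    a_t <- approx(att$time, att$attention, xout = (seq_len(n) - 1) / fs,
                  rule = 2)$y
  }

  acc <- matrix(0, n, length(chans)) # samples x channels, transposed once
  margin <- as.integer(3 * fs) # generate-and-trim: no filter edge transients
  for (b in seq_len(nrow(bands))) {
    sos <- butter_bandpass_sos(bands$f_low[b], bands$f_high[b], fs)
    noise <- gauss_matrix(n + 2L * margin, length(chans),
                          derive_seed(seed, profile$subject_id,
                                      condition, "band", bands$band[b]))
    comp <- .sosfiltfilt_mat(noise, sos, 0L)
    comp <- comp[(margin + 1L):(margin + n), , drop = FALSE]
    # unit RMS per channel, then scale to the target component amplitude
    amp_rest <- rms_uv * sqrt(v_rest[region_of, b])
    comp <- sweep(comp, 2, amp_rest / sqrt(colMeans(comp^2)), "*")
    if (condition == "task") {
      amp_ratio <- sqrt(v_task[region_of, b] / v_rest[region_of, b])
      # the index channel is driven by the attention trace alone: regional
      # cue modulation would otherwise confound the beta/alpha ratio
      fp1 <- which(chans == "Fp1")
      amp_ratio[fp1] <- 1
      comp[cue_ind, ] <- sweep(comp[cue_ind, , drop = FALSE], 2,
                               amp_ratio, "*")
      if (bands$band[b] == "beta")
        comp[, fp1] <- comp[, fp1] * sqrt(1 + shift_max * a_t)
      if (bands$band[b] == "alpha")
        comp[, fp1] <- comp[, fp1] / sqrt(1 + shift_max * a_t)
    }
    acc <- acc + comp
  }
  data <- matrix(0, length(chans) + 1L, n,
                 dimnames = list(c(chans, "EOG"), NULL))
  data[seq_along(chans), ] <- t(acc)

  # EOG background: broadband low-amplitude noise
  eog_noise <- gauss_matrix(n, 1L, derive_seed(seed, profile$subject_id,
                                               condition, "eog"))
  data["EOG", ] <- 5 * drop(eog_noise)

  artifacts <- inject_artifacts(data, fs, artifact_rate, blink_rate,
                                derive_seed(seed, profile$subject_id,
                                            condition, "artifacts"),
                                avoid = if (condition == "task") cue_ind)
  rec <- eeg_recording(artifacts$data, fs,
                       channel_names = rownames(data),
                       condition = condition, events = events)
  attr(rec, "artifacts") <- artifacts$log
  if (!is.null(att)) attr(rec, "attention_trace") <- att
  rec
}

# blinks: frontal-dominant slow biphasic waves, mirrored (amplified) on EOG;
# spikes: short single-channel transients exceeding the 75 uV screen.
# During task sessions events are placed outside cue windows (`avoid`),
# emulating blink suppression during engaged imagery.
inject_artifacts <- function(data, fs, spike_rate, blink_rate, seed,
                             avoid = NULL) {
  n <- ncol(data)
  minutes <- n / fs / 60
  chans <- rownames(data)
  scalp <- setdiff(chans, "EOG")
  pos <- montage_positions()
  frontal_w <- exp(-((1 - pos$y[match(scalp, pos$channel)]) / 0.6)^2)
  log <- data.frame(sample = integer(0), type = character(0),
                    channel = character(0), amplitude = numeric(0),
                    stringsAsFactors = FALSE)
  draw_at <- function(width) {
    ok <- seq_len(n - width)
    if (!is.null(avoid)) {
      free <- ok[!avoid[ok]]
      if (length(free)) return(sample(free, 1))
    }
    sample(ok, 1)
  }
  with_seed(seed, {
    n_blink <- if (blink_rate > 0) stats::rpois(1, blink_rate * minutes) else 0L
    if (n_blink > 0) {
      width <- as.integer(round(0.35 * fs))
      shape <- sin(pi * seq_len(width) / width)^2
      for (k in seq_len(n_blink)) {
        at <- draw_at(width)
        amp <- runif(1, 120, 180)
        idx <- at:(at + width - 1L)
        data[scalp, idx] <- data[scalp, idx] +
          outer(frontal_w * amp, shape)
        data["EOG", idx] <- data["EOG", idx] + 2.5 * amp * shape
        log <- rbind(log, data.frame(sample = at + width %/% 2L,
                                     type = "blink", channel = "Fp1",
                                     amplitude = amp))
      }
    }
    n_spike <- if (spike_rate > 0) stats::rpois(1, spike_rate * minutes) else 0L
    if (n_spike > 0) {
      width <- max(3L, as.integer(round(0.04 * fs)))
      shape <- sin(pi * seq_len(width) / width)^2
      for (k in seq_len(n_spike)) {
        at <- draw_at(width)
        ch <- sample(scalp, 1)
        amp <- runif(1, 120, 180) * sample(c(-1, 1), 1)
        idx <- at:(at + width - 1L)
        data[ch, idx] <- data[ch, idx] + amp * shape
        log <- rbind(log, data.frame(sample = at + width %/% 2L,
                                     type = "spike", channel = ch,
                                     amplitude = amp))
      }
    }
    list(data = data, log = log)
  })
}
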