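# Preprocessing chain: bad-channel interpolation, ICA ocular-artifact
# attenuation, common average reference, 5-s epoch screening and the
# task/baseline SNR gauge. Filtering lives in filters.R.

#' Flag channels with deviant amplitude
#'
#' Automated surrogate for visual bad-channel marking: a channel is flagged
#' when its log RMS deviates from the montage median by more than
#' `threshold` robust SDs (MAD).
#'
#' @param rec an [eeg_recording()].
#' @param threshold robust-SD cutoff.
#' @return character vector of flagged scalp channel names.
#' @export
detect_bad_channels <- function(rec, threshold = 4) {
  x <- scalp_data(rec)
  lr <- log(sqrt(rowMeans(x^2)) + 1e-12)
  # MAD floored at 0.1 log units so a homogeneous montage does not flag
  # ordinary physiological variation (a flat or 3x-RMS channel still trips)
  dev <- abs(lr - median(lr)) / max(mad(lr), 0.1)
  names(dev)[dev > threshold]
}

#' Interpolate bad channels from their neighbours
#'
#' Flagged channels are replaced by inverse-squared-distance weighted
#' averages of the remaining good scalp channels (planar montage
#' coordinates); all other channels are untouched. More than 30% bad
#' channels is a subject-level processing failure.
#'
#' @param rec an [eeg_recording()].
#' @param bad character vector of channel names (e.g. from
#'   [detect_bad_channels()]); empty means identity.
#' @return the repaired recording, with attribute `interpolated`.
#' @export
interpolate_bad_channels <- function(rec, bad = detect_bad_channels(rec)) {
  bad <- intersect(bad, scalp_channels(rec))
  if (!length(bad)) {
    attr(rec, "interpolated") <- character(0)
    return(rec)
  }
  if (length(bad) >= 0.3 * 30)
    stop("too many bad channels (", length(bad), "): subject flagged")
  pos <- montage_positions()
  good <- setdiff(scalp_channels(rec), bad)
  for (ch in bad) {
    p0 <- pos[pos$channel == ch, ]
    pg <- pos[match(good, pos$channel), ]
    d2 <- (pg$x - p0$x)^2 + (pg$y - p0$y)^2
    w <- 1 / pmax(d2, 1e-6)
    w <- w / sum(w)
    rec$data[ch, ] <- as.numeric(w %*% rec$data[good, , drop = FALSE])
  }
  attr(rec, "interpolated") <- bad
  rec
}

# compact symmetric FastICA (tanh contrast) on a channels x samples matrix;
# returns unmixed sources and the mixing matrix, deterministic given seed
fastica_fit <- function(x, n_comp = nrow(x), seed = 1, max_iter = 200,
                        tol = 1e-6) {
  nch <- nrow(x)
  n <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_comp)
  K <- diag(1 / sqrt(pmax(eg$values[keep], 1e-12))) %*% t(eg$vectors[, keep])
  z <- K %*% xc
  W <- with_seed(seed, matrix(rnorm(n_comp^2), n_comp))
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(W)
  converged <- FALSE
  failed <- FALSE
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- rowMeans(1 - g^2)
    W1 <- try(sym_decor(tcrossprod(g, z) / n - diag(gp) %*% W),
              silent = TRUE)
    if (inherits(W1, "try-error") || any(!is.finite(W1))) {
      failed <- TRUE
      break
    }
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  unmix <- W %*% K                       # sources = unmix %*% (x - mu)
  mix <- eg$vectors[, keep] %*% diag(sqrt(pmax(eg$values[keep], 1e-12))) %*%
    t(W)                                 # x ~ mix %*% sources + mu
  list(sources = W %*% z, mixing = mix, unmixing = unmix, mean = mu,
       converged = converged, failed = failed)
}

#' Attenuate ocular artifacts by ICA
#'
#' Independent component analysis (symmetric FastICA, tanh contrast, seeded)
#' on the scalp channels; components whose absolute correlation with the
#' EOG reference exceeds `cor_threshold` are zeroed before back-projection.
#' Channel count and rank are preserved. If the ICA iteration does not
#' converge the function falls back to channel-wise EOG regression and
#' records that in the result.
#'
#' @param rec an [eeg_recording()] with at least 60 s of data.
#' @param eog name of the EOG reference channel in the recording.
#' @param cor_threshold absolute source-EOG correlation above which a
#'   component is removed.
#' @param seed integer seed for the ICA initialisation.
#' @return the cleaned recording; attributes `ica_removed` (number of
#'   zeroed components) and `ica_method` (`"ica"` or `"regression"`).
#' @export
attenuate_artifacts_ica <- function(rec, eog = "EOG", cor_threshold = 0.7,
                                    seed = 1) {
  if (!eog %in% rec$channel_names) stop("EOG reference channel not found")
  if (ncol(rec$data) < 60 * rec$fs)
    warning("less than 60 s of data: ICA estimates may be unstable")
  x <- scalp_data(rec)
  e <- rec$data[eog, ]
  fit <- fastica_fit(x, seed = seed)
  # With near-Gaussian background rhythms the global rotation need not
  # settle (the Gaussian subspace has no ICA contrast), which is harmless:
  # back-projection only depends on the removed (non-Gaussian, EOG-locked)
  # components. Regression on the EOG reference is the fallback for
  # numerical failure only.
  if (fit$failed) {
    beta <- as.numeric(x %*% e) / sum(e^2)
    rec$data[rownames(x), ] <- x - outer(beta, e)
    attr(rec, "ica_removed") <- NA_integer_
    attr(rec, "ica_method") <- "regression"
    return(rec)
  }
  r <- abs(apply(fit$sources, 1, cor, y = e))
  drop_i <- which(r > cor_threshold)
  if (length(drop_i)) {
    src <- fit$sources
    src[drop_i, ] <- 0
    rec$data[rownames(x), ] <- fit$mixing %*% src + fit$mean
  }
  attr(rec, "ica_removed") <- length(drop_i)
  attr(rec, "ica_method") <- "ica"
  rec
}

#' Common average reference
#'
#' Subtracts the instantaneous mean of the 30 scalp channels from each
#' scalp channel; non-EEG channels (EOG) are excluded from the average and
#' left untouched. After referencing, the scalp-channel mean is zero at
#' every sample.
#'
#' @param rec an [eeg_recording()].
#' @return the re-referenced recording.
#' @export
rereference_car <- function(rec) {
  sc <- scalp_channels(rec)
  avg <- colMeans(rec$data[sc, , drop = FALSE])
  rec$data[sc, ] <- sweep(rec$data[sc, , drop = FALSE], 2, avg)
  rec
}

#' Segment into 5-s epochs and reject high-amplitude segments
#'
#' Non-overlapping windows of `window_s` seconds; an epoch is rejected iff
#' any scalp-channel sample within it exceeds `threshold_uv` microvolts in
#' absolute value. A recording whose epochs are all rejected is a
#' subject-level quality failure, reported in the result rather than
#' raised.
#'
#' @param rec an [eeg_recording()].
#' @param window_s epoch length in seconds.
#' @param threshold_uv amplitude rejection threshold in microvolts.
#' @return an `epoch_set`: list with `data` (channels x samples x epochs,
#'   scalp channels only), `fs`, `keep` logical vector, `reason`,
#'   `condition`, `channel_names`.
#' @export
epoch_and_reject <- function(rec, window_s = 5, threshold_uv = 75) {
  ns <- as.integer(round(window_s * rec$fs))
  if (ncol(rec$data) < ns) stop("recording shorter than one epoch window")
  x <- scalp_data(rec)
  n_ep <- ncol(x) %/% ns
  dat <- array(x[, seq_len(n_ep * ns)], dim = c(nrow(x), ns, n_ep),
               dimnames = list(rownames(x), NULL, NULL))
  peak <- apply(abs(dat), 3, max)
  keep <- peak <= threshold_uv
  structure(list(data = dat, fs = rec$fs, keep = keep,
                 reason = ifelse(keep, "", "amplitude"),
                 condition = rec$condition, window_s = window_s,
                 threshold_uv = threshold_uv,
                 channel_names = rownames(x)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s: %d epochs of %g s (%d kept, %d rejected)\n",
              x$condition, length(x$keep), x$window_s, sum(x$keep),
              sum(!x$keep)))
  invisible(x)
}

#' Task/baseline signal-to-noise ratio in the 8-30 Hz band
#'
#' SNR_dB = 10 log10 of the ratio of mean 8-30 Hz Welch power during cue
#' (task) windows to that during the pre-stimulus baseline windows, with
#' power averaged over all scalp channels and windows.
#'
#' @param rec a task [eeg_recording()] with `cue_on` events.
#' @param baseline_s baseline window length (seconds immediately before
#'   each cue onset).
#' @param task_s task window length (seconds from cue onset); defaults to
#'   the gap to the next event or 5 s.
#' @param band frequency band in Hz.
#' @param screen_uv when given, windows containing any sample above this
#'   amplitude are excluded (the post-cleaning SNR is conventionally
#'   computed after the bad-segment screen; the raw SNR is not).
#' @return a list with `snr_db`, `task_power`, `baseline_power`,
#'   `n_windows` (task/baseline windows used).
#' @export
compute_snr <- function(rec, baseline_s = 4, task_s = 5, band = c(8, 30),
                        screen_uv = NULL) {
  on <- event_samples(rec, "cue_on")
  if (!length(on)) stop("no cue_on events: cannot compute task SNR")
  fs <- rec$fs
  x <- scalp_data(rec)
  nb <- as.integer(round(baseline_s * fs))
  nt <- as.integer(round(task_s * fs))
  bp <- function(idx) {
    if (!is.null(screen_uv) && max(abs(x[, idx])) > screen_uv)
      return(NA_real_)
    r <- welch_psd_matrix(x[, idx, drop = FALSE], fs)
    sel <- r$freq >= band[1] & r$freq < band[2]
    mean(rowSums(r$psd[, sel, drop = FALSE]))
  }
  tp <- bs <- numeric(0)
  for (s in on) {
    if (s - nb >= 1) bs <- c(bs, bp((s - nb):(s - 1)))
    if (s + nt - 1 <= ncol(x)) tp <- c(tp, bp(s:(s + nt - 1)))
  }
  tp <- tp[!is.na(tp)]
  bs <- bs[!is.na(bs)]
  if (!length(tp) || !length(bs))
    stop("events leave no usable task/baseline windows")
  list(snr_db = 10 * log10(mean(tp) / mean(bs)),
       task_power = mean(tp), baseline_power = mean(bs),
       n_windows = c(task = length(tp), baseline = length(bs)))
}

#' Run the full preprocessing chain on one recording
#'
#' Fixed stage order: broadband filter and notch, bad-channel
#' interpolation, ICA ocular-artifact attenuation (optional), common
#' average reference, epoch segmentation with the 75 uV screen. Sub-band
#' decomposition is available separately via [decompose_bands()]. For task
#' recordings with cue events the 8-30 Hz SNR is computed before and after
#' artifact attenuation.
#'
#' @param rec an [eeg_recording()].
#' @param ica run the ICA stage (requires an EOG channel).
#' @param ica_seed seed for the ICA initialisation.
#' @param window_s,threshold_uv epoch screen parameters.
#' @param snr compute the 8-30 Hz task/baseline SNR before and after
#'   artifact attenuation (task recordings with cue events only).
#' @return list with `rec` (cleaned continuous recording), `epochs`
#'   (an `epoch_set`) and `qc` (bad channels, components removed, epochs
#'   kept/rejected, SNR before/after, stage order).
#' @export
preprocess_recording <- function(rec, ica = TRUE, ica_seed = 1,
                                 window_s = 5, threshold_uv = 75,
                                 snr = TRUE) {
  out <- bandpass_and_notch(rec)
  snr_pre <- snr_post <- NA_real_
  has_cues <- snr && length(event_samples(rec, "cue_on")) > 0
  if (has_cues) snr_pre <- compute_snr(out)$snr_db
  out <- interpolate_bad_channels(out)
  bad <- attr(out, "interpolated")
  removed <- 0L
  method <- "none"
  if (ica && "EOG" %in% out$channel_names) {
    out <- attenuate_artifacts_ica(out, seed = ica_seed)
    removed <- attr(out, "ica_removed")
    method <- attr(out, "ica_method")
  }
  if (has_cues)
    snr_post <- tryCatch(
      compute_snr(out, screen_uv = threshold_uv)$snr_db,
      error = function(e) NA_real_)
  out <- rereference_car(out)
  epochs <- epoch_and_reject(out, window_s, threshold_uv)
  list(rec = out, epochs = epochs,
       qc = list(bad_channels = bad, ica_removed = removed,
                 ica_method = method,
                 epochs_kept = sum(epochs$keep),
                 epochs_rejected = sum(!epochs$keep),
                 all_rejected = !any(epochs$keep),
                 snr_pre_db = snr_pre, snr_post_db = snr_post,
                 stage_order = paste("filter", "interpolate", "ica", "car",
                                     "epoch", sep = " -> ")))
}
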