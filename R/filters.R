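# Butterworth band-pass design as second-order sections and zero-phase
# application. The transfer-function (b, a) form of a 12-pole band-pass is
# numerically unstable for the narrow 1-4 Hz band at 500 Hz, so the filter
# is designed and applied as a cascade of biquads.

#' Design a Butterworth band-pass filter as second-order sections
#'
#' An order-`n` Butterworth band-pass design (2n poles: analog low-pass
#' prototype, low-pass-to-band-pass transform, bilinear mapping), returned
#' as a biquad cascade. The default `order = 6` gives the 12-pole filter
#' conventionally reported as a "6th-order Butterworth band-pass".
#'
#' @param f_lo,f_hi band edges in Hz.
#' @param fs sampling rate in Hz; requires `f_hi < fs / 2`.
#' @param order design order (number of prototype poles).
#' @return numeric matrix with `order` rows and columns
#'   `b0 b1 b2 a0 a1 a2` (`a0 = 1`).
#' @export
butter_bandpass_sos <- function(f_lo, f_hi, fs, order = 6) {
  stopifnot(f_lo > 0, f_hi > f_lo, fs > 2 * f_hi, order >= 1)
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * f_lo / fs)
  w2 <- fs2 * tan(pi * f_hi / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # LHP prototype poles
  q <- proto * bw
  disc <- sqrt(q^2 - 4 * w0^2)
  s_poles <- c((q + disc) / 2, (q - disc) / 2)
  z_poles <- (fs2 + s_poles) / (fs2 - s_poles)
  # pair poles into conjugate biquads
  cplx <- z_poles[Im(z_poles) > 1e-9]
  real_p <- sort(Re(z_poles[abs(Im(z_poles)) <= 1e-9]))
  sections <- list()
  for (p in cplx)
    sections[[length(sections) + 1L]] <- c(1, -2 * Re(p), Mod(p)^2)
  if (length(real_p)) {
    stopifnot(length(real_p) %% 2 == 0)
    for (i in seq(1, length(real_p), by = 2)) {
      p1 <- real_p[i]; p2 <- real_p[i + 1]
      sections[[length(sections) + 1L]] <- c(1, -(p1 + p2), p1 * p2)
    }
  }
  stopifnot(length(sections) == order)
  sos <- do.call(rbind, lapply(sections, function(a) c(1, 0, -1, a)))
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  # unity gain at the (digital) centre frequency, distributed across sections
  f0 <- fs / pi * atan(w0 / fs2)
  g <- 1 / abs(sos_response(sos, f0, fs))
  sos[, 1:3] <- sos[, 1:3] * g^(1 / order)
  sos
}

#' Design a biquad notch filter
#'
#' Standard constrained-zero IIR notch (zeros on the unit circle at the
#' notch frequency), used for 50 Hz line-noise suppression.
#'
#' @param f0 notch frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param bw -3 dB bandwidth in Hz.
#' @return a 1 x 6 second-order-section matrix.
#' @export
notch_sos <- function(f0, fs, bw = 2) {
  stopifnot(f0 > 0, f0 < fs / 2, bw > 0)
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) * sinh(log(2) / 2 * (bw / f0) * w0 / sin(w0))
  a0 <- 1 + alpha
  sos <- matrix(c(1 / a0, -2 * cos(w0) / a0, 1 / a0,
                  1, -2 * cos(w0) / a0, (1 - alpha) / a0), nrow = 1)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  sos
}

# complex frequency response of an SOS cascade at frequencies f (Hz)
sos_response <- function(sos, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * z + sos[s, 3] * z^2
    den <- sos[s, 4] + sos[s, 5] * z + sos[s, 6] * z^2
    h <- h * num / den
  }
  unname(h)
}

#' Zero-phase filtering with a second-order-section cascade
#'
#' Forward-backward application (no phase distortion, squared magnitude
#' response) with odd-symmetric edge extension and steady-state initial
#' conditions per biquad.
#'
#' @param x numeric vector or samples x channels matrix.
#' @param sos second-order-section matrix (`n x 6`).
#' @param padlen edge-extension length in samples; default 3 s worth capped
#'   at the signal length.
#' @param fs sampling rate (only used for the default `padlen`).
#' @return filtered data, same shape as `x`.
#' @export
sos_filtfilt <- function(x, sos, fs = NULL, padlen = NULL) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  if (is.null(padlen))
    padlen <- if (is.null(fs)) min(nrow(xm) - 1L, 1000L)
              else min(nrow(xm) - 1L, as.integer(3 * fs))
  out <- .sosfiltfilt_mat(xm, sos, as.integer(padlen))
  if (vec) drop(out) else out
}

#' Broadband band-pass and line-notch filtering
#'
#' The first preprocessing stage: 1-45 Hz Butterworth band-pass (order-6
#' design, biquad cascade) followed by a 50 Hz notch, both applied
#' forward-backward so event latencies are preserved. All channels
#' (including EOG) are filtered.
#'
#' @param rec an [eeg_recording()].
#' @param f_lo,f_hi broadband edges in Hz.
#' @param order Butterworth design order.
#' @param notch notch frequency in Hz (`NULL` to skip).
#' @param notch_bw notch bandwidth in Hz.
#' @return the filtered recording.
#' @export
bandpass_and_notch <- function(rec, f_lo = 1, f_hi = 45, order = 6,
                               notch = 50, notch_bw = 2) {
  if (rec$fs <= 2 * f_hi)
    stop("sampling rate too low for the ", f_hi, " Hz band edge")
  sos <- butter_bandpass_sos(f_lo, f_hi, rec$fs, order)
  if (!is.null(notch) && notch < rec$fs / 2)
    sos <- rbind(sos, notch_sos(notch, rec$fs, notch_bw))
  out <- t(sos_filtfilt(t(rec$data), sos, fs = rec$fs))
  replace_data(rec, out)
}

#' Decompose a recording into the five analysis sub-bands
#'
#' One band-limited copy of the recording per band, filtered with the same
#' Butterworth design used for the broadband stage so generator and
#' analyser agree on band edges.
#'
#' @param rec a broadband-filtered [eeg_recording()].
#' @param bands an [analysis_bands()] set.
#' @param order Butterworth design order.
#' @return named list of `eeg_recording` objects, one per band.
#' @export
decompose_bands <- function(rec, bands = analysis_bands(), order = 6) {
  out <- lapply(seq_len(nrow(bands)), function(i) {
    sos <- butter_bandpass_sos(bands$f_low[i], bands$f_high[i], rec$fs, order)
    replace_data(rec, t(sos_filtfilt(t(rec$data), sos, fs = rec$fs)))
  })
  names(out) <- bands$band
  out
}
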