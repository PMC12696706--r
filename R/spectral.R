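# Welch power spectral density with 500 ms Hamming windows, 250 ms overlap,
# and relative band power aggregated by cortical region.

hamming_window <- function(L) 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))

# modified periodograms of all sliding segments of a samples x channels
# matrix; returns list(freq, pgram = nfreq x nseg x nch array-ish matrix,
# starts). One-sided density scaling: integrating over frequency recovers
# the windowed signal variance.
welch_periodograms <- function(x, fs, window_s = 0.5, overlap_s = 0.25,
                               nfft_factor = 8, detrend = "none") {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  L <- as.integer(round(window_s * fs))
  hop <- L - as.integer(round(overlap_s * fs))
  stopifnot(L >= 8, hop >= 1)
  n <- nrow(x)
  if (n < L) stop("signal shorter than one Welch window")
  nch <- ncol(x)
  starts <- seq.int(1L, n - L + 1L, by = hop)
  nseg <- length(starts)
  w <- hamming_window(L)
  U <- fs * sum(w^2)
  nfft <- nfft_factor * L
  seg <- matrix(0, nfft, nseg * nch)
  idx <- outer(seq_len(L) - 1L, starts, "+") # L x nseg gather index
  for (c in seq_len(nch)) {
    m <- matrix(x[, c][idx], L, nseg)
    if (detrend == "constant")
      m <- m - rep(colMeans(m), each = L)
    seg[seq_len(L), ((c - 1L) * nseg + 1L):(c * nseg)] <- m * w
  }
  X <- mvfft(seg)
  nfreq <- nfft %/% 2L + 1L
  P <- (Mod(X[seq_len(nfreq), , drop = FALSE])^2) / U
  P[2:(nfreq - 1L), ] <- 2 * P[2:(nfreq - 1L), , drop = FALSE]
  list(freq = (seq_len(nfreq) - 1L) * fs / nfft, pgram = P,
       starts = starts, nseg = nseg, nch = nch, L = L, hop = hop,
       nfft = nfft)
}

# average periodograms -> channels x nfreq PSD matrix
average_pgram <- function(pg) {
  psd <- matrix(0, pg$nch, length(pg$freq))
  for (c in seq_len(pg$nch)) {
    cols <- ((c - 1L) * pg$nseg + 1L):(c * pg$nseg)
    psd[c, ] <- rowMeans(pg$pgram[, cols, drop = FALSE])
  }
  psd
}

# Welch PSD of one channels x samples matrix
welch_psd_matrix <- function(x, fs, window_s = 0.5, overlap_s = 0.25,
                             nfft_factor = 8, detrend = "none") {
  pg <- welch_periodograms(t(x), fs, window_s, overlap_s, nfft_factor,
                           detrend)
  list(freq = pg$freq, psd = average_pgram(pg))
}

#' Welch power spectral density of an epoch set
#'
#' Modified periodograms from 500 ms Hamming windows with 250 ms (50%)
#' overlap, averaged within each kept epoch and then across epochs with
#' equal weights. The FFT is zero-padded to a 0.25 Hz grid so band-edge
#' bin assignment tracks the analytic bandwidth fractions. One-sided
#' density scaling (power per Hz): summing `psd * df` recovers the signal
#' variance. Per-segment mean removal is available but off by default:
#' the broadband 1 Hz high-pass already enforces zero mean, and removing
#' the mean of a 500 ms segment attenuates genuine 1-2 Hz delta content
#' (the window is shorter than one delta period).
#'
#' @param epochs an [epoch_and_reject()] result (only kept epochs enter).
#' @param window_s,overlap_s Welch window length and overlap in seconds.
#' @param nfft_factor zero-padding factor (FFT length = factor x window).
#' @param detrend `"none"` (default) or `"constant"` (per-segment mean
#'   removal).
#' @return a `psd_result`: list with `psd` (channels x frequencies,
#'   microvolts squared per Hz), `freq` (Hz), channel names and metadata.
#' @export
welch_psd <- function(epochs, window_s = 0.5, overlap_s = 0.25,
                      nfft_factor = 8, detrend = "none") {
  keep <- which(epochs$keep)
  if (!length(keep)) stop("no kept epochs: subject fails quality screen")
  acc <- NULL
  freq <- NULL
  nch <- dim(epochs$data)[1]
  for (e in keep) {
    m <- matrix(epochs$data[, , e], nrow = nch)
    r <- welch_psd_matrix(m, epochs$fs, window_s,
                          overlap_s, nfft_factor, detrend)
    freq <- r$freq
    acc <- if (is.null(acc)) r$psd else acc + r$psd
  }
  structure(list(psd = acc / length(keep), freq = freq,
                 fs = epochs$fs, window_s = window_s,
                 overlap_s = overlap_s, nfft_factor = nfft_factor,
                 detrend = detrend, n_epochs = length(keep),
                 channel_names = epochs$channel_names),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("<psd_result> %d channels, %d frequency bins (0-%g Hz, df=%g), %d epochs\n",
              nrow(x$psd), length(x$freq), max(x$freq),
              x$freq[2] - x$freq[1], x$n_epochs))
  invisible(x)
}

# band power per channel: half-open bins [f1, f2), top band closed at f_H
band_power_matrix <- function(psd, bands) {
  nb <- nrow(bands)
  out <- matrix(0, nrow(psd$psd), nb,
                dimnames = list(psd$channel_names, bands$band))
  for (j in seq_len(nb)) {
    sel <- if (j == nb)
      psd$freq >= bands$f_low[j] & psd$freq <= bands$f_high[j]
    else
      psd$freq >= bands$f_low[j] & psd$freq < bands$f_high[j]
    if (!any(sel)) stop("frequency grid does not cover band ", bands$band[j])
    out[, j] <- rowSums(psd$psd[, sel, drop = FALSE])
  }
  out
}

#' Relative band power by cortical region
#'
#' Per channel, band power is the sum of PSD bins with `f1 <= f < f2` (the
#' top band closed at 45 Hz) and relative power is band power divided by
#' total power over the 1-45 Hz analysis range; region values are unweighted
#' means of the region's channels, so the five band values sum to one for
#' every region.
#'
#' @param psd a [welch_psd()] result.
#' @param bands an [analysis_bands()] set.
#' @param regions a [brain_regions()] map.
#' @return data.frame with columns `region`, `band`, `rel_power`; attribute
#'   `channel` holds the channels x bands relative-power matrix.
#' @export
relative_power <- function(psd, bands = analysis_bands(),
                           regions = brain_regions()) {
  bp <- band_power_matrix(psd, bands)
  rel <- bp / rowSums(bp)
  rows <- expand.grid(band = bands$band, region = names(regions),
                      stringsAsFactors = FALSE)[, 2:1]
  rows$rel_power <- mapply(function(rg, bd) {
    chs <- intersect(regions[[rg]], rownames(rel))
    mean(rel[chs, bd])
  }, rows$region, rows$band)
  attr(rows, "channel") <- rel
  rows
}

#' Channel-resolved relative power for topographic maps
#'
#' The 30 x 5 per-channel relative-power table with planar 10-10 montage
#' coordinates attached, ready to be written as CSV for external plotting
#' (no rendering is done here).
#'
#' @param psd a [welch_psd()] result.
#' @param bands an [analysis_bands()] set.
#' @param file optional path; when given the table is written as CSV.
#' @return data.frame: `channel`, `x`, `y`, then one column per band;
#'   band columns sum to 1 within each row.
#' @export
export_topography <- function(psd, bands = analysis_bands(), file = NULL) {
  bp <- band_power_matrix(psd, bands)
  scalp <- intersect(montage_channels(), rownames(bp))
  rel <- bp[scalp, , drop = FALSE] / rowSums(bp[scalp, , drop = FALSE])
  pos <- montage_positions()
  out <- data.frame(channel = scalp,
                    x = pos$x[match(scalp, pos$channel)],
                    y = pos$y[match(scalp, pos$channel)],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(rel))
  rownames(out) <- NULL
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
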