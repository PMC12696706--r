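#' The five analysis frequency bands
#'
#' Canonical EEG sub-bands used throughout the package: delta (1-4 Hz),
#' theta (4-8 Hz), alpha (8-15 Hz), beta (15-30 Hz) and gamma (30-45 Hz),
#' which tile the broadband analysis range \[1, 45\] Hz exactly. Band edges
#' are configurable because reported alpha/beta boundaries vary between
#' studies (13 vs 15 Hz); the defaults follow the 8-15/15-30 convention.
#'
#' @param edges numeric vector of band boundaries, strictly increasing,
#'   length 6 (five contiguous bands).
#' @param names band names, length 5.
#' @return a `band_set`: data.frame with columns `band`, `f_low`, `f_high`,
#'   and attributes `f_range` (the broadband range).
#' @export
#' @examples
#' analysis_bands()
analysis_bands <- function(edges = c(1, 4, 8, 15, 30, 45),
                           names = c("delta", "theta", "alpha", "beta", "gamma")) {
  stopifnot(length(edges) == 6, all(diff(edges) > 0), length(names) == 5)
  bs <- data.frame(band = names,
                   f_low = edges[-6],
                   f_high = edges[-1],
                   stringsAsFactors = FALSE)
  attr(bs, "f_range") <- c(edges[1], edges[6])
  class(bs) <- c("band_set", "data.frame")
  bs
}

#' @export
print.band_set <- function(x, ...) {
  cat("EEG band set over [", attr(x, "f_range")[1], ",",
      attr(x, "f_range")[2], "] Hz\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' The 30-channel 10-10 scalp montage
#'
#' Channel names of the 30 scalp electrodes, in a fixed order (frontal,
#' central/parietal, temporal, occipital). `T3/T4/T5/T6` are the classic
#' names for the temporal row (modern `T7/T8/P7/P8`).
#'
#' @return character vector of 30 channel names.
#' @export
montage_channels <- function() {
  c("Fp1", "Fp2", "F3", "F4", "Fz", "FC3", "FC4", "FCz", "F7", "F8",
    "FT7", "FT8",
    "C3", "C4", "Cz", "CP3", "CP4", "CPz", "P3", "P4", "Pz",
    "T3", "T4", "TP7", "TP8", "T5", "T6",
    "O1", "O2", "Oz")
}

#' Planar electrode coordinates for the montage
#'
#' Approximate 2-D positions on the unit head disc (nose up), used for
#' neighbour-weighted bad-channel interpolation and for the topography
#' export. Derived from the standard 10-10 angular layout.
#'
#' @return data.frame with columns `channel`, `x`, `y`.
#' @export
montage_positions <- function() {
  # (radius, angle in degrees from +y axis, clockwise positive to the right)
  pol <- c(
    Fp1 = "0.95,-18", Fp2 = "0.95,18",
    F3 = "0.56,-39", F4 = "0.56,39", Fz = "0.48,0",
    FC3 = "0.33,-59", FC4 = "0.33,59", FCz = "0.24,0",
    F7 = "0.95,-54", F8 = "0.95,54",
    FT7 = "0.95,-72", FT8 = "0.95,72",
    C3 = "0.48,-90", C4 = "0.48,90", Cz = "0,0",
    CP3 = "0.33,-121", CP4 = "0.33,121", CPz = "0.24,180",
    P3 = "0.56,-141", P4 = "0.56,141", Pz = "0.48,180",
    T3 = "0.95,-90", T4 = "0.95,90",
    TP7 = "0.95,-108", TP8 = "0.95,108",
    T5 = "0.95,-126", T6 = "0.95,126",
    O1 = "0.95,-162", O2 = "0.95,162", Oz = "0.95,180")
  parts <- do.call(rbind, lapply(strsplit(unname(pol), ","), as.numeric))
  ang <- parts[, 2] * pi / 180
  out <- data.frame(channel = names(pol),
                    x = parts[, 1] * sin(ang),
                    y = parts[, 1] * cos(ang),
                    stringsAsFactors = FALSE)
  out[match(montage_channels(), out$channel), , drop = FALSE]
}

#' The four cortical region groups
#'
#' Region-of-interest grouping of the 30 scalp channels into frontal,
#' parietal (sensorimotor/centro-parietal), temporal and occipital sets.
#' The four groups are disjoint and cover the montage exactly.
#'
#' @return named list of character vectors.
#' @export
#' @examples
#' lengths(brain_regions())
brain_regions <- function() {
  list(
    frontal  = c("Fp1", "Fp2", "F3", "F4", "Fz", "FC3", "FC4", "FCz",
                 "F7", "F8", "FT7", "FT8"),
    parietal = c("C3", "C4", "Cz", "CP3", "CP4", "CPz", "P3", "P4", "Pz"),
    temporal = c("T3", "T4", "TP7", "TP8", "T5", "T6"),
    occipital = c("O1", "O2", "Oz"))
}

# internal sanity check used by validators
check_region_map <- function(regions = brain_regions()) {
  all_ch <- unlist(regions, use.names = FALSE)
  if (anyDuplicated(all_ch)) stop("region groups overlap")
  if (!setequal(all_ch, montage_channels()) || length(all_ch) != 30)
    stop("region groups must partition the 30-channel montage")
  invisible(TRUE)
}
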