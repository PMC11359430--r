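# Preprocessing: local-maxima peak detection, peak-anchored segmentation to a
# fixed sample count, and normalization. Indices are 1-based at the R
# surface; segments are pure slices so sample values pass through bit-exact.

#' Detect pulse peaks in a PPG record
#'
#' Local maxima filtered by a minimum inter-peak distance and a minimum
#' prominence expressed as a fraction of the signal range, so detection is
#' invariant to positive affine rescaling of the waveform. The distance and
#' prominence defaults (0.3 s, 10%) reject dicrotic lobes at plausible heart
#' rates.
#'
#' @param record A [ppg_record()] or numeric vector (then `fs_hz` is used).
#' @param min_distance_s Minimum separation between accepted peaks, seconds.
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   signal range (max - min).
#' @param fs_hz Sampling rate, only used when `record` is a bare vector.
#' @return Integer vector of 1-based peak sample indices, strictly
#'   increasing; empty for a flat signal.
#' @examples
#' x <- sin(2 * pi * seq(0, 10, by = 1 / 125))
#' length(detect_peaks(ppg_record(x, 125))) # ~10 peaks
#' @export
detect_peaks <- function(record, min_distance_s = 0.3, prominence_frac = 0.1,
                         fs_hz = NULL) {
  if (inherits(record, "ppg_record")) {
    x <- record$samples
    fs <- record$fs_hz
  } else {
    x <- as.numeric(record)
    fs <- if (is.null(fs_hz)) 125 else fs_hz
  }
  n <- length(x)
  if (n == 0L) stop_invalid("record must be non-empty")
  rng <- max(x) - min(x)
  if (rng == 0) return(integer(0))

  # strict local maxima (plateau interiors excluded; plateau edges count if
  # strictly above both outer neighbours)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[x[cand] > x[cand - 1L] & x[cand] > x[cand + 1L]]
  if (!length(cand)) return(integer(0))

  # prominence relative to the signal range: height above the higher of the
  # two key saddles (deepest valley between the peak and the nearest higher
  # peak, or the record edge). Computed from candidate peaks and the signal
  # minima in the gaps between them, so cost is O(n + k^2) not O(n * k).
  k <- length(cand)
  bounds <- c(1L, cand, n)
  gap_min <- vapply(seq_len(k + 1L), function(j) {
    min(x[seq.int(bounds[j], bounds[j + 1L])])
  }, numeric(1))
  h <- x[cand]
  prom <- vapply(seq_len(k), function(i) {
    m <- gap_min[i]                     # walk left to the nearest higher peak
    j <- i - 1L
    while (j >= 1L && h[j] <= h[i]) {
      m <- min(m, gap_min[j])
      j <- j - 1L
    }
    base_l <- m
    m <- gap_min[i + 1L]                # walk right likewise
    j <- i + 1L
    while (j <= k && h[j] <= h[i]) {
      m <- min(m, gap_min[j + 1L])
      j <- j + 1L
    }
    h[i] - max(base_l, m)
  }, numeric(1))
  cand <- cand[prom >= prominence_frac * rng]
  if (!length(cand)) return(integer(0))

  # greedy minimum-distance enforcement, highest peaks first
  min_dist <- round(min_distance_s * fs)
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Segmentation configuration
#'
#' @param n_points Number of samples per segment (default 15000 = 2 min at
#'   125 Hz).
#' @param anchor Anchoring rule; only `"first_peak"` is defined.
#' @param normalization Normalization mode applied after segmentation.
#' @return An object of class `segment_config`.
#' @export
segment_config <- function(n_points = 15000L,
                           anchor = "first_peak",
                           normalization = c("minmax", "zscore")) {
  normalization <- match.arg(normalization)
  anchor <- match.arg(anchor, "first_peak")
  if (!is_count(n_points, min = 2L)) stop_invalid("n_points must be >= 2")
  structure(list(n_points = as.integer(n_points), anchor = anchor,
                 normalization = normalization),
            class = "segment_config")
}

#' Extract a fixed-length segment starting at the first detected peak
#'
#' The returned segment starts exactly at the first detected peak and
#' contains exactly `cfg$n_points` samples (a pure slice: values are
#' propagated bit-exactly). Sampling rate and rhythm label are preserved.
#'
#' @param record A [ppg_record()].
#' @param cfg A [segment_config()].
#' @param ... Passed to [detect_peaks()].
#' @return A [ppg_record()] of length `cfg$n_points`.
#' @export
segment_from_peak <- function(record, cfg = segment_config(), ...) {
  if (!inherits(record, "ppg_record")) stop_invalid("record must be a ppg_record")
  peaks <- detect_peaks(record, ...)
  if (!length(peaks)) stop_invalid("no detectable peak in record '",
                                   record$record_id, "'")
  start <- peaks[1L]
  avail <- length(record$samples) - start + 1L
  if (avail < cfg$n_points) {
    stop_invalid(sprintf(
      "record '%s' too short: %d samples required from first peak, %d available",
      record$record_id, cfg$n_points, avail))
  }
  seg <- record$samples[seq.int(start, start + cfg$n_points - 1L)]
  out <- record
  out$samples <- seg
  out
}

#' Normalize a sample vector
#'
#' `"minmax"` maps the range exactly onto \[0, 1\]; `"zscore"` centres to
#' mean 0 and scales to unit standard deviation (n-1 convention).
#'
#' @param samples Non-empty numeric vector.
#' @param mode `"minmax"` or `"zscore"`.
#' @return Normalized numeric vector of the same length.
#' @examples
#' normalize_signal(c(0, 5, 10))            # 0, 0.5, 1
#' normalize_signal(c(1, 2, 3), "zscore")   # -1, 0, 1
#' @export
normalize_signal <- function(samples, mode = c("minmax", "zscore")) {
  mode <- match.arg(mode)
  x <- as.numeric(samples)
  if (!length(x)) stop_invalid("samples must be non-empty")
  if (!all(is.finite(x))) stop_invalid("samples must be finite")
  if (mode == "minmax") {
    lo <- min(x)
    hi <- max(x)
    if (hi == lo) stop_invalid("cannot min-max normalize a constant vector")
    (x - lo) / (hi - lo)
  } else {
    s <- stats::sd(x)
    if (s == 0) stop_invalid("cannot z-score a constant vector")
    (x - mean(x)) / s
  }
}

#' Preprocess a record: segment from the first peak, then normalize
#'
#' @param record A [ppg_record()].
#' @param cfg A [segment_config()].
#' @param ... Passed to [detect_peaks()].
#' @return A [ppg_record()] of length `cfg$n_points`, normalized per
#'   `cfg$normalization`.
#' @export
preprocess_record <- function(record, cfg = segment_config(), ...) {
  seg <- segment_from_peak(record, cfg, ...)
  seg$samples <- normalize_signal(seg$samples, cfg$normalization)
  seg
}
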