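# Power-normalized Gammatone feature extraction.
#
# Chain: per-IMF framed power spectra -> sum over selected IMFs ->
# Gammatone filterbank energies -> division by the record's mean band power
# -> power-law compression (exponent in (0,1)) -> optional DCT. Because the
# normalization divides by the record's own mean power, the features are
# invariant to positive rescaling of the input waveform. A vector of
# inter-beat-interval statistics is attached per record.

#' Feature-extraction configuration
#'
#' @param n_filters Number of Gammatone filters (bands).
#' @param f_lo_hz,f_hi_hz Filterbank band edges in Hz; centers are
#'   log-spaced between them. Defaults 0.1-20 Hz cover the PPG band
#'   (heart rate fundamentals plus their first harmonics).
#' @param frame_len_s,frame_hop_s Frame length and hop in seconds. The
#'   4 s / 2 s defaults give 59 frames on a 2-minute record and keep at
#'   least three beats per frame at plausible heart rates.
#' @param power_law_theta Power-law compression exponent in (0, 1);
#'   default 1/15, the classic power-normalized-cepstrum value.
#' @param include_dct Apply a DCT-II across bands for cepstral output
#'   (off by default: the compressed band matrix itself is the feature).
#' @param n_timedomain Number of time-domain features appended (6).
#' @param stack_imfs Keep per-IMF spectra as stacked matrices instead of
#'   summing them before filtering (off by default).
#' @param per_band_norm Normalize each band by its own mean power instead
#'   of the global mean (off by default).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(n_filters = 32L, f_lo_hz = 0.1, f_hi_hz = 20,
                           frame_len_s = 4, frame_hop_s = 2,
                           power_law_theta = 1 / 15,
                           include_dct = FALSE,
                           n_timedomain = 6L,
                           stack_imfs = FALSE,
                           per_band_norm = FALSE) {
  if (!is_count(n_filters, 1L)) stop_invalid("n_filters must be >= 1")
  if (!is_number(f_lo_hz) || !is_number(f_hi_hz) ||
      f_lo_hz <= 0 || f_hi_hz <= f_lo_hz) {
    stop_invalid("band edges must satisfy 0 < f_lo_hz < f_hi_hz")
  }
  if (!is_number(power_law_theta) ||
      power_law_theta <= 0 || power_law_theta >= 1) {
    stop_invalid("power_law_theta must lie strictly in (0, 1)")
  }
  if (!is_number(frame_len_s) || !is_number(frame_hop_s) ||
      frame_len_s <= 0 || frame_hop_s <= 0 || frame_hop_s > frame_len_s) {
    stop_invalid("need 0 < frame_hop_s <= frame_len_s")
  }
  structure(list(n_filters = as.integer(n_filters), f_lo_hz = f_lo_hz,
                 f_hi_hz = f_hi_hz, frame_len_s = frame_len_s,
                 frame_hop_s = frame_hop_s, power_law_theta = power_law_theta,
                 include_dct = isTRUE(include_dct),
                 n_timedomain = as.integer(n_timedomain),
                 stack_imfs = isTRUE(stack_imfs),
                 per_band_norm = isTRUE(per_band_norm)),
            class = "feature_config")
}

#' Framed power spectrum of a signal
#'
#' Hann-windowed periodogram per frame: squared FFT magnitude divided by the
#' frame length, one-sided bins. Frames are half-open sample windows
#' `[k*hop, k*hop + len)`. A signal shorter than one frame is zero-padded
#' into a single frame (with a warning).
#'
#' @param x Numeric vector (one IMF or signal).
#' @param fs_hz Sampling rate.
#' @param frame_len_s,frame_hop_s Frame length and hop in seconds.
#' @return A frames x bins nonnegative matrix with attributes `freqs_hz`
#'   (bin center frequencies) and `frame_len` (samples per frame).
#' @export
power_spectrum <- function(x, fs_hz, frame_len_s = 4, frame_hop_s = 2) {
  x <- as.numeric(x)
  len <- round(frame_len_s * fs_hz)
  hop <- round(frame_hop_s * fs_hz)
  if (len < 8L) stop_invalid("frame must contain at least 8 samples")
  if (length(x) < len) {
    warning("signal shorter than one frame; zero-padding", call. = FALSE)
    x <- c(x, numeric(len - length(x)))
  }
  n_frames <- (length(x) - len) %/% hop + 1L
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(len) - 1L) / (len - 1L))  # Hann
  n_bins <- len %/% 2 + 1L
  out <- matrix(0, nrow = n_frames, ncol = n_bins)
  for (k in seq_len(n_frames)) {
    fr <- x[seq.int((k - 1L) * hop + 1L, (k - 1L) * hop + len)] * win
    sp <- Mod(stats::fft(fr))^2 / len
    one <- sp[seq_len(n_bins)]
    # energy-preserving one-sided spectrum: double the interior bins so the
    # bin sum equals the windowed frame's time-domain energy (Parseval)
    interior <- seq.int(2L, n_bins - if (len %% 2L == 0L) 1L else 0L)
    one[interior] <- 2 * one[interior]
    out[k, ] <- one
  }
  attr(out, "freqs_hz") <- (seq_len(n_bins) - 1L) * fs_hz / len
  attr(out, "frame_len") <- len
  out
}

#' Build a Gammatone filterbank as spectral weight vectors
#'
#' Each filter's impulse response is `a * t^(n-1) * exp(-2*pi*w*t) *
#' cos(2*pi*f0*t + phi)`; its spectral weight vector is the FFT magnitude of
#' that response sampled at the analysis bin frequencies, peak-normalized
#' to 1. Center frequencies are log-spaced on `[f_lo_hz, f_hi_hz]`;
#' bandwidths scale with center frequency (floored at 0.05 Hz) so low bands
#' stay narrow.
#'
#' @param cfg A [feature_config()].
#' @param fs_hz Sampling rate of the analysis frames.
#' @param n_fft FFT length of the analysis frames (samples per frame).
#' @param order Filter order n (default 4).
#' @param bw_frac Bandwidth as a fraction of center frequency.
#' @return A list of filters, each with `center_freq_hz`, `bandwidth_hz`,
#'   `order` and `weights` (nonnegative, length `n_fft %/% 2 + 1`, max 1).
#' @export
build_filterbank <- function(cfg, fs_hz, n_fft, order = 4L, bw_frac = 0.25) {
  if (cfg$f_hi_hz > fs_hz / 2) {
    stop_invalid("f_hi_hz exceeds the Nyquist frequency ", fs_hz / 2, " Hz")
  }
  centers <- exp(seq(log(cfg$f_lo_hz), log(cfg$f_hi_hz),
                     length.out = cfg$n_filters))
  if (cfg$n_filters == 1L) centers <- sqrt(cfg$f_lo_hz * cfg$f_hi_hz)
  n_bins <- n_fft %/% 2 + 1L
  lapply(centers, function(f0) {
    w <- max(0.05, bw_frac * f0)
    gammatone_weights(f0, w, order, fs_hz, n_fft, n_bins)
  })
}

# Spectral weight vector of one Gammatone filter: |FFT| of the impulse
# response over the frame grid, one-sided, peak-normalized.
gammatone_weights <- function(f0, w, order, fs_hz, n_fft, n_bins, phi = 0) {
  t <- (seq_len(n_fft) - 1L) / fs_hz
  g <- t^(order - 1) * exp(-2 * pi * w * t) * cos(2 * pi * f0 * t + phi)
  wt <- Mod(stats::fft(g))[seq_len(n_bins)]
  wt <- wt / max(wt)
  list(center_freq_hz = f0, bandwidth_hz = w, order = as.integer(order),
       weights = wt)
}

#' Apply a filterbank to framed power spectra
#'
#' Band energy = inner product of each frame's spectrum with each filter's
#' spectral weight vector.
#'
#' @param spec Frames x bins matrix from [power_spectrum()].
#' @param bank Filterbank from [build_filterbank()].
#' @return Frames x bands nonnegative matrix.
#' @export
apply_filterbank <- function(spec, bank) {
  wmat <- vapply(bank, function(f) f$weights,
                 numeric(length(bank[[1L]]$weights)))
  if (ncol(spec) != nrow(wmat)) {
    stop_invalid("spectrum bin count (", ncol(spec),
                 ") does not match filterbank (", nrow(wmat), ")")
  }
  spec %*% wmat
}

#' Power-normalize band energies
#'
#' Divides every entry by the record's mean band power, so the normalized
#' matrix has global mean exactly 1 and the chain becomes invariant to
#' rescaling the input waveform. With `per_band = TRUE` each band is divided
#' by its own mean instead.
#'
#' @param bands Frames x bands nonnegative matrix.
#' @param per_band Normalize per band rather than globally.
#' @return Matrix of the same shape; all-zero input passes through
#'   unchanged (with a warning).
#' @export
power_normalize <- function(bands, per_band = FALSE) {
  if (any(bands < 0)) stop_invalid("band energies must be nonnegative")
  if (all(bands == 0)) {
    warning("all-zero band energies; skipping normalization", call. = FALSE)
    return(bands)
  }
  if (per_band) {
    mu <- colMeans(bands)
    mu[mu == 0] <- 1
    sweep(bands, 2L, mu, "/")
  } else {
    bands / mean(bands)
  }
}

#' Power-law compression
#'
#' Elementwise `U^theta` with `0 < theta < 1`: compresses large energies and
#' expands small ones, mimicking the loudness nonlinearity the
#' power-normalized cepstrum borrows from auditory modelling.
#'
#' @param U Nonnegative matrix.
#' @param theta Exponent in (0, 1).
#' @return Compressed matrix of the same shape.
#' @export
power_law <- function(U, theta = 1 / 15) {
  if (!is_number(theta) || theta <= 0 || theta >= 1) {
    stop_invalid("theta must lie strictly in (0, 1)")
  }
  if (any(U < 0)) stop_invalid("entries must be nonnegative")
  U^theta
}

# Orthonormal DCT-II across the band dimension (applied per frame).
dct_rows <- function(m) {
  k <- ncol(m)
  j <- seq_len(k) - 1L
  basis <- sqrt(2 / k) * cos(pi * outer(j + 0.5, j) / k)
  basis[, 1L] <- basis[, 1L] / sqrt(2)
  m %*% basis
}

#' Inter-beat-interval time-domain features
#'
#' Six statistics of the detected peak train, in fixed order: mean IBI (s),
#' SD of IBI (s), RMSSD (s), pNN50 (fraction of successive-interval changes
#' above 50 ms), Shannon entropy of the 8-bin IBI histogram (nats), and the
#' coefficient of variation of peak amplitudes. These capture the
#' irregularly-irregular rhythm signature of AF directly in the time domain.
#'
#' @param record A [ppg_record()].
#' @param ... Passed to [detect_peaks()].
#' @return Named numeric vector of length 6.
#' @export
time_domain_features <- function(record, ...) {
  peaks <- detect_peaks(record, ...)
  if (length(peaks) < 4L) {
    stop_invalid("need at least 4 detected peaks for time-domain features (got ",
                 length(peaks), ")")
  }
  ibi <- diff(peaks) / record$fs_hz
  d <- diff(ibi)
  rmssd <- if (length(d)) sqrt(mean(d^2)) else 0
  pnn50 <- if (length(d)) mean(abs(d) > 0.05) else 0
  entropy <- if (diff(range(ibi)) < sqrt(.Machine$double.eps)) {
    0  # all intervals identical: a single occupied histogram bin
  } else {
    counts <- tabulate(cut(ibi, breaks = 8L, labels = FALSE), nbins = 8L)
    pr <- counts[counts > 0] / sum(counts)
    -sum(pr * log(pr))
  }
  amps <- record$samples[peaks]
  amp_cv <- if (mean(amps) == 0) 0 else stats::sd(amps) / abs(mean(amps))
  c(mean_ibi = mean(ibi), sd_ibi = stats::sd(ibi), rmssd = rmssd,
    pnn50 = pnn50, ibi_entropy = entropy, amp_cv = amp_cv)
}

#' Extract the full power-normalized Gammatone feature matrix
#'
#' Runs the complete chain on one (segmented, normalized) record:
#' complementary-ensemble decomposition, coherence-based IMF selection,
#' per-IMF framed power spectra summed over the selected IMFs, Gammatone
#' filterbank, division by mean band power, power-law compression, optional
#' DCT, and the time-domain feature vector attached per record.
#' Deterministic for a fixed `ens_cfg$seed`.
#'
#' @param record A [ppg_record()] (typically from [preprocess_record()]).
#' @param emd_cfg An [emd_config()].
#' @param ens_cfg An [ensemble_config()].
#' @param feat_cfg A [feature_config()].
#' @param imf_threshold Coherence threshold for [select_imfs()].
#' @return An object of class `feature_matrix`: `values` (frames x bands),
#'   `time_features` (length-6 vector), `record_id`, `rhythm_label`,
#'   `selected_imfs`, `mu`, and the config snapshot.
#' @export
extract_cepncc <- function(record,
                           emd_cfg = emd_config(),
                           ens_cfg = ensemble_config(),
                           feat_cfg = feature_config(),
                           imf_threshold = 0.1) {
  if (!inherits(record, "ppg_record")) stop_invalid("record must be a ppg_record")
  tf <- time_domain_features(record)
  dec <- ensemble_decompose(record$samples, emd_cfg, ens_cfg)
  sel <- select_imfs(dec, record$samples, threshold = imf_threshold)

  specs <- lapply(sel$imfset$imfs, power_spectrum, fs_hz = record$fs_hz,
                  frame_len_s = feat_cfg$frame_len_s,
                  frame_hop_s = feat_cfg$frame_hop_s)
  bank <- build_filterbank(feat_cfg, record$fs_hz, attr(specs[[1L]], "frame_len"))

  band_stack <- lapply(specs, apply_filterbank, bank = bank)
  combined <- if (feat_cfg$stack_imfs) {
    do.call(rbind, band_stack)
  } else {
    Reduce(`+`, band_stack)
  }
  U <- power_normalize(combined, per_band = feat_cfg$per_band_norm)
  V <- power_law(U, feat_cfg$power_law_theta)
  if (feat_cfg$include_dct) V <- dct_rows(V)

  structure(list(values = V, time_features = tf,
                 record_id = record$record_id,
                 rhythm_label = record$rhythm_label,
                 selected_imfs = sel$selected, mu = sel$mu,
                 config = list(emd = emd_cfg, ensemble = ens_cfg,
                               features = feat_cfg)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "Feature matrix '%s' (%s): %d frames x %d bands, %d IMFs selected\n",
    x$record_id, x$rhythm_label, nrow(x$values), ncol(x$values),
    length(x$selected_imfs)))
  invisible(x)
}

#' Serialize a feature matrix as CSV
#'
#' Frames x bands values, with the time-domain features as a footer row
#' labelled `time_features` (padded with NA beyond its length).
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(fm, path) {
  m <- fm$values
  footer <- rep(NA_real_, ncol(m))
  footer[seq_along(fm$time_features)] <- fm$time_features
  out <- rbind(m, footer)
  rownames(out) <- c(sprintf("frame%03d", seq_len(nrow(m))), "time_features")
  utils::write.csv(out, path, row.names = TRUE)
  invisible(path)
}
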