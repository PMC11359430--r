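# Synthetic PPG generator
#
# Produces labelled single-channel PPG records with the statistical structure
# that separates atrial fibrillation (AF) from normal sinus rhythm (NSR):
# NSR has quasi-regular inter-beat intervals (low CV, positive lag-1
# autocorrelation from respiratory sinus arrhythmia), AF has irregularly
# irregular intervals (high CV, no serial correlation) and beat-to-beat
# amplitude variability. Each beat is a two-lobe pulse (systolic peak plus a
# smaller dicrotic lobe); baseline wander and white measurement noise are
# added on top.

#' Rhythm model parameters for the synthetic PPG generator
#'
#' Bundles the inter-beat-interval (IBI) and amplitude statistics that define
#' a cardiac rhythm for simulation purposes. Two presets are provided:
#' `"NSR"` (regular rhythm, IBI coefficient of variation 0.04, lag-1 serial
#' correlation 0.6) and `"AF"` (irregularly irregular rhythm, IBI CV 0.20, no
#' serial correlation, elevated amplitude variability).
#'
#' @param rhythm_label `"AF"` or `"NSR"`; selects the preset defaults.
#' @param mean_ibi_s Mean inter-beat interval in seconds.
#' @param ibi_cv Coefficient of variation of the IBIs (dimensionless).
#' @param ibi_serial_corr Lag-1 correlation of successive IBIs.
#' @param amp_cv Coefficient of variation of per-beat pulse amplitudes.
#' @param baseline_wander_amp Amplitude of the 0.1 Hz sinusoidal baseline
#'   wander, as a fraction of the nominal pulse amplitude.
#' @param noise_sd Standard deviation of additive white Gaussian noise, as a
#'   fraction of the nominal pulse amplitude.
#' @return An object of class `rhythm_params`.
#' @examples
#' rhythm_params("AF")
#' rhythm_params("NSR", noise_sd = 0) # noiseless regular rhythm
#' @export
rhythm_params <- function(rhythm_label = c("NSR", "AF"),
                          mean_ibi_s = NULL,
                          ibi_cv = NULL,
                          ibi_serial_corr = NULL,
                          amp_cv = NULL,
                          baseline_wander_amp = 0.10,
                          noise_sd = 0.02) {
  rhythm_label <- match.arg(rhythm_label)
  preset <- switch(rhythm_label,
    NSR = list(mean_ibi_s = 0.8, ibi_cv = 0.04, ibi_serial_corr = 0.6,
               amp_cv = 0.03),
    AF  = list(mean_ibi_s = 0.7, ibi_cv = 0.20, ibi_serial_corr = 0.0,
               amp_cv = 0.15)
  )
  p <- list(
    rhythm_label = rhythm_label,
    mean_ibi_s = if (is.null(mean_ibi_s)) preset$mean_ibi_s else mean_ibi_s,
    ibi_cv = if (is.null(ibi_cv)) preset$ibi_cv else ibi_cv,
    ibi_serial_corr = if (is.null(ibi_serial_corr)) preset$ibi_serial_corr else ibi_serial_corr,
    amp_cv = if (is.null(amp_cv)) preset$amp_cv else amp_cv,
    baseline_wander_amp = baseline_wander_amp,
    noise_sd = noise_sd
  )
  if (!is_number(p$mean_ibi_s) || p$mean_ibi_s <= 0) {
    stop_invalid("mean_ibi_s must be a positive number")
  }
  if (!is_number(p$ibi_cv) || p$ibi_cv < 0) {
    stop_invalid("ibi_cv must be a nonnegative number")
  }
  if (!is_number(p$ibi_serial_corr) || abs(p$ibi_serial_corr) >= 1) {
    stop_invalid("ibi_serial_corr must lie in (-1, 1)")
  }
  for (f in c("amp_cv", "baseline_wander_amp", "noise_sd")) {
    if (!is_number(p[[f]]) || p[[f]] < 0) {
      stop_invalid(f, " must be a nonnegative number")
    }
  }
  structure(p, class = "rhythm_params")
}

#' @export
print.rhythm_params <- function(x, ...) {
  cat(sprintf("Rhythm model: %s\n", x$rhythm_label))
  cat(sprintf("  mean IBI %.3f s, CV %.3f, lag-1 corr %.2f\n",
              x$mean_ibi_s, x$ibi_cv, x$ibi_serial_corr))
  cat(sprintf("  amplitude CV %.3f, baseline wander %.2f, noise SD %.3f\n",
              x$amp_cv, x$baseline_wander_amp, x$noise_sd))
  invisible(x)
}

#' Construct a PPG record object
#'
#' A `ppg_record` is the package's container for a single-channel PPG
#' waveform: the sample vector, its sampling rate, the rhythm label (if
#' known) and provenance fields.
#'
#' @param samples Numeric vector of waveform samples; must be finite.
#' @param fs_hz Sampling rate in Hz (the reference recordings use 125 Hz).
#' @param rhythm_label `"AF"`, `"NSR"` or `"unknown"`.
#' @param record_id Identifier string.
#' @param seed Integer seed the record was generated from, or `NA`.
#' @return An object of class `ppg_record`.
#' @export
ppg_record <- function(samples, fs_hz = 125,
                       rhythm_label = c("unknown", "AF", "NSR"),
                       record_id = "record", seed = NA_integer_) {
  rhythm_label <- match.arg(rhythm_label)
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop_invalid("samples must be non-empty")
  if (!all(is.finite(samples))) stop_invalid("samples must all be finite")
  if (!is_number(fs_hz) || fs_hz <= 0) stop_invalid("fs_hz must be positive")
  structure(
    list(samples = samples, fs_hz = fs_hz, rhythm_label = rhythm_label,
         record_id = as.character(record_id), seed = seed),
    class = "ppg_record"
  )
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("PPG record '%s': %d samples @ %g Hz (%.1f s), rhythm %s\n",
              x$record_id, length(x$samples), x$fs_hz,
              length(x$samples) / x$fs_hz, x$rhythm_label))
  invisible(x)
}

# Draw n inter-beat intervals from a truncated-normal AR(1) model.
# Marginal mean/SD follow the params; lag-1 correlation via a stationary
# AR(1) on the latent normal; intervals floored at 0.3 s (physiological
# lower bound) by resampling-free truncation.
draw_ibis <- function(n, mean_ibi_s, ibi_cv, serial_corr, lower = 0.3) {
  sd_ibi <- mean_ibi_s * ibi_cv
  z <- numeric(n)
  z[1L] <- rnorm(1L)
  if (n > 1L) {
    innov <- rnorm(n - 1L)
    a <- serial_corr
    b <- sqrt(1 - a^2)
    for (i in 2:n) z[i] <- a * z[i - 1L] + b * innov[i - 1L]
  }
  pmax(lower, mean_ibi_s + sd_ibi * z)
}

# Two-lobe pulse evaluated on a sample grid: systolic Gaussian at the beat
# time plus a dicrotic Gaussian at +0.25*ibi with 30% amplitude. Widths
# scale with the interval so fast beats stay narrow.
add_pulse <- function(signal, t_grid, beat_time, ibi, amp) {
  sys_w <- 0.12 * ibi
  dic_w <- 0.16 * ibi
  lo <- beat_time - 4 * sys_w
  hi <- beat_time + 0.25 * ibi + 4 * dic_w
  idx <- which(t_grid >= lo & t_grid <= hi)
  if (!length(idx)) return(signal)
  tt <- t_grid[idx]
  signal[idx] <- signal[idx] +
    amp * exp(-0.5 * ((tt - beat_time) / sys_w)^2) +
    0.3 * amp * exp(-0.5 * ((tt - beat_time - 0.25 * ibi) / dic_w)^2)
  signal
}

#' Generate one synthetic PPG record
#'
#' Simulates a pulse train whose inter-beat intervals follow the rhythm
#' model in `params` (truncated-normal marginal with the stated mean and CV,
#' lag-1 autocorrelation via a latent AR(1), lower bound 0.3 s), with
#' per-beat amplitudes drawn around 1 with CV `params$amp_cv`, plus a 0.1 Hz
#' sinusoidal baseline wander and white Gaussian noise. Deterministic for a
#' fixed seed.
#'
#' @param params A [rhythm_params()] object.
#' @param duration_s Record duration in seconds (>= 10).
#' @param fs_hz Sampling rate in Hz (>= 25).
#' @param seed Integer seed.
#' @param record_id Identifier for the record.
#' @return A [ppg_record()] with `duration_s * fs_hz` samples.
#' @examples
#' rec <- generate_record(rhythm_params("NSR"), duration_s = 30, seed = 1)
#' length(rec$samples) # 30 * 125
#' @export
generate_record <- function(params, duration_s = 120, fs_hz = 125, seed = 1L,
                            record_id = NULL) {
  if (!inherits(params, "rhythm_params")) {
    stop_invalid("params must be a rhythm_params object")
  }
  if (!is_number(duration_s) || duration_s < 10) {
    stop_invalid("duration_s must be >= 10 seconds")
  }
  if (!is_number(fs_hz) || fs_hz < 25) {
    stop_invalid("fs_hz must be >= 25 Hz")
  }
  if (is.null(record_id)) {
    record_id <- sprintf("%s_seed%d", params$rhythm_label, as.integer(seed))
  }
  n <- round(duration_s * fs_hz)
  t_grid <- (seq_len(n) - 1L) / fs_hz

  samples <- with_seed(seed, {
    # enough beats to cover the record even with short intervals
    n_beats <- ceiling(duration_s / 0.3) + 8L
    ibis <- draw_ibis(n_beats, params$mean_ibi_s, params$ibi_cv,
                      params$ibi_serial_corr)
    beat_times <- cumsum(ibis)
    keep <- beat_times <= duration_s + 2 * params$mean_ibi_s
    beat_times <- beat_times[keep]
    ibis <- ibis[keep]
    amps <- pmax(0.1, rnorm(length(beat_times), mean = 1, sd = params$amp_cv))
    phase <- runif(1L, 0, 2 * pi)
    noise <- if (params$noise_sd > 0) {
      rnorm(n, sd = params$noise_sd)
    } else {
      numeric(n)
    }
    sig <- numeric(n)
    for (k in seq_along(beat_times)) {
      sig <- add_pulse(sig, t_grid, beat_times[k], ibis[k], amps[k])
    }
    sig + params$baseline_wander_amp * sin(2 * pi * 0.1 * t_grid + phase) + noise
  })

  ppg_record(samples, fs_hz = fs_hz, rhythm_label = params$rhythm_label,
             record_id = record_id, seed = as.integer(seed))
}

#' Generate a labelled synthetic PPG dataset
#'
#' Draws `n_af` AF records followed by `n_nsr` NSR records, each from a
#' per-record seed derived deterministically from `seed`. When
#' `split = TRUE` the records are flagged train/test per stratum at the
#' reference 2:1 ratio (66.6% train / 33.3% test), preserving label
#' proportions within rounding.
#'
#' @param n_af,n_nsr Number of AF and NSR records (>= 0).
#' @param duration_s,fs_hz Passed to [generate_record()].
#' @param seed Master seed; per-record seeds are derived from it.
#' @param split Logical; assign stratified train/test flags.
#' @param train_frac Fraction assigned to the training set when splitting.
#' @param af_params,nsr_params Optional [rhythm_params()] overriding the
#'   presets.
#' @return A list with `records` (list of [ppg_record()]) and `manifest`
#'   (data.frame with record_id, label, split, seed).
#' @examples
#' ds <- generate_dataset(n_af = 2, n_nsr = 2, duration_s = 20, seed = 7)
#' ds$manifest
#' @export
generate_dataset <- function(n_af, n_nsr, duration_s = 120, fs_hz = 125,
                             seed = 1L, split = FALSE, train_frac = 2 / 3,
                             af_params = rhythm_params("AF"),
                             nsr_params = rhythm_params("NSR")) {
  if (!is_count(n_af) || !is_count(n_nsr)) {
    stop_invalid("n_af and n_nsr must be nonnegative integers")
  }
  n <- n_af + n_nsr
  labels <- c(rep("AF", n_af), rep("NSR", n_nsr))
  seeds <- if (n > 0L) derive_seeds(seed, n) else integer(0)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    p <- if (labels[i] == "AF") af_params else nsr_params
    records[[i]] <- generate_record(
      p, duration_s = duration_s, fs_hz = fs_hz, seed = seeds[i],
      record_id = sprintf("%s_%03d", labels[i], i)
    )
  }
  split_flag <- rep(NA_character_, n)
  if (split && n > 0L) {
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      n_train <- round(train_frac * length(idx))
      split_flag[idx] <- c(rep("train", n_train),
                           rep("test", length(idx) - n_train))
    }
  }
  manifest <- data.frame(
    record_id = vapply(records, function(r) r$record_id, character(1)),
    label = labels,
    split = split_flag,
    seed = if (n > 0L) as.integer(seeds) else integer(0),
    stringsAsFactors = FALSE
  )
  list(records = records, manifest = manifest)
}

#' Write a PPG record and dataset manifest as CSV
#'
#' Records are written one sample per line under a two-line comment header
#' carrying the sampling rate and label, so they round-trip through
#' [read_ppg_csv()] bit-exactly.
#'
#' @param record A [ppg_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ppg_csv <- function(record, path) {
  if (!inherits(record, "ppg_record")) stop_invalid("record must be a ppg_record")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%s", format(record$fs_hz, digits = 17)), con)
  writeLines(sprintf("# label=%s", record$rhythm_label), con)
  writeLines(format(record$samples, digits = 17, trim = TRUE,
                    scientific = FALSE), con)
  invisible(path)
}

#' Write a dataset manifest CSV
#'
#' @param manifest Manifest data.frame as returned by [generate_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest_csv <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
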