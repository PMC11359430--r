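# Power-normalized Gammatone feature chain: spectra, filterbank,
# normalization, compression, time-domain statistics, and the composed
# extractor's invariances.

test_that("framed periodogram peaks at the tone frequency and obeys Parseval", {
  fs <- 125
  t <- (0:(12 * fs - 1)) / fs
  x <- sin(2 * pi * 5 * t)
  sp <- power_spectrum(x, fs, frame_len_s = 4, frame_hop_s = 2)
  freqs <- attr(sp, "freqs_hz")
  for (k in seq_len(nrow(sp))) {
    expect_lt(abs(freqs[which.max(sp[k, ])] - 5), 0.3)
  }
  expect_true(all(sp >= 0))

  expect_true(all(power_spectrum(numeric(600), fs) == 0))

  # Parseval: bin sum equals the windowed frame's time-domain energy
  set.seed(8)
  y <- rnorm(1000)
  spy <- power_spectrum(y, fs, frame_len_s = 4, frame_hop_s = 2)
  len <- attr(spy, "frame_len")
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(len) - 1) / (len - 1))
  fr1 <- y[1:len] * win
  expect_equal(sum(spy[1, ]), sum(fr1^2), tolerance = 1e-6)
})

test_that("Gammatone filterbank weights are normalized and centered", {
  cfg <- feature_config(n_filters = 8L, f_lo_hz = 0.5, f_hi_hz = 20)
  bank <- build_filterbank(cfg, fs_hz = 125, n_fft = 500)
  freqs <- (0:250) * 125 / 500
  for (f in bank) {
    expect_true(all(f$weights >= 0))
    expect_equal(max(f$weights), 1)
    expect_lt(abs(freqs[which.max(f$weights)] - f$center_freq_hz),
              125 / 500 + 1e-9)  # within one bin
  }
  centers <- vapply(bank, `[[`, numeric(1), "center_freq_hz")
  expect_true(all(diff(centers) > 0))
  expect_error(build_filterbank(feature_config(f_hi_hz = 80), 125, 500),
               "Nyquist")
})

test_that("-3 dB bandwidth of the order-4 filter grows with w", {
  n_fft <- 2000
  fs <- 125
  freqs <- (0:(n_fft / 2)) * fs / n_fft
  bw3db <- vapply(c(0.2, 0.5, 1, 2), function(w) {
    f <- ppgaf:::gammatone_weights(5, w, 4L, fs, n_fft, n_fft / 2 + 1)
    diff(range(freqs[f$weights^2 >= 0.5]))
  }, numeric(1))
  expect_true(all(diff(bw3db) > 0))
})

test_that("filterbank application selects bins, scales as power, ranks tones", {
  sp <- matrix(0, 2, 10)
  sp[, 4] <- c(3, 5)
  indicator <- list(list(weights = as.numeric(seq_len(10) == 4)))
  expect_equal(as.numeric(apply_filterbank(sp, indicator)), c(3, 5))

  cfg <- feature_config(n_filters = 6L, f_lo_hz = 0.5, f_hi_hz = 20)
  bank <- build_filterbank(cfg, 125, 500)
  fs <- 125
  t <- (0:(8 * fs - 1)) / fs
  x <- sin(2 * pi * bank[[3]]$center_freq_hz * t)
  b1 <- apply_filterbank(power_spectrum(x, fs), bank)
  expect_identical(unname(which.max(colMeans(b1))), 3L)
  b2 <- apply_filterbank(power_spectrum(2 * x, fs), bank)
  expect_equal(b2, 4 * b1, tolerance = 1e-12)
})

test_that("power normalization fixes the global mean at 1 and kills scale", {
  m <- matrix(c(2, 4, 6, 8), 2, 2)
  expect_equal(power_normalize(matrix(5, 3, 3)), matrix(1, 3, 3))
  expect_equal(power_normalize(m), power_normalize(100 * m))
  expect_equal(mean(power_normalize(m)), 1, tolerance = 1e-9)
  expect_warning(z <- power_normalize(matrix(0, 2, 2)), "all-zero")
  expect_equal(z, matrix(0, 2, 2))
})

test_that("power-law compression is monotone with fixed points 0 and 1", {
  expect_equal(power_law(matrix(1, 2, 2), 0.3), matrix(1, 2, 2))
  expect_equal(power_law(matrix(4, 1, 1), 0.5), matrix(2, 1, 1))
  u <- matrix(c(0, 0.2, 1, 5), 2, 2)
  v <- power_law(u, 1 / 15)
  expect_lt(v[2, 2], u[2, 2])   # compresses above 1
  expect_gt(v[2, 1], u[2, 1])   # expands below 1
  expect_error(power_law(u, 1.2), "theta")
  expect_error(power_law(u, 0), "theta")
})

test_that("time-domain features recover rhythm statistics", {
  per <- periodic_pulses()
  tf <- time_domain_features(per)
  expect_equal(unname(tf[c("sd_ibi", "rmssd", "ibi_entropy")]), c(0, 0, 0))
  expect_lt(tf[["amp_cv"]], 1e-9)

  # AF vs NSR at matched mean IBI: RMSSD ratio at least 3
  af <- generate_record(rhythm_params("AF", mean_ibi_s = 0.8, noise_sd = 0,
                                      baseline_wander_amp = 0),
                        duration_s = 170, seed = 31)
  nsr <- generate_record(rhythm_params("NSR", mean_ibi_s = 0.8, noise_sd = 0,
                                       baseline_wander_amp = 0),
                         duration_s = 170, seed = 32)
  tfa <- time_domain_features(af)
  tfn <- time_domain_features(nsr)
  expect_gte(tfa[["rmssd"]], 3 * tfn[["rmssd"]])

  expect_error(time_domain_features(ppg_record(sin(1:50 / 3), 125)),
               "4 detected peaks")
})

test_that("feature matrix is scale invariant, seed-deterministic, fixed shape", {
  rec <- preprocess_record(generate_record(rhythm_params("NSR"),
                                           duration_s = 45, seed = 41),
                           segment_config(n_points = 4000L))
  ens <- ensemble_config(n_realizations = 2L, seed = 7)
  fm1 <- extract_cepncc(rec, ens_cfg = ens)
  expect_s3_class(fm1, "feature_matrix")
  expect_true(all(is.finite(fm1$values)))
  expect_identical(ncol(fm1$values), 32L)
  expect_true(all(fm1$values >= 0))

  fm_same <- extract_cepncc(rec, ens_cfg = ens)
  expect_identical(fm1$values, fm_same$values)

  scaled <- rec
  scaled$samples <- 2 * rec$samples
  fm2 <- extract_cepncc(scaled, ens_cfg = ens)
  expect_equal(fm2$values, fm1$values, tolerance = 1e-9)
  expect_equal(fm2$time_features, fm1$time_features, tolerance = 1e-9)

  # frames depend only on config and record length
  rec2 <- preprocess_record(generate_record(rhythm_params("AF"),
                                            duration_s = 45, seed = 42),
                            segment_config(n_points = 4000L))
  fm3 <- extract_cepncc(rec2, ens_cfg = ensemble_config(2L, seed = 8))
  expect_identical(dim(fm3$values), dim(fm1$values))
})

test_that("AF and NSR feature matrices separate between classes", {
  mk <- function(lab, seed) {
    rec <- preprocess_record(generate_record(rhythm_params(lab),
                                             duration_s = 45, seed = seed),
                             segment_config(n_points = 4000L))
    extract_cepncc(rec, ens_cfg = ensemble_config(2L, seed = seed))
  }
  af <- lapply(1:5, function(i) mk("AF", 200 + i))
  nsr <- lapply(1:5, function(i) mk("NSR", 300 + i))
  vecs <- function(fms) t(vapply(fms, function(f) c(f$values, f$time_features),
                                 numeric(length(af[[1]]$values) + 6)))
  va <- vecs(af)
  vn <- vecs(nsr)
  dmat <- as.matrix(dist(rbind(va, vn)))
  within <- c(dmat[1:5, 1:5][lower.tri(diag(5))],
              dmat[6:10, 6:10][lower.tri(diag(5))])
  between <- dmat[1:5, 6:10]
  expect_gt(mean(between), mean(within))
})
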