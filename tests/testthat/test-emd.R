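# EMD, EEMD, CEEMD: reconstruction identities, component separation against
# the analytic two-tone oracle, ensemble mechanics and IMF selection.

test_that("EMD reconstruction is an exact additive identity", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(200:600, 1)
    x <- cumsum(rnorm(n)) + sin(seq(0, 20, length.out = n))
    d <- emd(x)
    rel <- sqrt(sum((reconstruct(d) - x)^2)) / sqrt(sum(x^2))
    expect_lt(rel, 1e-9)
  }
})

test_that("a pure sine decomposes into one IMF matching the sine", {
  tt <- two_tone()
  d <- emd(tt$hi)
  expect_gt(cor(d$imfs[[1]], tt$hi), 0.99)
  expect_lt(sd(d$residual), 0.05 * sd(tt$hi))
})

test_that("two-tone components split across IMFs with >10:1 band energy ratio", {
  tt <- two_tone()
  d <- emd(tt$sum)
  band_energy <- function(x, f, fs = fs_ref, halfwidth = 0.2) {
    X <- Mod(stats::fft(x))^2
    fr <- (seq_along(x) - 1) * fs / length(x)
    sum(X[abs(fr - f) < halfwidth | abs(fr - (fs - f)) < halfwidth])
  }
  expect_gt(band_energy(d$imfs[[1]], 5) / band_energy(d$imfs[[1]], 0.5), 10)
  expect_gt(band_energy(d$imfs[[2]], 0.5) / band_energy(d$imfs[[2]], 5), 10)
})

test_that("EMD IMFs agree with the analytic two-tone reference components", {
  tt <- two_tone()
  d <- emd(tt$sum)
  expect_gt(cor(d$imfs[[1]], tt$hi), 0.95)
  expect_gt(cor(d$imfs[[2]], tt$lo), 0.95)
})

test_that("IMFs approximately satisfy the extrema/zero-crossing condition", {
  tt <- two_tone()
  d <- emd(tt$sum)
  for (im in d$imfs[1:2]) {
    ext <- length(ppgaf:::find_extrema(im)$max) +
      length(ppgaf:::find_extrema(im)$min)
    zc <- sum(diff(sign(im[im != 0])) != 0)
    expect_lte(abs(ext - zc), 2)
  }
})

test_that("CEEMD is deterministic, noise-cancelling, and limits to plain EMD", {
  tt <- two_tone()
  ens <- ensemble_config(n_realizations = 8L, seed = 9, mode = "ceemd")
  d1 <- ceemd(tt$sum, ens_cfg = ens)
  d2 <- ceemd(tt$sum, ens_cfg = ens)
  expect_identical(d1$imfs, d2$imfs)
  expect_identical(d1$residual, d2$residual)

  # paired +/- noise cancels: CEEMD reconstructs the input essentially
  # exactly, while single-noise EMD runs carry the injected noise
  rel_err <- function(recon, x) sqrt(sum((recon - x)^2)) / sqrt(sum(x^2))
  ceemd_err <- rel_err(reconstruct(d1), tt$sum)
  single_errs <- vapply(1:20, function(i) {
    noise <- ppgaf:::with_seed(1000 + i,
                               rnorm(length(tt$sum), sd = 0.2 * sd(tt$sum)))
    rel_err(reconstruct(emd(tt$sum + noise)), tt$sum)
  }, numeric(1))
  expect_lt(ceemd_err, median(single_errs))
  expect_lt(ceemd_err, 1e-9)

  # vanishing noise with N = 1 approaches the plain decomposition
  tiny <- ensemble_config(n_realizations = 1L, noise_sd_frac = 1e-10,
                          seed = 3, mode = "ceemd")
  d_tiny <- ceemd(tt$sum, ens_cfg = tiny)
  d_plain <- emd(tt$sum)
  expect_lt(max(abs(d_tiny$imfs[[1]] - d_plain$imfs[[1]])), 1e-6)
})

test_that("EEMD with N = 1 equals EMD of the signal plus that noise draw", {
  tt <- two_tone(duration_s = 4)
  ens <- ensemble_config(n_realizations = 1L, noise_sd_frac = 0.2,
                         seed = 17, mode = "eemd")
  d <- eemd(tt$sum, ens_cfg = ens)
  noise <- ppgaf:::with_seed(17L, matrix(rnorm(length(tt$sum),
                                               sd = 0.2 * sd(tt$sum)),
                                         ncol = 1))[, 1]
  d_ref <- emd(tt$sum + noise)
  expect_equal(d$imfs[[1]], d_ref$imfs[[1]], tolerance = 1e-12)
  expect_equal(d$residual, d_ref$residual, tolerance = 1e-12)
})

test_that("EEMD reconstruction error falls with ensemble size on average", {
  tt <- two_tone(duration_s = 3)
  mean_err <- vapply(c(5L, 20L, 80L), function(N) {
    errs <- vapply(1:6, function(s) {
      d <- eemd(tt$sum, ens_cfg = ensemble_config(N, seed = s, mode = "eemd"))
      sqrt(sum((reconstruct(d) - tt$sum)^2)) / sqrt(sum(tt$sum^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) < 0))
})

test_that("ensembles cost exactly 2N (CEEMD) and N (EEMD) EMD invocations", {
  tt <- two_tone(duration_s = 3)
  reset_emd_call_count()
  ceemd(tt$sum, ens_cfg = ensemble_config(5L, seed = 1, mode = "ceemd"))
  expect_identical(emd_call_count(), 10L)
  reset_emd_call_count()
  eemd(tt$sum, ens_cfg = ensemble_config(5L, seed = 1, mode = "eemd"))
  expect_identical(emd_call_count(), 5L)
})

test_that("ensemble averaging is invariant to realization order", {
  tt <- two_tone(duration_s = 3)
  sets <- lapply(1:4, function(i) emd(tt$sum + 0.1 * sin(i + tt$t)))
  a <- ppgaf:::average_imfsets(sets, length(tt$sum))
  b <- ppgaf:::average_imfsets(rev(sets), length(tt$sum))
  expect_equal(a$imfs, b$imfs)
  expect_equal(a$residual, b$residual)
})

test_that("IMF selection ranks by coherence and keeps a fallback", {
  x <- two_tone()$sum
  fake <- structure(list(imfs = list(x), residual = numeric(length(x)),
                         source_length = length(x), config = NULL),
                    class = "imf_set")
  sel <- select_imfs(fake, x)
  expect_equal(sel$mu, 1.0)
  expect_identical(sel$selected, 1L)

  # orthogonal component: odd vs even function over symmetric support
  t <- seq(-1, 1, length.out = 400)
  odd <- t^3
  even <- t^2
  fake2 <- structure(list(imfs = list(even), residual = numeric(400),
                          source_length = 400L, config = NULL),
                     class = "imf_set")
  sel2 <- suppressWarnings(select_imfs(fake2, odd, threshold = 0.1))
  expect_lt(abs(sel2$mu), 0.05)
  expect_identical(sel2$selected, 1L)  # fallback keeps the best IMF
  expect_warning(select_imfs(fake2, odd, threshold = 0.1), "threshold")

  # coherence ranking follows per-component energy on a two-tone signal
  tt <- two_tone()
  d <- emd(tt$sum)
  sel3 <- select_imfs(d, tt$sum)
  energies <- vapply(d$imfs, function(i) sum(i^2), numeric(1))
  expect_identical(order(-sel3$mu)[1:2], order(-energies)[1:2])

  # zero-variance IMF gets coherence 0
  fake3 <- structure(list(imfs = list(numeric(400), odd), residual = even,
                          source_length = 400L, config = NULL),
                     class = "imf_set")
  sel4 <- select_imfs(fake3, odd)
  expect_identical(sel4$mu[1], 0)
})

test_that("invalid inputs are rejected", {
  expect_error(emd(c(1, 2, NA, 4, 5, 6, 7, 8)), "NaN")
  expect_error(emd(1:4), "length")
  expect_error(ensemble_config(0L), "n_realizations")
  expect_error(ceemd(1:100, ens_cfg = ensemble_config(mode = "eemd")),
               "ceemd")
})
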