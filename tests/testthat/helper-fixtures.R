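# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the full suite stays fast.

fs_ref <- 125

# Two-tone test signal whose true components are known analytically: the
# independent oracle for decomposition tests.
two_tone <- function(duration_s = 10, fs = fs_ref,
                     f_hi = 5, f_lo = 0.5, a_lo = 0.8) {
  t <- (seq_len(duration_s * fs) - 1L) / fs
  list(t = t,
       hi = sin(2 * pi * f_hi * t),
       lo = a_lo * sin(2 * pi * f_lo * t),
       sum = sin(2 * pi * f_hi * t) + a_lo * sin(2 * pi * f_lo * t))
}

# Perfectly periodic pulse train (period an integer number of samples).
periodic_pulses <- function(n_beats = 30, period_samples = 100, fs = fs_ref) {
  n <- n_beats * period_samples + period_samples
  x <- numeric(n)
  t <- (seq_len(n) - 1L) / fs
  centers <- (seq_len(n_beats) * period_samples) / fs
  for (ct in centers) x <- x + exp(-0.5 * ((t - ct) / 0.08)^2)
  ppg_record(x, fs_hz = fs, record_id = "periodic")
}

# Small toy feature matrices, linearly separable by a shift in band 1.
toy_features <- function(n_per_class = 20, frames = 10, bands = 4,
                         shift = 2, seed = 3) {
  ppgaf:::with_seed(seed, {
    mk <- function(s) {
      m <- matrix(runif(frames * bands), frames, bands)
      m[, 1] <- m[, 1] + s
      m
    }
    list(x = c(replicate(n_per_class, mk(shift), simplify = FALSE),
               replicate(n_per_class, mk(0), simplify = FALSE)),
         y = c(rep("AF", n_per_class), rep("NSR", n_per_class)))
  })
}

quiet_warnings <- function(expr) suppressWarnings(expr)
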