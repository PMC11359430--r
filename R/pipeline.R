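# End-to-end orchestration: synthesize (or load) records, preprocess,
# decompose, extract features, train, evaluate; plus the CSV / WFDB readers.
# Every stage seed derives deterministically from the run's master seed, so
# a rerun with the same config reproduces the summary metrics exactly.

#' Default pipeline configuration
#'
#' Nested configuration for a full synthetic-benchmark run. Stage seeds are
#' derived from `master_seed`; every value can be overridden via `...`
#' using the names shown in the return value.
#'
#' @param master_seed Master seed for the run.
#' @param n_af_train,n_nsr_train,n_af_test,n_nsr_test Records per class and
#'   split.
#' @param duration_s Record duration in seconds.
#' @param fs_hz Sampling rate.
#' @param n_realizations Ensemble size N for the complementary
#'   decomposition.
#' @param hidden_units,fc_units,max_epochs,batch_size Network settings.
#' @param initial_lr,lrdf,decay_period Learning-rate schedule.
#' @param n_points Samples per preprocessed segment (defaults to 2 minutes
#'   at `fs_hz`).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(master_seed = 1L,
                       n_af_train = 20L, n_nsr_train = 20L,
                       n_af_test = 10L, n_nsr_test = 10L,
                       duration_s = 150, fs_hz = 125,
                       n_realizations = 8L,
                       hidden_units = 64L, fc_units = 32L,
                       max_epochs = 40L, batch_size = 16L,
                       initial_lr = 0.01525, lrdf = 0.5, decay_period = 10L,
                       n_points = NULL) {
  if (is.null(n_points)) n_points <- as.integer(round(120 * fs_hz))
  structure(list(
    master_seed = as.integer(master_seed),
    n_af_train = as.integer(n_af_train), n_nsr_train = as.integer(n_nsr_train),
    n_af_test = as.integer(n_af_test), n_nsr_test = as.integer(n_nsr_test),
    duration_s = duration_s, fs_hz = fs_hz,
    n_realizations = as.integer(n_realizations),
    hidden_units = as.integer(hidden_units), fc_units = as.integer(fc_units),
    max_epochs = as.integer(max_epochs), batch_size = as.integer(batch_size),
    initial_lr = initial_lr, lrdf = lrdf,
    decay_period = as.integer(decay_period),
    n_points = as.integer(n_points)
  ), class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Featurize a set of records
#'
#' Preprocesses (segment from first peak + min-max normalization) and
#' extracts the power-normalized Gammatone feature matrix for each record.
#' Per-record decomposition seeds derive from `seed`.
#'
#' @param records List of [ppg_record()].
#' @param cfg A [run_config()] (supplies ensemble size and segment length).
#' @param seed Seed for the per-record decomposition noise.
#' @param progress Report per-record progress via `message()`.
#' @return List of `feature_matrix` objects.
#' @export
featurize_records <- function(records, cfg = run_config(), seed = 1L,
                              progress = FALSE) {
  seg_cfg <- segment_config(n_points = cfg$n_points)
  feat_cfg <- feature_config()
  emd_cfg <- emd_config()
  seeds <- derive_seeds(seed, length(records))
  out <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- preprocess_record(records[[i]], seg_cfg)
    ens_cfg <- ensemble_config(n_realizations = cfg$n_realizations,
                               seed = seeds[i])
    out[[i]] <- extract_cepncc(rec, emd_cfg, ens_cfg, feat_cfg)
    if (progress) message(sprintf("featurized %d/%d (%s)", i,
                                  length(records), rec$record_id))
  }
  out
}

#' Run the full synthetic AF-detection benchmark
#'
#' Generates labelled synthetic records, featurizes them, trains the BiLSTM
#' classifier on the training split, predicts the held-out test split, and
#' reports the confusion matrix with per-class metrics and accuracy.
#' Deterministic for a fixed `cfg$master_seed`. When `out_dir` is given,
#' the resolved config, manifest, metrics and predictions are written
#' there.
#'
#' @param cfg A [run_config()].
#' @param out_dir Optional output directory for run artifacts.
#' @param progress Report stage progress.
#' @return List with `confusion`, `metrics_af`, `metrics_nsr`,
#'   `accuracy`, `predictions`, `model`, `manifest`.
#' @export
run_af_pipeline <- function(cfg = run_config(), out_dir = NULL,
                            progress = FALSE) {
  seeds <- derive_seeds(cfg$master_seed, 4L)
  train <- generate_dataset(cfg$n_af_train, cfg$n_nsr_train,
                            duration_s = cfg$duration_s, fs_hz = cfg$fs_hz,
                            seed = seeds[1L])
  test <- generate_dataset(cfg$n_af_test, cfg$n_nsr_test,
                           duration_s = cfg$duration_s, fs_hz = cfg$fs_hz,
                           seed = seeds[2L])
  if (progress) message("featurizing training records")
  f_train <- featurize_records(train$records, cfg, seed = seeds[3L],
                               progress = progress)
  if (progress) message("featurizing test records")
  f_test <- featurize_records(test$records, cfg, seed = seeds[3L] + 1L,
                              progress = progress)
  if (progress) message("training BiLSTM")
  model <- af_bilstm(f_train,
                     hidden_units = cfg$hidden_units, fc_units = cfg$fc_units,
                     initial_lr = cfg$initial_lr, lrdf = cfg$lrdf,
                     decay_period = cfg$decay_period,
                     max_epochs = cfg$max_epochs,
                     batch_size = cfg$batch_size, seed = seeds[4L])
  pred <- predict(model, f_test)
  truth <- test$manifest$label
  cm <- confusion(truth, pred$label)
  res <- list(
    confusion = cm,
    metrics_af = class_metrics(cm, "AF"),
    metrics_nsr = class_metrics(cm, "NSR"),
    accuracy = accuracy(cm),
    predictions = cbind(test$manifest[, c("record_id", "label")], pred),
    model = model,
    manifest = {
      tm <- train$manifest; tm$split <- "train"
      sm <- test$manifest; sm$split <- "test"
      rbind(tm, sm)
    }
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_run_config(cfg, file.path(out_dir, "config.yaml"))
    utils::write.csv(res$manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(res$predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    summary_df <- data.frame(
      accuracy = res$accuracy,
      recall_af = res$metrics_af$recall,
      precision_af = res$metrics_af$precision,
      f_af = res$metrics_af$f_measure,
      recall_nsr = res$metrics_nsr$recall,
      precision_nsr = res$metrics_nsr$precision,
      f_nsr = res$metrics_nsr$f_measure
    )
    utils::write.csv(summary_df, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  res
}

#' Sweep record duration and report metrics per duration
#'
#' Runs [run_af_pipeline()] once per duration (the preprocessed segment
#' covers the whole record minus the first-peak offset margin) and tabulates
#' the resulting metrics, emulating a recording-length pre-experiment.
#' Metrics are reported, not asserted: which duration wins depends on the
#' rhythm mix and timing environment.
#'
#' @param durations_s Vector of record durations (seconds).
#' @param cfg Base [run_config()].
#' @return data.frame with one row per duration: accuracy, per-class F, and
#'   feature-extraction wall time.
#' @export
duration_sweep <- function(durations_s = c(60, 120, 300),
                           cfg = run_config()) {
  rows <- lapply(durations_s, function(d) {
    cfg_d <- cfg
    cfg_d$duration_s <- d + 30          # margin past the anchor peak
    cfg_d$n_points <- as.integer(round(d * cfg$fs_hz))
    t0 <- proc.time()[["elapsed"]]
    res <- run_af_pipeline(cfg_d)
    data.frame(duration_s = d,
               accuracy = res$accuracy,
               f_af = res$metrics_af$f_measure,
               f_nsr = res$metrics_nsr$f_measure,
               wall_time_s = proc.time()[["elapsed"]] - t0)
  })
  do.call(rbind, rows)
}

# ---- readers --------------------------------------------------------------

#' Read a PPG record from CSV
#'
#' Reads the one-sample-per-line CSV written by [write_ppg_csv()]; `# key=value`
#' comment headers carry the sampling rate and label.
#'
#' @param path File path.
#' @param fs_hz Fallback sampling rate when the header lacks one.
#' @param record_id Identifier; defaults to the file name.
#' @return A [ppg_record()].
#' @export
read_ppg_csv <- function(path, fs_hz = 125, record_id = NULL) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  label <- "unknown"
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) {
      if (kv[1L] == "fs_hz") fs_hz <- as.numeric(kv[2L])
      if (kv[1L] == "label" && kv[2L] %in% c("AF", "NSR")) label <- kv[2L]
    }
  }
  samples <- suppressWarnings(as.numeric(body))
  if (anyNA(samples)) {
    stop_invalid("malformed sample at line ",
                 which(!startsWith(lines, "#"))[which(is.na(samples))[1L]],
                 " of ", path)
  }
  if (is.null(record_id)) record_id <- sub("\\.[^.]*$", "", basename(path))
  ppg_record(samples, fs_hz = fs_hz, rhythm_label = label,
             record_id = record_id)
}

#' Read a WFDB record (format-16 signals)
#'
#' Minimal reader for the standard waveform-database format: parses the
#' `.hea` header (record line plus one signal-spec line per channel) and
#' the interleaved little-endian 16-bit `.dat` file, converts ADC units to
#' physical units via `(adc - baseline) / gain`, and returns the requested
#' channel. Only format 16 with a shared `.dat` file is supported.
#'
#' @param header_path Path to the `.hea` header file.
#' @param channel Channel to extract: name (description field) or index.
#' @return A [ppg_record()] with the channel's physical samples.
#' @export
read_wfdb <- function(header_path, channel = 1L) {
  if (!file.exists(header_path)) stop_invalid("file not found: ", header_path)
  lines <- readLines(header_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  rec_line <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rec_name <- rec_line[1L]
  n_sig <- as.integer(rec_line[2L])
  fs <- if (length(rec_line) >= 3L) as.numeric(rec_line[3L]) else 250
  n_samples <- if (length(rec_line) >= 4L) as.integer(rec_line[4L]) else NA_integer_
  if (is.na(n_sig) || n_sig < 1L) stop_invalid("malformed WFDB record line")
  sig_lines <- lines[seq.int(2L, 1L + n_sig)]
  specs <- lapply(sig_lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1L]]
    fmt <- sub("x.*$", "", f[2L])
    gain_field <- if (length(f) >= 3L) f[3L] else "200"
    # gain field is "<gain>(<baseline>)/<units>" with both suffixes optional
    gain <- suppressWarnings(as.numeric(sub("^(-?[0-9.]+).*$", "\\1",
                                            gain_field)))
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gain_field))
    } else if (length(f) >= 5L) {
      as.numeric(f[5L])
    } else {
      0
    }
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1L], format = fmt, gain = ifelse(is.na(gain) || gain == 0,
                                                   200, gain),
         baseline = ifelse(is.na(baseline), 0, baseline), desc = desc)
  })
  fmts <- vapply(specs, `[[`, character(1), "format")
  if (!all(fmts == "16")) {
    stop_invalid("only WFDB format 16 is supported (got ",
                 paste(unique(fmts), collapse = ", "), ")")
  }
  files <- vapply(specs, `[[`, character(1), "file")
  if (length(unique(files)) != 1L) {
    stop_invalid("only single .dat multiplexed records are supported")
  }
  dat_path <- file.path(dirname(header_path), files[1L])
  if (!file.exists(dat_path)) stop_invalid("file not found: ", dat_path)
  raw_n <- file.size(dat_path) / 2L
  adc <- readBin(dat_path, "integer", n = raw_n, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(adc) %% n_sig != 0L) {
    stop_invalid("dat file length is not a multiple of the channel count")
  }
  mat <- matrix(adc, nrow = n_sig)  # channels interleaved sample-major
  ch <- if (is.character(channel)) {
    hit <- which(vapply(specs, `[[`, character(1), "desc") == channel)
    if (!length(hit)) stop_invalid("no channel named '", channel, "'")
    hit[1L]
  } else {
    as.integer(channel)
  }
  if (ch < 1L || ch > n_sig) stop_invalid("channel index out of range")
  spec <- specs[[ch]]
  phys <- (mat[ch, ] - spec$baseline) / spec$gain
  if (!is.na(n_samples) && length(phys) > n_samples) {
    phys <- phys[seq_len(n_samples)]
  }
  ppg_record(phys, fs_hz = fs, record_id = paste0(rec_name, "_ch", ch))
}

#' Read a signal file by format
#'
#' @param path Path to a CSV sample file or WFDB `.hea` header.
#' @param format `"csv"` or `"wfdb"`; inferred from the extension by
#'   default.
#' @param ... Passed to the format-specific reader.
#' @return A [ppg_record()].
#' @export
read_signal <- function(path, format = c("auto", "csv", "wfdb"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.hea$", path)) "wfdb" else "csv"
  }
  switch(format,
         csv = read_ppg_csv(path, ...),
         wfdb = read_wfdb(path, ...))
}
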