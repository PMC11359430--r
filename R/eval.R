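# Evaluation: confusion matrices with AF as the positive class, per-class
# recall / precision / F-measure (reported as percentages), speed-rank time
# factors, and the ET-score — the harmonic-mean F-combination scaled by a
# computation-speed factor so that method comparisons weigh accuracy and
# efficiency together.

#' Confusion matrix for AF/NSR predictions
#'
#' AF is the positive class: `tp` counts AF records predicted AF, `tn` NSR
#' predicted NSR.
#'
#' @param labels True labels, `"AF"` or `"NSR"`.
#' @param predictions Predicted labels, same length and alphabet.
#' @return An object of class `af_confusion` with counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @examples
#' confusion(c("AF", "AF", "NSR"), c("AF", "NSR", "NSR"))
#' @export
confusion <- function(labels, predictions) {
  labels <- as.character(labels)
  predictions <- as.character(predictions)
  if (length(labels) != length(predictions)) {
    stop_invalid("labels and predictions must have equal length")
  }
  if (!length(labels)) stop_invalid("empty input")
  if (!all(c(labels, predictions) %in% c("AF", "NSR"))) {
    stop_invalid("labels must be 'AF' or 'NSR'")
  }
  structure(list(
    tp = sum(labels == "AF" & predictions == "AF"),
    fp = sum(labels == "NSR" & predictions == "AF"),
    fn = sum(labels == "AF" & predictions == "NSR"),
    tn = sum(labels == "NSR" & predictions == "NSR")
  ), class = "af_confusion")
}

#' @export
print.af_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("AF", "NSR"),
                              predicted = c("AF", "NSR")))
  print(m)
  invisible(x)
}

#' Per-class recall, precision and F-measure (percent)
#'
#' Standard definitions with the chosen class as positive:
#' recall = TP/(TP+FN), precision = TP/(TP+FP), F = 2rp/(r+p), all scaled
#' to percent. A zero denominator yields 0 with a warning.
#'
#' @param cm An [confusion()] object.
#' @param positive Which class to treat as positive.
#' @return List with `recall`, `precision`, `f_measure` (percent, full
#'   precision).
#' @export
class_metrics <- function(cm, positive = c("AF", "NSR")) {
  positive <- match.arg(positive)
  if (!inherits(cm, "af_confusion")) stop_invalid("cm must be an af_confusion")
  if (positive == "AF") {
    tp <- cm$tp; fp <- cm$fp; fn <- cm$fn
  } else {
    tp <- cm$tn; fp <- cm$fn; fn <- cm$fp
  }
  safe_pct <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting 0", call. = FALSE)
      return(0)
    }
    100 * num / den
  }
  recall <- safe_pct(tp, tp + fn, paste(positive, "recall"))
  precision <- safe_pct(tp, tp + fp, paste(positive, "precision"))
  f <- f_measure(recall, precision)
  list(recall = recall, precision = precision, f_measure = f)
}

#' F-measure from recall and precision percentages
#'
#' @param recall,precision Percentages in \[0, 100\].
#' @param beta Weighting parameter (1 = harmonic mean).
#' @return F-measure in percent; 0 when `recall + precision == 0`.
#' @examples
#' f_measure(93.5, 89.5)  # 91.46 after rounding
#' @export
f_measure <- function(recall, precision, beta = 1) {
  if (recall + precision == 0) return(0)
  (beta^2 + 1) * recall * precision / (beta^2 * recall + precision)
}

#' Speed-rank time factors for a set of methods
#'
#' Methods are ranked by measured time (fastest first; ties broken by input
#' order, with a warning). The fastest method gets factor 1.00; each
#' subsequent rank loses 0.02, flooring at 0.02. Ranks may also be supplied
#' directly instead of times (hardware-independent comparisons).
#'
#' @param methods data.frame with columns `method` and either
#'   `measured_time_s` or `speed_rank`.
#' @return The input with `speed_rank` and `time_factor` columns filled in.
#' @examples
#' time_factors(data.frame(method = c("ceemd", "eemd"),
#'                         measured_time_s = c(5.8291, 36.1267)))
#' @export
time_factors <- function(methods) {
  if (!is.data.frame(methods) || !nrow(methods)) {
    stop_invalid("methods must be a non-empty data.frame")
  }
  if (is.null(methods$speed_rank)) {
    if (is.null(methods$measured_time_s)) {
      stop_invalid("need either measured_time_s or speed_rank")
    }
    tt <- methods$measured_time_s
    if (anyDuplicated(tt)) {
      warning("tied times; breaking ties by input order", call. = FALSE)
    }
    methods$speed_rank <- rank(tt, ties.method = "first")
  }
  methods$time_factor <- time_factor_for_rank(methods$speed_rank)
  methods
}

#' Time factor for a 1-based speed rank
#'
#' `(100 - 2 * (rank - 1)) / 100`, floored at 0.02 so the factor never
#' reaches zero however many methods are compared.
#'
#' @param rank 1-based speed rank(s).
#' @return Time factor(s) in (0, 1\].
#' @export
time_factor_for_rank <- function(rank) {
  pmax(0.02, (100 - 2 * (rank - 1)) / 100)
}

#' ET-score: speed-weighted F-measure combination
#'
#' `ET = (beta^2 + 1) * F_AF * F_NSR / (beta^2 * (F_AF + F_NSR)) *
#' time_factor`. With `beta = 1` the F-combination is the harmonic mean of
#' the two per-class F-measures, so a method with equal F-measures and the
#' top speed rank scores exactly that F value. Returned at full precision;
#' reports round half-up to 2 decimals.
#'
#' @param f_af,f_nsr Per-class F-measures in percent.
#' @param time_factor Speed factor in (0, 1\] from [time_factor_for_rank()].
#' @param beta Weighting parameter (default 1).
#' @return The ET-score (percent scale, full precision).
#' @examples
#' et_score(85.06, 83.65, 1.00)  # 84.35 after rounding
#' et_score(96.18, 93.63, 0.98)  # 92.99 after rounding
#' @export
et_score <- function(f_af, f_nsr, time_factor, beta = 1) {
  if (!is_number(f_af) || !is_number(f_nsr) ||
      f_af < 0 || f_af > 100 || f_nsr < 0 || f_nsr > 100) {
    stop_invalid("F-measures must lie in [0, 100]")
  }
  if (!is_number(time_factor) || time_factor <= 0 || time_factor > 1) {
    stop_invalid("time_factor must lie in (0, 1]")
  }
  if (f_af + f_nsr == 0) return(0)
  (beta^2 + 1) * f_af * f_nsr / (beta^2 * (f_af + f_nsr)) * time_factor
}

#' Overall accuracy (percent)
#'
#' From a confusion matrix, `(tp + tn) / total * 100`; alternatively from
#' per-class recalls and class prevalences as the prevalence-weighted mean
#' recall (the two agree when prevalences match the confusion matrix).
#'
#' @param cm An [confusion()] object, or `NULL` when using recalls.
#' @param recalls Named or ordered numeric vector of per-class recalls
#'   (percent).
#' @param prevalences Class prevalences matching `recalls` (fractions or
#'   percentages; normalized to sum 1).
#' @return Accuracy in percent.
#' @examples
#' accuracy(recalls = c(AF = 100, NSR = 98), prevalences = c(60, 40)) # 99.2
#' @export
accuracy <- function(cm = NULL, recalls = NULL, prevalences = NULL) {
  if (!is.null(cm)) {
    if (!inherits(cm, "af_confusion")) stop_invalid("cm must be an af_confusion")
    total <- cm$tp + cm$fp + cm$fn + cm$tn
    if (total == 0) stop_invalid("empty confusion matrix")
    return(100 * (cm$tp + cm$tn) / total)
  }
  if (is.null(recalls) || is.null(prevalences)) {
    stop_invalid("supply either cm or recalls + prevalences")
  }
  if (length(recalls) != length(prevalences)) {
    stop_invalid("recalls and prevalences must have equal length")
  }
  w <- prevalences / sum(prevalences)
  sum(w * recalls)
}

#' Compare AF-detection methods by F-measure and ET-score
#'
#' Builds the method-comparison table: per-class F-measures from each
#' method's confusion matrix, speed ranks from measured times (or supplied
#' ranks), and the ET-score, sorted by ET-score descending.
#'
#' @param results data.frame with columns `method`, `tp`, `fp`, `fn`, `tn`
#'   and either `measured_time_s` or `speed_rank`.
#' @param beta ET-score weighting parameter.
#' @return An object of class `et_report`: data.frame with columns
#'   `method`, `f_af`, `f_nsr`, `speed_rank`, `time_factor`, `et_score`
#'   (full precision; printing rounds to 2 decimals).
#' @export
compare_methods <- function(results, beta = 1) {
  need <- c("method", "tp", "fp", "fn", "tn")
  if (!is.data.frame(results) || !all(need %in% names(results))) {
    stop_invalid("results must contain columns ", paste(need, collapse = ", "))
  }
  if (nrow(results) < 2L) stop_invalid("need at least 2 methods to compare")
  results <- time_factors(results)
  rows <- lapply(seq_len(nrow(results)), function(i) {
    cm <- structure(list(tp = results$tp[i], fp = results$fp[i],
                         fn = results$fn[i], tn = results$tn[i]),
                    class = "af_confusion")
    f_af <- class_metrics(cm, "AF")$f_measure
    f_nsr <- class_metrics(cm, "NSR")$f_measure
    data.frame(method = results$method[i], f_af = f_af, f_nsr = f_nsr,
               speed_rank = results$speed_rank[i],
               time_factor = results$time_factor[i],
               et_score = et_score(f_af, f_nsr, results$time_factor[i],
                                   beta = beta),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$et_score), ]
  rownames(out) <- NULL
  class(out) <- c("et_report", "data.frame")
  out
}

#' @export
print.et_report <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  for (col in c("f_af", "f_nsr", "et_score")) {
    y[[col]] <- round_half_up(y[[col]], digits)
  }
  print(y, row.names = FALSE)
  invisible(x)
}
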