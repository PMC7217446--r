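# Evaluation metrics: accuracy (identical to micro F-score in single-label
# classification), macro F-score (unweighted mean of per-class F1 over the
# classes present in the ground truth; zero-division components contribute 0),
# percentile-bootstrap confidence intervals, and McNemar's test for paired
# classifier comparison.

#' Per-class true-positive / false-positive / false-negative counts
#'
#' @param truth,pred aligned label vectors
#' @return data.frame with one row per ground-truth class
#' @export
eval_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) > 0L)
  classes <- sort(unique(truth))
  tp <- vapply(classes, function(k) sum(truth == k & pred == k), numeric(1L))
  fp <- vapply(classes, function(k) sum(truth != k & pred == k), numeric(1L))
  fn <- vapply(classes, function(k) sum(truth == k & pred != k), numeric(1L))
  data.frame(class = classes, tp = tp, fp = fp, fn = fn)
}

#' Classification accuracy (= micro F-score for single-label tasks)
#' @param truth,pred aligned label vectors
#' @return fraction of exactly correct predictions
#' @export
accuracy_score <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (length(truth) == 0L) stop("empty input")
  mean(truth == pred)
}

# micro F from counts; used as an independent identity check on accuracy
micro_f1 <- function(counts) {
  p <- sum(counts$tp) / (sum(counts$tp) + sum(counts$fp))
  r <- sum(counts$tp) / (sum(counts$tp) + sum(counts$fn))
  if (is.nan(p) || is.nan(r) || p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Macro F-score
#'
#' Per-class precision, recall and F1 averaged unweighted over the classes
#' present in the ground truth. A class with an undefined precision, recall or
#' F1 (zero denominator) contributes 0.
#'
#' @param truth,pred aligned label vectors
#' @return macro F-score in [0, 1]
#' @export
macro_f1 <- function(truth, pred) {
  counts <- eval_counts(truth, pred)
  f1 <- mapply(function(tp, fp, fn) {
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, counts$tp, counts$fp, counts$fn)
  mean(f1)
}

#' Percentile-bootstrap confidence interval for a metric
#'
#' Resamples prediction-truth pairs with replacement to the original size,
#' recomputes the metric on each resample, and reports the 2.5 and 97.5
#' percentiles (95% interval by default).
#'
#' @param truth,pred aligned label vectors
#' @param metric a function of (truth, pred), e.g. [accuracy_score()] or
#'   [macro_f1()]
#' @param reps number of bootstrap resamples (default 1000)
#' @param seed RNG seed; the interval is deterministic given the seed
#' @param level confidence level (default 0.95)
#' @return named numeric vector `c(lo, hi)` with attribute `values` holding
#'   the resampled metric values
#' @export
bootstrap_ci <- function(truth, pred, metric = accuracy_score, reps = 1000L,
                         seed = 1L, level = 0.95) {
  if (reps < 1L) stop("reps must be >= 1")
  n <- length(truth)
  stopifnot(n >= 1L, length(pred) == n)
  vals <- with_seed(seed, vapply(seq_len(reps), function(r) {
    ix <- sample.int(n, n, replace = TRUE)
    metric(truth[ix], pred[ix])
  }, numeric(1L)))
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(vals, c(a, 1 - a), type = 7))
  structure(c(lo = ci[1L], hi = ci[2L]), values = vals)
}

#' McNemar's test for a paired comparison of two classifiers
#'
#' Counts the discordant pairs b (A right, B wrong) and c (A wrong, B right).
#' Uses the exact two-sided binomial test when b + c < 25 and the chi-square
#' approximation with continuity correction ((|b - c| - 1)^2 / (b + c))
#' otherwise. When b + c = 0 the classifiers are indistinguishable and p = 1
#' with method "degenerate".
#'
#' @param predsA,predsB predictions of the two classifiers
#' @param truth ground-truth labels
#' @return list with `b`, `c`, `p_value`, `method`
#' @export
mcnemar_compare <- function(predsA, predsB, truth) {
  stopifnot(length(predsA) == length(truth), length(predsB) == length(truth))
  rightA <- predsA == truth
  rightB <- predsB == truth
  b <- sum(rightA & !rightB)
  c_ <- sum(!rightA & rightB)
  if (b + c_ == 0L) {
    return(list(b = b, c = c_, p_value = 1.0, method = "degenerate"))
  }
  if (b + c_ < 25L) {
    p <- stats::binom.test(b, b + c_, p = 0.5)$p.value
    method <- "exact"
  } else {
    chi <- (abs(b - c_) - 1)^2 / (b + c_)
    p <- stats::pchisq(chi, df = 1L, lower.tail = FALSE)
    method <- "chisq"
  }
  list(b = b, c = c_, p_value = min(p, 1.0), method = method)
}

#' Full evaluation report with bootstrap confidence intervals
#'
#' @param truth,pred aligned label vectors
#' @param reps bootstrap resamples (default 1000)
#' @param seed bootstrap seed
#' @return an `eval_report`: accuracy and macro F with their 95% percentile
#'   CIs, plus flags when a percentile interval excludes its point estimate
#' @export
evaluate_predictions <- function(truth, pred, reps = 1000L, seed = 1L) {
  acc <- accuracy_score(truth, pred)
  mf <- macro_f1(truth, pred)
  ci_acc <- bootstrap_ci(truth, pred, accuracy_score, reps = reps, seed = seed)
  ci_mf <- bootstrap_ci(truth, pred, macro_f1, reps = reps, seed = seed + 1L)
  structure(list(
    n = length(truth),
    accuracy = acc, accuracy_ci = unname(ci_acc[c("lo", "hi")]),
    macro_f = mf, macro_f_ci = unname(ci_mf[c("lo", "hi")]),
    accuracy_ci_excludes_point = acc < ci_acc[["lo"]] || acc > ci_acc[["hi"]],
    macro_f_ci_excludes_point = mf < ci_mf[["lo"]] || mf > ci_mf[["hi"]],
    reps = as.integer(reps), seed = as.integer(seed)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d\n  accuracy %.4f (%.4f, %.4f)\n  macro-F  %.4f (%.4f, %.4f)\n",
              x$n, x$accuracy, x$accuracy_ci[1L], x$accuracy_ci[2L],
              x$macro_f, x$macro_f_ci[1L], x$macro_f_ci[2L]))
  invisible(x)
}

#' Write an evaluation report as JSON
#' @param report an `eval_report`
#' @param path output path
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
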