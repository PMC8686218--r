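#' Score one dataset's identifications against ground truth
#'
#' A dataset contributes exactly one true combination: `tp = 1` when the
#' truth tuple appears among the significant findings, else `fn = 1`;
#' every other significant finding counts as a false positive.
#'
#' @param findings a data.frame of findings as returned by [clean()]
#'   (columns `locus1..locusk`, `significant`); only significant rows are
#'   counted.
#' @param truth ground-truth list with `causal_loci` (ascending tuple).
#' @return List with `tp`, `fp`, `fn`, `success`.
#' @export
score_dataset <- function(findings, truth) {
  k <- length(truth$causal_loci)
  sig <- findings[findings$significant, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(list(tp = 0L, fp = 0L, fn = 1L, success = FALSE))
  tuples <- as.matrix(sig[, paste0("locus", 1:k), drop = FALSE])
  tuples <- t(apply(tuples, 1L, sort))
  hit <- apply(tuples, 1L, function(r) all(r == sort(truth$causal_loci)))
  tp <- as.integer(any(hit))
  list(tp = tp, fp = sum(!hit), fn = 1L - tp, success = tp == 1L)
}

#' Aggregate per-dataset scores into benchmark metrics
#'
#' Micro-averaged over datasets: `power = N_s / N_d`,
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`,
#' `F1 = 2 * recall * precision / (recall + precision)` (0 when a
#' denominator is 0).
#'
#' @param scores list of [score_dataset()] results.
#' @param model_id optional label carried into the result.
#' @return Object of class `benchmark_result` with fields `model_id`,
#'   `n_datasets`, `n_success`, `tp`, `fp`, `fn`, `power`, `recall`,
#'   `precision`, `f1`.
#' @export
aggregate_benchmark <- function(scores, model_id = NA_integer_) {
  if (!length(scores)) stop("need at least one dataset score")
  tp <- sum(vapply(scores, `[[`, integer(1), "tp"))
  fp <- sum(vapply(scores, `[[`, integer(1), "fp"))
  fn <- sum(vapply(scores, `[[`, integer(1), "fn"))
  ns <- sum(vapply(scores, `[[`, logical(1), "success"))
  nd <- length(scores)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (recall + precision > 0)
    2 * recall * precision / (recall + precision) else 0
  structure(list(model_id = model_id, n_datasets = nd, n_success = ns,
                 tp = tp, fp = fp, fn = fn, power = ns / nd,
                 recall = recall, precision = precision, f1 = f1),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "benchmark_result (model %s): %d datasets, power %.3f, recall %.3f, precision %.3f, F1 %.3f\n",
    ifelse(is.na(x$model_id), "?", x$model_id), x$n_datasets,
    x$power, x$recall, x$precision, x$f1))
  invisible(x)
}
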