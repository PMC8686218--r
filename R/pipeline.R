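#' Two-stage epistasis scan of a case-control dataset
#'
#' The main entry point: runs the evolutionary screening stage
#' ([evolve()]) to accumulate a candidate archive, then the chi-square
#' cleaning stage ([clean()]) over every archived combination.  The
#' scan's final identification is the most significant finding (smallest
#' p-value, ties broken by K2 score then loci) provided it passes
#' `alpha`; the remaining significant findings are retained in the
#' findings table for inspection, since archived candidates overlapping
#' the identified pair are shadows of the same association signal.
#'
#' @param dataset a [genotype_dataset()].
#' @param k interaction order to scan for.
#' @param alpha cleaning-stage significance level.
#' @param seed integer seed making the scan reproducible.
#' @param bonferroni apply a Bonferroni-adjusted threshold in cleaning.
#' @param ... further arguments to [evolution_params()]
#'   (`population_size`, `n_iterations`, `head_length`, `initial_rate`,
#'   `archive_size`, `elitism_count`, `rate_bounds`, `fuzzy`).
#' @return Object of class `epigep_scan`: list with `archive`
#'   (the [evolve()] result), `findings` (the [clean()] table),
#'   `detection` (0- or 1-row data.frame with the identified
#'   combination), `params`, `alpha` and `call`.
#' @examples
#' sim <- simulate_dataset(disease_model(8), n_cases = 200, n_controls = 200,
#'                         n_snps = 20, seed = 7)
#' scan <- detect_epistasis(sim$data, k = 2, n_iterations = 50, seed = 7)
#' scan$detection
#' @export
detect_epistasis <- function(dataset, k = 2, alpha = 0.05, seed = NULL,
                             bonferroni = FALSE, ...) {
  params <- evolution_params(k = k, ...)
  archive <- evolve(dataset, params, seed = seed)
  findings <- clean(archive, dataset, alpha = alpha, bonferroni = bonferroni)
  sig <- findings[findings$significant, , drop = FALSE]
  detection <- utils::head(sig, 1L)
  structure(list(archive = archive, findings = findings,
                 detection = detection, params = params, alpha = alpha,
                 call = match.call()),
            class = "epigep_scan")
}

#' @export
print.epigep_scan <- function(x, ...) {
  k <- x$params$k
  cat(sprintf("epigep_scan (order %d): %d candidates cleaned, %d significant\n",
              k, nrow(x$findings), sum(x$findings$significant)))
  if (nrow(x$detection)) {
    loci <- unlist(x$detection[1, paste0("locus", 1:k)])
    cat(sprintf("  identified combination: (%s)  K2 = %.3f, chi2 = %.2f, p = %.3g\n",
                paste(loci, collapse = ", "), x$detection$k2_score,
                x$detection$chi2_stat, x$detection$p_value))
  } else {
    cat("  no combination significant at alpha =", x$alpha, "\n")
  }
  invisible(x)
}

#' @export
summary.epigep_scan <- function(object, n = 10L, ...) {
  print(object)
  cat("\nTop findings:\n")
  print(utils::head(object$findings, n))
  invisible(object)
}

#' @export
plot.epigep_scan <- function(x, ...) {
  tr <- x$archive$trace
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$iter, tr$best, type = "l", xlab = "generation",
                 ylab = "K2 score", main = "screening progress")
  graphics::lines(tr$iter, tr$mean, lty = 2)
  graphics::legend("topright", legend = c("best", "mean"), lty = 1:2,
                   bty = "n")
  graphics::plot(tr$iter, tr$crossover_rate, type = "l", ylim = c(0, 1),
                 xlab = "generation", ylab = "rate",
                 main = "genetic manipulation rates")
  graphics::lines(tr$iter, tr$mutation_rate, lty = 2)
  graphics::lines(tr$iter, tr$adjacent_rate, lty = 3)
  graphics::legend("topright", lty = 1:3, bty = "n",
                   legend = c("crossover", "mutation", "adjacent"))
  invisible(x)
}

#' Simulate-detect-evaluate benchmark over replicate datasets
#'
#' For each replicate `r`, simulates a dataset from `model` with seed
#' `base_seed + r`, runs the two-stage scan, and scores the identified
#' combination against the simulated ground truth; scores are aggregated
#' into power/recall/precision/F1.
#'
#' @param model a [disease_model()] or model id 1..22.
#' @param n_replicates number of replicate datasets.
#' @param n_cases,n_controls,n_snps simulation dimensions.
#' @param base_seed replicate `r` uses seed `base_seed + r`.
#' @param alpha cleaning-stage significance level.
#' @param ... further arguments to [evolution_params()].
#' @return Object of class `epigep_benchmark`: list with `result` (a
#'   [aggregate_benchmark()] object), `per_dataset` (per-replicate scores
#'   and detections) and `config`.
#' @export
run_pipeline <- function(model, n_replicates = 20, n_cases = 750,
                         n_controls = 750, n_snps = 100, base_seed = 1,
                         alpha = 0.05, ...) {
  if (is.numeric(model) && length(model) == 1L) model <- disease_model(model)
  scores <- vector("list", n_replicates)
  per <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    ok <- tryCatch({
      sim <- simulate_dataset(model, n_cases = n_cases,
                              n_controls = n_controls, n_snps = n_snps,
                              seed = base_seed + r)
      scan <- detect_epistasis(sim$data, alpha = alpha, ...)
      sc <- score_dataset(scan$detection, sim$truth)
      per[[r]] <- list(truth = sim$truth$causal_loci,
                       detection = scan$detection, score = sc)
      scores[[r]] <- sc
      TRUE
    }, error = function(e) {
      warning(sprintf("replicate %d failed: %s", r, conditionMessage(e)))
      FALSE
    })
    if (!ok) next
  }
  done <- !vapply(scores, is.null, logical(1))
  if (!any(done)) stop("all replicates failed")
  if (!all(done))
    warning("aggregate computed over ", sum(done), " of ", n_replicates,
            " replicates")
  res <- aggregate_benchmark(scores[done], model_id = model$model_id)
  structure(list(result = res, per_dataset = per[done],
                 config = list(model_id = model$model_id,
                               n_replicates = n_replicates,
                               n_cases = n_cases, n_controls = n_controls,
                               n_snps = n_snps, base_seed = base_seed,
                               alpha = alpha)),
            class = "epigep_benchmark")
}

#' @export
print.epigep_benchmark <- function(x, ...) {
  print(x$result)
  invisible(x)
}
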