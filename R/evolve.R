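#' Evolution parameters for the screening stage
#'
#' Defaults follow the method's standard setting: population 100, 1000
#' iterations, head length 5 (tail length 6 by the Karva rule
#' `t = h(arity - 1) + 1`), initial genetic manipulation rate 0.3 applied
#' to crossover, point mutation and adjacent mutation alike, archive of
#' the 100 best candidate combinations, one elite copied unchanged.
#'
#' @param k interaction order (genes per chromosome).
#' @param population_size chromosomes per generation.
#' @param n_iterations generations before termination.
#' @param head_length gene head length `h`.
#' @param initial_rate generation-0 rate for all three operators.
#' @param archive_size candidate combinations retained for cleaning.
#' @param elitism_count best chromosomes copied unchanged each generation.
#' @param rate_bounds fuzzy-controller output range `[rate_min, rate_max]`.
#' @param fuzzy use fuzzy adaptive rate control; `FALSE` freezes all
#'   three rates at `initial_rate` for every generation.
#' @return A list of class `evolution_params`.
#' @export
evolution_params <- function(k = 2, population_size = 100,
                             n_iterations = 1000, head_length = 5,
                             initial_rate = 0.3, archive_size = 100,
                             elitism_count = 1, rate_bounds = c(0.05, 0.95),
                             fuzzy = TRUE) {
  stopifnot(k >= 1, population_size >= 2, n_iterations >= 1,
            head_length >= 1, archive_size >= 1, elitism_count >= 0,
            initial_rate >= 0, initial_rate <= 1,
            rate_bounds[1] > 0, rate_bounds[1] < rate_bounds[2],
            rate_bounds[2] < 1)
  structure(list(k = as.integer(k),
                 population_size = as.integer(population_size),
                 n_iterations = as.integer(n_iterations),
                 head_length = as.integer(head_length),
                 initial_rate = initial_rate,
                 archive_size = as.integer(archive_size),
                 elitism_count = as.integer(elitism_count),
                 rate_bounds = rate_bounds, fuzzy = isTRUE(fuzzy)),
            class = "evolution_params")
}

#' Evolve a candidate archive on a dataset
#'
#' The screening stage: a population of tailor-made chromosomes evolves
#' under roulette selection with elitism, one-point crossover, point
#' mutation, adjacent mutation and multi-gene mutation, with the three
#' operator rates adapted each generation by fuzzy control of the
#' population-diversity ratio.  Every evaluated locus combination is
#' scored once by the K2 fitness and the best `archive_size` unique
#' combinations are returned.
#'
#' @param dataset a [genotype_dataset()].
#' @param params an [evolution_params()].
#' @param seed integer seed; same `(dataset, params, seed)` give an
#'   identical archive.
#' @return Object of class `candidate_archive`: list with `loci`
#'   (n x k matrix of ascending tuples, rows ordered by score), `k2`
#'   (scores, ascending), `gt` (GT domains recorded with each tuple),
#'   `trace` (per-generation best/mean score, diversity d and rates) and
#'   `n_evaluated` (unique combinations scored).
#' @export
evolve <- function(dataset, params = evolution_params(), seed = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(params, "evolution_params"))
  M <- ncol(dataset$genotypes)
  if (params$k >= M)
    stop("configuration error: interaction order must be below the SNP count")
  if (!is.null(seed)) set.seed(seed)
  controllers <- default_rate_controllers(params$rate_bounds[1],
                                          params$rate_bounds[2])
  rate_fn <- function(d, iter_frac)
    update_rates(list(d = d, iter_frac = iter_frac), controllers)
  res <- cpp_evolve(dataset$genotypes, dataset$phenotype, params$k,
                    params$head_length, params$population_size,
                    params$n_iterations, params$initial_rate,
                    params$archive_size, params$elitism_count, rate_fn,
                    params$fuzzy)
  res$trace <- as.data.frame(res$trace)
  structure(res, class = "candidate_archive", params = params)
}

#' @export
print.candidate_archive <- function(x, ...) {
  cat(sprintf("candidate_archive: %d combinations (best K2 = %.3f), %d evaluated\n",
              nrow(x$loci), x$k2[1], as.integer(x$n_evaluated)))
  invisible(x)
}
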