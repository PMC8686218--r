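#' Simulate a case-control dataset with embedded two-locus epistasis
#'
#' Rejection sampling from a penetrance model under Hardy-Weinberg
#' equilibrium: causal-locus genotypes are drawn from HWE at the model's
#' MAF, disease status is a coin flip with probability equal to the
#' penetrance of the drawn genotype pair, and individuals are kept while
#' their case/control quota is unfilled.  Neutral loci are independent HWE
#' draws with per-locus MAFs sampled once per dataset from
#' `Uniform(maf_range)`.  The causal loci are placed at positions drawn
#' uniformly without replacement and recorded in the returned ground
#' truth.
#'
#' @param model a [disease_model()] (or an integer model id 1..22).
#' @param n_cases,n_controls case/control quotas (defaults 750/750).
#' @param n_snps total SNP count (default 100).
#' @param seed integer seed; identical `(model, seed)` give identical
#'   datasets.
#' @param maf_range range from which neutral-locus MAFs are drawn.
#' @param max_attempts cap on rejection-sampling draws before the
#'   penetrance table is declared degenerate.
#' @return A list with elements `data` (a [genotype_dataset()]), `truth`
#'   (list with `causal_loci`, ascending 1-based pair, and `model_id`)
#'   and `mafs` (the per-locus MAFs used, causal loci included).
#' @examples
#' sim <- simulate_dataset(disease_model(8), n_cases = 50, n_controls = 50,
#'                         n_snps = 20, seed = 1)
#' sim$truth$causal_loci
#' @export
simulate_dataset <- function(model, n_cases = 750, n_controls = 750,
                             n_snps = 100, seed = NULL,
                             maf_range = c(0.05, 0.5),
                             max_attempts = 1e7) {
  if (is.numeric(model) && length(model) == 1L) model <- disease_model(model)
  stopifnot(inherits(model, "disease_model"))
  tab <- build_penetrance(model)
  k <- tab$k
  if (n_snps < k) stop("n_snps must be at least the interaction order")
  if (n_cases < 1 || n_controls < 1) stop("case/control counts must be positive")
  if (!is.null(seed)) set.seed(seed)

  n_neutral <- n_snps - k
  neutral_mafs <- stats::runif(n_neutral, maf_range[1], maf_range[2])
  causal_pos <- sort(sample.int(n_snps, k))

  freqs <- lapply(tab$mafs, hwe_genotype_freqs)
  N <- n_cases + n_controls
  causal <- matrix(0L, N, k)
  pheno <- integer(N)
  got_cases <- 0L; got_controls <- 0L; filled <- 0L; drawn <- 0L
  batch <- max(4096L, N)
  while (filled < N) {
    if (drawn >= max_attempts)
      stop("simulation error: case/control quotas unreachable under this penetrance table")
    g1 <- sample.int(3L, batch, replace = TRUE, prob = freqs[[1]]) - 1L
    g2 <- sample.int(3L, batch, replace = TRUE, prob = freqs[[2]]) - 1L
    pen <- tab$entries[cbind(g1 + 1L, g2 + 1L)]
    y <- as.integer(stats::runif(batch) < pen)
    drawn <- drawn + batch
    for (i in seq_len(batch)) {
      if (y[i] == 1L) {
        if (got_cases >= n_cases) next
        got_cases <- got_cases + 1L
      } else {
        if (got_controls >= n_controls) next
        got_controls <- got_controls + 1L
      }
      filled <- filled + 1L
      causal[filled, 1L] <- g1[i]
      causal[filled, 2L] <- g2[i]
      pheno[filled] <- y[i]
      if (filled == N) break
    }
  }

  geno <- matrix(0L, N, n_snps)
  if (n_neutral > 0) {
    neutral <- matrix(
      stats::rbinom(N * n_neutral, 2L, rep(neutral_mafs, each = N)),
      N, n_neutral)
    geno[, setdiff(seq_len(n_snps), causal_pos)] <- neutral
  }
  geno[, causal_pos] <- causal
  maf_by_locus <- numeric(n_snps)
  maf_by_locus[setdiff(seq_len(n_snps), causal_pos)] <- neutral_mafs
  maf_by_locus[causal_pos] <- tab$mafs
  list(data = genotype_dataset(geno, pheno),
       truth = list(causal_loci = causal_pos, model_id = model$model_id),
       mafs = maf_by_locus)
}
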