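#' Genotype-combination x disease-state contingency counts
#'
#' Tallies individuals by the base-3 encoding of their genotypes at the
#' given loci, split by phenotype.  The table has `3^k` rows (one per
#' genotype combination, first locus varying fastest) and two columns
#' (controls, cases).
#'
#' @param dataset a [genotype_dataset()].
#' @param loci distinct 1-based locus indices.
#' @return Object of class `combo_counts`: list with `table` (`3^k x 2`
#'   integer matrix), `k`, `loci`, `n`.
#' @export
count_genotype_combinations <- function(dataset, loci) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  loci <- as.integer(loci)
  M <- ncol(dataset$genotypes)
  if (any(loci < 1L | loci > M)) stop("locus index out of range 1..", M)
  if (anyDuplicated(loci)) stop("loci must be distinct")
  k <- length(loci)
  idx <- rep(0L, nrow(dataset$genotypes))
  p3 <- 1L
  for (j in seq_len(k)) {
    idx <- idx + dataset$genotypes[, loci[j]] * p3
    p3 <- p3 * 3L
  }
  I <- 3L^k
  tab <- matrix(0L, I, 2L, dimnames = list(NULL, c("control", "case")))
  t0 <- tabulate(idx[dataset$phenotype == 0L] + 1L, nbins = I)
  t1 <- tabulate(idx[dataset$phenotype == 1L] + 1L, nbins = I)
  tab[, 1L] <- t0
  tab[, 2L] <- t1
  structure(list(table = tab, k = k, loci = loci,
                 n = nrow(dataset$genotypes)),
            class = "combo_counts")
}

#' K2 Bayesian-network score of a contingency table
#'
#' Negative log marginal likelihood of the disease node given the SNP
#' combination, computed via log-gamma:
#' `sum_i [ ln((r_i + 1)!) - sum_j ln(r_ij!) ]`, where `r_i` is the count
#' of the i-th genotype combination and `r_ij` its count in disease state
#' j.  Empty combinations contribute 0.  Lower is better; the score is
#' always non-negative.
#'
#' @param counts a [count_genotype_combinations()] result, or a two-column
#'   count matrix.
#' @return Non-negative numeric score.
#' @examples
#' k2_log_score(matrix(c(1, 1), 1))  # ln(3!) - 0 - 0 = log(6)
#' @export
k2_log_score <- function(counts) {
  tab <- if (inherits(counts, "combo_counts")) counts$table else as.matrix(counts)
  if (any(tab < 0)) stop("counts must be non-negative")
  ri <- rowSums(tab)
  sum(lgamma(ri + 2) - rowSums(lgamma(tab + 1)))
}

#' K2 score of a locus tuple on a dataset
#'
#' Convenience wrapper equal to
#' `k2_log_score(count_genotype_combinations(dataset, loci))`, evaluated by
#' the compiled scoring routine used inside the search.
#'
#' @inheritParams count_genotype_combinations
#' @export
k2_score <- function(dataset, loci) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  loci <- as.integer(loci)
  M <- ncol(dataset$genotypes)
  if (any(loci < 1L | loci > M)) stop("locus index out of range 1..", M)
  if (anyDuplicated(loci)) stop("loci must be distinct")
  cpp_k2_score(dataset$genotypes, dataset$phenotype, loci)
}
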