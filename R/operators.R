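# R surface over the genetic operators implemented in src/.  All operators
# draw from R's RNG, so set.seed() makes them reproducible.

.chrom_attrs <- function(x, template) {
  structure(x, class = "epi_chromosome", k = attr(template, "k"),
            head_length = attr(template, "head_length"))
}

#' Point mutation
#'
#' Each symbol position mutates independently with probability `rate`.
#' Head positions resample uniformly from functors and terminals, tail
#' positions from terminals only, the GT domain from \{0, 1, 2\}, so the
#' structural invariants are preserved by construction.
#'
#' @param chrom an [epi_chromosome()].
#' @param n_snps total SNP count (terminal alphabet is `1..n_snps`).
#' @param rate per-position mutation probability.
#' @return The mutated chromosome.
#' @export
point_mutation <- function(chrom, n_snps, rate) {
  stopifnot(rate >= 0, rate <= 1)
  out <- cpp_point_mutation(as.integer(chrom), attr(chrom, "k"),
                            attr(chrom, "head_length"), as.integer(n_snps),
                            rate)
  .chrom_attrs(out, chrom)
}

#' Adjacent mutation
#'
#' Mutates only the tail or the GT domain of a gene: a tail terminal is
#' replaced by one of its two neighbouring locus indices (wrapping at the
#' boundaries 1 and `n_snps`), or the GT domain by one of the two other
#' genotype values.  The head is never modified.
#'
#' @param gene an [epi_gene()].
#' @param n_snps total SNP count.
#' @return The mutated gene.
#' @export
adjacent_mutation <- function(gene, n_snps) {
  if (n_snps < 2) stop("adjacent mutation needs at least two loci")
  h <- attr(gene, "head_length")
  out <- cpp_adjacent_mutation(as.integer(gene), h, as.integer(n_snps))
  structure(out, class = "epi_gene", head_length = h)
}

#' Multi-gene mutation
#'
#' Resamples one uniformly chosen position in each of `m >= 2` distinct
#' genes (`m` uniform in `[2, k]`), under the same alphabet rules as
#' [point_mutation()].  A no-op (with a warning) for `k = 1`.
#'
#' @inheritParams point_mutation
#' @export
multi_gene_mutation <- function(chrom, n_snps) {
  k <- attr(chrom, "k")
  if (k < 2) {
    warning("multi-gene mutation is a no-op for single-gene chromosomes")
    return(chrom)
  }
  out <- cpp_multi_gene_mutation(as.integer(chrom), k,
                                 attr(chrom, "head_length"),
                                 as.integer(n_snps))
  .chrom_attrs(out, chrom)
}

#' One-point crossover
#'
#' With probability `rate`, one-point recombination over the flattened
#' symbol string of the two parents (GT domains included, cut point
#' uniform over all positions); otherwise the parents are copied.  Because
#' head/tail alphabets align position-wise, offspring always satisfy the
#' structural invariants.
#'
#' @param a,b parent chromosomes with identical structure parameters.
#' @param rate crossover probability.
#' @return List of two offspring chromosomes.
#' @export
crossover <- function(a, b, rate) {
  if (attr(a, "k") != attr(b, "k") ||
      attr(a, "head_length") != attr(b, "head_length"))
    stop("parents must have identical structure parameters")
  out <- cpp_crossover(as.integer(a), as.integer(b), rate)
  list(.chrom_attrs(out[[1]], a), .chrom_attrs(out[[2]], a))
}

#' Repair a chromosome to distinct loci
#'
#' While two genes decode to the same locus, adjacent-mutates one of the
#' colliding genes (chosen uniformly); after a bounded number of rounds it
#' falls back to random tail re-initialisation.  The result always decodes
#' to pairwise-distinct loci.
#'
#' @inheritParams point_mutation
#' @export
repair <- function(chrom, n_snps) {
  k <- attr(chrom, "k")
  if (n_snps < k) stop("cannot repair: fewer loci than genes")
  out <- cpp_repair(as.integer(chrom), k, attr(chrom, "head_length"),
                    as.integer(n_snps))
  .chrom_attrs(out, chrom)
}

#' Random valid chromosome
#'
#' Uniform random symbols per alphabet (head: functors and terminals;
#' tail: terminals; GT: genotypes), followed by [repair()].
#'
#' @param k interaction order (number of genes).
#' @param head_length head length `h`; tail length is `h + 1`.
#' @param n_snps total SNP count.
#' @export
random_chromosome <- function(k, head_length, n_snps) {
  out <- cpp_random_chromosome(as.integer(k), as.integer(head_length),
                               as.integer(n_snps))
  structure(out, class = "epi_chromosome", k = as.integer(k),
            head_length = as.integer(head_length))
}

#' Roulette-wheel parent selection under minimisation
#'
#' Selection probability is proportional to `F_worst - F_i + eps`
#' (`eps = 1e-9 * F_worst + 1e-12`), so the lowest-score individual is the
#' most likely parent and an all-equal population is sampled uniformly.
#'
#' @param fitness numeric vector of K2 scores (lower is better).
#' @return 1-based index of the selected individual.
#' @export
roulette_select <- function(fitness) {
  if (!length(fitness) || any(!is.finite(fitness)))
    stop("fitness values must be finite and non-empty")
  cpp_roulette_select(as.numeric(fitness))
}
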