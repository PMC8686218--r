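#' Pearson chi-square test of a genotype-combination x disease table
#'
#' Tests independence of genotype combination and disease state on the
#' `3^k x 2` contingency table after dropping all-zero rows; degrees of
#' freedom are `(non-empty rows - 1) x (J - 1)`; no continuity
#' correction; the p-value is the upper tail of the chi-square
#' distribution.  With fewer than two non-empty rows or a zero column
#' marginal the test is undefined and `p = 1` is returned with
#' `degenerate = TRUE`.
#'
#' @param counts a [count_genotype_combinations()] result or a two-column
#'   count matrix.
#' @return List with `statistic`, `dof`, `p_value`, `degenerate`.
#' @export
chi_square_test <- function(counts) {
  tab <- if (inherits(counts, "combo_counts")) counts$table else as.matrix(counts)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L || any(colSums(tab) == 0))
    return(list(statistic = 0, dof = 0L, p_value = 1, degenerate = TRUE))
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - expected)^2 / expected)
  dof <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, dof = dof,
       p_value = stats::pchisq(stat, dof, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Cleaning stage: chi-square testing of every archived candidate
#'
#' Each combination in the candidate archive is tested for association
#' with disease status; combinations with `p < alpha` are flagged
#' significant.  Raw p-values are reported (no multiplicity correction)
#' unless `bonferroni = TRUE`, in which case the threshold is divided by
#' the number of tested combinations.
#'
#' @param archive a [evolve()] result (or any list with a `loci` matrix,
#'   `k2` scores and optionally `gt`).
#' @param dataset the [genotype_dataset()] the archive was built on.
#' @param alpha significance level (default 0.05).
#' @param bonferroni divide `alpha` by the number of candidates.
#' @return A `data.frame` of findings sorted by p-value, then K2 score,
#'   then loci: columns `locus1..locusk`, `gt1..gtk`, `k2_score`,
#'   `chi2_stat`, `dof`, `p_value`, `significant`.
#' @export
clean <- function(archive, dataset, alpha = 0.05, bonferroni = FALSE) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  loci <- archive$loci
  if (is.null(loci) || nrow(loci) == 0L) {
    message("empty candidate archive; nothing to clean")
    k <- if (is.null(loci)) 2L else ncol(loci)
    out <- as.data.frame(matrix(numeric(0), 0,  2 * k + 5))
    names(out) <- c(paste0("locus", 1:k), paste0("gt", 1:k),
                    "k2_score", "chi2_stat", "dof", "p_value", "significant")
    return(out)
  }
  k <- ncol(loci)
  M <- ncol(dataset$genotypes)
  if (any(loci < 1L | loci > M)) stop("archive loci out of dataset range")
  n <- nrow(loci)
  stat <- dof <- pval <- numeric(n)
  for (i in seq_len(n)) {
    ct <- chi_square_test(count_genotype_combinations(dataset, loci[i, ]))
    stat[i] <- ct$statistic; dof[i] <- ct$dof; pval[i] <- ct$p_value
  }
  thr <- if (bonferroni) alpha / n else alpha
  gt <- if (!is.null(archive$gt)) archive$gt else matrix(NA_integer_, n, k)
  out <- data.frame(loci, gt, k2_score = archive$k2, chi2_stat = stat,
                    dof = as.integer(dof), p_value = pval,
                    significant = pval < thr)
  names(out)[1:(2 * k)] <- c(paste0("locus", 1:k), paste0("gt", 1:k))
  ord <- do.call(order, c(list(out$p_value, out$k2_score),
                          lapply(1:k, function(j) out[[j]])))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
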