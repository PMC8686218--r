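#' Case-control genotype dataset
#'
#' Container for an N x M matrix of genotype codes (minor-allele counts
#' 0/1/2) together with a binary phenotype vector (0 = control, 1 = case).
#' Locus indices are 1-based throughout the package and follow the column
#' order of the matrix.
#'
#' @param genotypes integer matrix with entries in \{0, 1, 2\}; one column
#'   per SNP, one row per individual.
#' @param phenotype integer vector in \{0, 1\}, one entry per row of
#'   `genotypes`.
#' @param locus_names optional character vector of SNP names; defaults to
#'   `S1..SM`.
#' @return An object of class `genotype_dataset`: a list with elements
#'   `genotypes`, `phenotype`, `locus_names`, `n_cases`, `n_controls`.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L), nrow = 2)
#' genotype_dataset(g, c(0L, 1L))
#' @export
genotype_dataset <- function(genotypes, phenotype, locus_names = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  phenotype <- as.integer(phenotype)
  if (nrow(genotypes) != length(phenotype))
    stop("phenotype length must equal the number of genotype rows")
  if (length(genotypes) && !all(genotypes %in% 0:2))
    stop("genotype entries must be 0, 1 or 2")
  if (length(phenotype) && !all(phenotype %in% 0:1))
    stop("phenotype entries must be 0 (control) or 1 (case)")
  if (is.null(locus_names)) locus_names <- paste0("S", seq_len(ncol(genotypes)))
  if (length(locus_names) != ncol(genotypes))
    stop("locus_names must have one entry per SNP column")
  if (anyDuplicated(locus_names)) stop("locus names must be distinct")
  colnames(genotypes) <- locus_names
  structure(
    list(genotypes = genotypes, phenotype = phenotype,
         locus_names = locus_names,
         n_cases = sum(phenotype == 1L), n_controls = sum(phenotype == 0L)),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals (%d cases, %d controls), %d SNPs\n",
              nrow(x$genotypes), x$n_cases, x$n_controls, ncol(x$genotypes)))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' Read a tab-delimited case-control genotype file
#'
#' Expects the GAMETES-style layout: a header row of SNP names followed by
#' the class column, then one row of 0/1/2 genotype codes per individual
#' with the 0/1 disease status last.  Column order defines the 1-based
#' locus indices.
#'
#' @param path file to read.
#' @param class_col name of the phenotype column (default `"Class"`); it
#'   must be the final column.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, class_col = "Class") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "integer")
  if (ncol(tab) < 1L || names(tab)[ncol(tab)] != class_col)
    stop("format error: last column must be the class column '", class_col, "'")
  geno <- as.matrix(tab[, -ncol(tab), drop = FALSE])
  bad <- which(!(geno %in% c(0L, 1L, 2L)) | is.na(geno))
  if (length(bad)) {
    row <- (bad[1] - 1L) %% nrow(geno) + 1L
    col <- (bad[1] - 1L) %/% nrow(geno) + 1L
    stop(sprintf("parse error: genotype value '%s' at row %d, column %d is not 0/1/2",
                 geno[bad[1]], row, col))
  }
  genotype_dataset(geno, tab[[ncol(tab)]], locus_names = colnames(geno))
}

#' Write a genotype dataset as tab-delimited text
#'
#' Inverse of [read_genotypes()]: one header row (`locus names` then the
#' class column), one row per individual.  `read_genotypes(write_genotypes(d))`
#' reproduces `d` exactly.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output file.
#' @param class_col name for the phenotype column.
#' @export
write_genotypes <- function(dataset, path, class_col = "Class") {
  stopifnot(inherits(dataset, "genotype_dataset"))
  tab <- cbind(as.data.frame(dataset$genotypes), dataset$phenotype)
  names(tab) <- c(dataset$locus_names, class_col)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
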