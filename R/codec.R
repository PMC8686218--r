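# Karva (K-expression) codec.  Two routes exist on purpose: a generic
# symbolic codec handling arbitrary functor sets (including unary ones such
# as the square root Q), and the fast integer-coded route in src/ restricted
# to the {+, -, *, /} x {1..n} alphabet actually used by the search.  Tests
# cross-check the two.

.functor_codes <- c("+" = -1L, "-" = -2L, "*" = -3L, "/" = -4L)

.default_arities <- c("+" = 2L, "-" = 2L, "*" = 2L, "/" = 2L, "Q" = 1L)

#' Convert a K-expression to an expression tree
#'
#' Breadth-first decoding: the first symbol is the root; each functor
#' consumes the next unconsumed symbols as its children, level by level.
#' Trailing unused symbols are ignored (they are the unexpressed part of
#' the gene).
#'
#' @param symbols character vector of symbols, e.g.
#'   `c("Q","*","-","+","a","b","2","d","c")`.
#' @param arities named integer vector giving each functor's arity;
#'   symbols absent from it are terminals.
#' @return A nested list with elements `symbol` and (for functors)
#'   `children`.
#' @examples
#' tr <- kexpression_to_tree(strsplit("Q*-+ab2dc", "")[[1]])
#' evaluate_tree(tr, c(a = 9, b = 2, d = 5))  # sqrt((9-2)*(2+5)) = 7
#' @export
kexpression_to_tree <- function(symbols, arities = .default_arities) {
  symbols <- as.character(symbols)
  if (!length(symbols)) stop("empty K-expression")
  nodes <- list(list(symbol = symbols[1], children = integer(0)))
  queue <- 1L
  used <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    sym <- nodes[[i]]$symbol
    ar <- if (sym %in% names(arities)) arities[[sym]] else 0L
    if (ar > 0L) {
      if (used + ar > length(symbols))
        stop("malformed gene: K-expression exhausted before tree completed")
      kids <- integer(ar)
      for (j in seq_len(ar)) {
        used <- used + 1L
        nodes[[used]] <- list(symbol = symbols[used], children = integer(0))
        kids[j] <- used
      }
      nodes[[i]]$children <- kids
      queue <- c(queue, kids)
    }
  }
  build <- function(i) {
    nd <- nodes[[i]]
    if (!length(nd$children)) return(list(symbol = nd$symbol))
    list(symbol = nd$symbol, children = lapply(nd$children, build))
  }
  build(1L)
}

#' Evaluate an expression tree
#'
#' Recursive arithmetic evaluation with protected division (`x / 0` is 1).
#' Terminal symbols are parsed as numbers or looked up in `env`.
#'
#' @param tree a [kexpression_to_tree()] result.
#' @param env named numeric vector or list binding symbolic terminals.
#' @return A numeric scalar.
#' @export
evaluate_tree <- function(tree, env = NULL) {
  sym <- tree$symbol
  if (is.null(tree$children)) {
    v <- suppressWarnings(as.numeric(sym))
    if (!is.na(v)) return(v)
    if (!is.null(env) && sym %in% names(env)) return(as.numeric(env[[sym]]))
    stop("unbound terminal: ", sym)
  }
  vals <- vapply(tree$children, evaluate_tree, numeric(1), env = env)
  switch(sym,
         "+" = vals[1] + vals[2],
         "-" = vals[1] - vals[2],
         "*" = vals[1] * vals[2],
         "/" = if (vals[2] == 0) 1 else vals[1] / vals[2],
         "Q" = sqrt(vals[1]),
         stop("unknown functor: ", sym))
}

#' Construct an integer-coded EpiGEP gene
#'
#' A gene is a head of `h` symbols (functors `+ - * /` or locus-index
#' terminals), a tail of `h + 1` terminals, and a GT domain holding a
#' genotype value 0/1/2.
#'
#' @param head character or numeric vector of `h` symbols.
#' @param tail numeric vector of `h + 1` locus indices.
#' @param gt genotype value in \{0, 1, 2\}.
#' @return Integer vector of length `2h + 2` (class `epi_gene`, attribute
#'   `head_length`).
#' @examples
#' epi_gene(c("*", "-", "+"), c(1, 8, 2, 5), 0)
#' @export
epi_gene <- function(head, tail, gt = 0L) {
  enc <- function(s) {
    s <- as.character(s)
    ifelse(s %in% names(.functor_codes), .functor_codes[s],
           suppressWarnings(as.integer(s)))
  }
  h <- length(head)
  head_i <- enc(head)
  tail_i <- as.integer(tail)
  if (length(tail_i) != h + 1L)
    stop("tail must have head_length + 1 terminals")
  if (any(is.na(head_i))) stop("head symbols must be functors or integers")
  if (any(is.na(tail_i) | tail_i < 1L)) stop("tail must hold positive locus indices")
  gt <- as.integer(gt)
  if (!gt %in% 0:2) stop("GT domain must be 0, 1 or 2")
  structure(c(head_i, tail_i, gt), class = "epi_gene", head_length = h)
}

#' Assemble an EpiGEP chromosome from genes
#'
#' @param ... [epi_gene()] objects, one per interaction locus.
#' @return Integer vector of class `epi_chromosome` with attributes `k`
#'   and `head_length`.
#' @export
epi_chromosome <- function(...) {
  genes <- list(...)
  if (!length(genes)) stop("chromosome needs at least one gene")
  hs <- vapply(genes, function(g) attr(g, "head_length"), integer(1))
  if (length(unique(hs)) != 1L) stop("all genes must share the head length")
  structure(unlist(lapply(genes, as.integer)), class = "epi_chromosome",
            k = length(genes), head_length = hs[1])
}

#' Decode one gene to a locus index
#'
#' Evaluates the gene's K-expression arithmetically, truncates toward
#' zero, takes the truncated remainder modulo `n_snps` (sign following the
#' dividend) and then the absolute value; remainder 0 maps to `n_snps`.
#'
#' @param gene an [epi_gene()].
#' @param n_snps total SNP count.
#' @return Locus index in `[1, n_snps]`.
#' @examples
#' decode_gene(epi_gene(c("*", "-", "+"), c(1, 8, 2, 5), 0), 100)  # 49
#' @export
decode_gene <- function(gene, n_snps) {
  h <- attr(gene, "head_length")
  cpp_decode_gene(as.integer(gene)[seq_len(2 * h + 1)], h, as.integer(n_snps))
}

#' Decode a chromosome to a locus tuple
#'
#' @param chrom an [epi_chromosome()].
#' @param n_snps total SNP count.
#' @return List with `loci` (integer k-tuple, gene order) and `valid`
#'   (FALSE when any two genes decode to the same locus).
#' @export
decode_chromosome <- function(chrom, n_snps) {
  k <- attr(chrom, "k"); h <- attr(chrom, "head_length")
  loci <- cpp_decode_chromosome(as.integer(chrom), k, h, as.integer(n_snps))
  list(loci = loci, valid = !anyDuplicated(loci))
}
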