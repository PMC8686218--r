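#' @useDynLib epigep, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# (alpha, beta) pairs of the twelve parametric disease models with marginal
# effects: models 1-4 multiplicative, 5-8 threshold, 9-12 concrete.
.dme_params <- list(
  c(0.0980, 0.7464), c(0.0960, 0.4329), c(0.0921, 0.2526), c(0.0782, 0.1610),
  c(0.0958, 4.5647), c(0.0918, 2.4771), c(0.0836, 1.5108), c(0.0519, 1.6474),
  c(0.0804, 1.3856), c(0.0717, 1.2817), c(0.0608, 1.3997), c(0.0671, 1.3070))

.dme_mafs <- rep(c(0.05, 0.1, 0.2, 0.5), 3)
.dme_h2 <- c(rep(0.005, 4), rep(0.02, 8))

# Explicit 3x3 penetrance tables of the ten models with no marginal
# effects (13-22), rows = genotype of SNP A (AA, Aa, aa), columns =
# genotype of SNP B (BB, Bb, bb).
.dnme_tables <- list(
  matrix(c(0.6377, 0.4884, 0.3826, 0.4638, 0.7645, 0.9566,
           0.5798, 0.5624, 0.7189), 3, 3, byrow = TRUE),
  matrix(c(0.2216, 0.2758, 0.1414, 0.2587, 0.1690, 0.4013,
           0.2781, 0.1279, 0.4196), 3, 3, byrow = TRUE),
  matrix(c(0.2216, 0.2758, 0.1414, 0.2587, 0.1690, 0.4013,
           0.2781, 0.1279, 0.4196), 3, 3, byrow = TRUE),
  matrix(c(0.1391, 0.1882, 0.2214, 0.1901, 0.1114, 0.0198,
           0.2056, 0.0514, 0.2530), 3, 3, byrow = TRUE),
  matrix(c(0.1391, 0.1882, 0.2214, 0.1901, 0.1114, 0.0198,
           0.2056, 0.0514, 0.2530), 3, 3, byrow = TRUE),
  matrix(c(0.1032, 0.0634, 0.1242, 0.0978, 0.0858, 0.0693,
           0.0210, 0.1467, 0.0595), 3, 3, byrow = TRUE),
  matrix(c(0.1852, 0.2908, 0.2340, 0.2860, 0.2009, 0.2770,
           0.2486, 0.2661, 0.1657), 3, 3, byrow = TRUE),
  matrix(c(0.0731, 0.0418, 0.0146, 0.0240, 0.0639, 0.0591,
           0.0682, 0.0188, 0.0946), 3, 3, byrow = TRUE),
  matrix(c(0.0462, 0.1275, 0.0694, 0.1150, 0.0667, 0.0971,
           0.1067, 0.0691, 0.1085), 3, 3, byrow = TRUE),
  matrix(c(0.0950, 0.1222, 0.1267, 0.0973, 0.1294, 0.0999,
           0.2014, 0.0439, 0.1222), 3, 3, byrow = TRUE))

.dnme_mafs <- c(rep(0.2, 5), rep(0.4, 5))

#' Disease-model specification
#'
#' Builds the specification of a two-locus disease model, either from the
#' built-in registry of 22 epistasis models (12 parametric models with
#' marginal effects and 10 explicit-table models with no marginal effects)
#' or from user-supplied parameters.
#'
#' @param model_id integer 1..22 selecting a registry model, or `NULL` when
#'   specifying a custom model.
#' @param family one of `"multiplicative"`, `"threshold"`, `"concrete"`,
#'   `"explicit"`.
#' @param alpha baseline penetrance (ignored for `"explicit"`).
#' @param beta effect parameter (ignored for `"explicit"`).
#' @param maf minor allele frequency of each causal locus, in (0, 0.5].
#' @param h2 genetic heritability, carried as metadata only.
#' @param explicit_table 3x3 penetrance matrix, required when
#'   `family = "explicit"`.
#' @return An object of class `disease_model`.
#' @examples
#' disease_model(5)   # threshold model, alpha = 0.0958, beta = 4.5647
#' @export
disease_model <- function(model_id = NULL, family = NULL, alpha = NULL,
                          beta = NULL, maf = NULL, h2 = NA_real_,
                          explicit_table = NULL) {
  if (!is.null(model_id)) {
    model_id <- as.integer(model_id)
    if (model_id < 1L || model_id > 22L) stop("model_id must be in 1..22")
    if (model_id <= 12L) {
      family <- c("multiplicative", "threshold", "concrete")[(model_id - 1L) %/% 4L + 1L]
      p <- .dme_params[[model_id]]
      alpha <- p[1]; beta <- p[2]
      maf <- .dme_mafs[model_id]; h2 <- .dme_h2[model_id]
    } else {
      family <- "explicit"
      explicit_table <- .dnme_tables[[model_id - 12L]]
      maf <- .dnme_mafs[model_id - 12L]; h2 <- 0.01
      alpha <- NA_real_; beta <- NA_real_
    }
  }
  family <- match.arg(family,
                      c("multiplicative", "threshold", "concrete", "explicit"))
  if (family == "explicit") {
    if (is.null(explicit_table)) stop("explicit family requires a penetrance table")
    explicit_table <- as.matrix(explicit_table)
    if (!all(dim(explicit_table) == c(3L, 3L)))
      stop("explicit_table must be 3x3")
    if (any(explicit_table < 0 | explicit_table > 1))
      stop("penetrance entries must lie in [0, 1]")
  } else {
    if (is.null(alpha) || is.null(beta) || alpha < 0 || beta < 0)
      stop("parametric families require alpha >= 0 and beta >= 0")
  }
  if (is.null(maf) || maf <= 0 || maf > 0.5)
    stop("maf must lie in (0, 0.5]")
  structure(list(model_id = if (is.null(model_id)) NA_integer_ else model_id,
                 family = family, alpha = alpha, beta = beta,
                 maf = maf, h2 = h2, explicit_table = explicit_table),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat(sprintf("disease_model %s: family=%s, MAF=%.2g, h2=%.3g",
              ifelse(is.na(x$model_id), "(custom)", x$model_id),
              x$family, x$maf, x$h2))
  if (x$family != "explicit")
    cat(sprintf(", alpha=%.4f, beta=%.4f", x$alpha, x$beta))
  cat("\n")
  invisible(x)
}

#' Registry of the 22 built-in epistasis models
#'
#' @return A list of 22 [disease_model()] objects.
#' @export
disease_models <- function() lapply(1:22, disease_model)

#' Build the penetrance table of a disease model
#'
#' For the parametric families the 3x3 table is filled from the baseline
#' penetrance `alpha` and the effect parameter `beta`:
#' * multiplicative: `alpha` whenever either locus is homozygous major;
#'   `alpha*(1+beta)^2`, `^3`, `^4` as the joint minor-allele dose grows;
#' * threshold: `alpha*(1+beta)` whenever both loci carry a minor allele,
#'   `alpha` otherwise;
#' * concrete: `alpha*(1+beta)` in the cells (AA,Bb), (AA,bb), (Aa,BB),
#'   (aa,BB), `alpha` elsewhere.
#' Explicit models copy their stored table.
#'
#' @param model a [disease_model()].
#' @return An object of class `penetrance_table`: 3x3 matrix `entries`
#'   (rows = genotype of locus A coded 0/1/2, columns = locus B), per-locus
#'   `mafs`, interaction order `k = 2`.
#' @examples
#' build_penetrance(disease_model(5))$entries["Aa", "Bb"]  # 0.5331
#' @export
build_penetrance <- function(model) {
  stopifnot(inherits(model, "disease_model"))
  a <- model$alpha; b <- model$beta
  entries <- switch(model$family,
    multiplicative = {
      m <- matrix(a, 3, 3)
      m[2, 2] <- a * (1 + b)^2
      m[2, 3] <- m[3, 2] <- a * (1 + b)^3
      m[3, 3] <- a * (1 + b)^4
      m
    },
    threshold = {
      m <- matrix(a * (1 + b), 3, 3)
      m[1, ] <- m[, 1] <- a
      m
    },
    concrete = {
      m <- matrix(a, 3, 3)
      m[1, 2] <- m[1, 3] <- m[2, 1] <- m[3, 1] <- a * (1 + b)
      m
    },
    explicit = model$explicit_table)
  dimnames(entries) <- list(c("AA", "Aa", "aa"), c("BB", "Bb", "bb"))
  if (any(entries < 0 | entries > 1))
    stop("penetrance values fall outside [0, 1]; check alpha and beta")
  structure(list(k = 2L, entries = entries, mafs = rep(model$maf, 2),
                 model_id = model$model_id),
            class = "penetrance_table")
}

#' Hardy-Weinberg genotype frequencies
#'
#' @param maf minor allele frequency, in (0, 0.5].
#' @return Probabilities of the genotypes (0, 1, 2) = (homozygous major,
#'   heterozygous, homozygous minor): `((1-p)^2, 2p(1-p), p^2)`.
#' @examples
#' hwe_genotype_freqs(0.5)  # 0.25 0.50 0.25
#' @export
hwe_genotype_freqs <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1L || maf <= 0 || maf > 0.5)
    stop("maf must be a single value in (0, 0.5]")
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

#' Population disease prevalence implied by a penetrance table
#'
#' Sums penetrance over all genotype combinations weighted by the product
#' of per-locus Hardy-Weinberg genotype frequencies.
#'
#' @param table a [build_penetrance()] result.
#' @return P(disease), a probability.
#' @examples
#' prevalence(build_penetrance(disease_model(5)))  # about 0.1
#' @export
prevalence <- function(table) {
  stopifnot(inherits(table, "penetrance_table"))
  fA <- hwe_genotype_freqs(table$mafs[1])
  fB <- hwe_genotype_freqs(table$mafs[2])
  sum(outer(fA, fB) * table$entries)
}
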