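test_that("simulated datasets meet their quotas and record ground truth", {
  sim <- simulate_dataset(disease_model(8), n_cases = 120, n_controls = 80,
                          n_snps = 25, seed = 5)
  expect_equal(sim$data$n_cases, 120L)
  expect_equal(sim$data$n_controls, 80L)
  expect_equal(ncol(sim$data$genotypes), 25L)
  expect_length(sim$truth$causal_loci, 2L)
  expect_true(all(sim$truth$causal_loci %in% 1:25))
  expect_false(is.unsorted(sim$truth$causal_loci, strictly = TRUE))
  # with n_snps = k every locus is causal
  sim2 <- simulate_dataset(disease_model(8), n_cases = 20, n_controls = 20,
                           n_snps = 2, seed = 5)
  expect_equal(sim2$truth$causal_loci, c(1L, 2L))
})

test_that("identical (model, seed) reproduce the dataset bitwise", {
  a <- simulate_dataset(disease_model(3), n_cases = 60, n_controls = 60,
                        n_snps = 30, seed = 99)
  b <- simulate_dataset(disease_model(3), n_cases = 60, n_controls = 60,
                        n_snps = 30, seed = 99)
  expect_identical(a$data$genotypes, b$data$genotypes)
  expect_identical(a$data$phenotype, b$data$phenotype)
  expect_identical(a$truth, b$truth)
  c <- simulate_dataset(disease_model(3), n_cases = 60, n_controls = 60,
                        n_snps = 30, seed = 100)
  expect_false(identical(a$data$genotypes, c$data$genotypes))
})

test_that("an all-zero penetrance table raises a simulation error", {
  dead <- disease_model(family = "explicit", maf = 0.3,
                        explicit_table = matrix(0, 3, 3))
  expect_error(simulate_dataset(dead, n_cases = 10, n_controls = 10,
                                n_snps = 5, seed = 1, max_attempts = 1e5),
               "simulation error")
})

test_that("neutral loci track their drawn MAFs within 3 binomial SEs", {
  sim <- simulate_dataset(null_model(), n_cases = 750, n_controls = 750,
                          n_snps = 50, seed = 17)
  neutral <- setdiff(seq_len(50), sim$truth$causal_loci)
  n_alleles <- 2 * nrow(sim$data$genotypes)
  for (j in neutral) {
    p <- sim$mafs[j]
    phat <- sum(sim$data$genotypes[, j]) / n_alleles
    se <- sqrt(p * (1 - p) / n_alleles)
    expect_lt(abs(phat - p), 3 * se + 1e-12)
  }
})

test_that("causal genotype distributions follow the Bayes-rule prediction", {
  model <- disease_model(8)
  tab <- build_penetrance(model)
  pd <- prevalence(tab)
  n2 <- 5000L
  sim <- simulate_dataset(model, n_cases = n2, n_controls = n2,
                          n_snps = 2, seed = 23)
  fA <- hwe_genotype_freqs(tab$mafs[1]); fB <- hwe_genotype_freqs(tab$mafs[2])
  joint <- outer(fA, fB)
  p_case <- joint * tab$entries / pd
  p_ctrl <- joint * (1 - tab$entries) / (1 - pd)
  g <- sim$data$genotypes
  idx <- g[, 1] + 3L * g[, 2]
  for (cls in 0:1) {
    obs <- tabulate(idx[sim$data$phenotype == cls] + 1L, nbins = 9L)
    expected <- as.numeric(if (cls == 1) p_case else p_ctrl)
    gof <- suppressWarnings(stats::chisq.test(obs, p = expected))
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("case enrichment among minor-allele carriers matches the ascertainment oracle", {
  model <- disease_model(5)
  tab <- build_penetrance(model)
  pd <- prevalence(tab)
  n2 <- 5000L
  sim <- simulate_dataset(model, n_cases = n2, n_controls = n2,
                          n_snps = 2, seed = 31)
  fA <- hwe_genotype_freqs(tab$mafs[1]); fB <- hwe_genotype_freqs(tab$mafs[2])
  joint <- outer(fA, fB)
  carrier <- outer(0:2, 0:2, function(a, b) a >= 1 & b >= 1)
  p_c_case <- sum((joint * tab$entries)[carrier]) / pd
  p_c_ctrl <- sum((joint * (1 - tab$entries))[carrier]) / (1 - pd)
  expected <- n2 * p_c_case / (n2 * p_c_case + n2 * p_c_ctrl)
  g <- sim$data$genotypes
  in_c <- g[, 1] >= 1 & g[, 2] >= 1
  observed <- mean(sim$data$phenotype[in_c] == 1)
  mc_se <- sqrt(expected * (1 - expected) / sum(in_c))
  expect_lt(abs(observed - expected), 3 * mc_se)
})
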