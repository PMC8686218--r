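test_that("chi-square statistic matches the 2x2 closed form", {
  # n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)) = 80 * 800^2 / 40^4
  res <- chi_square_test(rbind(c(30, 10), c(10, 30)))
  expect_equal(res$statistic, 20)
  expect_equal(res$dof, 1L)
  expect_false(res$degenerate)
  # independence: identical case/control columns
  res0 <- chi_square_test(rbind(c(5, 5), c(7, 7)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
})

test_that("degenerate tables return p = 1 with a flag", {
  expect_true(chi_square_test(rbind(c(4, 6)))$degenerate)
  expect_true(chi_square_test(rbind(c(4, 0), c(6, 0)))$degenerate)
  expect_equal(chi_square_test(rbind(c(4, 0), c(6, 0)))$p_value, 1)
  # all-zero rows are dropped first; a single surviving row is degenerate
  expect_true(chi_square_test(rbind(c(0, 0), c(3, 4), c(0, 0)))$degenerate)
})

test_that("p-values agree with the stats implementation on random tables", {
  set.seed(60)
  for (i in 1:100) {
    tab <- random_count_table(max_n = 60, max_rows = 9) + 1L  # keep cells nonzero
    if (nrow(tab) < 2L) tab <- rbind(tab, tab + 1L)           # 1x2 is degenerate here
    mine <- chi_square_test(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$dof, unname(ref$parameter), ignore_attr = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("cleaning annotates every archive entry in deterministic order", {
  sim <- simulate_dataset(disease_model(8), n_cases = 200, n_controls = 200,
                          n_snps = 15, seed = 61)
  arch <- evolve(sim$data, evolution_params(n_iterations = 40), seed = 61)
  findings <- clean(arch, sim$data)
  expect_equal(nrow(findings), nrow(arch$loci))  # cleaning only annotates
  expect_true(!is.unsorted(findings$p_value))
  expect_true(all(findings$significant == (findings$p_value < 0.05)))
  # the archive's top entry is always retained in the report
  top <- arch$loci[1, ]
  expect_true(any(findings$locus1 == top[1] & findings$locus2 == top[2]))
  # alpha = 0 flags nothing
  expect_false(any(clean(arch, sim$data, alpha = 0)$significant))
  # bonferroni threshold is stricter than raw
  expect_lte(sum(clean(arch, sim$data, bonferroni = TRUE)$significant),
             sum(findings$significant))
  # determinism including tie-break ordering
  expect_identical(findings, clean(arch, sim$data))
})

test_that("cleaning flags the causal pair of a strong-effect simulation", {
  sim <- simulate_dataset(disease_model(8), seed = 62)
  arch <- evolve(sim$data, evolution_params(n_iterations = 150), seed = 62)
  findings <- clean(arch, sim$data)
  tr <- sim$truth$causal_loci
  row <- findings[findings$locus1 == tr[1] & findings$locus2 == tr[2], ]
  expect_equal(nrow(row), 1L)
  expect_true(row$significant)
})

test_that("an empty archive cleans to an empty findings table", {
  sim <- simulate_dataset(disease_model(8), n_cases = 20, n_controls = 20,
                          n_snps = 5, seed = 63)
  empty <- list(loci = matrix(integer(0), 0, 2), k2 = numeric(0))
  expect_message(out <- clean(empty, sim$data), "empty")
  expect_equal(nrow(out), 0L)
})
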