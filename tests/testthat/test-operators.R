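make_chrom <- function(k = 2, h = 5, n = 100, seed = 1) {
  set.seed(seed)
  random_chromosome(k, h, n)
}

gene_of <- function(chrom, g) {
  h <- attr(chrom, "head_length")
  gl <- 2 * h + 2
  structure(as.integer(chrom)[(g - 1) * gl + seq_len(gl)],
            class = "epi_gene", head_length = h)
}

chrom_structure_ok <- function(chrom, n) {
  k <- attr(chrom, "k"); h <- attr(chrom, "head_length")
  x <- matrix(as.integer(chrom), ncol = k)
  head_ok <- all(x[1:h, ] %in% c(-(1:4), 1:n))
  tail_ok <- all(x[(h + 1):(2 * h + 1), ] %in% 1:n)
  gt_ok <- all(x[2 * h + 2, ] %in% 0:2)
  head_ok && tail_ok && gt_ok
}

test_that("point mutation respects rate bounds and per-position alphabets", {
  chrom <- make_chrom()
  set.seed(2)
  expect_identical(as.integer(point_mutation(chrom, 100, 0)),
                   as.integer(chrom))
  for (i in 1:50) {
    out <- point_mutation(chrom, 100, 1)
    expect_true(chrom_structure_ok(out, 100))
  }
  # at rate 1 a head position is a functor with probability 4/(n+4)
  set.seed(3)
  n_tr <- 2000
  hits <- sum(replicate(n_tr, as.integer(point_mutation(chrom, 100, 1))[1] < 0))
  p <- 4 / 104
  expect_lt(abs(hits / n_tr - p), 3 * sqrt(p * (1 - p) / n_tr))
})

test_that("adjacent mutation touches only tail neighbours or the GT domain", {
  h <- 4; n <- 50
  gene <- epi_gene(c("*", "-", "+", "7"), c(10, 20, 30, 40, 1), 0)
  set.seed(4)
  seen_gt <- c()
  for (i in 1:300) {
    out <- adjacent_mutation(gene, n)
    a <- as.integer(gene); b <- as.integer(out)
    expect_identical(a[1:h], b[1:h])             # head untouched
    changed <- which(a != b)
    expect_length(changed, 1L)
    if (changed == 2 * h + 2) {
      expect_true(b[changed] %in% c(1L, 2L))     # GT = 0 flips to 1 or 2
      seen_gt <- c(seen_gt, b[changed])
    } else {
      old <- a[changed]; new <- b[changed]
      wrapped <- c(if (old == 1) n else old - 1, if (old == n) 1 else old + 1)
      expect_true(new %in% wrapped)
    }
  }
  expect_setequal(unique(seen_gt), c(1L, 2L))
  # explicit wrap at the lower boundary: terminal 1 can step to n
  set.seed(5)
  low <- epi_gene("+", c(1, 1), 0)
  outs <- replicate(200, {
    o <- adjacent_mutation(low, n)
    as.integer(o)[2:3][as.integer(o)[2:3] != 1]
  })
  expect_true(n %in% unlist(outs))
})

test_that("multi-gene mutation hits at least two genes and keeps structure", {
  chrom <- make_chrom(k = 3)
  set.seed(6)
  for (i in 1:100) {
    out <- multi_gene_mutation(chrom, 100)
    expect_true(chrom_structure_ok(out, 100))
  }
  # k = 2 forces one mutation point in each gene
  chrom2 <- make_chrom(k = 2, seed = 8)
  set.seed(7)
  for (i in 1:100) {
    out <- multi_gene_mutation(chrom2, 100)
    gl <- 2 * 5 + 2
    diffs <- which(as.integer(out) != as.integer(chrom2))
    genes_hit <- unique((diffs - 1) %/% gl + 1)
    expect_lte(length(diffs), 2L)  # one point per gene, resampling may be silent
    expect_true(all(genes_hit %in% 1:2))
  }
  set.seed(9)
  a <- multi_gene_mutation(chrom, 100)
  set.seed(9)
  b <- multi_gene_mutation(chrom, 100)
  expect_identical(as.integer(a), as.integer(b))
  expect_warning(multi_gene_mutation(make_chrom(k = 1), 100), "no-op")
})

test_that("crossover is one-point over the flattened string and invariant-safe", {
  a <- make_chrom(seed = 10); b <- make_chrom(seed = 11)
  set.seed(12)
  out <- crossover(a, b, 0)
  expect_identical(as.integer(out[[1]]), as.integer(a))
  expect_identical(as.integer(out[[2]]), as.integer(b))
  av <- as.integer(a); bv <- as.integer(b)
  for (i in 1:500) {
    kids <- crossover(a, b, 1)
    k1 <- as.integer(kids[[1]]); k2 <- as.integer(kids[[2]])
    expect_true(chrom_structure_ok(kids[[1]], 100))
    expect_true(chrom_structure_ok(kids[[2]], 100))
    # position-wise the pair of offspring is the pair of parents
    expect_true(all((k1 == av & k2 == bv) | (k1 == bv & k2 == av)))
    # one-point: the parent origin switches at most once along the string
    src <- ifelse(k1 == av & k1 != bv, 0L, ifelse(k1 == bv & k1 != av, 1L, NA))
    src <- src[!is.na(src)]
    if (length(src) > 1) expect_lte(sum(diff(src) != 0), 1L)
  }
  expect_error(crossover(a, make_chrom(k = 3, seed = 13), 1), "structure")
})

test_that("repair yields valid chromosomes and fixes near-duplicates", {
  n <- 100
  valid <- epi_chromosome(epi_gene("+", c(10, 10), 0), epi_gene("+", c(5, 14), 1))
  set.seed(14)
  expect_identical(as.integer(repair(valid, n)), as.integer(valid))
  # duplicate pair differing by one tail terminal
  dup <- epi_chromosome(epi_gene("+", c(10, 10), 0), epi_gene("+", c(11, 9), 1))
  set.seed(15)
  for (i in 1:50) {
    fixed <- repair(dup, n)
    expect_true(decode_chromosome(fixed, n)$valid)
  }
  expect_error(repair(valid, 1), "fewer loci")
})

test_that("roulette selection follows the minimisation weighting", {
  set.seed(16)
  draws <- replicate(10000, roulette_select(rep(2.5, 4)))
  freq <- tabulate(draws, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 10000)))
  # weights (F_worst - F_i): fitness (0, 2, 3) -> weights 3:1:0
  set.seed(17)
  draws <- replicate(10000, roulette_select(c(0, 2, 3)))
  freq <- tabulate(draws, 3) / 10000
  expect_lt(abs(freq[1] - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
  expect_lt(abs(freq[2] - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
  expect_lt(freq[3], 0.01)
  expect_equal(which.max(freq), 1L)  # the best scores most often
  expect_error(roulette_select(numeric(0)), "finite")
  expect_error(roulette_select(c(1, Inf)), "finite")
})
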