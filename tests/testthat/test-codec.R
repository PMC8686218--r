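test_that("breadth-first decoding reproduces the square-root worked example", {
  tr <- kexpression_to_tree(strsplit("Q*-+ab2dc", "")[[1]])
  # tree is sqrt((a-b)*(2+d)); c is an unexpressed trailing symbol
  expect_equal(tr$symbol, "Q")
  expect_equal(tr$children[[1]]$symbol, "*")
  kids <- tr$children[[1]]$children
  expect_equal(kids[[1]]$symbol, "-")
  expect_equal(kids[[2]]$symbol, "+")
  for (env in list(c(a = 9, b = 2, d = 5), c(a = 5, b = 1, d = 2))) {
    expect_equal(evaluate_tree(tr, env),
                 sqrt((env["a"] - env["b"]) * (2 + env["d"])),
                 ignore_attr = TRUE)
  }
})

test_that("tree construction handles terminals, exhaustion and evaluation rules", {
  expect_equal(kexpression_to_tree("7"), list(symbol = "7"))
  expect_equal(evaluate_tree(kexpression_to_tree("7")), 7)
  expect_error(kexpression_to_tree(c("+", "1")), "exhausted")
  # protected division
  expect_equal(evaluate_tree(kexpression_to_tree(c("/", "5", "0"))), 1)
  # level-order structure of the first worked-example gene
  tr <- kexpression_to_tree(c("*", "-", "+", "1", "8", "2", "5"))
  expect_equal(evaluate_tree(tr), (1 - 8) * (2 + 5))
  expect_equal(evaluate_tree(kexpression_to_tree(c("+", "*", "+", "3", "6", "7", "4"))),
               3 * 6 + (7 + 4))
})

test_that("the worked-example chromosome decodes to loci 49 and 29", {
  g1 <- epi_gene(c("*", "-", "+"), c(1, 8, 2, 5), 0)
  g2 <- epi_gene(c("+", "*", "+"), c(3, 6, 7, 4), 2)
  expect_equal(decode_gene(g1, 100), 49L)
  expect_equal(decode_gene(g2, 100), 29L)
  dec <- decode_chromosome(epi_chromosome(g1, g2), 100)
  expect_equal(dec$loci, c(49L, 29L))
  expect_true(dec$valid)
})

test_that("decoding boundary conventions: zero remainder maps to n_snps", {
  # head "+", tail (50, 50): evaluates to 100, remainder 0 -> locus 100
  expect_equal(decode_gene(epi_gene("+", c(50, 50), 0), 100), 100L)
  # negative value: 1 - 50 = -49 -> |−49 mod 100| = 49
  expect_equal(decode_gene(epi_gene("-", c(1, 50), 1), 100), 49L)
  # value beyond n wraps: 60 + 60 = 120 -> 20
  expect_equal(decode_gene(epi_gene("+", c(60, 60), 2), 100), 20L)
})

test_that("chromosome validity flags duplicate loci; k = 1 is always valid", {
  dup <- epi_chromosome(epi_gene("+", c(10, 10), 0), epi_gene("+", c(5, 15), 1))
  dec <- decode_chromosome(dup, 100)
  expect_equal(dec$loci, c(20L, 20L))
  expect_false(dec$valid)
  one <- epi_chromosome(epi_gene("+", c(10, 10), 0))
  expect_true(decode_chromosome(one, 100)$valid)
})

test_that("compiled decoding agrees with the generic symbolic codec", {
  set.seed(404)
  n <- 37
  decode_via_generic <- function(gene, h) {
    ints <- as.integer(gene)[seq_len(2 * h + 1)]
    syms <- as.character(ints)
    syms[ints < 0] <- c("+", "-", "*", "/")[-ints[ints < 0]]
    v <- trunc(evaluate_tree(kexpression_to_tree(syms)))
    r <- abs(v - trunc(v / n) * n)
    as.integer(if (r == 0) n else r)
  }
  for (i in 1:200) {
    h <- sample(1:5, 1)
    chrom <- random_chromosome(1, h, n)
    gene <- structure(as.integer(chrom), class = "epi_gene", head_length = h)
    expect_identical(decode_gene(gene, n), decode_via_generic(gene, h))
  }
})
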