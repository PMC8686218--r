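# shared fixture builders

tiny_dataset <- function() {
  genotype_dataset(
    matrix(c(0L, 0L, 2L, 2L,
             0L, 0L, 2L, 2L), nrow = 4),
    c(0L, 0L, 1L, 1L))
}

# a disease model with no association signal (constant penetrance)
null_model <- function() {
  disease_model(family = "threshold", alpha = 0.1, beta = 0, maf = 0.3)
}

random_count_table <- function(max_n = 12, max_rows = 9) {
  nr <- sample.int(max_rows, 1)
  n <- sample.int(max_n, 1)
  tab <- matrix(0L, nr, 2)
  for (i in seq_len(n)) {
    r <- sample.int(nr, 1)
    j <- sample.int(2, 1)
    tab[r, j] <- tab[r, j] + 1L
  }
  tab
}

# exact-factorial route to the K2 score; factorials up to 13! are exact
# in double precision
k2_factorial_oracle <- function(tab) {
  ri <- rowSums(tab)
  sum(log(factorial(ri + 1))) - sum(log(factorial(tab)))
}
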