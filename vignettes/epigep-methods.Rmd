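---
title: "Methods: two-stage epistasis detection by Gene Expression Programming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage epistasis detection by Gene Expression Programming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epigep)
```

## The model

`epigep` treats k-locus epistasis detection in case-control data as a
combinatorial optimisation problem: find the k-tuple of SNPs whose
genotype combination best predicts disease status. Two stages divide
the labour. The *screening* stage is a stochastic search that only has
to get the true combination into a 100-entry candidate archive; the
*cleaning* stage then applies a classical chi-square test of
independence to every archived candidate, and the most significant
candidate below α is the reported identification.

### Chromosomes and decoding

A candidate solution is a chromosome of k genes. Each gene is a Karva
expression: a head of `h` symbols drawn from the functors
`{+, −, *, /}` (all binary) and the locus terminals `{1..M}`, a tail of
`t = h(arity − 1) + 1 = h + 1` terminals, and a GT domain holding a
genotype value in {0, 1, 2}. Decoding builds the expression tree
breadth-first (the first symbol is the root; each functor consumes the
next unconsumed symbols level by level), evaluates it arithmetically,
and maps the result `v` to a locus.

Numerical conventions, chosen once and applied everywhere:

* division is protected: `x / 0` evaluates to 1 (the usual GEP
  convention for total evaluation);
* non-integer results are truncated toward zero before the modulo;
* the remainder is the *truncated* remainder (sign follows the
  dividend) and its absolute value is taken, so an evaluation of −49
  with M = 100 yields locus 49 — a floor-style modulo would give 51
  and break the decoding convention the chromosome design relies on;
* a zero remainder maps to locus M, keeping decoding total rather than
  triggering repair.

A chromosome whose genes decode to colliding loci is invalid; `repair()`
applies adjacent mutations to a colliding gene (the operator designed
for small moves) and, because a gene whose root symbol is a terminal
ignores its tail entirely, falls back to re-randomising the whole gene
after 50 rounds. The GT domain never enters the fitness — the K2 score
uses the full 3^k genotype contingency — but it is retained, mutated
under the documented rules and reported with each archive entry, so the
information is available to downstream consumers.

### Fitness

The K2 score of a locus tuple is
`Σ_i [ ln((r_i + 1)!) − Σ_j ln(r_ij!) ]` over the `3^k` genotype
combinations, with `r_i` the number of individuals carrying combination
`i` and `r_ij` the split by disease state. It is the negative log
marginal likelihood of the disease node given the tuple under a uniform
Dirichlet prior, so *lower is better* and the score is non-negative;
empty combinations contribute exactly zero. Natural logarithms are
used — the base is a positive rescaling that cannot change any argmin —
and the computation goes through `lgamma` for overflow safety (tests
verify agreement with exact factorials to 1e−10). Selection, elitism,
diversity and the archive ordering all use the minimisation convention
consistently; roulette weights are `F_worst − F_i + ε` with
`ε = 1e−9 · F_worst + 1e−12` so that an all-equal population is sampled
uniformly.

### Genetic operators and the generation loop

Each generation evaluates the population (memoizing the score of every
distinct tuple — the archive is simply the best 100 of everything ever
evaluated), copies the single best chromosome unchanged, and fills the
remainder by roulette-selected parents passed through, in order:
one-point crossover over the flattened symbol string (GT domains
included), per-position point mutation, adjacent mutation (one random
gene, gated by the adjacent rate), multi-gene mutation, and repair. The
operator order is a fixed implementation choice; each operator is gated
by its own rate. Multi-gene mutation has no rate of its own in the
three-controller design, so it is gated per chromosome by the mutation
rate — the natural host, since it is a mutation-family operator.

Adjacent mutation interprets "neighbouring loci" in index space
(`v ± 1`, wrapping at 1 and M): input files carry no genomic map, so
index adjacency is the only adjacency available, and it preserves the
operator's intent of small local moves.

### Fuzzy adaptive rates

The population-diversity ratio is `d = F_min / (F_ave + 1e−12)`. With
non-negative minimised scores `F_min ≤ F_ave` always, so `d ∈ (0, 1]`:
d near 1 means the fitness spread has collapsed (the population is
converging, diversity is *low*), d near 0 means a wide spread (high
diversity). Three fuzzy controllers map (d, iteration fraction) to the
crossover, mutation and adjacent-mutation rates with five linguistic
levels {XL, ML, M, MH, XH} on each axis — triangular interior
memberships, trapezoidal shoulders, breakpoints at 0, 0.25, 0.5, 0.75,
1 (a partition of unity). The rule bases encode two monotone control
laws: as diversity falls (d rises) the mutation and adjacent-mutation
rates rise to re-diversify the population, and the crossover rate falls;
in the last quarter of the run every output shifts one level toward
exploitation (less mutation, more crossover). The exact breakpoints and
the 25-rule tables are this package's own design — the qualitative laws
pin down only monotonicity — and both are configurable through
`fuzzy_controller()`.

Defuzzification uses scaled implication with *additive* aggregation and
a centroid over [rate_min, rate_max] = [0.05, 0.95]. We deliberately do
not use max-aggregation: wherever two adjacent diversity levels fire
the same output level, the max of their memberships dips and recovers
as d crosses the shared region, making the centroid non-monotone in d
and violating the control laws above (we measured this on a 101-point
grid). The additive aggregate is a weighted average of the output sets
and is provably weakly monotone whenever the rule table is. With fuzzy
control disabled (`fuzzy = FALSE`, CLI `--no-fuzzy`) all three rates
stay at the initial rate (default 0.3) for every generation, which is
the ablation configuration.

### Cleaning and identification

Every archived tuple is tested by a Pearson chi-square on its
`3^k × 2` table after dropping all-zero rows, with
`df = (non-empty rows − 1)` and no continuity correction; dropping
empty rows matters because 3^k tables from 1500 individuals are sparse
at low MAF. Fewer than two non-empty rows, or a zero column marginal,
make the test undefined: `p = 1` with a degenerate flag. Raw p-values
at α = 0.05 are the default (a Bonferroni option exists but is off, to
match the benchmark protocol).

The scan's *identification* is the single most significant finding
(ties broken by K2 score, then loci). The archive deliberately retains
the 100 best-scoring tuples, and on models with marginal effects most
of them share one locus with the causal pair — shadows of the same
association signal that are individually "significant" but not separate
discoveries. Counting them as identifications would make precision
meaningless (tens of false positives per dataset by construction);
reporting the best significant candidate matches how the benchmark
metrics treat a dataset as contributing one true combination. The full
annotated findings table remains available in every scan object.

## The simulator

`simulate_dataset()` replaces an external data generator with rejection
sampling that reproduces exactly the quantities the disease models
specify: causal genotypes are drawn from Hardy–Weinberg equilibrium at
the model MAF, disease status is Bernoulli with probability equal to
the penetrance cell, and individuals fill fixed case/control quotas
(750/750 by default). This yields the stated prevalence, MAF and HWE
properties in expectation, and the case/control genotype distributions
follow the Bayes-rule prediction from the penetrance table (verified by
goodness-of-fit at N = 10,000 in the tests).

Choices where the study conditions leave freedom, fixed once:

* neutral-locus MAFs are drawn per dataset from Uniform(0.05, 0.5) —
  the range spanned by the registry's causal MAFs — and recorded;
* the causal pair is placed uniformly at random among the M positions
  and recorded in the ground-truth manifest, so detection cannot
  exploit position;
* heritability is metadata only; it is implied by (α, β, MAF) for the
  parametric models and not re-derived.

The registry's 12 parametric models build their 3×3 tables from
(α, β): multiplicative (`α(1+β)^2..^4` as joint minor dose grows),
threshold (`α(1+β)` when both loci carry a minor allele), concrete
(`α(1+β)` on the (AA, B_) and (_, BB) flanks). The 10 explicit models
carry their tables verbatim. All are calibrated so the implied
prevalence is about 0.1.

What the simulator does *not* emulate: linkage disequilibrium between
loci (all loci independent), missing genotypes, covariates or
population structure, quantitative traits. Passing benchmarks here
therefore demonstrate correctness of the search and calibration of the
tests under idealised panels, not robustness to the correlation
structure of real GWAS data.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `population_size` | 100 | chromosomes per generation |
| `n_iterations` | 1000 | generations (the standard full-scale setting) |
| `head_length` | 5 | gene head; tail is 6, gene length 12 with GT |
| `initial_rate` | 0.3 | generation-0 crossover/mutation/adjacent rate |
| `archive_size` | 100 | candidate combinations kept for cleaning |
| `elitism_count` | 1 | best chromosomes copied unchanged |
| `rate_bounds` | (0.05, 0.95) | fuzzy output range |
| `alpha` | 0.05 | cleaning significance level |

Benchmarks in the tests and the acceptance script run at desk scale —
20 replicates per model and 300 iterations — which we chose because on
100-SNP panels the archive demonstrably stabilises well before 300
generations (the strong-effect models reach power 1 there); the
full-scale 1000-iteration, 100-replicate protocol is available through
the same functions.

## Known limitations

* Orders k > 5 make chromosome length (and the 3^k contingency) grow
  quickly; the implementation is correct for general k but tuned for
  k = 2–3.
* GEP transposition operators (IS/RIS/gene transposition, two-point and
  gene recombination) are not implemented; the operator set is
  selection, one-point crossover and the three mutations.
* The chi-square cleaning uses asymptotic p-values; no exact or
  permutation tests.
* Between-method comparisons (other epistasis detectors) are out of
  scope; the benchmark utilities score this method only.

## Reproducibility

All randomness flows through R's RNG: `simulate_dataset()`,
`evolve()` / `detect_epistasis()` and `run_pipeline()` take explicit
seeds, and identical inputs give bitwise-identical outputs (a tested
contract). `run_pipeline()` derives replicate seeds as
`base_seed + r`.
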