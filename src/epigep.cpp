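// Core of the GEP screening stage: K-expression decoding, K2 scoring,
// genetic operators and the generation loop.  Symbol encoding shared with
// the R level: functors + - * / are -1 -2 -3 -4, terminals are 1..n_snps,
// the GT domain is the last position of each gene and holds 0/1/2.
// Gene layout: h head symbols, h+1 tail symbols (Karva tail length for
// arity-2 functors), 1 GT value.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int gene_len(int h) { return 2 * h + 2; }

static inline int runif_int(int m) {
  int v = (int)(unif_rand() * m);
  return v >= m ? m - 1 : v;
}

// Evaluate the K-expression of one gene (head + tail, GT excluded) and map
// the result to a 1-based locus index: truncate toward zero, truncated
// remainder modulo n_snps (sign follows the dividend), absolute value,
// remainder 0 maps to n_snps.
static int decode_gene_core(const int *s, int h, int n_snps) {
  int len = 2 * h + 1;
  std::vector<int> left(len, -1), right(len, -1), order;
  order.reserve(len);
  int used = 1;
  std::queue<int> q;
  q.push(0);
  while (!q.empty()) {
    int i = q.front();
    q.pop();
    order.push_back(i);
    if (s[i] < 0) { // functor, arity 2: consume next two symbols level-wise
      if (used + 2 > len)
        stop("malformed gene: K-expression exhausted before tree completed");
      left[i] = used++;
      right[i] = used++;
      q.push(left[i]);
      q.push(right[i]);
    }
  }
  std::vector<double> val(used, 0.0);
  for (int oi = (int)order.size() - 1; oi >= 0; --oi) {
    int i = order[oi];
    if (s[i] > 0) {
      val[i] = s[i];
      continue;
    }
    double a = val[left[i]], b = val[right[i]];
    switch (s[i]) {
    case -1: val[i] = a + b; break;
    case -2: val[i] = a - b; break;
    case -3: val[i] = a * b; break;
    default: val[i] = (b == 0.0) ? 1.0 : a / b; break; // protected division
    }
  }
  double v = std::trunc(val[0]);
  // truncated remainder (sign follows the dividend); exact for the
  // integer-valued v reachable from this alphabet
  double r = v - std::trunc(v / n_snps) * n_snps;
  int loc = (int)std::lround(std::fabs(r));
  if (loc == 0) loc = n_snps;
  return loc;
}

static void decode_chrom_core(const int *chrom, int k, int h, int n_snps,
                              int *loci) {
  int gl = gene_len(h);
  for (int g = 0; g < k; ++g)
    loci[g] = decode_gene_core(chrom + g * gl, h, n_snps);
}

// K2 negative-log marginal likelihood of the disease node given the loci
// (0-based), via log-gamma.  Lower is better.  Empty combinations
// contribute 0.
static double k2_core(const int *geno, const int *pheno, int N,
                      const int *loci0, int k) {
  int I = 1;
  for (int j = 0; j < k; ++j) I *= 3;
  std::vector<int> cnt(2 * I, 0);
  for (int r = 0; r < N; ++r) {
    int idx = 0, p3 = 1;
    for (int j = 0; j < k; ++j) {
      idx += geno[(size_t)loci0[j] * N + r] * p3;
      p3 *= 3;
    }
    cnt[2 * idx + pheno[r]]++;
  }
  double score = 0.0;
  for (int i = 0; i < I; ++i) {
    int r0 = cnt[2 * i], r1 = cnt[2 * i + 1];
    int ri = r0 + r1;
    if (ri == 0) continue;
    score += R::lgammafn(ri + 2.0) - R::lgammafn(r0 + 1.0) -
             R::lgammafn(r1 + 1.0);
  }
  return score;
}

static inline void resample_position(int *gene, int pos, int h, int n) {
  if (pos < h) { // head: uniform over functors U terminals
    int v = runif_int(n + 4);
    gene[pos] = (v < 4) ? -(v + 1) : (v - 3);
  } else if (pos < 2 * h + 1) { // tail: terminals only
    gene[pos] = runif_int(n) + 1;
  } else { // GT domain
    gene[pos] = runif_int(3);
  }
}

static void point_mutation_core(int *chrom, int k, int h, int n, double rate) {
  int gl = gene_len(h);
  for (int g = 0; g < k; ++g)
    for (int pos = 0; pos < gl; ++pos)
      if (unif_rand() < rate) resample_position(chrom + g * gl, pos, h, n);
}

// Adjacent mutation: tail terminal steps to a neighbouring locus index
// (wrapping at 1 and n) or the GT domain flips to one of the other two
// genotypes.  The head is never touched.
static void adjacent_mutation_core(int *gene, int h, int n) {
  if (unif_rand() < 0.5) {
    int pos = h + runif_int(h + 1);
    int v = gene[pos] + ((unif_rand() < 0.5) ? -1 : 1);
    if (v < 1) v = n;
    else if (v > n) v = 1;
    gene[pos] = v;
  } else {
    int gt = gene[2 * h + 1];
    gene[2 * h + 1] = (gt + 1 + runif_int(2)) % 3;
  }
}

// Multi-gene mutation: one uniformly chosen position resampled in each of
// m >= 2 distinct genes, m uniform in [2, k].
static void multi_gene_mutation_core(int *chrom, int k, int h, int n) {
  if (k < 2) return;
  int m = 2 + runif_int(k - 1);
  std::vector<int> idx(k);
  for (int i = 0; i < k; ++i) idx[i] = i;
  for (int i = 0; i < m; ++i) {
    int j = i + runif_int(k - i);
    std::swap(idx[i], idx[j]);
  }
  int gl = gene_len(h);
  for (int i = 0; i < m; ++i) {
    int *gene = chrom + idx[i] * gl;
    resample_position(gene, runif_int(gl), h, n);
  }
}

// One-point recombination over the flattened symbol string (GT included).
// Cut 0 or len leaves the pair unchanged up to order.
static void crossover_core(int *a, int *b, int len, double rate) {
  if (unif_rand() >= rate) return;
  int cut = runif_int(len + 1);
  for (int i = 0; i < cut; ++i) std::swap(a[i], b[i]);
}

// Enforce distinct decoded loci: adjacent-mutate a colliding gene (up to 50
// rounds), then fall back to random tail re-initialisation.
static void repair_core(int *chrom, int k, int h, int n) {
  if (k < 2) return;
  int gl = gene_len(h);
  std::vector<int> loci(k);
  for (int tries = 0; tries < 500; ++tries) {
    decode_chrom_core(chrom, k, h, n, loci.data());
    std::vector<int> bad;
    for (int i = 0; i < k; ++i)
      for (int j = i + 1; j < k; ++j)
        if (loci[i] == loci[j]) {
          bad.push_back(i);
          bad.push_back(j);
        }
    if (bad.empty()) return;
    int pick = bad[runif_int((int)bad.size())];
    if (tries < 50) {
      adjacent_mutation_core(chrom + pick * gl, h, n);
    } else {
      // tail edits cannot move a gene whose root symbol is a terminal;
      // re-randomise the whole gene (GT kept: it does not affect decoding)
      int *gene = chrom + pick * gl;
      for (int pos = 0; pos < 2 * h + 1; ++pos)
        resample_position(gene, pos, h, n);
    }
  }
  stop("repair failed to produce distinct loci (need n_snps >= k)");
}

static void random_chromosome_core(int *chrom, int k, int h, int n) {
  int gl = gene_len(h);
  for (int g = 0; g < k; ++g)
    for (int pos = 0; pos < gl; ++pos)
      resample_position(chrom + g * gl, pos, h, n);
  repair_core(chrom, k, h, n);
}

// ---- exported wrappers -------------------------------------------------

// [[Rcpp::export]]
int cpp_decode_gene(IntegerVector symbols, int head_length, int n_snps) {
  if (symbols.size() != 2 * head_length + 1)
    stop("gene must have head_length + head_length + 1 symbols");
  return decode_gene_core(INTEGER(symbols), head_length, n_snps);
}

// [[Rcpp::export]]
IntegerVector cpp_decode_chromosome(IntegerVector chrom, int k,
                                    int head_length, int n_snps) {
  IntegerVector out(k);
  decode_chrom_core(INTEGER(chrom), k, head_length, n_snps, INTEGER(out));
  return out;
}

// [[Rcpp::export]]
double cpp_k2_score(IntegerMatrix geno, IntegerVector pheno,
                    IntegerVector loci) {
  int k = loci.size();
  std::vector<int> l0(k);
  for (int j = 0; j < k; ++j) l0[j] = loci[j] - 1;
  return k2_core(INTEGER(geno), INTEGER(pheno), geno.nrow(), l0.data(), k);
}

// [[Rcpp::export]]
IntegerVector cpp_point_mutation(IntegerVector chrom, int k, int head_length,
                                 int n_snps, double rate) {
  IntegerVector out = clone(chrom);
  point_mutation_core(INTEGER(out), k, head_length, n_snps, rate);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_adjacent_mutation(IntegerVector gene, int head_length,
                                    int n_snps) {
  IntegerVector out = clone(gene);
  adjacent_mutation_core(INTEGER(out), head_length, n_snps);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_multi_gene_mutation(IntegerVector chrom, int k,
                                      int head_length, int n_snps) {
  IntegerVector out = clone(chrom);
  multi_gene_mutation_core(INTEGER(out), k, head_length, n_snps);
  return out;
}

// [[Rcpp::export]]
List cpp_crossover(IntegerVector a, IntegerVector b, double rate) {
  if (a.size() != b.size()) stop("parents must have identical structure");
  IntegerVector ca = clone(a), cb = clone(b);
  crossover_core(INTEGER(ca), INTEGER(cb), a.size(), rate);
  return List::create(ca, cb);
}

// [[Rcpp::export]]
IntegerVector cpp_repair(IntegerVector chrom, int k, int head_length,
                         int n_snps) {
  IntegerVector out = clone(chrom);
  repair_core(INTEGER(out), k, head_length, n_snps);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_random_chromosome(int k, int head_length, int n_snps) {
  IntegerVector out(k * gene_len(head_length));
  random_chromosome_core(INTEGER(out), k, head_length, n_snps);
  return out;
}

// Roulette selection under minimisation: weight_i = F_worst - F_i + eps.
// [[Rcpp::export]]
int cpp_roulette_select(NumericVector fitness) {
  int L = fitness.size();
  if (L == 0) stop("empty population");
  double worst = *std::max_element(fitness.begin(), fitness.end());
  double eps = 1e-9 * worst + 1e-12;
  std::vector<double> cum(L);
  double tot = 0.0;
  for (int i = 0; i < L; ++i) {
    tot += worst - fitness[i] + eps;
    cum[i] = tot;
  }
  double u = unif_rand() * tot;
  return (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin()) + 1;
}

struct ArchiveEntry {
  double score;
  std::vector<int> loci;
  std::vector<int> gts;
};

// Main generation loop of the screening stage.  rate_fn(d, iter_frac) must
// be a deterministic R function returning c(crossover, mutation, adjacent)
// rates; it is consulted each generation when use_fuzzy is TRUE.
// [[Rcpp::export]]
List cpp_evolve(IntegerMatrix geno, IntegerVector pheno, int k,
                int head_length, int pop_size, int n_iter, double init_rate,
                int archive_size, int elitism, Function rate_fn,
                bool use_fuzzy) {
  int N = geno.nrow(), M = geno.ncol(), h = head_length;
  if (k >= M) stop("interaction order k must be smaller than the SNP count");
  if (elitism < 0 || elitism >= pop_size) stop("invalid elitism count");
  int gl = gene_len(h), clen = k * gl;
  const int *G = INTEGER(geno);
  std::vector<int> ph(pheno.begin(), pheno.end());

  std::vector<int> pop((size_t)pop_size * clen);
  for (int i = 0; i < pop_size; ++i)
    random_chromosome_core(pop.data() + (size_t)i * clen, k, h, M);

  std::unordered_map<long long, ArchiveEntry> seen;
  double cx = init_rate, mu = init_rate, adj = init_rate;
  NumericMatrix trace(n_iter, 7);
  colnames(trace) = CharacterVector::create("iter", "best", "mean", "d",
                                            "crossover_rate", "mutation_rate",
                                            "adjacent_rate");
  std::vector<double> fit(pop_size);
  std::vector<int> loci(k);
  std::vector<std::pair<int, int>> lg(k);

  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < pop_size; ++i) {
      const int *chrom = pop.data() + (size_t)i * clen;
      decode_chrom_core(chrom, k, h, M, loci.data());
      for (int j = 0; j < k; ++j)
        lg[j] = std::make_pair(loci[j], chrom[j * gl + 2 * h + 1]);
      std::sort(lg.begin(), lg.end());
      long long key = 0;
      for (int j = 0; j < k; ++j) key = key * (M + 1) + lg[j].first;
      auto f = seen.find(key);
      if (f == seen.end()) {
        std::vector<int> l0(k);
        for (int j = 0; j < k; ++j) l0[j] = lg[j].first - 1;
        ArchiveEntry e;
        e.score = k2_core(G, ph.data(), N, l0.data(), k);
        e.loci.resize(k);
        e.gts.resize(k);
        for (int j = 0; j < k; ++j) {
          e.loci[j] = lg[j].first;
          e.gts[j] = lg[j].second;
        }
        fit[i] = e.score;
        seen.emplace(key, std::move(e));
      } else {
        fit[i] = f->second.score;
      }
    }

    int best_i = 0;
    double fbest = fit[0], fworst = fit[0], fsum = 0.0;
    for (int i = 0; i < pop_size; ++i) {
      if (fit[i] < fbest) { fbest = fit[i]; best_i = i; }
      if (fit[i] > fworst) fworst = fit[i];
      fsum += fit[i];
    }
    double fmean = fsum / pop_size;
    double d = fbest / (fmean + 1e-12);

    if (use_fuzzy) {
      NumericVector r = rate_fn(d, (double)(it + 1) / n_iter);
      if (r.size() != 3) stop("rate function must return three rates");
      cx = r[0];
      mu = r[1];
      adj = r[2];
    }
    trace(it, 0) = it + 1;
    trace(it, 1) = fbest;
    trace(it, 2) = fmean;
    trace(it, 3) = d;
    trace(it, 4) = cx;
    trace(it, 5) = mu;
    trace(it, 6) = adj;
    if (it == n_iter - 1) break;

    // breed next generation: elitism then roulette + operators
    std::vector<int> ord(pop_size);
    for (int i = 0; i < pop_size; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return fit[a] < fit[b]; });
    std::vector<int> next((size_t)pop_size * clen);
    for (int e = 0; e < elitism; ++e)
      std::copy(pop.begin() + (size_t)ord[e] * clen,
                pop.begin() + (size_t)(ord[e] + 1) * clen,
                next.begin() + (size_t)e * clen);

    double eps = 1e-9 * fworst + 1e-12;
    std::vector<double> cum(pop_size);
    double tot = 0.0;
    for (int i = 0; i < pop_size; ++i) {
      tot += fworst - fit[i] + eps;
      cum[i] = tot;
    }
    auto pick = [&]() {
      double u = unif_rand() * tot;
      return (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    };

    int filled = elitism;
    std::vector<int> c1(clen), c2(clen);
    while (filled < pop_size) {
      int p1 = pick(), p2 = pick();
      std::copy(pop.begin() + (size_t)p1 * clen,
                pop.begin() + (size_t)(p1 + 1) * clen, c1.begin());
      std::copy(pop.begin() + (size_t)p2 * clen,
                pop.begin() + (size_t)(p2 + 1) * clen, c2.begin());
      crossover_core(c1.data(), c2.data(), clen, cx);
      int *kids[2] = {c1.data(), c2.data()};
      for (int c = 0; c < 2 && filled < pop_size; ++c) {
        int *kid = kids[c];
        point_mutation_core(kid, k, h, M, mu);
        if (unif_rand() < adj)
          adjacent_mutation_core(kid + (size_t)runif_int(k) * gl, h, M);
        if (k >= 2 && unif_rand() < mu)
          multi_gene_mutation_core(kid, k, h, M);
        repair_core(kid, k, h, M);
        std::copy(kid, kid + clen, next.begin() + (size_t)filled * clen);
        ++filled;
      }
    }
    pop.swap(next);
  }

  // archive: best archive_size unique tuples, ordered by score then loci
  std::vector<const ArchiveEntry *> entries;
  entries.reserve(seen.size());
  for (auto &kv : seen) entries.push_back(&kv.second);
  std::sort(entries.begin(), entries.end(),
            [](const ArchiveEntry *a, const ArchiveEntry *b) {
              if (a->score != b->score) return a->score < b->score;
              return a->loci < b->loci;
            });
  int nkeep = std::min((int)entries.size(), archive_size);
  IntegerMatrix arch_loci(nkeep, k), arch_gts(nkeep, k);
  NumericVector arch_scores(nkeep);
  for (int i = 0; i < nkeep; ++i) {
    for (int j = 0; j < k; ++j) {
      arch_loci(i, j) = entries[i]->loci[j];
      arch_gts(i, j) = entries[i]->gts[j];
    }
    arch_scores[i] = entries[i]->score;
  }
  return List::create(_["loci"] = arch_loci, _["k2"] = arch_scores,
                      _["gt"] = arch_gts, _["trace"] = trace,
                      _["n_evaluated"] = (double)seen.size());
}
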