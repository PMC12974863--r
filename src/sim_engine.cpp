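#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// One haploid genome: sparse sorted map position -> mutation type (1 or 2),
// relative to an empty ancestral chromosome.
struct Genome {
  std::vector<int> pos;           // sorted, 0-based
  std::vector<signed char> type;  // 1 = m1, 2 = m2
  int deme;
  signed char label;              // mutation-het label: 1 = p1, 2 = p2, 0 = none
};

// uniform integer in [0, n)
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  if (k < 0) k = 0;
  return k;
}

// insert a mutation; a repeat hit at an occupied site replaces the resident
static inline void add_mutation(Genome &g, int p, signed char t) {
  std::vector<int>::iterator it =
      std::lower_bound(g.pos.begin(), g.pos.end(), p);
  size_t idx = it - g.pos.begin();
  if (it != g.pos.end() && *it == p) {
    g.type[idx] = t;
  } else {
    g.pos.insert(it, p);
    g.type.insert(g.type.begin() + idx, t);
  }
}

// replace recipient's mutations in [s, e) with the donor's (half-open tract)
static void apply_hgt(Genome &r, const Genome &d, int s, int e) {
  size_t ilo = std::lower_bound(r.pos.begin(), r.pos.end(), s) - r.pos.begin();
  size_t ihi = std::lower_bound(r.pos.begin(), r.pos.end(), e) - r.pos.begin();
  size_t jlo = std::lower_bound(d.pos.begin(), d.pos.end(), s) - d.pos.begin();
  size_t jhi = std::lower_bound(d.pos.begin(), d.pos.end(), e) - d.pos.begin();
  std::vector<int> np;
  std::vector<signed char> nt;
  np.reserve(ilo + (jhi - jlo) + (r.pos.size() - ihi));
  nt.reserve(ilo + (jhi - jlo) + (r.pos.size() - ihi));
  np.insert(np.end(), r.pos.begin(), r.pos.begin() + ilo);
  nt.insert(nt.end(), r.type.begin(), r.type.begin() + ilo);
  np.insert(np.end(), d.pos.begin() + jlo, d.pos.begin() + jhi);
  nt.insert(nt.end(), d.type.begin() + jlo, d.type.begin() + jhi);
  np.insert(np.end(), r.pos.begin() + ihi, r.pos.end());
  nt.insert(nt.end(), r.type.begin() + ihi, r.type.end());
  r.pos.swap(np);
  r.type.swap(nt);
}

// additive trait: sum of coefficients over m1 sites minus sum over m2 sites
static inline double score_of(const Genome &g, const NumericVector &coef,
                              bool uniform) {
  double s = 0.0;
  for (size_t i = 0; i < g.pos.size(); ++i) {
    double c = uniform ? 1.0 : coef[g.pos[i]];
    s += (g.type[i] == 1) ? c : -c;
  }
  return s;
}

// sample k distinct indices from [0, n) by partial Fisher-Yates; returns them
// in the first k slots of idx (idx must hold 0..n-1 on entry)
static void sample_k(std::vector<int> &idx, int k) {
  int n = (int)idx.size();
  for (int i = 0; i < k; ++i) {
    int j = i + runif_int(n - i);
    std::swap(idx[i], idx[j]);
  }
}

// [[Rcpp::export]]
List sim_engine(int genome_length, int pop_size, int n_demes, int migrants,
                double mutation_rate, int hgt_events, int tract_length,
                IntegerVector hotspots, double hotspot_fraction,
                int generations, int selection_start, bool selection_on,
                double amplitude, double exponent, double epsilon,
                double base_lambda, NumericVector coefficients, bool mut_het) {
  if (pop_size % n_demes != 0)
    stop("pop_size must be divisible by n_demes");
  const int cap = pop_size / n_demes;
  const bool uniform_eff = (coefficients.size() == 0);
  const int nh = hotspots.size();
  const double mu_genome = mutation_rate * (double)genome_length;

  std::vector<Genome> pop(pop_size);
  for (int i = 0; i < pop_size; ++i) {
    pop[i].deme = (n_demes > 1) ? (i / cap) : 0;
    pop[i].label = mut_het ? ((i < pop_size / 2) ? 1 : 2) : 0;
  }

  std::vector<double> log_size, log_mean_score, log_mean_lambda,
      log_mean_offspring, log_frac_hgt;
  std::vector<int> log_gen;

  for (int g = 1; g <= generations; ++g) {
    const int n = (int)pop.size();

    // --- mutation (disabled for p1-labelled individuals under mut_het) ---
    for (int i = 0; i < n; ++i) {
      if (mut_het && pop[i].label == 1) continue;
      int nm = (int)R::rpois(mu_genome);
      for (int m = 0; m < nm; ++m) {
        int p = runif_int(genome_length);
        signed char t = (unif_rand() < 0.5) ? 1 : 2;
        add_mutation(pop[i], p, t);
      }
    }

    // --- HGT: every individual receives hgt_events tract copies per
    // generation; donors are drawn from a start-of-stage snapshot ---
    int n_recipients = 0;
    if (hgt_events > 0 && tract_length > 0 && n > 1) {
      std::vector<Genome> snap(pop);  // donor states
      // donor pools
      std::vector<std::vector<int> > deme_idx;
      std::vector<int> lab_idx1, lab_idx2;
      if (n_demes > 1) {
        deme_idx.assign(n_demes, std::vector<int>());
        for (int i = 0; i < n; ++i) deme_idx[snap[i].deme].push_back(i);
      }
      if (mut_het) {
        for (int i = 0; i < n; ++i) {
          if (snap[i].label == 1) lab_idx1.push_back(i);
          else lab_idx2.push_back(i);
        }
      }
      for (int i = 0; i < n; ++i) {
        bool got = false;
        for (int e = 0; e < hgt_events; ++e) {
          // donor choice: uniform over the pool, excluding the recipient
          int j = -1;
          const std::vector<int> *pool = 0;
          if (mut_het) {
            pool = (unif_rand() < 0.5) ? &lab_idx1 : &lab_idx2;
          } else if (n_demes > 1) {
            pool = &deme_idx[pop[i].deme];
          }
          if (pool) {
            if (pool->size() < 2 && (pool->empty() || (*pool)[0] == i))
              continue;  // no eligible donor in this pool
            do { j = (*pool)[runif_int((int)pool->size())]; } while (j == i);
          } else {
            do { j = runif_int(n); } while (j == i);
          }
          int start;
          if (nh > 0 && unif_rand() < hotspot_fraction)
            start = hotspots[runif_int(nh)];
          else
            start = runif_int(genome_length);
          int endp = start + tract_length;
          if (endp > genome_length) endp = genome_length;
          apply_hgt(pop[i], snap[j], start, endp);
          got = true;
        }
        if (got) ++n_recipients;
      }
    }

    // --- migration (linear stepping stone) ---
    if (n_demes > 1 && migrants > 0) {
      std::vector<std::vector<int> > members(n_demes);
      for (int i = 0; i < n; ++i) members[pop[i].deme].push_back(i);
      std::vector<int> new_deme(n);
      for (int i = 0; i < n; ++i) new_deme[i] = pop[i].deme;
      for (int d = 0; d < n_demes; ++d) {
        std::vector<int> nb;
        if (d > 0) nb.push_back(d - 1);
        if (d < n_demes - 1) nb.push_back(d + 1);
        int need = migrants * (int)nb.size();
        if ((int)members[d].size() < need)
          stop("stepping-stone migration: deme %d has %d individuals, "
               "needs %d migrants", d, (int)members[d].size(), need);
        std::vector<int> idx(members[d]);
        sample_k(idx, need);
        int k = 0;
        for (size_t b = 0; b < nb.size(); ++b)
          for (int m = 0; m < migrants; ++m) new_deme[idx[k++]] = nb[b];
      }
      for (int i = 0; i < n; ++i) pop[i].deme = new_deme[i];
    }

    // --- trait scores and per-individual offspring rate ---
    std::vector<double> score(n);
    double sum_s = 0.0;
    for (int i = 0; i < n; ++i) {
      score[i] = score_of(pop[i], coefficients, uniform_eff);
      sum_s += score[i];
    }
    std::vector<double> lambda(n, base_lambda);
    if (selection_on && g >= selection_start) {
      double mu = sum_s / n, dmax = 0.0;
      std::vector<double> dev(n);
      for (int i = 0; i < n; ++i) {
        dev[i] = std::pow(std::fabs(score[i] - mu), exponent);
        if (dev[i] > dmax) dmax = dev[i];
      }
      for (int i = 0; i < n; ++i)
        lambda[i] = 2.0 + amplitude * dev[i] / (dmax + epsilon);
    }

    // --- reproduction (Poisson offspring) + per-deme capacity regulation ---
    std::vector<int> noff(n);
    long total = 0;
    double sum_lambda = 0.0;
    for (int i = 0; i < n; ++i) {
      noff[i] = (int)R::rpois(lambda[i]);
      total += noff[i];
      sum_lambda += lambda[i];
    }
    if (total == 0)
      stop("population went extinct at generation %d (zero offspring)", g);
    std::vector<Genome> off;
    off.reserve((size_t)std::min<long>(total, (long)pop_size * 4));
    std::vector<std::vector<int> > off_by_deme(n_demes);
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < noff[i]; ++c) {
        off.push_back(pop[i]);  // clonal copy
        off_by_deme[pop[i].deme].push_back((int)off.size() - 1);
      }
    }
    std::vector<Genome> next;
    next.reserve(pop_size);
    for (int d = 0; d < n_demes; ++d) {
      std::vector<int> &ids = off_by_deme[d];
      if (n_demes > 1 && ids.empty())
        stop("deme %d went extinct at generation %d", d, g);
      if ((int)ids.size() > cap) {
        sample_k(ids, cap);
        ids.resize(cap);
        std::sort(ids.begin(), ids.end());
      }
      for (size_t k = 0; k < ids.size(); ++k) next.push_back(off[ids[k]]);
    }
    pop.swap(next);

    log_gen.push_back(g);
    log_size.push_back((double)pop.size());
    log_mean_score.push_back(sum_s / n);
    log_mean_lambda.push_back(sum_lambda / n);
    log_mean_offspring.push_back((double)total / n);
    log_frac_hgt.push_back((double)n_recipients / n);
  }

  // --- package results ---
  const int nf = (int)pop.size();
  List positions(nf), types(nf);
  IntegerVector deme(nf), label(nf);
  NumericVector trait(nf);
  for (int i = 0; i < nf; ++i) {
    positions[i] = IntegerVector(pop[i].pos.begin(), pop[i].pos.end());
    IntegerVector tv(pop[i].type.size());
    for (size_t k = 0; k < pop[i].type.size(); ++k) tv[k] = pop[i].type[k];
    types[i] = tv;
    deme[i] = pop[i].deme;
    label[i] = pop[i].label;
    trait[i] = score_of(pop[i], coefficients, uniform_eff);
  }
  DataFrame glog = DataFrame::create(
      _["generation"] = log_gen, _["size"] = log_size,
      _["mean_score"] = log_mean_score, _["mean_lambda"] = log_mean_lambda,
      _["mean_offspring"] = log_mean_offspring,
      _["frac_hgt"] = log_frac_hgt);
  return List::create(_["positions"] = positions, _["types"] = types,
                      _["deme"] = deme, _["label"] = label,
                      _["trait"] = trait, _["log"] = glog);
}
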