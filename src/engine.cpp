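// Death-birth engine for cooperation on a dynamic network with social
// inheritance. All randomness comes from R's RNG (set.seed() at the R level
// makes runs bit-reproducible). Draw order within one selection step is
// fixed: death index, parent lottery, allele mutation, p_n mutation,
// p_r mutation, then one uniform per wiring candidate in increasing index
// order (the parent itself consumes no draw; it is linked with certainty).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Game {
  double B, C, D, Dpl, Clink, delta;
  bool per_link;
};

inline int unif_index(int n) {
  int k = static_cast<int>(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

inline double clamp01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

class Engine {
public:
  int n;
  Game g;
  std::vector<unsigned char> adj;  // n x n, row-major, symmetric, 0 diagonal
  std::vector<int> deg;
  std::vector<int> typ;            // 0 defector, 1 cooperator
  std::vector<double> pn, pr;
  std::vector<double> u, w;        // payoff / fitness cache (end of last step)
  int ncoop;
  long steps;

  Engine(int n_, const Game& g_) :
    n(n_), g(g_), adj((size_t)n_ * n_, 0), deg(n_, 0), typ(n_, 0),
    pn(n_, 0.0), pr(n_, 0.0), u(n_, 0.0), w(n_, 1.0), ncoop(0), steps(0) {}

  void init_er(double p0) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (unif_rand() < p0) set_edge(i, j);
  }

  void set_edge(int i, int j) {
    adj[(size_t)i * n + j] = 1;
    adj[(size_t)j * n + i] = 1;
    ++deg[i]; ++deg[j];
  }

  // payoff of the diluted (total-benefit) game or the per-link variant,
  // for every individual, plus fitness w = (1+delta)^u via log space
  void payoffs_fitness() {
    const double lg = std::log1p(g.delta);
    for (int i = 0; i < n; ++i)
      u[i] = -(typ[i] ? g.C * (g.per_link ? (double)deg[i] : 1.0) : 0.0)
             - deg[i] * g.Clink;
    for (int i = 0; i < n; ++i) {
      const unsigned char* row = &adj[(size_t)i * n];
      for (int j = i + 1; j < n; ++j) {
        if (!row[j]) continue;
        if (g.per_link) {
          if (typ[j]) u[i] += g.B + (typ[i] ? g.Dpl : 0.0);
          if (typ[i]) u[j] += g.B + (typ[j] ? g.Dpl : 0.0);
        } else {
          if (typ[j])
            u[i] += g.B / deg[j] +
                    (typ[i] ? g.D / ((double)deg[i] * deg[j]) : 0.0);
          if (typ[i])
            u[j] += g.B / deg[i] +
                    (typ[j] ? g.D / ((double)deg[i] * deg[j]) : 0.0);
        }
      }
    }
    for (int i = 0; i < n; ++i) w[i] = std::exp(u[i] * lg);
  }

  // remove `dead`, install the newborn in its slot, wire it
  void replace(int dead, int parent, int ctype, double cpn, double cpr) {
    unsigned char* drow = &adj[(size_t)dead * n];
    for (int j = 0; j < n; ++j) {
      if (drow[j]) {
        drow[j] = 0;
        adj[(size_t)j * n + dead] = 0;
        --deg[j];
      }
    }
    deg[dead] = 0;
    ncoop += ctype - typ[dead];
    typ[dead] = ctype;
    pn[dead] = cpn;
    pr[dead] = cpr;
    const unsigned char* prow = &adj[(size_t)parent * n];
    for (int j = 0; j < n; ++j) {
      if (j == dead) continue;
      bool link;
      if (j == parent) {
        link = true;
      } else {
        double r = unif_rand();
        link = prow[j] ? (r < cpn) : (r < cpr);
      }
      if (link) set_edge(dead, j);
    }
  }

  // one neutral event: uniform death, uniform parent, no mutation,
  // newborn wired with the population-wide initial traits
  void burnin_step(double pn0, double pr0) {
    int dead = unif_index(n);
    int k = unif_index(n - 1);
    int parent = (k >= dead) ? k + 1 : k;
    replace(dead, parent, typ[dead], pn0, pr0);
    ++steps;
  }

  // one selection step; fitness cache w is the previous step's
  void select_step(double mu, double mu_l, double sigma_n, double sigma_r,
                   bool evolve_pn, bool evolve_pr, bool include_dead) {
    int dead = unif_index(n);
    double total = 0.0;
    for (int i = 0; i < n; ++i) total += w[i];
    if (!include_dead) total -= w[dead];
    if (!(total > 0.0)) stop("degenerate reproduction lottery: total weight is not positive");
    double r = unif_rand() * total;
    int parent = -1;
    double cum = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!include_dead && i == dead) continue;
      cum += w[i];
      if (r < cum) { parent = i; break; }
    }
    if (parent < 0) {  // guard against rounding at the upper edge
      parent = n - 1;
      if (!include_dead && parent == dead) parent = n - 2;
    }
    int ctype = typ[parent];
    if (unif_rand() < mu) ctype = 1 - ctype;
    double cpn = pn[parent], cpr = pr[parent];
    if (evolve_pn && unif_rand() < mu_l)
      cpn = clamp01(cpn + norm_rand() * sigma_n);
    if (evolve_pr && unif_rand() < mu_l)
      cpr = clamp01(cpr + norm_rand() * sigma_r);
    replace(dead, parent, ctype, cpn, cpr);
    payoffs_fitness();
    ++steps;
  }

  void verify() const {
    int nc = 0;
    for (int i = 0; i < n; ++i) {
      if (adj[(size_t)i * n + i] != 0) stop("invariant violated: self-loop");
      int d = 0;
      for (int j = 0; j < n; ++j) {
        unsigned char a = adj[(size_t)i * n + j];
        if (a > 1) stop("invariant violated: non-binary entry");
        if (a != adj[(size_t)j * n + i]) stop("invariant violated: asymmetry");
        d += a;
      }
      if (d != deg[i]) stop("invariant violated: stale degree");
      if (typ[i] != 0 && typ[i] != 1) stop("invariant violated: allele");
      if (pn[i] < 0 || pn[i] > 1 || pr[i] < 0 || pr[i] > 1)
        stop("invariant violated: trait outside [0,1]");
      if (!(w[i] > 0)) stop("invariant violated: non-positive fitness");
      nc += typ[i];
    }
    if (nc != ncoop) stop("invariant violated: cooperator count");
  }

  void observe(double* row, int gen) const {
    double spn = 0, spr = 0, su = 0, sw = 0;
    long sdeg = 0;
    for (int i = 0; i < n; ++i) {
      spn += pn[i]; spr += pr[i]; su += u[i]; sw += w[i]; sdeg += deg[i];
    }
    double prim, newman;
    assortment(prim, newman);
    row[0] = gen;
    row[1] = (double)ncoop / n;
    row[2] = spn / n;
    row[3] = spr / n;
    row[4] = (double)sdeg / n;
    row[5] = su / n;
    row[6] = sw / n;
    row[7] = prim;
    row[8] = newman;
  }

  // prim: mean neighbour-cooperator fraction of cooperators minus that of
  // defectors (degree-0 individuals excluded); newman: nominal edge
  // assortativity of the allele
  void assortment(double& prim, double& newman) const {
    double sC = 0, sD = 0;
    int nC = 0, nD = 0;
    long eCC = 0, eCD = 0, eDD = 0;
    for (int i = 0; i < n; ++i) {
      if (deg[i] == 0) continue;
      const unsigned char* row = &adj[(size_t)i * n];
      int k = 0;
      for (int j = 0; j < n; ++j) if (row[j] && typ[j]) ++k;
      double frac = (double)k / deg[i];
      if (typ[i]) { sC += frac; ++nC; } else { sD += frac; ++nD; }
      for (int j = i + 1; j < n; ++j) {
        if (!row[j]) continue;
        if (typ[i] && typ[j]) ++eCC;
        else if (!typ[i] && !typ[j]) ++eDD;
        else ++eCD;
      }
    }
    prim = (nC > 0 && nD > 0) ? sC / nC - sD / nD : NA_REAL;
    double m2 = 2.0 * (eCC + eCD + eDD);
    if (m2 == 0) { newman = NA_REAL; return; }
    double ecc = 2.0 * eCC / m2, edd = 2.0 * eDD / m2;
    double aC = (2.0 * eCC + eCD) / m2, aD = (2.0 * eDD + eCD) / m2;
    double sum2 = aC * aC + aD * aD;
    double den = 1.0 - sum2;
    newman = (den == 0.0) ? NA_REAL : (ecc + edd - sum2) / den;
  }
};

}  // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(int n, double p0, int burnin_gens, int generations,
                double B, double C, double D, double Dpl, double Clink,
                double delta, bool per_link,
                double mu, double mu_l, double sigma_n, double sigma_r,
                bool evolve_pn, bool evolve_pr,
                double init_pn, double init_pr,
                int record_every, bool include_dead_in_lottery,
                bool stop_at_fixation, bool check_invariants) {
  if (n < 3) stop("population size must be at least 3");
  if (p0 < 0 || p0 > 1) stop("initial density p0 must lie in [0,1]");
  Game g{B, C, D, Dpl, Clink, delta, per_link};
  Engine e(n, g);
  e.init_er(p0);
  if (check_invariants) e.verify();

  for (long s = 0; s < (long)burnin_gens * n; ++s) {
    e.burnin_step(init_pn, init_pr);
    if (check_invariants) e.verify();
  }

  // alleles at expected frequency 0.5; individual linking traits for the
  // evolving scenarios are drawn around the initial means with the
  // mutational standard deviations, clamped to [0,1]
  e.ncoop = 0;
  for (int i = 0; i < n; ++i) {
    e.typ[i] = unif_rand() < 0.5 ? 1 : 0;
    e.ncoop += e.typ[i];
  }
  for (int i = 0; i < n; ++i)
    e.pn[i] = evolve_pn ? clamp01(init_pn + norm_rand() * sigma_n) : init_pn;
  for (int i = 0; i < n; ++i)
    e.pr[i] = evolve_pr ? clamp01(init_pr + norm_rand() * sigma_r) : init_pr;
  e.payoffs_fitness();

  int nrec = generations / record_every + 1;
  NumericMatrix rec(nrec, 9);
  std::vector<double> rowbuf(9);
  int irec = 0;
  e.observe(rowbuf.data(), 0);
  for (int c = 0; c < 9; ++c) rec(irec, c) = rowbuf[c];
  ++irec;

  int fixation = NA_INTEGER;
  int gens_run = 0;
  bool done = false;
  for (int gen = 1; gen <= generations && !done; ++gen) {
    for (int s = 0; s < n; ++s) {
      e.select_step(mu, mu_l, sigma_n, sigma_r, evolve_pn, evolve_pr,
                    include_dead_in_lottery);
      if (check_invariants) e.verify();
      if (stop_at_fixation && (e.ncoop == 0 || e.ncoop == n)) {
        fixation = (e.ncoop == n) ? 1 : 0;
        done = true;
        break;
      }
    }
    if (!done) {
      gens_run = gen;
      if (gen % record_every == 0) {
        e.observe(rowbuf.data(), gen);
        for (int c = 0; c < 9; ++c) rec(irec, c) = rowbuf[c];
        ++irec;
      }
    }
  }

  NumericMatrix records = rec(Range(0, irec - 1), Range(0, 8));
  colnames(records) = CharacterVector::create(
      "generation", "coop_freq", "mean_pn", "mean_pr", "mean_degree",
      "mean_payoff", "mean_fitness", "assortment", "assort_newman");

  IntegerMatrix A(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      A(i, j) = e.adj[(size_t)i * n + j];

  return List::create(
      _["records"] = records,
      _["adjacency"] = A,
      _["types"] = IntegerVector(e.typ.begin(), e.typ.end()),
      _["p_n"] = NumericVector(e.pn.begin(), e.pn.end()),
      _["p_r"] = NumericVector(e.pr.begin(), e.pr.end()),
      _["payoffs"] = NumericVector(e.u.begin(), e.u.end()),
      _["fitness"] = NumericVector(e.w.begin(), e.w.end()),
      _["fixation"] = fixation,
      _["generations_run"] = gens_run,
      _["steps"] = (double)e.steps);
}

// Payoffs of a static network, same code path as the simulation engine;
// exposed so tests can compare it with the R reference implementation.
// [[Rcpp::export(name = ".engine_payoffs")]]
NumericVector engine_payoffs(IntegerMatrix adjacency, IntegerVector types,
                             double B, double C, double D, double Dpl,
                             double Clink, bool per_link) {
  int n = adjacency.nrow();
  Game g{B, C, D, Dpl, Clink, 0.0, per_link};
  Engine e(n, g);
  for (int i = 0; i < n; ++i) {
    e.typ[i] = types[i];
    for (int j = i + 1; j < n; ++j)
      if (adjacency(i, j)) e.set_edge(i, j);
  }
  e.payoffs_fitness();
  return NumericVector(e.u.begin(), e.u.end());
}
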