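// Deme-based spatial model of tumor growth.
//
// Demes (well-mixed glands) live on a 3D lattice. A deme fills to its
// carrying capacity by a discrete-generation birth-death update of its
// cells, then fissions into an adjacent empty lattice site (binomial split).
// Demes at capacity with no empty neighbor become quiescent, which yields
// peripherally dominated growth. Genotypes are nodes of a parent-pointer
// tree; each node stores the contiguous block of mutation ids it introduced,
// so per-sample mutation frequencies are subtree sums. Uses R's RNG
// throughout so set.seed() makes whole tumors reproducible.

#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Genotype {
  int parent;          // -1 for root
  int n_new;           // mutations introduced by this node
  long long mut_start; // first mutation id of the block
  uint8_t drivers;     // cumulative driver count
};

struct Deme {
  int x, y, z;
  std::vector<std::pair<int, int> > counts; // (genotype id, cells)
  long long n_cells;
  bool alive;
};

struct Tumor {
  std::vector<Genotype> genotypes;
  std::vector<Deme> demes;
  std::unordered_map<long long, int> lattice;
  long long total_cells;
  long long next_mut;
  int deme_size;
  int restarts;
  double birth, death, mut_rate, driver_prob, s;
  int n_truncal;
};

inline long long site_key(int x, int y, int z) {
  return ((long long)(x + 2048) << 24) | ((long long)(y + 2048) << 12) |
         (long long)(z + 2048);
}

inline int fast_binom(int n, double p) {
  if (n <= 0) return 0;
  if (p <= 0.0) return 0;
  if (p >= 1.0) return n;
  if (n < 16) {
    int k = 0;
    for (int i = 0; i < n; ++i)
      if (unif_rand() < p) ++k;
    return k;
  }
  return (int)R::rbinom((double)n, p);
}

// zero-truncated Poisson
inline int ztpois(double mu) {
  for (;;) {
    int k = (int)R::rpois(mu);
    if (k > 0) return k;
  }
}

// division probability per generation given driver count, cached
struct PDiv {
  std::vector<double> p;
  double birth, death, s;
  double get(int k) {
    while ((int)p.size() <= k) {
      double b = birth * std::pow(1.0 + s, (double)p.size());
      p.push_back(b / (b + death));
    }
    return p[k];
  }
};

const int NB = 26; // 3D Moore neighborhood
const int NBD[26][3] = {
  {-1,-1,-1},{-1,-1,0},{-1,-1,1},{-1,0,-1},{-1,0,0},{-1,0,1},
  {-1,1,-1},{-1,1,0},{-1,1,1},{0,-1,-1},{0,-1,0},{0,-1,1},
  {0,0,-1},{0,0,1},{0,1,-1},{0,1,0},{0,1,1},
  {1,-1,-1},{1,-1,0},{1,-1,1},{1,0,-1},{1,0,0},{1,0,1},
  {1,1,-1},{1,1,0},{1,1,1}};

void init_tumor(Tumor &T) {
  T.genotypes.clear();
  T.demes.clear();
  T.lattice.clear();
  Genotype root;
  root.parent = -1;
  root.n_new = T.n_truncal;
  root.mut_start = 0;
  root.drivers = 0;
  T.genotypes.push_back(root);
  T.next_mut = T.n_truncal;
  Deme d0;
  d0.x = d0.y = d0.z = 0;
  d0.counts.push_back(std::make_pair(0, 1));
  d0.n_cells = 1;
  d0.alive = true;
  T.demes.push_back(d0);
  T.lattice[site_key(0, 0, 0)] = 0;
  T.total_cells = 1;
}

// one birth-death generation inside a deme
void deme_generation(Tumor &T, Deme &d, PDiv &pdiv, double p_anymut) {
  std::vector<std::pair<int, int> > nc;
  nc.reserve(d.counts.size() + 8);
  long long total = 0;
  for (size_t i = 0; i < d.counts.size(); ++i) {
    int g = d.counts[i].first;
    int n = d.counts[i].second;
    double p = pdiv.get(T.genotypes[g].drivers);
    int births = fast_binom(n, p);
    if (births == 0) continue;
    int muts = fast_binom(births, p_anymut);
    int plain = 2 * births - muts;
    if (plain > 0) nc.push_back(std::make_pair(g, plain));
    total += plain;
    for (int j = 0; j < muts; ++j) {
      Genotype child;
      child.parent = g;
      child.n_new = ztpois(T.mut_rate);
      child.mut_start = T.next_mut;
      T.next_mut += child.n_new;
      int nd = fast_binom(child.n_new, T.driver_prob);
      int dr = (int)T.genotypes[g].drivers + nd;
      child.drivers = (uint8_t)std::min(dr, 255);
      T.genotypes.push_back(child);
      nc.push_back(std::make_pair((int)T.genotypes.size() - 1, 1));
      total += 1;
    }
  }
  T.total_cells += total - d.n_cells;
  d.counts.swap(nc);
  d.n_cells = total;
}

// split a full deme into an empty neighboring site; returns false when
// no empty neighbor exists (deme becomes quiescent)
bool deme_fission(Tumor &T, int di, std::vector<int> &active) {
  Deme &d = T.demes[di];
  int empty[NB];
  int ne = 0;
  for (int k = 0; k < NB; ++k) {
    int x = d.x + NBD[k][0], y = d.y + NBD[k][1], z = d.z + NBD[k][2];
    if (T.lattice.find(site_key(x, y, z)) == T.lattice.end())
      empty[ne++] = k;
  }
  if (ne == 0) return false;
  int k = empty[(int)(unif_rand() * ne) % ne];
  Deme nd;
  nd.x = d.x + NBD[k][0];
  nd.y = d.y + NBD[k][1];
  nd.z = d.z + NBD[k][2];
  nd.alive = true;
  nd.n_cells = 0;
  long long stay = 0;
  for (size_t i = 0; i < d.counts.size(); ++i) {
    int move = fast_binom(d.counts[i].second, 0.5);
    if (move > 0)
      nd.counts.push_back(std::make_pair(d.counts[i].first, move));
    d.counts[i].second -= move;
    nd.n_cells += move;
    stay += d.counts[i].second;
  }
  d.counts.erase(std::remove_if(d.counts.begin(), d.counts.end(),
                                [](const std::pair<int, int> &p) {
                                  return p.second == 0;
                                }),
                 d.counts.end());
  d.n_cells = stay;
  T.demes.push_back(nd);
  int ni = (int)T.demes.size() - 1;
  T.lattice[site_key(nd.x, nd.y, nd.z)] = ni;
  active.push_back(ni);
  return true;
}

} // namespace

// [[Rcpp::export]]
SEXP cpp_grow_tumor(int deme_size, double birth, double death,
                    double mut_rate, double driver_prob, double s,
                    int n_truncal, double target_cells, int max_restarts) {
  Tumor *T = new Tumor();
  T->deme_size = deme_size;
  T->birth = birth;
  T->death = death;
  T->mut_rate = mut_rate;
  T->driver_prob = driver_prob;
  T->s = s;
  T->n_truncal = n_truncal;
  T->restarts = 0;

  PDiv pdiv;
  pdiv.birth = birth;
  pdiv.death = death;
  pdiv.s = s;
  double p_anymut = 1.0 - std::exp(-mut_rate);

  RNGScope scope;
  init_tumor(*T);
  std::vector<int> active;
  active.push_back(0);

  long long target = (long long)target_cells;
  int guard = 0;
  while (T->total_cells < target) {
    if (++guard > 2000000) {
      delete T;
      stop("growth did not reach target size (guard tripped)");
    }
    if (active.empty() || T->total_cells <= 0) {
      // founding lineage extinct (or boxed in before reaching target):
      // restart, conditioning the tumor on survival
      if (++T->restarts > max_restarts) {
        delete T;
        stop("tumor went extinct more than max_restarts times");
      }
      init_tumor(*T);
      active.clear();
      active.push_back(0);
      continue;
    }
    size_t n_active = active.size(); // daughters join next sweep
    std::vector<int> still;
    still.reserve(n_active + 16);
    for (size_t ai = 0; ai < n_active; ++ai) {
      int di = active[ai];
      Deme &d = T->demes[di];
      if (!d.alive) continue;
      if (d.n_cells < T->deme_size)
        deme_generation(*T, d, pdiv, p_anymut);
      if (d.n_cells == 0) {
        // deme died out: free the lattice site
        T->lattice.erase(site_key(d.x, d.y, d.z));
        d.alive = false;
        continue;
      }
      bool quiescent = false;
      while (T->demes[di].n_cells >= T->deme_size) {
        if (!deme_fission(*T, di, still)) {
          quiescent = true;
          break;
        }
      }
      if (!quiescent) still.push_back(di);
      if (T->total_cells >= target) break;
    }
    // carry over daughters created late in the sweep
    for (size_t ai = n_active; ai < active.size(); ++ai)
      still.push_back(active[ai]);
    active.swap(still);
  }

  XPtr<Tumor> ptr(T, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_tumor_summary(SEXP ptr) {
  XPtr<Tumor> T(ptr);
  long long alive = 0;
  for (size_t i = 0; i < T->demes.size(); ++i)
    if (T->demes[i].alive) ++alive;
  return List::create(
      _["n_cells"] = (double)T->total_cells,
      _["n_demes"] = (double)alive,
      _["n_genotypes"] = (double)T->genotypes.size(),
      _["n_mutations"] = (double)T->next_mut,
      _["restarts"] = T->restarts,
      _["deme_size"] = T->deme_size);
}

// [[Rcpp::export]]
DataFrame cpp_deme_info(SEXP ptr) {
  XPtr<Tumor> T(ptr);
  std::vector<int> x, y, z, idx;
  std::vector<double> n;
  for (size_t i = 0; i < T->demes.size(); ++i) {
    if (!T->demes[i].alive) continue;
    idx.push_back((int)i + 1);
    x.push_back(T->demes[i].x);
    y.push_back(T->demes[i].y);
    z.push_back(T->demes[i].z);
    n.push_back((double)T->demes[i].n_cells);
  }
  return DataFrame::create(_["deme"] = idx, _["x"] = x, _["y"] = y,
                           _["z"] = z, _["n_cells"] = n);
}

// Sample ~target_cells contiguous cells: the focal deme plus its nearest
// occupied neighbors by Euclidean lattice distance. Returns mutation ids
// present in the sample and their true cell fractions.
// [[Rcpp::export]]
List cpp_take_sample(SEXP ptr, int focal, double target_cells) {
  XPtr<Tumor> T(ptr);
  int fi = focal - 1;
  if (fi < 0 || fi >= (int)T->demes.size() || !T->demes[fi].alive)
    stop("invalid focal deme");
  const Deme &f = T->demes[fi];

  std::vector<std::pair<double, int> > order;
  order.reserve(T->demes.size());
  for (size_t i = 0; i < T->demes.size(); ++i) {
    if (!T->demes[i].alive) continue;
    double dx = T->demes[i].x - f.x, dy = T->demes[i].y - f.y,
           dz = T->demes[i].z - f.z;
    order.push_back(std::make_pair(dx * dx + dy * dy + dz * dz, (int)i));
  }
  std::sort(order.begin(), order.end());

  // aggregate genotype counts over the sampled demes
  std::map<int, long long, std::greater<int> > agg;
  long long n_cells = 0;
  for (size_t i = 0; i < order.size() && n_cells < (long long)target_cells;
       ++i) {
    const Deme &d = T->demes[order[i].second];
    for (size_t j = 0; j < d.counts.size(); ++j)
      agg[d.counts[j].first] += d.counts[j].second;
    n_cells += d.n_cells;
  }

  // subtree sums: children have larger ids than parents, so one descending
  // pass pushes each node's total into its parent
  for (std::map<int, long long, std::greater<int> >::iterator it = agg.begin();
       it != agg.end(); ++it) {
    int parent = T->genotypes[it->first].parent;
    if (parent >= 0) agg[parent] += it->second;
  }

  std::vector<double> mut_id, frac;
  for (std::map<int, long long, std::greater<int> >::iterator it = agg.begin();
       it != agg.end(); ++it) {
    if (it->second <= 0) continue;
    const Genotype &g = T->genotypes[it->first];
    double fr = (double)it->second / (double)n_cells;
    for (int j = 0; j < g.n_new; ++j) {
      mut_id.push_back((double)(g.mut_start + j));
      frac.push_back(fr);
    }
  }
  return List::create(_["mut_id"] = mut_id, _["fraction"] = frac,
                      _["n_cells"] = (double)n_cells);
}
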