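// Forward-time Wright-Fisher diploid engine.
//
// Haplotypes are sparse sorted vectors of derived-mutation positions on a
// continuous coordinate in [0, L) (infinite-sites).  Demography is supplied
// as a per-generation size schedule plus founding events and per-generation
// migration rates, so one engine serves the structured founder-effect model,
// its constant-Ne counterfactual and simple single/two-deme scenarios.
//
// The RNG is a std::mt19937_64 engine with hand-rolled uniform / Poisson
// draws so the stream depends only on the seed, not on the C++ standard
// library's distribution implementations.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

typedef std::vector<double> Hap;

struct Rng {
  std::mt19937_64 eng;
  explicit Rng(uint64_t s) : eng(s ^ 0x9E3779B97F4A7C15ULL) {}
  double u() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }  // [0,1)
  int pois(double lam) {
    if (lam <= 0.0) return 0;
    if (lam > 50.0) {  // split to keep Knuth's product method in range
      double h = lam * 0.5;
      int k = pois(h);
      return k + pois(lam - h);
    }
    double limit = std::exp(-lam), p = 1.0;
    int k = 0;
    do {
      ++k;
      p *= u();
    } while (p > limit);
    return k - 1;
  }
  int upto(int n) {  // uniform integer in [0, n)
    int r = static_cast<int>(u() * n);
    return r >= n ? n - 1 : r;
  }
};

static inline bool has_pos(const Hap& h, double pos) {
  return std::binary_search(h.begin(), h.end(), pos);
}

// meiosis: one recombinant gamete from parental haplotypes a/b plus new
// mutations; crossover count ~ Poisson(rec*L), positions uniform.
static void gamete(const Hap& a, const Hap& b, double L, double recL,
                   double muL, Rng& rng, Hap& out) {
  out.clear();
  int nco = rng.pois(recL);
  int cur = (rng.u() < 0.5) ? 0 : 1;
  if (nco == 0) {
    const Hap& src = (cur == 0) ? a : b;
    out.assign(src.begin(), src.end());
  } else {
    std::vector<double> cuts(nco);
    for (int i = 0; i < nco; ++i) cuts[i] = rng.u() * L;
    std::sort(cuts.begin(), cuts.end());
    out.reserve(std::max(a.size(), b.size()) + 8);
    double lo = 0.0;
    for (int c = 0; c <= nco; ++c) {
      double hi = (c < nco) ? cuts[c] : L;
      const Hap& src = (cur == 0) ? a : b;
      Hap::const_iterator i1 = std::lower_bound(src.begin(), src.end(), lo);
      Hap::const_iterator i2 = std::lower_bound(src.begin(), src.end(), hi);
      out.insert(out.end(), i1, i2);
      lo = hi;
      cur ^= 1;
    }
  }
  int nmut = rng.pois(muL);
  for (int i = 0; i < nmut; ++i) {
    double pos = rng.u() * L;
    Hap::iterator it = std::lower_bound(out.begin(), out.end(), pos);
    if (it == out.end() || *it != pos) out.insert(it, pos);
  }
}

typedef std::vector<Hap> Deme;  // 2N haplotypes; individual i -> (2i, 2i+1)

// remove mutations fixed in every haplotype of every extant deme
static void purge_fixed(std::vector<Deme>& pops, double keep_pos) {
  size_t tot = 0;
  std::unordered_map<double, size_t> cnt;
  for (size_t d = 0; d < pops.size(); ++d)
    for (size_t h = 0; h < pops[d].size(); ++h) {
      ++tot;
      const Hap& hp = pops[d][h];
      for (size_t i = 0; i < hp.size(); ++i) ++cnt[hp[i]];
    }
  if (tot == 0) return;
  std::vector<double> fixed;
  for (std::unordered_map<double, size_t>::iterator it = cnt.begin();
       it != cnt.end(); ++it)
    if (it->second == tot && it->first != keep_pos) fixed.push_back(it->first);
  if (fixed.empty()) return;
  std::sort(fixed.begin(), fixed.end());
  Hap tmp;
  for (size_t d = 0; d < pops.size(); ++d)
    for (size_t h = 0; h < pops[d].size(); ++h) {
      Hap& hp = pops[d][h];
      tmp.clear();
      tmp.reserve(hp.size());
      std::set_difference(hp.begin(), hp.end(), fixed.begin(), fixed.end(),
                          std::back_inserter(tmp));
      hp.swap(tmp);
    }
}

// weighted parent index via cumulative weights (uniform case handled by
// the same code path, weights all one)
static int pick_parent(const std::vector<double>& cum, Rng& rng) {
  double x = rng.u() * cum.back();
  return static_cast<int>(
      std::lower_bound(cum.begin(), cum.end(), x) - cum.begin());
}

// [[Rcpp::export]]
List wf_engine_cpp(IntegerMatrix sizes,   // n_demes x (T+1); col t = size at gen t
                   IntegerMatrix founders,  // rows: gen (1..T), deme, source
                   List migrations,         // list of list(a, b, rates[T])
                   double L, double mu, double rec,
                   List selection,          // empty list for neutral
                   IntegerMatrix samples,   // rows: deme, n_individuals
                   int purge_every, double seed) {
  const int n_demes = sizes.nrow();
  const int T = sizes.ncol() - 1;
  Rng rng(static_cast<uint64_t>(seed));

  const double recL = rec * L, muL = mu * L;

  // selection setup
  bool sel_on = selection.size() > 0;
  int sel_deme = -1, sel_origin = -1;
  double sel_s = 0.0, sel_h = 0.5, sel_pos = -1.0;
  double sel_flo = 0.0, sel_fhi = 1.0;  // standing-variant frequency window
  bool sel_standing = false, sel_active = false;
  if (sel_on) {
    sel_deme = as<int>(selection["deme"]);
    sel_s = as<double>(selection["s"]);
    sel_h = as<double>(selection["h"]);
    sel_pos = as<double>(selection["pos"]);
    sel_origin = as<int>(selection["origin_gen"]);
    sel_standing = as<bool>(selection["standing"]);
    sel_flo = as<double>(selection["freq_lo"]);
    sel_fhi = as<double>(selection["freq_hi"]);
    if (sel_s <= 0.0) sel_on = false;  // s = 0 is exactly the neutral path
  }

  // founding event lookup: per generation, per deme -> source
  std::vector<std::vector<std::pair<int, int> > > found_at(T + 1);
  for (int i = 0; i < founders.nrow(); ++i)
    found_at[founders(i, 0)].push_back(
        std::make_pair(founders(i, 1), founders(i, 2)));

  // migration schedules
  struct Mig {
    int a, b;
    NumericVector rates;
  };
  std::vector<Mig> migs;
  for (int i = 0; i < migrations.size(); ++i) {
    List m = migrations[i];
    Mig mg;
    mg.a = as<int>(m["a"]);
    mg.b = as<int>(m["b"]);
    mg.rates = as<NumericVector>(m["rates"]);
    migs.push_back(mg);
  }

  std::vector<Deme> pops(n_demes), next(n_demes);
  for (int d = 0; d < n_demes; ++d) pops[d].resize(2 * sizes(d, 0));

  bool sel_failed_standing = false;

  for (int t = 1; t <= T; ++t) {
    if (t % 512 == 0) Rcpp::checkUserInterrupt();
    // source deme for each target deme this generation
    std::vector<int> src(n_demes);
    for (int d = 0; d < n_demes; ++d) src[d] = d;
    for (size_t e = 0; e < found_at[t].size(); ++e)
      src[found_at[t][e].first] = found_at[t][e].second;

    // cumulative fitness weights per source deme (computed on demand)
    std::vector<std::vector<double> > cum(n_demes);
    for (int d = 0; d < n_demes; ++d) {
      int Nnew = sizes(d, t);
      if (Nnew <= 0) {
        next[d].clear();
        continue;
      }
      int s = src[d];
      int Nsrc = static_cast<int>(pops[s].size()) / 2;
      if (Nsrc <= 0) stop("deme %d has no source individuals at gen %d", d, t);
      if (cum[s].empty()) {
        cum[s].resize(Nsrc);
        double acc = 0.0;
        bool weighted = sel_on && sel_active && s == sel_deme;
        for (int i = 0; i < Nsrc; ++i) {
          double w = 1.0;
          if (weighted) {
            int g = (has_pos(pops[s][2 * i], sel_pos) ? 1 : 0) +
                    (has_pos(pops[s][2 * i + 1], sel_pos) ? 1 : 0);
            w = (g == 2) ? 1.0 + sel_s : (g == 1 ? 1.0 + sel_h * sel_s : 1.0);
          }
          acc += w;
          cum[s][i] = acc;
        }
      }
      next[d].resize(2 * Nnew);
      for (int i = 0; i < Nnew; ++i) {
        int p1 = pick_parent(cum[s], rng);
        int p2 = pick_parent(cum[s], rng);
        if (Nsrc > 1)
          while (p2 == p1) p2 = pick_parent(cum[s], rng);
        gamete(pops[s][2 * p1], pops[s][2 * p1 + 1], L, recL, muL, rng,
               next[d][2 * i]);
        gamete(pops[s][2 * p2], pops[s][2 * p2 + 1], L, recL, muL, rng,
               next[d][2 * i + 1]);
      }
    }

    // conservative migration: each individual replaced by a copy of a random
    // individual from the partner deme with the active probability; plans are
    // drawn against the pre-migration state of both demes
    for (size_t m = 0; m < migs.size(); ++m) {
      double r = migs[m].rates[t - 1];
      if (r <= 0.0) continue;
      Deme& A = next[migs[m].a];
      Deme& B = next[migs[m].b];
      int Na = static_cast<int>(A.size()) / 2, Nb = static_cast<int>(B.size()) / 2;
      if (Na == 0 || Nb == 0) continue;
      std::vector<std::pair<int, int> > planA, planB;  // (target ind, donor ind)
      for (int i = 0; i < Na; ++i)
        if (rng.u() < r) planA.push_back(std::make_pair(i, rng.upto(Nb)));
      for (int i = 0; i < Nb; ++i)
        if (rng.u() < r) planB.push_back(std::make_pair(i, rng.upto(Na)));
      std::vector<Hap> donorA(2 * planA.size()), donorB(2 * planB.size());
      for (size_t i = 0; i < planA.size(); ++i) {
        donorA[2 * i] = B[2 * planA[i].second];
        donorA[2 * i + 1] = B[2 * planA[i].second + 1];
      }
      for (size_t i = 0; i < planB.size(); ++i) {
        donorB[2 * i] = A[2 * planB[i].second];
        donorB[2 * i + 1] = A[2 * planB[i].second + 1];
      }
      for (size_t i = 0; i < planA.size(); ++i) {
        A[2 * planA[i].first].swap(donorA[2 * i]);
        A[2 * planA[i].first + 1].swap(donorA[2 * i + 1]);
      }
      for (size_t i = 0; i < planB.size(); ++i) {
        B[2 * planB[i].first].swap(donorB[2 * i]);
        B[2 * planB[i].first + 1].swap(donorB[2 * i + 1]);
      }
    }

    pops.swap(next);

    // beneficial allele arises (or starts being selected) this generation
    if (sel_on && t == sel_origin) {
      Deme& D = pops[sel_deme];
      if (D.empty()) stop("selection deme empty at origin generation");
      if (sel_standing) {
        // nearest variant segregating within the focal deme
        std::unordered_map<double, size_t> dc;
        for (size_t h = 0; h < D.size(); ++h)
          for (size_t i = 0; i < D[h].size(); ++i) ++dc[D[h][i]];
        double best = -1.0, bestd = 1e300;
        for (std::unordered_map<double, size_t>::iterator it = dc.begin();
             it != dc.end(); ++it) {
          if (it->second == 0 || it->second >= D.size()) continue;
          double f = static_cast<double>(it->second) / D.size();
          if (f < sel_flo || f > sel_fhi) continue;
          double dd = std::fabs(it->first - sel_pos);
          if (dd < bestd || (dd == bestd && it->first < best)) {
            bestd = dd;
            best = it->first;
          }
        }
        if (best < 0.0) {
          sel_failed_standing = true;
          sel_on = false;
        } else {
          sel_pos = best;
        }
      } else {
        int h = rng.upto(static_cast<int>(D.size()));
        Hap::iterator it =
            std::lower_bound(D[h].begin(), D[h].end(), sel_pos);
        if (it == D[h].end() || *it != sel_pos) D[h].insert(it, sel_pos);
      }
      sel_active = true;
    }

    if (purge_every > 0 && t % purge_every == 0)
      purge_fixed(pops, sel_on ? sel_pos : -1.0);
  }

  // final beneficial frequency per deme
  NumericVector ben_freq(n_demes, NA_REAL);
  if (sel_on) {
    for (int d = 0; d < n_demes; ++d) {
      if (pops[d].empty()) continue;
      int c = 0;
      for (size_t h = 0; h < pops[d].size(); ++h)
        if (has_pos(pops[d][h], sel_pos)) ++c;
      ben_freq[d] = static_cast<double>(c) / pops[d].size();
    }
  }

  // sample individuals without replacement, deme by deme
  std::vector<const Hap*> shap;
  IntegerVector samp_deme;
  for (int r = 0; r < samples.nrow(); ++r) {
    int d = samples(r, 0), n = samples(r, 1);
    int N = static_cast<int>(pops[d].size()) / 2;
    if (n > N) stop("sample size %d exceeds deme %d size %d", n, d, N);
    std::vector<int> idx(N);
    for (int i = 0; i < N; ++i) idx[i] = i;
    for (int i = 0; i < n; ++i) {
      int j = i + rng.upto(N - i);
      std::swap(idx[i], idx[j]);
    }
    for (int i = 0; i < n; ++i) {
      shap.push_back(&pops[d][2 * idx[i]]);
      shap.push_back(&pops[d][2 * idx[i] + 1]);
      samp_deme.push_back(d);
    }
  }
  const int H = static_cast<int>(shap.size());

  // segregating sites among the sampled haplotypes
  std::unordered_map<double, int> cnt;
  for (int h = 0; h < H; ++h)
    for (size_t i = 0; i < shap[h]->size(); ++i) ++cnt[(*shap[h])[i]];
  std::vector<double> seg;
  for (std::unordered_map<double, int>::iterator it = cnt.begin();
       it != cnt.end(); ++it)
    if (it->second > 0 && it->second < H) seg.push_back(it->first);
  std::sort(seg.begin(), seg.end());
  const int S = static_cast<int>(seg.size());

  IntegerMatrix hm(H, S);
  for (int h = 0; h < H; ++h) {
    const Hap& hp = *shap[h];
    size_t i = 0;
    for (int s = 0; s < S; ++s) {
      while (i < hp.size() && hp[i] < seg[s]) ++i;
      hm(h, s) = (i < hp.size() && hp[i] == seg[s]) ? 1 : 0;
    }
  }

  return List::create(
      _["positions"] = NumericVector(seg.begin(), seg.end()),
      _["hap"] = hm, _["sample_deme"] = samp_deme,
      _["ben_freq"] = ben_freq,
      _["ben_pos"] = (sel_on ? sel_pos : NA_REAL),
      _["standing_failed"] = sel_failed_standing);
}
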