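// Extended-haplotype-homozygosity kernels.
//
// EHH at marker x for a set of haplotypes is the fraction of pairs that are
// identical at every SNP between the core and x, both inclusive.  Classes of
// identical haplotypes are refined one marker at a time; EHH is
// sum(C(size,2)) / C(n,2) over classes.  iHH integrates the EHH curve over
// physical distance by the trapezoid rule; SL statistics are mean pairwise
// identity lengths in marker units, obtained as the sum of the per-step EHH
// values (each pair contributes one unit per marker of shared run).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline double pairs2(double n) { return n * (n - 1.0) / 2.0; }

// refine classes by the allele column at marker m; returns EHH
static double refine(const IntegerMatrix& hap, const std::vector<int>& rows,
                     int m, std::vector<int>& cls, int& n_cls) {
  std::unordered_map<long long, int> remap;
  remap.reserve(rows.size() * 2);
  double num = 0.0;
  std::vector<int> size;
  size.reserve(n_cls * 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    long long key = 2LL * cls[i] + hap(rows[i], m);
    std::unordered_map<long long, int>::iterator it = remap.find(key);
    int id;
    if (it == remap.end()) {
      id = static_cast<int>(remap.size());
      remap[key] = id;
      size.push_back(0);
    } else {
      id = it->second;
    }
    cls[i] = id;
    ++size[id];
  }
  n_cls = static_cast<int>(remap.size());
  for (size_t k = 0; k < size.size(); ++k) num += pairs2(size[k]);
  return num / pairs2(static_cast<double>(rows.size()));
}

// EHH at distance zero: 1 for an allele-partitioned carrier set, the core
// homozygosity when the walk starts from all haplotypes of a population
static double init_classes(const IntegerMatrix& hap,
                           const std::vector<int>& rows, int core,
                           bool by_core, std::vector<int>& cls, int& n_cls) {
  cls.assign(rows.size(), 0);
  n_cls = 1;
  if (!by_core) return 1.0;
  return refine(hap, rows, core, cls, n_cls);
}

struct WalkResult {
  double ihh;
  bool complete;
};

// integrate EHH over physical distance in both directions, truncating at the
// first marker whose EHH drops below `cutoff` (that trapezoid is included);
// incomplete if the scaffold edge or max_extend is reached while still above
static WalkResult ihh_walk(const IntegerMatrix& hap, const NumericVector& pos,
                           const std::vector<int>& rows, int core,
                           double cutoff, double max_extend, bool by_core) {
  WalkResult res;
  res.ihh = 0.0;
  res.complete = true;
  const int S = hap.ncol();
  for (int dir = -1; dir <= 1; dir += 2) {
    std::vector<int> cls;
    int n_cls;
    double e_prev = init_classes(hap, rows, core, by_core, cls, n_cls);
    if (e_prev < cutoff) continue;  // nothing to integrate this side
    double x_prev = pos[core];
    for (int m = core + dir;; m += dir) {
      if (m < 0 || m >= S) {
        res.complete = false;
        break;
      }
      if (std::fabs(pos[m] - pos[core]) > max_extend) {
        res.complete = false;
        break;
      }
      double e = (n_cls == static_cast<int>(rows.size()))
                     ? 0.0
                     : refine(hap, rows, m, cls, n_cls);
      res.ihh += 0.5 * (e_prev + e) * std::fabs(pos[m] - x_prev);
      if (e < cutoff) break;
      e_prev = e;
      x_prev = pos[m];
    }
  }
  return res;
}

// mean pairwise identity length in marker units: EHH(0) + sum of per-step
// EHH both directions, each direction capped at max_sites markers
static double sl_walk(const IntegerMatrix& hap, const std::vector<int>& rows,
                      int core, int max_sites, bool by_core) {
  const int S = hap.ncol();
  std::vector<int> cls;
  int n_cls;
  double total = init_classes(hap, rows, core, by_core, cls, n_cls);
  double e0 = total;
  for (int dir = -1; dir <= 1; dir += 2) {
    std::vector<int> c2(cls);
    int nc = n_cls;
    double e = e0;
    int steps = 0;
    for (int m = core + dir; m >= 0 && m < S && steps < max_sites;
         m += dir, ++steps) {
      if (nc == static_cast<int>(rows.size())) break;  // all singletons
      e = refine(hap, rows, m, c2, nc);
      if (e <= 0.0) break;
      total += e;
    }
  }
  return total;
}

static std::vector<int> which_rows(const IntegerMatrix& hap,
                                   const IntegerVector& rows, int core,
                                   int allele) {
  std::vector<int> out;
  for (int i = 0; i < rows.size(); ++i)
    if (hap(rows[i], core) == allele) out.push_back(rows[i]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix ehh_within_scan_cpp(IntegerMatrix hap, NumericVector pos,
                                  IntegerVector rows, IntegerVector cores,
                                  double cutoff, double max_extend,
                                  int max_sites) {
  NumericMatrix out(cores.size(), 6);
  colnames(out) = CharacterVector::create("ihh_d", "ihh_a", "complete",
                                          "sl_d", "sl_a", "enough");
  for (int c = 0; c < cores.size(); ++c) {
    int core = cores[c];
    std::vector<int> der = which_rows(hap, rows, core, 1);
    std::vector<int> anc = which_rows(hap, rows, core, 0);
    if (der.size() < 2 || anc.size() < 2) {
      out(c, 5) = 0;
      continue;
    }
    out(c, 5) = 1;
    WalkResult wd = ihh_walk(hap, pos, der, core, cutoff, max_extend, false);
    WalkResult wa = ihh_walk(hap, pos, anc, core, cutoff, max_extend, false);
    out(c, 0) = wd.ihh;
    out(c, 1) = wa.ihh;
    out(c, 2) = (wd.complete && wa.complete) ? 1 : 0;
    out(c, 3) = sl_walk(hap, der, core, max_sites, false);
    out(c, 4) = sl_walk(hap, anc, core, max_sites, false);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix ehh_pop_scan_cpp(IntegerMatrix hap, NumericVector pos,
                               IntegerVector rows, IntegerVector cores,
                               double cutoff, double max_extend,
                               int max_sites) {
  NumericMatrix out(cores.size(), 3);
  colnames(out) = CharacterVector::create("ihh", "complete", "sl");
  std::vector<int> rr(rows.begin(), rows.end());
  for (int c = 0; c < cores.size(); ++c) {
    WalkResult w = ihh_walk(hap, pos, rr, cores[c], cutoff, max_extend, true);
    out(c, 0) = w.ihh;
    out(c, 1) = w.complete ? 1 : 0;
    out(c, 2) = sl_walk(hap, rr, cores[c], max_sites, true);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector ehh_curve_cpp(IntegerMatrix hap, IntegerVector rows, int core,
                            int dir, bool by_core) {
  const int S = hap.ncol();
  std::vector<int> rr(rows.begin(), rows.end());
  std::vector<int> cls;
  int n_cls;
  double e = init_classes(hap, rr, core, by_core, cls, n_cls);
  std::vector<double> vals;
  for (int m = core + dir; m >= 0 && m < S; m += dir) {
    e = (n_cls == static_cast<int>(rr.size()))
            ? 0.0
            : refine(hap, rr, m, cls, n_cls);
    vals.push_back(e);
  }
  return NumericVector(vals.begin(), vals.end());
}
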