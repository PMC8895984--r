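// Compiled meiosis core. Crossovers are drawn from R's RNG (so set.seed
// governs reproducibility): Poisson count at 1 per Morgan, uniform
// positions on the cM axis, mapped to bp by piecewise-linear
// interpolation of the map anchors. The gamete mosaic is assembled in one
// pass over the union of crossover and parental segment boundaries.

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

static double interp_pos(double x, const NumericVector& xs,
                         const NumericVector& ys) {
  int n = xs.size();
  int i = int(std::upper_bound(xs.begin(), xs.end(), x) - xs.begin()) - 1;
  if (i < 0) i = 0;
  if (i > n - 2) i = n - 2;
  double dx = xs[i + 1] - xs[i];
  double w = dx > 0 ? (x - xs[i]) / dx : 0.0;
  if (w < 0) w = 0;
  if (w > 1) w = 1;
  return ys[i] + w * (ys[i + 1] - ys[i]);
}

// founder label of the parental segment covering position p
static double founder_at(const NumericMatrix& seg, double p) {
  int m = seg.nrow();
  int lo = 0, hi = m - 1;
  while (lo < hi) {
    int mid = (lo + hi + 1) / 2;
    if (seg(mid, 0) <= p) lo = mid; else hi = mid - 1;
  }
  return seg(lo, 2);
}

// [[Rcpp::export]]
List meiosis_cpp(const List& h1, const List& h2, const NumericVector& len_bp,
                 const NumericVector& len_cm, const List& anch_cm,
                 const List& anch_bp) {
  int nc = h1.size();
  List out(nc);
  CharacterVector colnm = CharacterVector::create("start", "end", "founder");
  for (int c = 0; c < nc; c++) {
    double Lcm = len_cm[c], Lbp = len_bp[c];
    int n_xo = int(R::rpois(Lcm / 100.0));
    int first = (unif_rand() < 0.5) ? 1 : 2;
    NumericMatrix segA = as<NumericMatrix>(h1[c]);
    NumericMatrix segB = as<NumericMatrix>(h2[c]);
    if (n_xo == 0) {
      out[c] = (first == 1) ? h1[c] : h2[c];
      continue;
    }
    std::vector<double> pos(n_xo);
    for (int k = 0; k < n_xo; k++) pos[k] = unif_rand() * Lcm;
    std::sort(pos.begin(), pos.end());
    NumericVector acm = as<NumericVector>(anch_cm[c]);
    NumericVector abp = as<NumericVector>(anch_bp[c]);
    std::vector<double> bounds;
    bounds.push_back(0.0);
    for (int k = 0; k < n_xo; k++) {
      double b = interp_pos(pos[k], acm, abp);
      if (b > bounds.back() && b < Lbp) bounds.push_back(b);
    }
    bounds.push_back(Lbp);
    // event positions: interval bounds plus parental segment starts
    std::vector<double> ev(bounds.begin(), bounds.end() - 1);
    for (int r = 0; r < segA.nrow(); r++) ev.push_back(segA(r, 0));
    for (int r = 0; r < segB.nrow(); r++) ev.push_back(segB(r, 0));
    std::sort(ev.begin(), ev.end());
    ev.erase(std::unique(ev.begin(), ev.end()), ev.end());
    while (!ev.empty() && ev.back() >= Lbp) ev.pop_back();

    std::vector<double> st, fo;
    for (size_t k = 0; k < ev.size(); k++) {
      // which crossover interval: count of bounds <= ev[k], alternating
      int itv = int(std::upper_bound(bounds.begin(), bounds.end(), ev[k]) -
                    bounds.begin());
      int src = (itv % 2 == 1) ? first : 3 - first;
      double f = (src == 1) ? founder_at(segA, ev[k]) : founder_at(segB, ev[k]);
      if (st.empty() || f != fo.back()) {
        st.push_back(ev[k]);
        fo.push_back(f);
      }
    }
    int m = st.size();
    NumericMatrix res(m, 3);
    for (int r = 0; r < m; r++) {
      res(r, 0) = st[r];
      res(r, 1) = (r + 1 < m) ? st[r + 1] : Lbp;
      res(r, 2) = fo[r];
    }
    colnames(res) = colnm;
    out[c] = res;
  }
  out.attr("names") = h1.attr("names");
  return out;
}
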