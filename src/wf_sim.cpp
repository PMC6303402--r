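#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Forward Wright-Fisher core over a dense haplotype-by-site byte matrix.
//
// Layout: row-major, one row per haplotype, columns sorted by global genomic
// position (0-based, scaffold index * scaffold_length + position). Each
// generation: fitness -> parent sampling (with selfing) -> gamete formation by
// segment copy between crossovers -> mutation -> compaction (lost columns
// dropped, fixed columns moved to the substitution ledger, new columns merged
// into position order).
//
// All randomness comes from R's RNG stream, so set.seed() in R makes runs
// byte-reproducible.

namespace {

struct Buf {
  std::vector<uint8_t> d;
  int nhap = 0, cap = 0;
  uint8_t* row(int i) { return d.data() + static_cast<size_t>(i) * cap; }
  void ensure(int nh, int c) {
    if (c > cap || nh > nhap) {
      int ncap = std::max(c, cap);
      d.assign(static_cast<size_t>(nh) * ncap, 0);
      nhap = nh; cap = ncap;
    } else {
      nhap = nh;
    }
  }
};

inline int pick_parent(const std::vector<double>& cw, double W, int n,
                       bool uniform) {
  double u = unif_rand();
  if (uniform) {
    int i = static_cast<int>(u * n);
    return i >= n ? n - 1 : i;
  }
  double t = u * W;
  int lo = 0, hi = n - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cw[mid] < t) lo = mid + 1; else hi = mid;
  }
  return lo;
}

} // namespace

// [[Rcpp::export(name = ".wf_run")]]
List wf_run(RawMatrix H0, IntegerVector pos0, IntegerVector cls0,
            NumericVector s0, NumericVector h0, IntegerVector alt0,
            IntegerVector origin0, IntegerVector used0,
            IntegerVector n_sched, NumericVector selfing_sched,
            double mu_site, double recomb_per_bp,
            int n_scaf, int scaf_len,
            NumericVector class_frac, NumericVector class_s,
            NumericVector class_h, LogicalVector class_coding,
            IntegerVector coding_pool, int gen0) {
  const double L_total = static_cast<double>(n_scaf) * scaf_len;
  const double recomb_per_scaf = recomb_per_bp * scaf_len;
  const int n_gen = n_sched.size();
  const int n_class = class_frac.size();

  std::vector<double> cum_frac(n_class);
  double acc = 0.0;
  for (int k = 0; k < n_class; ++k) { acc += class_frac[k]; cum_frac[k] = acc; }

  // state
  int nhap = H0.nrow();
  int ncol = H0.ncol();
  Buf A, B;
  A.ensure(std::max(nhap, 2 * Rcpp::max(n_sched)), ncol + 256);
  for (int i = 0; i < nhap; ++i)
    for (int j = 0; j < ncol; ++j) A.row(i)[j] = H0(i, j);
  A.nhap = nhap;

  std::vector<int> pos(pos0.begin(), pos0.end());
  std::vector<int> cls(cls0.begin(), cls0.end());
  std::vector<double> sv(s0.begin(), s0.end());
  std::vector<double> hv(h0.begin(), h0.end());
  std::vector<int> alt(alt0.begin(), alt0.end());
  std::vector<int> origin(origin0.begin(), origin0.end());

  std::unordered_set<int> used(used0.begin(), used0.end());
  for (int p : pos) used.insert(p);

  // substitution ledger
  std::vector<int> fpos, fcls, falt, forigin, fgen;
  std::vector<double> fs, fh;

  std::vector<int> sel_cols;
  auto rebuild_sel = [&]() {
    sel_cols.clear();
    for (int j = 0; j < ncol; ++j) if (sv[j] < 0) sel_cols.push_back(j);
  };
  rebuild_sel();

  std::vector<double> w, cw;
  std::vector<int> mom, dad, xo;
  std::vector<int> cnt, keep, order;
  std::vector<int> npos, ncls, nalt, norigin;
  std::vector<double> nsv, nhv;

  int gen = gen0;
  for (int g = 0; g < n_gen; ++g) {
    const int N_cur = nhap / 2;
    const int N_next = n_sched[g];
    const int nhap_next = 2 * N_next;
    const double sigma = selfing_sched[g];

    // --- fitness ---
    const bool any_sel = !sel_cols.empty();
    double W = 0.0;
    w.assign(N_cur, 1.0);
    if (any_sel) {
      for (int i = 0; i < N_cur; ++i) {
        const uint8_t* a = A.row(2 * i);
        const uint8_t* b = A.row(2 * i + 1);
        double wi = 1.0;
        for (int c : sel_cols) {
          int gt = a[c] + b[c];
          if (gt == 1) wi *= 1.0 + hv[c] * sv[c];
          else if (gt == 2) wi *= 1.0 + sv[c];
        }
        w[i] = wi;
      }
    }
    cw.assign(N_cur, 0.0);
    for (int i = 0; i < N_cur; ++i) { W += w[i]; cw[i] = W; }
    if (any_sel && W <= 0.0)
      stop("population extinct at generation %d: all individual fitnesses are zero",
           gen + 1);

    // --- parents ---
    mom.resize(N_next); dad.resize(N_next);
    for (int k = 0; k < N_next; ++k) {
      mom[k] = pick_parent(cw, W, N_cur, !any_sel);
      dad[k] = (unif_rand() < sigma) ? mom[k]
                                     : pick_parent(cw, W, N_cur, !any_sel);
    }

    // --- mutation count for this generation (placed after copying) ---
    int n_new = static_cast<int>(::Rf_rpois(mu_site * L_total * nhap_next));

    // --- gametes ---
    B.ensure(std::max(nhap_next, B.nhap), std::max(ncol + n_new + 64, B.cap));
    B.nhap = nhap_next;
    // scaffold column ranges in sorted pos
    std::vector<int> scaf_c0(n_scaf + 1);
    for (int sc = 0; sc <= n_scaf; ++sc)
      scaf_c0[sc] = std::lower_bound(pos.begin(), pos.end(), sc * scaf_len) -
                    pos.begin();
    for (int k = 0; k < nhap_next; ++k) {
      const int p = (k % 2 == 0) ? mom[k / 2] : dad[k / 2];
      const uint8_t* srcA = A.row(2 * p);
      const uint8_t* srcB = A.row(2 * p + 1);
      uint8_t* dst = B.row(k);
      for (int sc = 0; sc < n_scaf; ++sc) {
        const int c0 = scaf_c0[sc], c1 = scaf_c0[sc + 1];
        const uint8_t* cur = (unif_rand() < 0.5) ? srcA : srcB;
        const uint8_t* oth = (cur == srcA) ? srcB : srcA;
        int nxo = static_cast<int>(::Rf_rpois(recomb_per_scaf));
        if (nxo == 0 || c1 == c0) {
          if (c1 > c0) std::memcpy(dst + c0, cur + c0, c1 - c0);
          continue;
        }
        xo.resize(nxo);
        for (int t = 0; t < nxo; ++t)
          xo[t] = sc * scaf_len + static_cast<int>(unif_rand() * scaf_len);
        std::sort(xo.begin(), xo.end());
        int cs = c0;
        for (int t = 0; t < nxo; ++t) {
          int ce = std::upper_bound(pos.begin() + cs, pos.begin() + c1, xo[t]) -
                   pos.begin();
          if (ce > cs) std::memcpy(dst + cs, cur + cs, ce - cs);
          std::swap(cur, oth);
          cs = ce;
        }
        if (c1 > cs) std::memcpy(dst + cs, cur + cs, c1 - cs);
      }
    }

    // --- mutations: appended as a tail block, zeroed then single carrier ---
    ++gen;
    int appended = 0;
    for (int m = 0; m < n_new; ++m) {
      double u = unif_rand();
      int k = 0;
      while (k < n_class - 1 && u > cum_frac[k]) ++k;
      int gpos = -1;
      for (int tries = 0; tries < 200; ++tries) {
        int cand;
        if (class_coding[k] && coding_pool.size() > 0) {
          int idx = static_cast<int>(unif_rand() * coding_pool.size());
          if (idx >= coding_pool.size()) idx = coding_pool.size() - 1;
          cand = coding_pool[idx];
        } else {
          cand = static_cast<int>(unif_rand() * L_total);
          if (cand >= L_total) cand = static_cast<int>(L_total) - 1;
        }
        if (used.insert(cand).second) { gpos = cand; break; }
      }
      if (gpos < 0) continue; // saturated; infinite-sites grid full here
      int col = ncol + appended;
      for (int i = 0; i < nhap_next; ++i) B.row(i)[col] = 0;
      int carrier = static_cast<int>(unif_rand() * nhap_next);
      if (carrier >= nhap_next) carrier = nhap_next - 1;
      B.row(carrier)[col] = 1;
      npos.push_back(gpos);
      ncls.push_back(k);
      nsv.push_back(class_s[k]);
      nhv.push_back(class_h[k]);
      nalt.push_back(1 + static_cast<int>(unif_rand() * 3));
      norigin.push_back(gen);
      ++appended;
    }
    // merge metadata tails
    pos.insert(pos.end(), npos.begin(), npos.end());
    cls.insert(cls.end(), ncls.begin(), ncls.end());
    sv.insert(sv.end(), nsv.begin(), nsv.end());
    hv.insert(hv.end(), nhv.begin(), nhv.end());
    alt.insert(alt.end(), nalt.begin(), nalt.end());
    origin.insert(origin.end(), norigin.begin(), norigin.end());
    npos.clear(); ncls.clear(); nsv.clear(); nhv.clear(); nalt.clear();
    norigin.clear();
    int ncol_b = ncol + appended;

    // --- compaction: drop lost, ledger fixed, sort kept by position ---
    cnt.assign(ncol_b, 0);
    for (int i = 0; i < nhap_next; ++i) {
      const uint8_t* r = B.row(i);
      for (int j = 0; j < ncol_b; ++j) cnt[j] += r[j];
    }
    keep.clear();
    for (int j = 0; j < ncol_b; ++j) {
      if (cnt[j] == 0) continue;
      if (cnt[j] == nhap_next) {
        fpos.push_back(pos[j]); fcls.push_back(cls[j]);
        fs.push_back(sv[j]); fh.push_back(hv[j]);
        falt.push_back(alt[j]); forigin.push_back(origin[j]);
        fgen.push_back(gen);
        continue;
      }
      keep.push_back(j);
    }
    order = keep;
    std::sort(order.begin(), order.end(),
              [&](int a2, int b2) { return pos[a2] < pos[b2]; });
    int ncol_new = order.size();
    A.ensure(nhap_next, std::max(ncol_new + 64, A.cap));
    A.nhap = nhap_next;
    for (int i = 0; i < nhap_next; ++i) {
      const uint8_t* src = B.row(i);
      uint8_t* dst = A.row(i);
      for (int j = 0; j < ncol_new; ++j) dst[j] = src[order[j]];
    }
    std::vector<int> tp(ncol_new), tc(ncol_new), ta(ncol_new), to(ncol_new);
    std::vector<double> ts(ncol_new), th(ncol_new);
    for (int j = 0; j < ncol_new; ++j) {
      int o = order[j];
      tp[j] = pos[o]; tc[j] = cls[o]; ts[j] = sv[o]; th[j] = hv[o];
      ta[j] = alt[o]; to[j] = origin[o];
    }
    pos.swap(tp); cls.swap(tc); sv.swap(ts); hv.swap(th);
    alt.swap(ta); origin.swap(to);
    ncol = ncol_new;
    nhap = nhap_next;
    rebuild_sel();

    if (g % 64 == 0) Rcpp::checkUserInterrupt();
  }

  RawMatrix H(nhap, ncol);
  for (int i = 0; i < nhap; ++i)
    for (int j = 0; j < ncol; ++j) H(i, j) = A.row(i)[j];

  return List::create(
      _["H"] = H, _["pos"] = wrap(pos), _["cls"] = wrap(cls),
      _["s"] = wrap(sv), _["h"] = wrap(hv), _["alt"] = wrap(alt),
      _["origin"] = wrap(origin), _["gen"] = gen,
      _["fixed_pos"] = wrap(fpos), _["fixed_cls"] = wrap(fcls),
      _["fixed_s"] = wrap(fs), _["fixed_h"] = wrap(fh),
      _["fixed_alt"] = wrap(falt), _["fixed_origin"] = wrap(forigin),
      _["fixed_gen"] = wrap(fgen));
}
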