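#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Forward recursion over alignment scenarios between a read s and a template
// t. A diagonal step emits the match/mismatch probability pm/pmm, a gap
// consuming l template bases emits gdel[l-1], a gap consuming l read bases
// emits gins[l-1]. Cells are stored linearly, rescaled per row by the row
// maximum so that products over ~300 bp cannot underflow; log scales are
// accumulated in c[i]. Masked-out cells are held at exactly zero.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct DPWork {
  std::vector<double> v;   // (Ls+1) x (Lt+1), row-major, rescaled values
  std::vector<double> c;   // per-row cumulative log scale
  std::vector<double> rm;  // per-row rescale multiplier exp(c[i]-c[i-1])
};

static void dp_fill(const int* s, int Ls, const int* t, int Lt,
                    const double* gdel, int Td, const double* gins, int Ti,
                    double pm, double pmm, const int* mask,
                    const int* jlo, const int* jhi, DPWork& w) {
  const int ncol = Lt + 1;
  // cells outside the mask window are never written and must stay zero;
  // the mask is constant within one exported call, so the full clear is
  // needed only when the work buffer is (re)sized
  size_t need = (size_t)(Ls + 1) * ncol;
  if (w.v.size() != need) w.v.assign(need, 0.0);
  w.c.assign(Ls + 1, 0.0);
  w.rm.assign(Ls + 1, 1.0);
  double* v = w.v.data();
  std::vector<double> rowfac(Ti + 1, 1.0);

  // row 0: only initial deletions (template bases absent from the read)
  if (!mask || mask[0]) v[0] = 1.0;
  int j0hi = jhi ? jhi[0] : Lt;
  for (int j = 1; j <= j0hi; ++j) {
    if (mask && !mask[j]) continue;
    double acc = 0.0;
    int lmax = Td < j ? Td : j;
    for (int l = 1; l <= lmax; ++l) acc += v[j - l] * gdel[l - 1];
    v[j] = acc;
  }

  for (int i = 1; i <= Ls; ++i) {
    const double cref = w.c[i - 1];
    int limax = Ti < i ? Ti : i;
    // rowfac[l] = exp(c[i-l] - c[i-1]), built from the stored per-row
    // rescale multipliers to avoid exp() in the inner loops
    rowfac[1] = 1.0;
    for (int l = 2; l <= limax; ++l)
      rowfac[l] = rowfac[l - 1] / w.rm[i - l + 1];
    double* row = v + (size_t)i * ncol;
    double rowmax = 0.0;
    int ja = jlo ? jlo[i] : 0, jb = jhi ? jhi[i] : Lt;
    for (int j = ja; j <= jb; ++j) {
      if (mask && !mask[(size_t)i * ncol + j]) { row[j] = 0.0; continue; }
      double acc = 0.0;
      if (j > 0) {
        const double* prev = v + (size_t)(i - 1) * ncol;
        acc += prev[j - 1] * (s[i - 1] == t[j - 1] ? pm : pmm);
      }
      int ldmax = Td < j ? Td : j;
      for (int l = 1; l <= ldmax; ++l) acc += row[j - l] * gdel[l - 1];
      for (int l = 1; l <= limax; ++l)
        acc += v[(size_t)(i - l) * ncol + j] * rowfac[l] * gins[l - 1];
      row[j] = acc;
      if (acc > rowmax) rowmax = acc;
    }
    if (rowmax > 0.0) {
      for (int j = ja; j <= jb; ++j) row[j] /= rowmax;
      w.c[i] = cref + std::log(rowmax);
      w.rm[i] = rowmax;
    } else {
      w.c[i] = cref;
      w.rm[i] = 1.0;
    }
  }
}

struct MaskInfo {
  std::vector<int> cells;   // row-major admissibility
  std::vector<int> jlo, jhi;  // per-row admissible column window
  bool active = false;
  const int* cells_ptr() const { return active ? cells.data() : nullptr; }
  const int* jlo_ptr() const { return active ? jlo.data() : nullptr; }
  const int* jhi_ptr() const { return active ? jhi.data() : nullptr; }
};

static void unpack_mask(const Nullable<LogicalMatrix>& mask, int Ls, int Lt,
                        MaskInfo& mi) {
  if (mask.isNull()) { mi.active = false; return; }
  LogicalMatrix mm(mask.get());
  if (mm.nrow() != Ls + 1 || mm.ncol() != Lt + 1)
    stop("mask must have dimensions (Ls+1) x (Lt+1)");
  mi.active = true;
  mi.cells.assign((size_t)(Ls + 1) * (Lt + 1), 0);
  mi.jlo.assign(Ls + 1, 1); mi.jhi.assign(Ls + 1, 0);
  const int* raw = LOGICAL(mm);  // column-major
  for (int i = 0; i <= Ls; ++i) {
    int lo = Lt + 1, hi = -1;
    for (int j = 0; j <= Lt; ++j) {
      if (raw[(size_t)j * (Ls + 1) + i]) {
        mi.cells[(size_t)i * (Lt + 1) + j] = 1;
        if (j < lo) lo = j;
        if (j > hi) hi = j;
      }
    }
    if (hi >= 0) { mi.jlo[i] = lo; mi.jhi[i] = hi; }
  }
}

static double dp_total(const DPWork& w, int Ls, int Lt) {
  double last = w.v[(size_t)Ls * (Lt + 1) + Lt];
  return last > 0.0 ? std::log(last) + w.c[Ls] : NEG_INF;
}

// build per-mu emission tables from the model parameterization
static void mu_tables(double mu, double beta_del, double beta_ins,
                      const NumericVector& pdel, const NumericVector& pins,
                      std::vector<double>& gdel, std::vector<double>& gins,
                      double& pm, double& pmm) {
  int Td = pdel.size(), Ti = pins.size();
  gdel.resize(Td); gins.resize(Ti);
  for (int l = 1; l <= Td; ++l) gdel[l - 1] = mu * beta_del * pdel[l - 1];
  double q = 0.25;
  double f = q;
  for (int l = 1; l <= Ti; ++l) {
    gins[l - 1] = mu * beta_ins * pins[l - 1] * f;
    f *= q;
  }
  double stay = 1.0 - mu * beta_del - mu * beta_ins;
  pm = stay * (1.0 - mu);
  pmm = stay * mu;
}

// [[Rcpp::export(name = ".cpp_forward_logmat")]]
NumericMatrix cpp_forward_logmat(IntegerVector s, IntegerVector t,
                                 NumericVector gdel, NumericVector gins,
                                 double pm, double pmm,
                                 Nullable<LogicalMatrix> mask = R_NilValue) {
  int Ls = s.size(), Lt = t.size();
  MaskInfo mi;
  unpack_mask(mask, Ls, Lt, mi);
  DPWork w;
  dp_fill(INTEGER(s), Ls, INTEGER(t), Lt, REAL(gdel), gdel.size(),
          REAL(gins), gins.size(), pm, pmm, mi.cells_ptr(), mi.jlo_ptr(),
          mi.jhi_ptr(), w);
  NumericMatrix out(Ls + 1, Lt + 1);
  for (int i = 0; i <= Ls; ++i)
    for (int j = 0; j <= Lt; ++j) {
      double val = w.v[(size_t)i * (Lt + 1) + j];
      out(i, j) = val > 0.0 ? std::log(val) + w.c[i] : NEG_INF;
    }
  return out;
}

// log-likelihood for a vector of mutation rates (shared mask)
// [[Rcpp::export(name = ".cpp_loglik_mu")]]
NumericVector cpp_loglik_mu(IntegerVector s, IntegerVector t, NumericVector mu,
                            double beta_del, double beta_ins,
                            NumericVector pdel, NumericVector pins,
                            Nullable<LogicalMatrix> mask = R_NilValue) {
  int Ls = s.size(), Lt = t.size();
  MaskInfo mi;
  unpack_mask(mask, Ls, Lt, mi);
  NumericVector out(mu.size());
  DPWork w;
  std::vector<double> gdel, gins;
  double pm, pmm;
  for (int k = 0; k < mu.size(); ++k) {
    mu_tables(mu[k], beta_del, beta_ins, pdel, pins, gdel, gins, pm, pmm);
    dp_fill(INTEGER(s), Ls, INTEGER(t), Lt, gdel.data(), gdel.size(),
            gins.data(), gins.size(), pm, pmm, mi.cells_ptr(), mi.jlo_ptr(),
            mi.jhi_ptr(), w);
    out[k] = dp_total(w, Ls, Lt);
  }
  return out;
}

// log-likelihood for a batch of packed phi vectors at fixed mu.
// each row of `phis` is c(beta_del, beta_ins, pdel[1..Td], pins[1..Ti]).
// [[Rcpp::export(name = ".cpp_loglik_phi_batch")]]
NumericVector cpp_loglik_phi_batch(IntegerVector s, IntegerVector t, double mu,
                                   NumericMatrix phis, int theta_del,
                                   Nullable<LogicalMatrix> mask = R_NilValue) {
  int Ls = s.size(), Lt = t.size();
  int Ti = phis.ncol() - 2 - theta_del;
  MaskInfo mi;
  unpack_mask(mask, Ls, Lt, mi);
  NumericVector out(phis.nrow());
  DPWork w;
  NumericVector pdel(theta_del), pins(Ti);
  std::vector<double> gdel, gins;
  double pm, pmm;
  for (int r = 0; r < phis.nrow(); ++r) {
    double bd = phis(r, 0), bi = phis(r, 1);
    for (int l = 0; l < theta_del; ++l) pdel[l] = phis(r, 2 + l);
    for (int l = 0; l < Ti; ++l) pins[l] = phis(r, 2 + theta_del + l);
    mu_tables(mu, bd, bi, pdel, pins, gdel, gins, pm, pmm);
    dp_fill(INTEGER(s), Ls, INTEGER(t), Lt, gdel.data(), gdel.size(),
            gins.data(), gins.size(), pm, pmm, mi.cells_ptr(), mi.jlo_ptr(),
            mi.jhi_ptr(), w);
    out[r] = dp_total(w, Ls, Lt);
  }
  return out;
}

// event lengths that the pruning mask leaves admissible anywhere
// [[Rcpp::export(name = ".cpp_admissible_lengths")]]
List cpp_admissible_lengths(LogicalMatrix mask, int theta_del, int theta_ins) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalVector del(theta_del), ins(theta_ins);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j)) continue;
      for (int l = 1; l <= theta_del && l <= j; ++l)
        if (mask(i, j - l)) del[l - 1] = true;
      for (int l = 1; l <= theta_ins && l <= i; ++l)
        if (mask(i - l, j)) ins[l - 1] = true;
    }
  return List::create(_["del"] = del, _["ins"] = ins);
}

// -------------------------------------------------------------------------
// Deterministic affine-gap global alignment (Needleman-Wunsch, three-state)
// with explicit backpointers. Deletions are gaps in the read (consume
// template bases); insertions are gaps in the template (consume read bases).
// Gap-open penalties include the first extension step.

// [[Rcpp::export(name = ".cpp_nw_align")]]
List cpp_nw_align(IntegerVector s, IntegerVector t, double match,
                  double mismatch, double del_open, double del_extend,
                  double ins_open, double ins_extend) {
  const int Ls = s.size(), Lt = t.size();
  const int ncol = Lt + 1;
  const double NEG = -1e30;
  // states: 0 = M (diagonal), 1 = D (gap in read), 2 = I (gap in template)
  std::vector<double> M((size_t)(Ls + 1) * ncol, NEG), D = M, I = M;
  std::vector<signed char> bM(M.size(), -1), bD(M.size(), -1), bI(M.size(), -1);

  M[0] = 0.0;
  for (int j = 1; j <= Lt; ++j) {
    D[j] = del_open + (j - 1) * del_extend;
    bD[j] = j == 1 ? 0 : 1;
  }
  for (int i = 1; i <= Ls; ++i) {
    I[(size_t)i * ncol] = ins_open + (i - 1) * ins_extend;
    bI[(size_t)i * ncol] = i == 1 ? 0 : 2;
  }

  for (int i = 1; i <= Ls; ++i) {
    for (int j = 1; j <= Lt; ++j) {
      size_t ij = (size_t)i * ncol + j;
      size_t dg = (size_t)(i - 1) * ncol + (j - 1);
      size_t lf = ij - 1;
      size_t up = (size_t)(i - 1) * ncol + j;
      double sub = (s[i - 1] == t[j - 1]) ? match : mismatch;
      // diagonal: prefer M > D > I on ties
      double best = M[dg]; signed char bp = 0;
      if (D[dg] > best) { best = D[dg]; bp = 1; }
      if (I[dg] > best) { best = I[dg]; bp = 2; }
      M[ij] = sub + best; bM[ij] = bp;
      // deletion: prefer continuing the gap on ties (leftmost placement)
      best = D[lf] + del_extend; bp = 1;
      if (M[lf] + del_open > best) { best = M[lf] + del_open; bp = 0; }
      if (I[lf] + del_open > best) { best = I[lf] + del_open; bp = 2; }
      D[ij] = best; bD[ij] = bp;
      // insertion
      best = I[up] + ins_extend; bp = 2;
      if (M[up] + ins_open > best) { best = M[up] + ins_open; bp = 0; }
      if (D[up] + ins_open > best) { best = D[up] + ins_open; bp = 1; }
      I[ij] = best; bI[ij] = bp;
    }
  }

  size_t end = (size_t)Ls * ncol + Lt;
  double score = M[end]; int state = 0;
  if (D[end] > score) { score = D[end]; state = 1; }
  if (I[end] > score) { score = I[end]; state = 2; }

  // traceback: collect columns (op, i, j) then merge runs into events
  std::vector<int> ops, ois, ojs;  // op: 0 match, 1 mismatch, 2 del, 3 ins
  int i = Ls, j = Lt;
  while (i > 0 || j > 0) {
    size_t ij = (size_t)i * ncol + j;
    if (state == 0) {
      ops.push_back(s[i - 1] == t[j - 1] ? 0 : 1);
      ois.push_back(i); ojs.push_back(j);
      state = bM[ij]; --i; --j;
    } else if (state == 1) {
      ops.push_back(2); ois.push_back(i); ojs.push_back(j);
      state = bD[ij]; --j;
    } else {
      ops.push_back(3); ois.push_back(i); ojs.push_back(j);
      state = bI[ij]; --i;
    }
  }

  // events in left-to-right order (traceback was right-to-left)
  std::vector<int> kind, tpos, rpos, len;
  int n = ops.size();
  for (int k = n - 1; k >= 0; --k) {
    int op = ops[k];
    if (op == 0) continue;
    if (op == 1) {
      kind.push_back(0); tpos.push_back(ojs[k] - 1);
      rpos.push_back(ois[k] - 1); len.push_back(1);
    } else if (op == 2) {
      int start = ojs[k] - 1, l = 1;
      while (k - 1 >= 0 && ops[k - 1] == 2) { --k; ++l; }
      kind.push_back(1); tpos.push_back(start);
      rpos.push_back(ois[k]); len.push_back(l);
    } else {
      int start = ois[k] - 1, l = 1;
      while (k - 1 >= 0 && ops[k - 1] == 3) { --k; ++l; }
      kind.push_back(2); tpos.push_back(ojs[k]);
      rpos.push_back(start); len.push_back(l);
    }
  }
  int n_aligned = 0;
  for (int k = 0; k < n; ++k) if (ops[k] <= 1) ++n_aligned;
  return List::create(_["score"] = score, _["kind"] = wrap(kind),
                      _["tpos"] = wrap(tpos), _["rpos"] = wrap(rpos),
                      _["len"] = wrap(len), _["n_aligned"] = n_aligned);
}
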