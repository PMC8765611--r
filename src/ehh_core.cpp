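// Core EHH machinery: identity-partition refinement outward from a focal
// marker, curve integration with cutoff / support / gap / boundary stopping,
// and the fused per-marker genome scan used by unihs_scan() / ies_scan().
//
// Conventions used throughout:
//   * allele matrix A is markers x sequences, integer codes >= 0, NA missing
//   * a sequence with missing data at marker t leaves every shared haplotype
//     at t (conservative mismatch) and never re-enters
//   * phased support = number of sequences inside a shared (size >= 2) class;
//     unphased support = 2 x number of individuals still homozygous over the
//     whole interval (so both are counted in sequences)

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// stop reasons for one integration side
enum StopReason { STOP_NONE = -1, STOP_CUTOFF = 0, STOP_SUPPORT = 1,
                  STOP_BOUNDARY = 2, STOP_GAP = 3 };

struct SideCurve {
  std::vector<double> pos;   // marker positions, focal first, outward order
  std::vector<double> val;   // EHH / EHHS values
  std::vector<int> supp;     // supporting count in sequences
  int gen_reason;            // why curve generation stopped
};

// ---------------------------------------------------------------------------
// phased partition refinement
//
// Reused scratch buffers: the scan calls this for every marker of a
// chromosome, so per-step allocations are avoided. R is single-threaded;
// function-level statics are safe here.

struct PhasedState {
  std::vector<int> seq;  // active sequence ids
  std::vector<int> cls;  // class id per entry of seq
  int ncls;
  double denom;          // n(n-1) fixed at the focal marker
};

// counting-based refinement by the alleles at marker t; missing -> drop.
// Computes the class-size statistics in the same pass.
static void phased_refine(PhasedState& st, const int* A, int M, int t,
                          int width, double& num, int& supp) {
  static std::vector<int> remap, sz;
  size_t m = st.seq.size();
  num = 0.0;
  supp = 0;
  if (m == 0) return;
  remap.assign((size_t)st.ncls * width, -1);
  sz.clear();
  int newn = 0;
  size_t w = 0;
  for (size_t i = 0; i < m; ++i) {
    int al = A[t + (size_t)M * st.seq[i]];
    if (al == NA_INTEGER || al >= width) continue;  // dead singleton
    int key = st.cls[i] * width + al;
    int id = remap[key];
    if (id < 0) {
      id = newn++;
      remap[key] = id;
      sz.push_back(0);
    }
    sz[id]++;
    st.seq[w] = st.seq[i];
    st.cls[w] = id;
    ++w;
  }
  st.seq.resize(w);
  st.cls.resize(w);
  st.ncls = newn;
  for (int k = 0; k < newn; ++k) {
    num += (double)sz[k] * (sz[k] - 1);
    if (sz[k] >= 2) supp += sz[k];
  }
}

// Build one side of a phased curve. `restrict_allele` < 0 means pooled EHHS.
// `amax` holds, per marker, the maximum allele code (for the counting
// refinement). Pass cutoff < 0, min_support <= 0 and max_gap = Inf for a
// full curve to the chromosome end.
static SideCurve phased_side(const IntegerMatrix& Am, const NumericVector& pos,
                             int s, int dir, int restrict_allele,
                             const std::vector<int>& amax,
                             double cutoff, int min_support, double max_gap) {
  int M = Am.nrow(), n = Am.ncol();
  const int* A = INTEGER(Am);
  PhasedState st;
  // active sequences and initial classes at the focal marker
  std::vector<int> al0;
  for (int i = 0; i < n; ++i) {
    int a = A[s + (size_t)M * i];
    if (a == NA_INTEGER) continue;
    if (restrict_allele >= 0 && a != restrict_allele) continue;
    st.seq.push_back(i);
    al0.push_back(a);
  }
  double num = 0.0;
  int supp = 0;
  if (restrict_allele >= 0) {
    st.cls.assign(st.seq.size(), 0);
    st.ncls = st.seq.empty() ? 0 : 1;
    num = (double)st.seq.size() * ((double)st.seq.size() - 1.0);
    supp = st.seq.size() >= 2 ? (int)st.seq.size() : 0;
  } else {
    // classes = allele groups at s
    std::vector<int> map(amax[s] + 1, -1), sz;
    st.cls.assign(st.seq.size(), 0);
    int newn = 0;
    for (size_t i = 0; i < st.seq.size(); ++i) {
      int id = map[al0[i]];
      if (id < 0) { id = newn++; map[al0[i]] = id; sz.push_back(0); }
      st.cls[i] = id;
      sz[id]++;
    }
    st.ncls = newn;
    for (int k = 0; k < newn; ++k) {
      num += (double)sz[k] * (sz[k] - 1);
      if (sz[k] >= 2) supp += sz[k];
    }
  }
  st.denom = (double)st.seq.size() * ((double)st.seq.size() - 1.0);

  SideCurve out;
  out.gen_reason = STOP_BOUNDARY;
  double v0 = st.denom > 0 ? num / st.denom : NA_REAL;
  out.pos.push_back(pos[s]);
  out.val.push_back(v0);
  out.supp.push_back(supp);
  if (st.denom <= 0) return out;
  if (cutoff >= 0 && v0 <= cutoff) { out.gen_reason = STOP_CUTOFF; return out; }

  for (int t = s + dir; t >= 0 && t < M; t += dir) {
    if (std::abs(pos[t] - out.pos.back()) > max_gap) {
      out.gen_reason = STOP_GAP;
      return out;
    }
    phased_refine(st, A, M, t, amax[t] + 1, num, supp);
    double v = num / st.denom;
    out.pos.push_back(pos[t]);
    out.val.push_back(v);
    out.supp.push_back(supp);
    if (cutoff >= 0 && v <= cutoff) { out.gen_reason = STOP_CUTOFF; return out; }
    if (min_support > 0 && supp < min_support) {
      out.gen_reason = STOP_SUPPORT;
      return out;
    }
  }
  return out;  // chromosome end
}

static std::vector<int> marker_amax(const IntegerMatrix& Am) {
  int M = Am.nrow(), n = Am.ncol();
  const int* A = INTEGER(Am);
  std::vector<int> amax(M, 0);
  for (int i = 0; i < n; ++i) {
    const int* col = A + (size_t)M * i;
    for (int t = 0; t < M; ++t) {
      int a = col[t];
      if (a != NA_INTEGER && a > amax[t]) amax[t] = a;
    }
  }
  return amax;
}

// ---------------------------------------------------------------------------
// unphased (homozygote-based) curves

// individuals: 0-based individual index per sequence
static SideCurve unphased_side(const IntegerMatrix& A, const NumericVector& pos,
                               int s, int dir, int restrict_allele,
                               const IntegerVector& ind, int n_ind,
                               double cutoff, int min_support, double max_gap) {
  int M = A.nrow(), n = A.ncol();
  // collect the two sequences of each individual
  std::vector<int> s1(n_ind, -1), s2(n_ind, -1);
  for (int i = 0; i < n; ++i) {
    int j = ind[i];
    if (s1[j] < 0) s1[j] = i; else s2[j] = i;
  }
  // alive = homozygous at focal (for the target allele, if restricted)
  std::vector<int> alive;
  for (int j = 0; j < n_ind; ++j) {
    if (s1[j] < 0 || s2[j] < 0) continue;
    int a1 = A(s, s1[j]), a2 = A(s, s2[j]);
    if (a1 == NA_INTEGER || a2 == NA_INTEGER || a1 != a2) continue;
    if (restrict_allele >= 0 && a1 != restrict_allele) continue;
    alive.push_back(j);
  }
  int I_ss = (int)alive.size();

  SideCurve out;
  out.gen_reason = STOP_BOUNDARY;
  out.pos.push_back(pos[s]);
  out.val.push_back(I_ss > 0 ? 1.0 : NA_REAL);
  out.supp.push_back(2 * I_ss);
  if (I_ss == 0) return out;
  if (cutoff >= 0 && 1.0 <= cutoff) { out.gen_reason = STOP_CUTOFF; return out; }

  for (int t = s + dir; t >= 0 && t < M; t += dir) {
    if (std::abs(pos[t] - out.pos.back()) > max_gap) {
      out.gen_reason = STOP_GAP;
      return out;
    }
    std::vector<int> keep;
    keep.reserve(alive.size());
    for (size_t r = 0; r < alive.size(); ++r) {
      int j = alive[r];
      int a1 = A(t, s1[j]), a2 = A(t, s2[j]);
      if (a1 == NA_INTEGER || a2 == NA_INTEGER || a1 != a2) continue;
      keep.push_back(j);
    }
    alive.swap(keep);
    double v = (double)alive.size() / I_ss;
    out.pos.push_back(pos[t]);
    out.val.push_back(v);
    out.supp.push_back(2 * (int)alive.size());
    if (cutoff >= 0 && v <= cutoff) { out.gen_reason = STOP_CUTOFF; return out; }
    if (min_support > 0 && 2 * (int)alive.size() < min_support) {
      out.gen_reason = STOP_SUPPORT;
      return out;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// integration of one side

struct SideIntegral {
  double area;
  int reason;
  double stop_pos;
};

// pos/val/supp ordered outward from the focal marker (focal first).
// `extent` is the chromosome end in this direction.
static SideIntegral integrate_side(const std::vector<double>& pos,
                                   const std::vector<double>& val,
                                   const std::vector<int>& supp,
                                   double cutoff, int min_support, bool linear,
                                   double max_gap, double extent) {
  SideIntegral r;
  r.area = 0.0;
  size_t m = pos.size();
  if (m == 0) { r.reason = STOP_BOUNDARY; r.stop_pos = NA_REAL; return r; }
  if (val[0] <= cutoff) { r.reason = STOP_CUTOFF; r.stop_pos = pos[0]; return r; }
  for (size_t i = 0; i + 1 < m; ++i) {
    double d = std::abs(pos[i + 1] - pos[i]);
    if (d > max_gap) { r.reason = STOP_GAP; r.stop_pos = pos[i]; return r; }
    double vi = val[i], vj = val[i + 1];
    double dir = (pos[i + 1] >= pos[i]) ? 1.0 : -1.0;
    if (vj <= cutoff) {
      if (linear) {
        double xc = (vi <= vj) ? 0.0 : d * (vi - cutoff) / (vi - vj);
        r.area += 0.5 * (vi + cutoff) * xc;
        r.stop_pos = pos[i] + dir * xc;
      } else {
        r.area += vi * d;
        r.stop_pos = pos[i + 1];
      }
      r.reason = STOP_CUTOFF;
      return r;
    }
    r.area += linear ? 0.5 * (vi + vj) * d : vi * d;
    if (min_support > 0 && supp[i + 1] < min_support) {
      r.reason = STOP_SUPPORT;
      r.stop_pos = pos[i + 1];
      return r;
    }
  }
  // chromosome boundary: hold the last value out to the extent
  double dlast = std::abs(extent - pos[m - 1]);
  r.area += val[m - 1] * dlast;
  r.reason = STOP_BOUNDARY;
  r.stop_pos = extent;
  return r;
}

// ---------------------------------------------------------------------------
// exported: one full curve (both sides)

// [[Rcpp::export]]
List cpp_ehh_curve(IntegerMatrix A, NumericVector pos, int s, int allele,
                   bool unphased, IntegerVector ind, int n_ind,
                   double cutoff, int min_support, double max_gap) {
  SideCurve L, R;
  if (unphased) {
    L = unphased_side(A, pos, s, -1, allele, ind, n_ind, cutoff, min_support, max_gap);
    R = unphased_side(A, pos, s, +1, allele, ind, n_ind, cutoff, min_support, max_gap);
  } else {
    std::vector<int> amax = marker_amax(A);
    L = phased_side(A, pos, s, -1, allele, amax, cutoff, min_support, max_gap);
    R = phased_side(A, pos, s, +1, allele, amax, cutoff, min_support, max_gap);
  }
  return List::create(
      _["left_pos"] = wrap(L.pos), _["left_val"] = wrap(L.val),
      _["left_supp"] = wrap(L.supp), _["left_reason"] = L.gen_reason,
      _["right_pos"] = wrap(R.pos), _["right_val"] = wrap(R.val),
      _["right_supp"] = wrap(R.supp), _["right_reason"] = R.gen_reason,
      _["value_at_s"] = L.val.empty() ? NA_REAL : L.val[0],
      _["focal_support"] = L.supp.empty() ? 0 : L.supp[0]);
}

// [[Rcpp::export]]
List cpp_integrate_side(NumericVector pos, NumericVector val, IntegerVector supp,
                        double cutoff, int min_support, bool linear,
                        double max_gap, double extent) {
  std::vector<double> p(pos.begin(), pos.end());
  std::vector<double> v(val.begin(), val.end());
  std::vector<int> sp(supp.begin(), supp.end());
  SideIntegral r = integrate_side(p, v, sp, cutoff, min_support, linear, max_gap, extent);
  return List::create(_["area"] = r.area, _["reason"] = r.reason,
                      _["stop_pos"] = r.stop_pos);
}

// ---------------------------------------------------------------------------
// fused genome scan

// flag bits
static const int FLAG_BELOW_MAF = 1;
static const int FLAG_INSUFFICIENT = 2;
static const int FLAG_MULTIALLELIC = 4;
static const int FLAG_UNDEFINED = 8;
static const int FLAG_TRUNCATED = 16;

static bool side_truncated(int reason) {
  return reason == STOP_BOUNDARY || reason == STOP_GAP;
}

// integrate both sides of the curve for (s, allele)
static double integrate_marker(const IntegerMatrix& A, const NumericVector& pos,
                               int s, int allele, bool unphased,
                               const IntegerVector& ind, int n_ind,
                               const std::vector<int>& amax,
                               double cutoff, int min_support, bool linear,
                               double max_gap, double ext_lo, double ext_hi,
                               bool& truncated, double& value_at_s) {
  SideCurve L, R;
  if (unphased) {
    L = unphased_side(A, pos, s, -1, allele, ind, n_ind, cutoff, min_support, max_gap);
    R = unphased_side(A, pos, s, +1, allele, ind, n_ind, cutoff, min_support, max_gap);
  } else {
    L = phased_side(A, pos, s, -1, allele, amax, cutoff, min_support, max_gap);
    R = phased_side(A, pos, s, +1, allele, amax, cutoff, min_support, max_gap);
  }
  value_at_s = L.val.empty() ? NA_REAL : L.val[0];
  // when curve generation already stopped at a gap, do not extend the last
  // value towards the chromosome end
  double elo = (L.gen_reason == STOP_GAP) ? L.pos.back() : ext_lo;
  double ehi = (R.gen_reason == STOP_GAP) ? R.pos.back() : ext_hi;
  SideIntegral il = integrate_side(L.pos, L.val, L.supp, cutoff, min_support,
                                   linear, max_gap, elo);
  SideIntegral ir = integrate_side(R.pos, R.val, R.supp, cutoff, min_support,
                                   linear, max_gap, ehi);
  if (L.gen_reason == STOP_GAP && il.reason == STOP_BOUNDARY) il.reason = STOP_GAP;
  if (R.gen_reason == STOP_GAP && ir.reason == STOP_BOUNDARY) ir.reason = STOP_GAP;
  truncated = side_truncated(il.reason) || side_truncated(ir.reason);
  return il.area + ir.area;
}

// Per-marker scan.  stat = 0: per-allele iHH of the two most frequent alleles
// (for uniHS); stat = 1: EHHS integrals iES and inES.
// [[Rcpp::export]]
List cpp_scan(IntegerMatrix A, NumericVector pos, IntegerVector ind, int n_ind,
              bool unphased, int stat, double cutoff, int min_support,
              int min_focal_seqs, double maf_min, bool linear, double max_gap,
              double ext_lo, double ext_hi) {
  int M = A.nrow(), n = A.ncol();

  IntegerVector n_s(M), flag(M);
  IntegerVector code1(M, NA_INTEGER), code2(M, NA_INTEGER);
  IntegerVector cnt1(M, NA_INTEGER), cnt2(M, NA_INTEGER);
  IntegerVector hom1(M, NA_INTEGER), hom2(M, NA_INTEGER);
  NumericVector ihh1(M, NA_REAL), ihh2(M, NA_REAL);
  NumericVector ies(M, NA_REAL), ines(M, NA_REAL), ehhs_s(M, NA_REAL);
  NumericVector maf(M, NA_REAL);

  // individual sequence lookup for homozygote counts
  std::vector<int> s1(n_ind, -1), s2(n_ind, -1);
  for (int i = 0; i < n; ++i) {
    int j = ind[i];
    if (s1[j] < 0) s1[j] = i; else s2[j] = i;
  }

  std::vector<int> amax = marker_amax(A);

  std::vector<int> cnt;  // allele counts scratch
  for (int s = 0; s < M; ++s) {
    // allele counts
    cnt.assign(1, 0);
    int ns = 0;
    for (int i = 0; i < n; ++i) {
      int a = A(s, i);
      if (a == NA_INTEGER) continue;
      if (a >= (int)cnt.size()) cnt.resize(a + 1, 0);
      cnt[a]++;
      ns++;
    }
    n_s[s] = ns;
    int k = 0;
    for (size_t a = 0; a < cnt.size(); ++a) if (cnt[a] > 0) k++;
    // two most frequent alleles, ties broken by lower code
    int a1 = -1, a2 = -1;
    for (size_t a = 0; a < cnt.size(); ++a) {
      if (cnt[a] == 0) continue;
      if (a1 < 0 || cnt[a] > cnt[a1]) { a2 = a1; a1 = (int)a; }
      else if (a2 < 0 || cnt[a] > cnt[a2]) { a2 = (int)a; }
    }
    if (k >= 1) { code1[s] = a1; cnt1[s] = cnt[a1]; }
    if (k >= 2) { code2[s] = a2; cnt2[s] = cnt[a2]; maf[s] = (double)cnt[a2] / ns; }

    if (stat == 0) {
      // ------- per-allele iHH for uniHS -------
      if (k < 2) { flag[s] |= FLAG_UNDEFINED; continue; }
      if (k > 2) { flag[s] |= FLAG_MULTIALLELIC; continue; }
      if (maf[s] < maf_min) { flag[s] |= FLAG_BELOW_MAF; continue; }
      if (unphased) {
        int h1 = 0, h2 = 0;
        for (int j = 0; j < n_ind; ++j) {
          if (s1[j] < 0 || s2[j] < 0) continue;
          int b1 = A(s, s1[j]), b2 = A(s, s2[j]);
          if (b1 == NA_INTEGER || b1 != b2) continue;
          if (b1 == a1) h1++; else if (b1 == a2) h2++;
        }
        hom1[s] = h1; hom2[s] = h2;
        if (2 * h1 < min_focal_seqs || 2 * h2 < min_focal_seqs) {
          flag[s] |= FLAG_INSUFFICIENT;
          continue;
        }
      } else {
        if (cnt[a1] < 2 || cnt[a2] < 2) { flag[s] |= FLAG_INSUFFICIENT; continue; }
      }
      bool tr1 = false, tr2 = false;
      double v_at_s;
      ihh1[s] = integrate_marker(A, pos, s, a1, unphased, ind, n_ind, amax,
                                 cutoff, min_support, linear, max_gap, ext_lo,
                                 ext_hi, tr1, v_at_s);
      ihh2[s] = integrate_marker(A, pos, s, a2, unphased, ind, n_ind, amax,
                                 cutoff, min_support, linear, max_gap, ext_lo,
                                 ext_hi, tr2, v_at_s);
      if (tr1 || tr2) flag[s] |= FLAG_TRUNCATED;
      if (!(ihh1[s] > 0.0) || !(ihh2[s] > 0.0)) flag[s] |= FLAG_UNDEFINED;
    } else {
      // ------- EHHS integrals -------
      if (unphased) {
        int hs = 0;
        for (int j = 0; j < n_ind; ++j) {
          if (s1[j] < 0 || s2[j] < 0) continue;
          int b1 = A(s, s1[j]), b2 = A(s, s2[j]);
          if (b1 == NA_INTEGER || b2 == NA_INTEGER || b1 != b2) continue;
          hs++;
        }
        hom1[s] = hs;
        if (2 * hs < min_focal_seqs) { flag[s] |= FLAG_INSUFFICIENT; continue; }
      } else {
        if (ns < 2) { flag[s] |= FLAG_INSUFFICIENT; continue; }
      }
      bool tr = false;
      double v_at_s;
      double a = integrate_marker(A, pos, s, -1, unphased, ind, n_ind, amax,
                                  cutoff, min_support, linear, max_gap, ext_lo,
                                  ext_hi, tr, v_at_s);
      ies[s] = a;
      ehhs_s[s] = v_at_s;
      if (tr) flag[s] |= FLAG_TRUNCATED;
      if (v_at_s > 0.0) {
        ines[s] = a / v_at_s;
      } else {
        flag[s] |= FLAG_UNDEFINED;
      }
      if (!(ies[s] > 0.0)) flag[s] |= FLAG_UNDEFINED;
    }
  }

  return List::create(
      _["n_s"] = n_s, _["maf"] = maf, _["flag"] = flag,
      _["code1"] = code1, _["code2"] = code2,
      _["cnt1"] = cnt1, _["cnt2"] = cnt2,
      _["hom1"] = hom1, _["hom2"] = hom2,
      _["ihh1"] = ihh1, _["ihh2"] = ihh2,
      _["ies"] = ies, _["ines"] = ines, _["ehhs_s"] = ehhs_s);
}
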