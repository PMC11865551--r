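// Determinant-space FCI kernels: occupation strings, spin-summed excitation
// tables, a direct sigma build (compressed orbital-pair dgemm), transition
// 1-/2-RDMs between CI vectors, diagonal preconditioner and <S^2>.
//
// Conventions:
//  * strings are orbital-occupation bitmasks (bit k = orbital k occupied),
//    listed in ascending numeric order; a determinant index is
//    I = Ialpha * Nbeta + Ibeta (beta fastest).
//  * a string |s> = c_k1^+ c_k2^+ ... |0> with k1 < k2 < ...; E_pq = c_p^+ c_q
//    (per spin, spin-summed where noted); signs follow from that ordering.
//  * two-electron integrals enter in chemists' notation (pq|rs) as an
//    L^2 x L^2 matrix with pair index p + L*q.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static int popcount_below(unsigned s, int p) {
  unsigned mask = (p == 0) ? 0u : ((1u << p) - 1u);
  return __builtin_popcount(s & mask);
}

// [[Rcpp::export]]
IntegerVector cpp_fci_strings(int norb, int nel) {
  if (nel < 0 || nel > norb) stop("invalid electron count");
  std::vector<int> out;
  for (unsigned s = 0; s < (1u << norb); ++s)
    if (__builtin_popcount(s) == nel) out.push_back((int)s);
  std::sort(out.begin(), out.end());
  return wrap(out);
}

// Excitation table grouped by orbital pair u = p + norb*q for E_pq = c_p^+ c_q:
// CSR offsets (norb^2+1) into parallel arrays (src string index, dst string
// index, sign). Includes the diagonal p == q (occupation) entries.
// [[Rcpp::export]]
List cpp_exc_table(IntegerVector strings, int norb) {
  int ns = strings.size();
  std::vector<int> rank(1 << norb, -1);
  for (int i = 0; i < ns; ++i) rank[strings[i]] = i;
  int ngrp = norb * norb;
  std::vector<std::vector<int>> gsrc(ngrp), gdst(ngrp), gsgn(ngrp);
  for (int I = 0; I < ns; ++I) {
    unsigned s = (unsigned)strings[I];
    for (int q = 0; q < norb; ++q) {
      if (!(s & (1u << q))) continue;
      for (int p = 0; p < norb; ++p) {
        int u = p + norb * q;
        if (p == q) {
          gsrc[u].push_back(I); gdst[u].push_back(I); gsgn[u].push_back(1);
        } else if (!(s & (1u << p))) {
          unsigned t = (s ^ (1u << q)) | (1u << p);
          int sgn_q = popcount_below(s, q) & 1;
          int sgn_p = popcount_below(s ^ (1u << q), p) & 1;
          int sgn = ((sgn_q + sgn_p) & 1) ? -1 : 1;
          gsrc[u].push_back(I); gdst[u].push_back(rank[t]);
          gsgn[u].push_back(sgn);
        }
      }
    }
  }
  int tot = 0;
  IntegerVector off(ngrp + 1);
  for (int u = 0; u < ngrp; ++u) { off[u] = tot; tot += gsrc[u].size(); }
  off[ngrp] = tot;
  IntegerVector src(tot), dst(tot), sgn(tot);
  int w = 0;
  for (int u = 0; u < ngrp; ++u)
    for (size_t k = 0; k < gsrc[u].size(); ++k, ++w) {
      src[w] = gsrc[u][k]; dst[w] = gdst[u][k]; sgn[w] = gsgn[u][k];
    }
  return List::create(_["offsets"] = off, _["src"] = src, _["dst"] = dst,
                      _["sign"] = sgn);
}

struct Tbl {
  const int *off, *src, *dst, *sgn;
};
static Tbl get_tbl(const List& t) {
  return Tbl{INTEGER(((SEXP)t["offsets"])), INTEGER(((SEXP)t["src"])),
             INTEGER(((SEXP)t["dst"])), INTEGER(((SEXP)t["sign"]))};
}

// Persistent workspace: first-touch page faults are far more expensive than
// streaming writes on typical containerized hosts, so the large scratch
// tensors are faulted once and reused across sigma/RDM calls.
#include <map>
#include <string>
struct WsBuf { std::vector<double> v; };
static std::map<std::string, WsBuf> g_fci_ws;
static double* ws_get(const std::string& name, size_t n) {
  WsBuf& b = g_fci_ws[name];
  if (b.v.size() < n) b.v.resize(n);
  return b.v.data();
}

// Release the cached FCI workspace buffers.
// [[Rcpp::export]]
void cpp_fci_release_workspace() { g_fci_ws.clear(); }

// Layouts: "normal" vectors index determinants as Ib + Nb*Ia (beta fastest);
// "transposed" vectors as Ia + Na*Ib. Alpha excitations are contiguous
// column operations in the normal layout, beta excitations in the
// transposed one; blocked transposes glue the two together so every string
// operation streams contiguous memory.

static void transpose_add(const double* src, double* dst, int Na, int Nb) {
  // dst (normal) += src (transposed)
  const int B = 64;
  for (int ib0 = 0; ib0 < Nb; ib0 += B) {
    int ib1 = std::min(ib0 + B, Nb);
    for (int ia0 = 0; ia0 < Na; ia0 += B) {
      int ia1 = std::min(ia0 + B, Na);
      for (int ib = ib0; ib < ib1; ++ib)
        for (int ia = ia0; ia < ia1; ++ia)
          dst[(size_t)ia * Nb + ib] += src[(size_t)ib * Na + ia];
    }
  }
}

static void transpose_copy_nt(const double* src, double* dst, int Na, int Nb) {
  // dst (transposed) = src (normal)
  const int B = 64;
  for (int ia0 = 0; ia0 < Na; ia0 += B) {
    int ia1 = std::min(ia0 + B, Na);
    for (int ib0 = 0; ib0 < Nb; ib0 += B) {
      int ib1 = std::min(ib0 + B, Nb);
      for (int ia = ia0; ia < ia1; ++ia)
        for (int ib = ib0; ib < ib1; ++ib)
          dst[(size_t)ib * Na + ia] = src[(size_t)ia * Nb + ib];
    }
  }
}

// Alpha part of E_pq (group u) applied to normal-layout x, into normal y.
static void apply_alpha(const Tbl& ta, int u, int Nb, const double* x,
                        double* y) {
  for (int e = ta.off[u]; e < ta.off[u + 1]; ++e) {
    const double* xs = x + (size_t)ta.src[e] * Nb;
    double* yd = y + (size_t)ta.dst[e] * Nb;
    double s = ta.sgn[e];
    for (int k = 0; k < Nb; ++k) yd[k] += s * xs[k];
  }
}

// Beta part of E_pq applied to transposed-layout xt, into transposed yt.
static void apply_beta_t(const Tbl& tb, int u, int Na, const double* xt,
                         double* yt) {
  for (int e = tb.off[u]; e < tb.off[u + 1]; ++e) {
    const double* xs = xt + (size_t)tb.src[e] * Na;
    double* yd = yt + (size_t)tb.dst[e] * Na;
    double s = tb.sgn[e];
    for (int k = 0; k < Na; ++k) yd[k] += s * xs[k];
  }
}

// Full spin-summed E_pq applied to normal-layout x, accumulated into normal
// y, given the transposed copy xt and a transposed scratch buffer.
static void apply_group(const Tbl& ta, const Tbl& tb, int u, int Na, int Nb,
                        const double* x, const double* xt, double* y,
                        double* scratch_t) {
  apply_alpha(ta, u, Nb, x, y);
  if (tb.off[u + 1] > tb.off[u]) {
    std::fill(scratch_t, scratch_t + (size_t)Na * Nb, 0.0);
    apply_beta_t(tb, u, Na, xt, scratch_t);
    transpose_add(scratch_t, y, Na, Nb);
  }
}

// sigma = H c with H = sum_pq hbar_pq E_pq + 1/2 sum (pq|rs) E_pq E_rs,
// hbar_pq = h_pq - 1/2 sum_r (pr|rq). Compressed over pq <-> qp symmetry.
// [[Rcpp::export]]
arma::vec cpp_fci_sigma(arma::vec cvec, int Na, int Nb, List tblA, List tblB,
                        arma::mat h1, arma::mat g2, int norb) {
  Tbl ta = get_tbl(tblA), tb = get_tbl(tblB);
  size_t Nd = (size_t)Na * Nb;
  int npair = norb * (norb + 1) / 2;
  // compressed pair list: u < npair maps to (p >= q)
  std::vector<int> pr(npair), qr(npair);
  {
    int w = 0;
    for (int p = 0; p < norb; ++p)
      for (int q = 0; q <= p; ++q, ++w) { pr[w] = p; qr[w] = q; }
  }
  arma::mat hbar(norb, norb);
  for (int p = 0; p < norb; ++p)
    for (int q = 0; q < norb; ++q) {
      double v = h1(p, q);
      for (int r = 0; r < norb; ++r) v -= 0.5 * g2(p + norb * r, r + norb * q);
      hbar(p, q) = v;
    }
  // compressed integrals and one-body vector
  arma::mat G(npair, npair);
  arma::vec hv(npair);
  for (int w = 0; w < npair; ++w) {
    hv[w] = hbar(pr[w], qr[w]);
    for (int v = 0; v < npair; ++v)
      G(w, v) = 0.5 * g2(pr[w] + norb * qr[w], pr[v] + norb * qr[v]);
  }
  // persistent buffers (views, no ownership)
  arma::mat t(ws_get("big", Nd * npair), Nd, npair, false, true);
  arma::vec ct(ws_get("ct", Nd), Nd, false, true);
  arma::vec scratch(ws_get("scratch", Nd), Nd, false, true);
  arma::vec sigmat(ws_get("sigmat", Nd), Nd, false, true);
  const int blk = 48;
  arma::mat F(ws_get("F", Nd * blk), Nd, blk, false, true);
  // gather t~(.,u) = (E_pq + E_qp) c   (single term when p == q)
  transpose_copy_nt(cvec.memptr(), ct.memptr(), Na, Nb);
  for (int w = 0; w < npair; ++w) {
    int u1 = pr[w] + norb * qr[w], u2 = qr[w] + norb * pr[w];
    double* col = t.colptr(w);
    std::fill(col, col + Nd, 0.0);
    apply_alpha(ta, u1, Nb, cvec.memptr(), col);
    if (u1 != u2) apply_alpha(ta, u2, Nb, cvec.memptr(), col);
    scratch.zeros();
    apply_beta_t(tb, u1, Na, ct.memptr(), scratch.memptr());
    if (u1 != u2) apply_beta_t(tb, u2, Na, ct.memptr(), scratch.memptr());
    transpose_add(scratch.memptr(), col, Na, Nb);
  }
  arma::vec sigma(Nd, arma::fill::zeros);
  // one-body part
  sigma += t * hv;
  // two-body: F = t G (blockwise), then scatter sigma += (E_pq + E_qp) F_u
  sigmat.zeros();
  for (int w0 = 0; w0 < npair; w0 += blk) {
    int w1 = std::min(w0 + blk, npair);
    F.cols(0, w1 - w0 - 1) = t * G.cols(w0, w1 - 1);
    for (int w = w0; w < w1; ++w) {
      int u1 = pr[w] + norb * qr[w], u2 = qr[w] + norb * pr[w];
      apply_alpha(ta, u1, Nb, F.colptr(w - w0), sigma.memptr());
      if (u1 != u2) apply_alpha(ta, u2, Nb, F.colptr(w - w0), sigma.memptr());
      transpose_copy_nt(F.colptr(w - w0), scratch.memptr(), Na, Nb);
      apply_beta_t(tb, u1, Na, scratch.memptr(), sigmat.memptr());
      if (u1 != u2) apply_beta_t(tb, u2, Na, scratch.memptr(), sigmat.memptr());
    }
  }
  transpose_add(sigmat.memptr(), sigma.memptr(), Na, Nb);
  return sigma;
}

// Spin-symmetric sigma for Ms = 0 singlet states (Na == Nb, C = C^T in the
// alpha/beta string indices). Only alpha excitations are applied; the beta
// half follows from the determinant-transpose symmetry, halving the string
// work. The input is projected onto the symmetric subspace.
// [[Rcpp::export]]
arma::vec cpp_fci_sigma_sym(arma::vec cvec, int N, List tblA, arma::mat h1,
                            arma::mat g2, int norb) {
  Tbl ta = get_tbl(tblA);
  size_t Nd = (size_t)N * N;
  int npair = norb * (norb + 1) / 2;
  std::vector<int> pr(npair), qr(npair);
  {
    int w = 0;
    for (int p = 0; p < norb; ++p)
      for (int q = 0; q <= p; ++q, ++w) { pr[w] = p; qr[w] = q; }
  }
  arma::mat hbar(norb, norb);
  for (int p = 0; p < norb; ++p)
    for (int q = 0; q < norb; ++q) {
      double v = h1(p, q);
      for (int r = 0; r < norb; ++r) v -= 0.5 * g2(p + norb * r, r + norb * q);
      hbar(p, q) = v;
    }
  arma::mat G(npair, npair);
  arma::vec hv(npair);
  for (int w = 0; w < npair; ++w) {
    hv[w] = hbar(pr[w], qr[w]);
    for (int v = 0; v < npair; ++v)
      G(w, v) = 0.5 * g2(pr[w] + norb * qr[w], pr[v] + norb * qr[v]);
  }
  arma::mat A(ws_get("big", Nd * npair), Nd, npair, false, true);
  arma::vec x(ws_get("ct", Nd), Nd, false, true);
  arma::vec S(ws_get("scratch", Nd), Nd, false, true);
  const int blk = 48;
  arma::mat B(ws_get("F", Nd * blk), Nd, blk, false, true);
  // project input on the symmetric subspace: x = (c + P c)/2
  transpose_copy_nt(cvec.memptr(), x.memptr(), N, N);
  x += cvec;
  x *= 0.5;
  // alpha-only gather A_u = (E^a_pq + E^a_qp) x
  arma::vec X(Nd, arma::fill::zeros);
  for (int w = 0; w < npair; ++w) {
    int u1 = pr[w] + norb * qr[w], u2 = qr[w] + norb * pr[w];
    double* col = A.colptr(w);
    std::fill(col, col + Nd, 0.0);
    apply_alpha(ta, u1, N, x.memptr(), col);
    if (u1 != u2) apply_alpha(ta, u2, N, x.memptr(), col);
  }
  // one-body half
  X += A * hv;
  // two-body half: B = A G; S_u = B_u + P B_u; X += (E^a_u1 + E^a_u2) S_u
  for (int w0 = 0; w0 < npair; w0 += blk) {
    int w1 = std::min(w0 + blk, npair);
    B.cols(0, w1 - w0 - 1) = A * G.cols(w0, w1 - 1);
    for (int w = w0; w < w1; ++w) {
      int u1 = pr[w] + norb * qr[w], u2 = qr[w] + norb * pr[w];
      transpose_copy_nt(B.colptr(w - w0), S.memptr(), N, N);
      S += arma::vec(B.colptr(w - w0), Nd, false, true);
      apply_alpha(ta, u1, N, S.memptr(), X.memptr());
      if (u1 != u2) apply_alpha(ta, u2, N, S.memptr(), X.memptr());
    }
  }
  // sigma = X + P X
  arma::vec sigma(Nd);
  transpose_copy_nt(X.memptr(), sigma.memptr(), N, N);
  sigma += X;
  return sigma;
}

// Diagonal <I|H|I> for the Davidson preconditioner (and guess selection).
// [[Rcpp::export]]
arma::vec cpp_fci_hdiag(IntegerVector stringsA, IntegerVector stringsB,
                        arma::mat h1, arma::mat g2, int norb) {
  int Na = stringsA.size(), Nb = stringsB.size();
  auto occ_of = [norb](unsigned s) {
    std::vector<int> o;
    for (int k = 0; k < norb; ++k)
      if (s & (1u << k)) o.push_back(k);
    return o;
  };
  auto Jel = [&](int p, int q) { return g2(p + norb * p, q + norb * q); };
  auto Kel = [&](int p, int q) { return g2(p + norb * q, q + norb * p); };
  // per-string one-body + same-spin two-body energies, and occupation matrix
  auto str_terms = [&](IntegerVector strs, arma::vec& e, arma::mat& occ) {
    int N = strs.size();
    e.zeros(N);
    occ.zeros(N, norb);
    for (int i = 0; i < N; ++i) {
      std::vector<int> o = occ_of((unsigned)strs[i]);
      double v = 0;
      for (size_t x = 0; x < o.size(); ++x) {
        v += h1(o[x], o[x]);
        occ(i, o[x]) = 1.0;
        for (size_t y = 0; y < x; ++y) v += Jel(o[x], o[y]) - Kel(o[x], o[y]);
      }
      e[i] = v;
    }
  };
  arma::vec ea, eb;
  arma::mat occa, occb;
  str_terms(stringsA, ea, occa);
  str_terms(stringsB, eb, occb);
  arma::mat Jm(norb, norb);
  for (int p = 0; p < norb; ++p)
    for (int q = 0; q < norb; ++q) Jm(p, q) = Jel(p, q);
  arma::mat cross = occa * Jm * occb.t();  // Na x Nb
  arma::vec out((size_t)Na * Nb);
  for (int Ia = 0; Ia < Na; ++Ia)
    for (int Ib = 0; Ib < Nb; ++Ib)
      out[(size_t)Ia * Nb + Ib] = ea[Ia] + eb[Ib] + cross(Ia, Ib);
  return out;
}


// x (normal layout over an N x N determinant grid) += P x, done in place.
static void symmetrize_inplace(double* x, int N) {
  const int B = 64;
  for (int i0 = 0; i0 < N; i0 += B) {
    int i1 = std::min(i0 + B, N);
    for (int j0 = 0; j0 <= i0; j0 += B) {
      int j1 = std::min(j0 + B, N);
      if (i0 == j0) {
        for (int i = i0; i < i1; ++i) {
          x[(size_t)i * N + i] *= 2.0;
          for (int j = j0; j < i; ++j) {
            double s = x[(size_t)i * N + j] + x[(size_t)j * N + i];
            x[(size_t)i * N + j] = s;
            x[(size_t)j * N + i] = s;
          }
        }
      } else {
        for (int i = i0; i < i1; ++i) {
          for (int j = j0; j < j1; ++j) {
            double s = x[(size_t)i * N + j] + x[(size_t)j * N + i];
            x[(size_t)i * N + j] = s;
            x[(size_t)j * N + i] = s;
          }
        }
      }
    }
  }
}

static bool is_det_symmetric(const double* x, int N) {
  // sample-based check that x equals its determinant transpose
  double nrm = 0, diff = 0;
  for (int i = 0; i < N; i += 3) {
    for (int j = 0; j < N; j += 7) {
      double a = x[(size_t)i * N + j], b = x[(size_t)j * N + i];
      nrm += a * a + b * b;
      diff += (a - b) * (a - b);
    }
  }
  return diff < 1e-16 * (nrm + 1e-300);
}

// Transition RDMs between two CI vectors in the same determinant space.
// gamma1[i,j] = <a| E_ij |b> (spin-summed); gamma2[i,j,k,l] =
// <a| sum_{st} c_is^+ c_jt^+ c_lt c_ks |b> = <a|E_ik E_jl|b> - d_jk gamma1[i,l].
// [[Rcpp::export]]
List cpp_trans_rdm(arma::vec avec, arma::vec bvec, List tblA, List tblB,
                   int Na, int Nb, int norb) {
  Tbl ta = get_tbl(tblA), tb = get_tbl(tblB);
  size_t Nd = (size_t)Na * Nb;
  int L2 = norb * norb;
  arma::vec at(ws_get("ct", Nd), Nd, false, true);
  arma::vec bt(ws_get("sigmat", Nd), Nd, false, true);
  arma::vec scratch(ws_get("scratch", Nd), Nd, false, true);
  transpose_copy_nt(avec.memptr(), at.memptr(), Na, Nb);
  transpose_copy_nt(bvec.memptr(), bt.memptr(), Na, Nb);
  // Ms = 0 singlet fast path: for determinant-transpose-symmetric vectors
  // the beta half of every E application is P (alpha half), so only alpha
  // excitations are applied and each column is symmetrized in place.
  bool sym = (Na == Nb) && is_det_symmetric(avec.memptr(), Na) &&
             is_det_symmetric(bvec.memptr(), Na);
  arma::mat A(ws_get("big", Nd * L2), Nd, L2, false, true);  // A.col(u) = E_pq |a>
  for (int u = 0; u < L2; ++u) {
    double* col = A.colptr(u);
    std::fill(col, col + Nd, 0.0);
    if (sym) {
      apply_alpha(ta, u, Nb, avec.memptr(), col);
      symmetrize_inplace(col, Na);
    } else {
      apply_group(ta, tb, u, Na, Nb, avec.memptr(), at.memptr(), col,
                  scratch.memptr());
    }
  }
  arma::mat M(L2, L2);          // M(u(k,i), u(j,l)) = <a| E_ik E_jl |b>
  arma::vec g1v(L2);            // g1v(u(i,l)) = <a| E_il |b>
  const int blk = 48;
  arma::mat B(ws_get("F", Nd * (size_t)blk), Nd, blk, false, true);
  for (int u0 = 0; u0 < L2; u0 += blk) {
    int u1 = std::min(u0 + blk, L2);
    for (int u = u0; u < u1; ++u) {
      double* col = B.colptr(u - u0);
      std::fill(col, col + Nd, 0.0);
      if (sym) {
        apply_alpha(ta, u, Nb, bvec.memptr(), col);
        symmetrize_inplace(col, Na);
      } else {
        apply_group(ta, tb, u, Na, Nb, bvec.memptr(), bt.memptr(), col,
                    scratch.memptr());
      }
    }
    M.cols(u0, u1 - 1) = A.t() * B.cols(0, u1 - u0 - 1);
    for (int u = u0; u < u1; ++u)
      g1v[u] = arma::dot(avec, B.col(u - u0));
  }
  arma::mat gamma1(norb, norb);
  for (int i = 0; i < norb; ++i)
    for (int j = 0; j < norb; ++j) gamma1(i, j) = g1v[i + norb * j];
  NumericVector gamma2((R_xlen_t)norb * norb * norb * norb);
  double* g = gamma2.begin();
  for (int l = 0; l < norb; ++l)
    for (int k = 0; k < norb; ++k)
      for (int j = 0; j < norb; ++j)
        for (int i = 0; i < norb; ++i) {
          double v = M(k + norb * i, j + norb * l);
          if (j == k) v -= gamma1(i, l);
          g[((R_xlen_t)l * norb + k) * norb * norb + (R_xlen_t)j * norb + i] = v;
        }
  gamma2.attr("dim") = IntegerVector::create(norb, norb, norb, norb);
  return List::create(_["gamma1"] = gamma1, _["gamma2"] = gamma2,
                      _["overlap"] = arma::dot(avec, bvec));
}

// <S^2> of a CI vector: Sz(Sz+1) + |S_+ psi|^2.
// [[Rcpp::export]]
double cpp_s2(arma::vec cvec, IntegerVector stringsA, IntegerVector stringsB,
              int norb) {
  int Na = stringsA.size(), Nb = stringsB.size();
  int na = __builtin_popcount((unsigned)stringsA[0]);
  int nb = __builtin_popcount((unsigned)stringsB[0]);
  double sz = 0.5 * (na - nb);
  if (nb == 0) return sz * sz + sz;
  IntegerVector sA2 = cpp_fci_strings(norb, na + 1);
  IntegerVector sB2 = cpp_fci_strings(norb, nb - 1);
  std::vector<int> rankA(1 << norb, -1), rankB(1 << norb, -1);
  for (int i = 0; i < sA2.size(); ++i) rankA[sA2[i]] = i;
  for (int i = 0; i < sB2.size(); ++i) rankB[sB2[i]] = i;
  int Nb2 = sB2.size();
  arma::vec out((size_t)sA2.size() * Nb2, arma::fill::zeros);
  for (int Ia = 0; Ia < Na; ++Ia) {
    unsigned sa = (unsigned)stringsA[Ia];
    for (int Ib = 0; Ib < Nb; ++Ib) {
      unsigned sb = (unsigned)stringsB[Ib];
      double c = cvec[(size_t)Ia * Nb + Ib];
      if (c == 0.0) continue;
      for (int p = 0; p < norb; ++p) {
        if (!(sb & (1u << p)) || (sa & (1u << p))) continue;
        unsigned sa2 = sa | (1u << p), sb2 = sb ^ (1u << p);
        int sgn = ((popcount_below(sa, p) + popcount_below(sb, p)) & 1) ? -1 : 1;
        out[(size_t)rankA[sa2] * Nb2 + rankB[sb2]] += sgn * c;
      }
    }
  }
  return sz * sz + sz + arma::dot(out, out);
}
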