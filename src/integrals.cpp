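// Contracted-Gaussian integral engine (McMurchie-Davidson scheme).
//
// User-facing shells are s and p; internally arbitrary small Cartesian
// angular momenta are supported so that analytic nuclear derivatives can be
// assembled from the exponent-ladder relation
//   d/dAx [x_A^l exp(-a r_A^2)] = 2a (l+1 component) - l (l-1 component).
// All quantities are in hartree / bohr atomic units.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------- Boys F_n
// Series + downward recursion below x = 35, closed form / upward above
// (relative error < 1e-13 over the whole range).
static void boys_fill(int nmax, double x, double* F) {
  if (x < 1e-13) {
    for (int n = 0; n <= nmax; ++n) F[n] = 1.0 / (2.0 * n + 1.0);
    return;
  }
  if (x < 35.0) {
    double ex = std::exp(-x);
    double s = 0.0, term = 1.0 / (2.0 * nmax + 1.0);
    for (int k = 1; k < 400; ++k) {
      s += term;
      term *= 2.0 * x / (2.0 * nmax + 2.0 * k + 1.0);
      if (term < 1e-17 * s) { s += term; break; }
    }
    F[nmax] = ex * s;
    for (int n = nmax; n > 0; --n)
      F[n - 1] = (2.0 * x * F[n] + ex) / (2.0 * n - 1.0);
  } else {
    double ex = std::exp(-x);
    F[0] = 0.5 * std::sqrt(PI / x) * std::erf(std::sqrt(x));
    for (int n = 0; n < nmax; ++n)
      F[n + 1] = ((2.0 * n + 1.0) * F[n] - ex) / (2.0 * x);
  }
}

// ------------------------------------------------- Hermite E coefficients
// E(i,j,t) for one Cartesian dimension, including exp(-mu*Xab^2).
static arma::cube fillE(int imax, int jmax, double a, double b,
                        double Ax, double Bx) {
  double p = a + b, mu = a * b / p;
  double Xab = Ax - Bx;
  double XPA = -b / p * Xab, XPB = a / p * Xab;
  double oo2p = 0.5 / p;
  arma::cube E(imax + 1, jmax + 1, imax + jmax + 1, arma::fill::zeros);
  E(0, 0, 0) = std::exp(-mu * Xab * Xab);
  for (int i = 0; i <= imax; ++i) {
    for (int j = 0; j <= jmax; ++j) {
      if (i == 0 && j == 0) continue;
      if (i > 0) {
        for (int t = 0; t <= i + j; ++t) {
          double v = XPA * E(i - 1, j, t);
          if (t > 0) v += oo2p * E(i - 1, j, t - 1);
          if (t + 1 <= i - 1 + j) v += (t + 1) * E(i - 1, j, t + 1);
          E(i, j, t) = v;
        }
      } else {
        for (int t = 0; t <= i + j; ++t) {
          double v = XPB * E(i, j - 1, t);
          if (t > 0) v += oo2p * E(i, j - 1, t - 1);
          if (t + 1 <= i + j - 1) v += (t + 1) * E(i, j - 1, t + 1);
          E(i, j, t) = v;
        }
      }
    }
  }
  return E;
}

// ------------------------------------------------- Hermite Coulomb R_tuv
// Fills the n = 0 slice of R^n_{tuv}(p, PC) for t+u+v <= L.
struct RTab {
  int L;
  std::vector<double> d;  // (L+1)^4, index ((n*(L+1)+t)*(L+1)+u)*(L+1)+v
  double& at(int n, int t, int u, int v) {
    return d[((size_t)(n * (L + 1) + t) * (L + 1) + u) * (L + 1) + v];
  }
};

static void fillR(RTab& R, int L, double p, double X, double Y, double Z) {
  R.L = L;
  R.d.assign((size_t)(L + 1) * (L + 1) * (L + 1) * (L + 1), 0.0);
  double T = p * (X * X + Y * Y + Z * Z);
  double F[32];
  boys_fill(L, T, F);
  double m2p = 1.0;
  for (int n = 0; n <= L; ++n) { R.at(n, 0, 0, 0) = m2p * F[n]; m2p *= -2.0 * p; }
  for (int s = 1; s <= L; ++s) {
    for (int t = 0; t <= s; ++t) {
      for (int u = 0; u + t <= s; ++u) {
        int v = s - t - u;
        for (int n = 0; n <= L - s; ++n) {
          double val;
          if (t > 0) {
            val = X * R.at(n + 1, t - 1, u, v);
            if (t > 1) val += (t - 1) * R.at(n + 1, t - 2, u, v);
          } else if (u > 0) {
            val = Y * R.at(n + 1, t, u - 1, v);
            if (u > 1) val += (u - 1) * R.at(n + 1, t, u - 2, v);
          } else {
            val = Z * R.at(n + 1, t, u, v - 1);
            if (v > 1) val += (v - 1) * R.at(n + 1, t, u, v - 2);
          }
          R.at(n, t, u, v) = val;
        }
      }
    }
  }
}

// ------------------------------------------------------------ shell setup
struct Shell {
  int atom, l, off, ncart, nprim;
  double A[3];
  std::vector<double> a, c;  // exponents, effective coefficients
};

static double dfact(int n) {  // (2n-1)!! with n>=0 convention dfact(0)=1
  double r = 1.0;
  for (int k = 2 * n - 1; k > 1; k -= 2) r *= k;
  return r;
}

static double prim_norm(int l, double a) {
  return std::pow(2.0 * a / PI, 0.75) * std::pow(4.0 * a, 0.5 * l) /
         std::sqrt(dfact(l));
}

struct CartComp { int x, y, z; };
static std::vector<CartComp> cart_comps(int l) {
  std::vector<CartComp> v;
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly)
      v.push_back({lx, ly, l - lx - ly});
  return v;
}

static std::vector<Shell> parse_shells(const List& args) {
  NumericMatrix coords = args["coords"];
  IntegerVector sh_atom = args["sh_atom"], sh_l = args["sh_l"],
                sh_nprim = args["sh_nprim"];
  NumericVector sh_scale = args["sh_scale"], pexp = args["prim_exp"],
                pcoef = args["prim_coef"];
  int ns = sh_atom.size();
  std::vector<Shell> sh(ns);
  int pp = 0, off = 0;
  for (int s = 0; s < ns; ++s) {
    sh[s].atom = sh_atom[s] - 1;
    sh[s].l = sh_l[s];
    sh[s].ncart = (sh_l[s] + 1) * (sh_l[s] + 2) / 2;
    sh[s].off = off;
    off += sh[s].ncart;
    sh[s].nprim = sh_nprim[s];
    for (int d = 0; d < 3; ++d) sh[s].A[d] = coords(sh[s].atom, d);
    for (int k = 0; k < sh_nprim[s]; ++k) {
      double a = pexp[pp], c = pcoef[pp];
      ++pp;
      sh[s].a.push_back(a);
      sh[s].c.push_back(c * prim_norm(sh_l[s], a) * sh_scale[s]);
    }
  }
  return sh;
}

static int total_nbf(const std::vector<Shell>& sh) {
  return sh.empty() ? 0 : sh.back().off + sh.back().ncart;
}

// Primitive-pair data with E cubes (margins: +2 on bra index, +3 on ket
// index so exponent-ladder derivatives and the kinetic j+2 shifts fit).
struct PairPrim {
  double a, b, p, cc, P[3];
  arma::cube Ex, Ey, Ez;
};

static void build_pair(const Shell& s1, const Shell& s2,
                       std::vector<PairPrim>& out, int exa = 2, int exb = 3) {
  out.clear();
  for (int i = 0; i < s1.nprim; ++i) {
    for (int j = 0; j < s2.nprim; ++j) {
      PairPrim q;
      q.a = s1.a[i]; q.b = s2.a[j];
      q.p = q.a + q.b;
      q.cc = s1.c[i] * s2.c[j];
      for (int d = 0; d < 3; ++d)
        q.P[d] = (q.a * s1.A[d] + q.b * s2.A[d]) / q.p;
      q.Ex = fillE(s1.l + exa, s2.l + exb, q.a, q.b, s1.A[0], s2.A[0]);
      q.Ey = fillE(s1.l + exa, s2.l + exb, q.a, q.b, s1.A[1], s2.A[1]);
      q.Ez = fillE(s1.l + exa, s2.l + exb, q.a, q.b, s1.A[2], s2.A[2]);
      out.push_back(std::move(q));
    }
  }
}

// 1D contracted building blocks for one primitive pair
static inline double s1d(const arma::cube& E, double p, int i, int j) {
  return E(i, j, 0) * std::sqrt(PI / p);
}
static inline double k1d(const arma::cube& E, double p, double b, int i, int j) {
  double v = -2.0 * b * b * s1d(E, p, i, j + 2) +
             b * (2.0 * j + 1.0) * s1d(E, p, i, j);
  if (j >= 2) v -= 0.5 * j * (j - 1.0) * s1d(E, p, i, j - 2);
  return v;
}

// ------------------------------------------------------- self overlap
// Contracted self-overlap of the first Cartesian component of each shell
// (all components of an s/p shell share one normalization).
// [[Rcpp::export]]
NumericVector cpp_shell_self_overlap(List args) {
  std::vector<Shell> sh = parse_shells(args);
  NumericVector out(sh.size());
  std::vector<PairPrim> pp;
  for (size_t s = 0; s < sh.size(); ++s) {
    build_pair(sh[s], sh[s], pp);
    std::vector<CartComp> cc = cart_comps(sh[s].l);
    double v = 0.0;
    for (auto& q : pp)
      v += q.cc * s1d(q.Ex, q.p, cc[0].x, cc[0].x) *
           s1d(q.Ey, q.p, cc[0].y, cc[0].y) *
           s1d(q.Ez, q.p, cc[0].z, cc[0].z);
    out[s] = v;
  }
  return out;
}

// ------------------------------------------------- S, T, V (one-electron)
// [[Rcpp::export]]
List cpp_ao_core(List args) {
  std::vector<Shell> sh = parse_shells(args);
  NumericMatrix coords = args["coords"];
  NumericVector zvals = args["zvals"];
  int L = total_nbf(sh), nat = coords.nrow();
  arma::mat S(L, L, arma::fill::zeros), T(L, L, arma::fill::zeros),
      V(L, L, arma::fill::zeros);
  std::vector<PairPrim> pp;
  RTab R;
  for (size_t s1 = 0; s1 < sh.size(); ++s1) {
    for (size_t s2 = 0; s2 <= s1; ++s2) {
      build_pair(sh[s1], sh[s2], pp);
      std::vector<CartComp> ca = cart_comps(sh[s1].l), cb = cart_comps(sh[s2].l);
      int Ltot = sh[s1].l + sh[s2].l;
      for (auto& q : pp) {
        for (size_t ia = 0; ia < ca.size(); ++ia) {
          for (size_t ib = 0; ib < cb.size(); ++ib) {
            double sx = s1d(q.Ex, q.p, ca[ia].x, cb[ib].x),
                   sy = s1d(q.Ey, q.p, ca[ia].y, cb[ib].y),
                   sz = s1d(q.Ez, q.p, ca[ia].z, cb[ib].z);
            S(sh[s1].off + ia, sh[s2].off + ib) += q.cc * sx * sy * sz;
            T(sh[s1].off + ia, sh[s2].off + ib) += q.cc *
                (k1d(q.Ex, q.p, q.b, ca[ia].x, cb[ib].x) * sy * sz +
                 sx * k1d(q.Ey, q.p, q.b, ca[ia].y, cb[ib].y) * sz +
                 sx * sy * k1d(q.Ez, q.p, q.b, ca[ia].z, cb[ib].z));
          }
        }
        // nuclear attraction
        for (int M = 0; M < nat; ++M) {
          fillR(R, Ltot, q.p, q.P[0] - coords(M, 0), q.P[1] - coords(M, 1),
                q.P[2] - coords(M, 2));
          double pref = -zvals[M] * q.cc * 2.0 * PI / q.p;
          for (size_t ia = 0; ia < ca.size(); ++ia) {
            for (size_t ib = 0; ib < cb.size(); ++ib) {
              double acc = 0.0;
              for (int t = 0; t <= ca[ia].x + cb[ib].x; ++t)
                for (int u = 0; u <= ca[ia].y + cb[ib].y; ++u)
                  for (int v = 0; v <= ca[ia].z + cb[ib].z; ++v)
                    acc += q.Ex(ca[ia].x, cb[ib].x, t) *
                           q.Ey(ca[ia].y, cb[ib].y, u) *
                           q.Ez(ca[ia].z, cb[ib].z, v) * R.at(0, t, u, v);
              V(sh[s1].off + ia, sh[s2].off + ib) += pref * acc;
            }
          }
        }
      }
      if (s1 != s2) {
        for (size_t ia = 0; ia < ca.size(); ++ia) {
          for (size_t ib = 0; ib < cb.size(); ++ib) {
            S(sh[s2].off + ib, sh[s1].off + ia) = S(sh[s1].off + ia, sh[s2].off + ib);
            T(sh[s2].off + ib, sh[s1].off + ia) = T(sh[s1].off + ia, sh[s2].off + ib);
            V(sh[s2].off + ib, sh[s1].off + ia) = V(sh[s1].off + ia, sh[s2].off + ib);
          }
        }
      }
    }
  }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V);
}

// --------------------------------------------------------------- dipole
// <a| r_c - origin_c |b> for c in x,y,z
// [[Rcpp::export]]
arma::cube cpp_dipole(List args, NumericVector origin) {
  std::vector<Shell> sh = parse_shells(args);
  int L = total_nbf(sh);
  arma::cube D(L, L, 3, arma::fill::zeros);
  std::vector<PairPrim> pp;
  for (size_t s1 = 0; s1 < sh.size(); ++s1) {
    for (size_t s2 = 0; s2 < sh.size(); ++s2) {
      build_pair(sh[s1], sh[s2], pp);
      std::vector<CartComp> ca = cart_comps(sh[s1].l), cb = cart_comps(sh[s2].l);
      for (auto& q : pp) {
        for (size_t ia = 0; ia < ca.size(); ++ia) {
          for (size_t ib = 0; ib < cb.size(); ++ib) {
            double sx = s1d(q.Ex, q.p, ca[ia].x, cb[ib].x),
                   sy = s1d(q.Ey, q.p, ca[ia].y, cb[ib].y),
                   sz = s1d(q.Ez, q.p, ca[ia].z, cb[ib].z);
            double mx = s1d(q.Ex, q.p, ca[ia].x, cb[ib].x + 1) +
                        (sh[s2].A[0] - origin[0]) * sx;
            double my = s1d(q.Ey, q.p, ca[ia].y, cb[ib].y + 1) +
                        (sh[s2].A[1] - origin[1]) * sy;
            double mz = s1d(q.Ez, q.p, ca[ia].z, cb[ib].z + 1) +
                        (sh[s2].A[2] - origin[2]) * sz;
            D(sh[s1].off + ia, sh[s2].off + ib, 0) += q.cc * mx * sy * sz;
            D(sh[s1].off + ia, sh[s2].off + ib, 1) += q.cc * sx * my * sz;
            D(sh[s1].off + ia, sh[s2].off + ib, 2) += q.cc * sx * sy * mz;
          }
        }
      }
    }
  }
  return D;
}

// ------------------------------------------------------------------- ERI
// One primitive-quartet component in chemists' notation (ab|cd), Cartesian
// components given explicitly (allows the ladder-shifted variants).
static inline double prim_eri_comp(const PairPrim& q1, const PairPrim& q2,
                                   RTab& R, int ax, int ay, int az, int bx,
                                   int by, int bz, int cx, int cy, int cz,
                                   int dx, int dy, int dz) {
  double acc = 0.0;
  for (int t = 0; t <= ax + bx; ++t) {
    for (int u = 0; u <= ay + by; ++u) {
      for (int v = 0; v <= az + bz; ++v) {
        double e1 = q1.Ex(ax, bx, t) * q1.Ey(ay, by, u) * q1.Ez(az, bz, v);
        if (e1 == 0.0) continue;
        double inner = 0.0;
        for (int tt = 0; tt <= cx + dx; ++tt) {
          for (int uu = 0; uu <= cy + dy; ++uu) {
            for (int vv = 0; vv <= cz + dz; ++vv) {
              double e2 = q2.Ex(cx, dx, tt) * q2.Ey(cy, dy, uu) *
                          q2.Ez(cz, dz, vv);
              if (((tt + uu + vv) & 1) != 0) e2 = -e2;
              inner += e2 * R.at(0, t + tt, u + uu, v + vv);
            }
          }
        }
        acc += e1 * inner;
      }
    }
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_eri(List args) {
  std::vector<Shell> sh = parse_shells(args);
  int L = total_nbf(sh), ns = sh.size();
  NumericVector out((R_xlen_t)L * L * L * L);
  double* o = out.begin();
  auto idx = [L](int p, int q, int r, int s) {
    return ((R_xlen_t)s * L + r) * L * L + (R_xlen_t)q * L + p;
  };
  // shell-pair primitive caches (margin 0 bra ext, needed only l)
  std::vector<std::vector<PairPrim>> pairs(ns * ns);
  RTab R;
  for (int s1 = 0; s1 < ns; ++s1)
    for (int s2 = 0; s2 <= s1; ++s2)
      build_pair(sh[s1], sh[s2], pairs[s1 * ns + s2], 0, 0);
  for (int s1 = 0; s1 < ns; ++s1) {
    for (int s2 = 0; s2 <= s1; ++s2) {
      for (int s3 = 0; s3 <= s1; ++s3) {
        for (int s4 = 0; s4 <= s3; ++s4) {
          if (s3 * ns + s4 > s1 * ns + s2) continue;
          std::vector<PairPrim>& p12 = pairs[s1 * ns + s2];
          std::vector<PairPrim>& p34 = pairs[s3 * ns + s4];
          std::vector<CartComp> ca = cart_comps(sh[s1].l),
                                cb = cart_comps(sh[s2].l),
                                cc = cart_comps(sh[s3].l),
                                cd = cart_comps(sh[s4].l);
          int na = ca.size(), nb = cb.size(), nc = cc.size(), nd = cd.size();
          std::vector<double> blk((size_t)na * nb * nc * nd, 0.0);
          int Ltot = sh[s1].l + sh[s2].l + sh[s3].l + sh[s4].l;
          for (auto& q1 : p12) {
            for (auto& q2 : p34) {
              double pref = 2.0 * std::pow(PI, 2.5) /
                            (q1.p * q2.p * std::sqrt(q1.p + q2.p)) *
                            q1.cc * q2.cc;
              if (std::fabs(pref) * q1.Ex(0, 0, 0) * q1.Ey(0, 0, 0) *
                      q1.Ez(0, 0, 0) * q2.Ex(0, 0, 0) * q2.Ey(0, 0, 0) *
                      q2.Ez(0, 0, 0) < 1e-16)
                continue;
              fillR(R, Ltot, q1.p * q2.p / (q1.p + q2.p),
                    q1.P[0] - q2.P[0], q1.P[1] - q2.P[1], q1.P[2] - q2.P[2]);
              size_t w = 0;
              for (int ia = 0; ia < na; ++ia)
                for (int ib = 0; ib < nb; ++ib)
                  for (int ic = 0; ic < nc; ++ic)
                    for (int id = 0; id < nd; ++id, ++w)
                      blk[w] += pref * prim_eri_comp(
                          q1, q2, R, ca[ia].x, ca[ia].y, ca[ia].z, cb[ib].x,
                          cb[ib].y, cb[ib].z, cc[ic].x, cc[ic].y, cc[ic].z,
                          cd[id].x, cd[id].y, cd[id].z);
            }
          }
          size_t w = 0;
          for (int ia = 0; ia < na; ++ia) {
            for (int ib = 0; ib < nb; ++ib) {
              for (int ic = 0; ic < nc; ++ic) {
                for (int id = 0; id < nd; ++id, ++w) {
                  int p = sh[s1].off + ia, q = sh[s2].off + ib,
                      r = sh[s3].off + ic, s = sh[s4].off + id;
                  double v = blk[w];
                  o[idx(p, q, r, s)] = v; o[idx(q, p, r, s)] = v;
                  o[idx(p, q, s, r)] = v; o[idx(q, p, s, r)] = v;
                  o[idx(r, s, p, q)] = v; o[idx(s, r, p, q)] = v;
                  o[idx(r, s, q, p)] = v; o[idx(s, r, q, p)] = v;
                }
              }
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(L, L, L, L);
  return out;
}

// ------------------------------------------- one-electron derivatives
// dS, dT+dV with respect to every nuclear Cartesian coordinate.
// Bra/ket ladders give d/dA; two-center translational invariance gives the
// partner center, and the nuclear-attraction operator centers follow from
// rigid-translation invariance of the three-center integral.
static inline double ladder1d_s(const arma::cube& E, double p, double a,
                                int i, int j) {
  // d/dA of the 1D overlap via exponent ladder on the bra index i
  double v = 2.0 * a * s1d(E, p, i + 1, j);
  if (i >= 1) v -= i * s1d(E, p, i - 1, j);
  return v;
}
static inline double ladder1d_k(const arma::cube& E, double p, double a,
                                double b, int i, int j) {
  double v = 2.0 * a * k1d(E, p, b, i + 1, j);
  if (i >= 1) v -= i * k1d(E, p, b, i - 1, j);
  return v;
}

static inline double prim_eri_like_V(const PairPrim& q, RTab& R,
                                     const int* sa, const int* sb) {
  double acc = 0.0;
  for (int t = 0; t <= sa[0] + sb[0]; ++t)
    for (int u = 0; u <= sa[1] + sb[1]; ++u)
      for (int v = 0; v <= sa[2] + sb[2]; ++v)
        acc += q.Ex(sa[0], sb[0], t) * q.Ey(sa[1], sb[1], u) *
               q.Ez(sa[2], sb[2], v) * R.at(0, t, u, v);
  return acc;
}

// [[Rcpp::export]]
List cpp_oei_derivs(List args) {
  std::vector<Shell> sh = parse_shells(args);
  NumericMatrix coords = args["coords"];
  NumericVector zvals = args["zvals"];
  int L = total_nbf(sh), nat = coords.nrow(), nc3 = 3 * nat;
  arma::cube dS(L, L, nc3, arma::fill::zeros), dH(L, L, nc3, arma::fill::zeros);
  std::vector<PairPrim> pp;
  RTab R;
  for (size_t s1 = 0; s1 < sh.size(); ++s1) {
    for (size_t s2 = 0; s2 < sh.size(); ++s2) {
      build_pair(sh[s1], sh[s2], pp);
      std::vector<CartComp> ca = cart_comps(sh[s1].l), cb = cart_comps(sh[s2].l);
      int A = sh[s1].atom, B = sh[s2].atom;
      int Ltot = sh[s1].l + sh[s2].l;
      for (auto& q : pp) {
        for (size_t ia = 0; ia < ca.size(); ++ia) {
          for (size_t ib = 0; ib < cb.size(); ++ib) {
            int ccA[3] = {ca[ia].x, ca[ia].y, ca[ia].z};
            int ccB[3] = {cb[ib].x, cb[ib].y, cb[ib].z};
            double s3[3] = {s1d(q.Ex, q.p, ccA[0], ccB[0]),
                            s1d(q.Ey, q.p, ccA[1], ccB[1]),
                            s1d(q.Ez, q.p, ccA[2], ccB[2])};
            double k3[3] = {k1d(q.Ex, q.p, q.b, ccA[0], ccB[0]),
                            k1d(q.Ey, q.p, q.b, ccA[1], ccB[1]),
                            k1d(q.Ez, q.p, q.b, ccA[2], ccB[2])};
            for (int c = 0; c < 3; ++c) {
              const arma::cube& E = (c == 0) ? q.Ex : (c == 1) ? q.Ey : q.Ez;
              double dsd = ladder1d_s(E, q.p, q.a, ccA[c], ccB[c]);
              double dkd = ladder1d_k(E, q.p, q.a, q.b, ccA[c], ccB[c]);
              double dSval = q.cc * dsd * s3[(c + 1) % 3] * s3[(c + 2) % 3];
              // dT: ladder on the differentiated dimension; both the kinetic
              // and overlap 1D factors of the other dims stay fixed
              double dTval = q.cc *
                  (dkd * s3[(c + 1) % 3] * s3[(c + 2) % 3] +
                   dsd * (k3[(c + 1) % 3] * s3[(c + 2) % 3] +
                          s3[(c + 1) % 3] * k3[(c + 2) % 3]));
              dS(sh[s1].off + ia, sh[s2].off + ib, 3 * A + c) += dSval;
              dS(sh[s1].off + ia, sh[s2].off + ib, 3 * B + c) -= dSval;
              dH(sh[s1].off + ia, sh[s2].off + ib, 3 * A + c) += dTval;
              dH(sh[s1].off + ia, sh[s2].off + ib, 3 * B + c) -= dTval;
            }
          }
        }
        // nuclear attraction: bra ladder + ket ladder; operator center by
        // translational invariance
        for (int M = 0; M < nat; ++M) {
          fillR(R, Ltot + 1, q.p, q.P[0] - coords(M, 0),
                q.P[1] - coords(M, 1), q.P[2] - coords(M, 2));
          double pref = -zvals[M] * q.cc * 2.0 * PI / q.p;
          for (size_t ia = 0; ia < ca.size(); ++ia) {
            for (size_t ib = 0; ib < cb.size(); ++ib) {
              int ccA[3] = {ca[ia].x, ca[ia].y, ca[ia].z};
              int ccB[3] = {cb[ib].x, cb[ib].y, cb[ib].z};
              for (int c = 0; c < 3; ++c) {
                int sa[3] = {ccA[0], ccA[1], ccA[2]};
                int sb[3] = {ccB[0], ccB[1], ccB[2]};
                // bra ladder
                sa[c] = ccA[c] + 1;
                double dA = 2.0 * q.a * prim_eri_like_V(q, R, sa, sb);
                if (ccA[c] >= 1) {
                  sa[c] = ccA[c] - 1;
                  dA -= ccA[c] * prim_eri_like_V(q, R, sa, sb);
                }
                sa[c] = ccA[c];
                // ket ladder
                sb[c] = ccB[c] + 1;
                double dB = 2.0 * q.b * prim_eri_like_V(q, R, sa, sb);
                if (ccB[c] >= 1) {
                  sb[c] = ccB[c] - 1;
                  dB -= ccB[c] * prim_eri_like_V(q, R, sa, sb);
                }
                sb[c] = ccB[c];
                dH(sh[s1].off + ia, sh[s2].off + ib, 3 * A + c) += pref * dA;
                dH(sh[s1].off + ia, sh[s2].off + ib, 3 * B + c) += pref * dB;
                dH(sh[s1].off + ia, sh[s2].off + ib, 3 * M + c) -=
                    pref * (dA + dB);
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dS"] = dS, _["dH"] = dH);
}

// --------------------------------------------------- ERI derivatives
static inline double prim_eri_comp_a(const PairPrim& q1, const PairPrim& q2,
                                     RTab& R, const int* a, const int* b,
                                     const int* c, const int* d) {
  return prim_eri_comp(q1, q2, R, a[0], a[1], a[2], b[0], b[1], b[2],
                       c[0], c[1], c[2], d[0], d[1], d[2]);
}

// Ladder derivative of one primitive-quartet component with respect to one
// Cartesian coordinate of centers A, B or C (which = 0,1,2). D follows from
// rigid-translation invariance at the caller.
static double prim_eri_ladder(const PairPrim& q1, const PairPrim& q2, RTab& R,
                              int cm[4][3], int which, int c) {
  double expo = (which == 0) ? q1.a : (which == 1) ? q1.b : q2.a;
  int* tgt = cm[which];
  int orig = tgt[c];
  tgt[c] = orig + 1;
  double v = 2.0 * expo * prim_eri_comp_a(q1, q2, R, cm[0], cm[1], cm[2], cm[3]);
  if (orig >= 1) {
    tgt[c] = orig - 1;
    v -= orig * prim_eri_comp_a(q1, q2, R, cm[0], cm[1], cm[2], cm[3]);
  }
  tgt[c] = orig;
  return v;
}

// Shared driver over canonical shell quartets. For every component tuple it
// produces the 12 center derivatives (A,B,C ladders; D by translation) and
// hands them to `sink(p,q,r,s, atoms[4], dvals[12])`.
template <typename Sink>
static void eri_deriv_driver(const std::vector<Shell>& sh, Sink&& sink) {
  int ns = sh.size();
  std::vector<std::vector<PairPrim>> pairs(ns * ns);
  for (int s1 = 0; s1 < ns; ++s1)
    for (int s2 = 0; s2 <= s1; ++s2)
      build_pair(sh[s1], sh[s2], pairs[s1 * ns + s2], 1, 1);
  RTab R;
  for (int s1 = 0; s1 < ns; ++s1) {
    for (int s2 = 0; s2 <= s1; ++s2) {
      for (int s3 = 0; s3 <= s1; ++s3) {
        for (int s4 = 0; s4 <= s3; ++s4) {
          if (s3 * ns + s4 > s1 * ns + s2) continue;
          std::vector<PairPrim>& p12 = pairs[s1 * ns + s2];
          std::vector<PairPrim>& p34 = pairs[s3 * ns + s4];
          std::vector<CartComp> ca = cart_comps(sh[s1].l),
                                cb = cart_comps(sh[s2].l),
                                cc = cart_comps(sh[s3].l),
                                cd = cart_comps(sh[s4].l);
          int na = ca.size(), nb = cb.size(), nc = cc.size(), nd = cd.size();
          int ncomp = na * nb * nc * nd;
          std::vector<double> dblk((size_t)ncomp * 12, 0.0);
          int Ltot = sh[s1].l + sh[s2].l + sh[s3].l + sh[s4].l + 1;
          for (auto& q1 : p12) {
            for (auto& q2 : p34) {
              double pref = 2.0 * std::pow(PI, 2.5) /
                            (q1.p * q2.p * std::sqrt(q1.p + q2.p)) *
                            q1.cc * q2.cc;
              if (std::fabs(pref) * q1.Ex(0, 0, 0) * q1.Ey(0, 0, 0) *
                      q1.Ez(0, 0, 0) * q2.Ex(0, 0, 0) * q2.Ey(0, 0, 0) *
                      q2.Ez(0, 0, 0) < 1e-16)
                continue;
              fillR(R, Ltot, q1.p * q2.p / (q1.p + q2.p),
                    q1.P[0] - q2.P[0], q1.P[1] - q2.P[1], q1.P[2] - q2.P[2]);
              int w = 0;
              for (int ia = 0; ia < na; ++ia) {
                for (int ib = 0; ib < nb; ++ib) {
                  for (int ic = 0; ic < nc; ++ic) {
                    for (int id = 0; id < nd; ++id, ++w) {
                      int cm[4][3] = {
                          {ca[ia].x, ca[ia].y, ca[ia].z},
                          {cb[ib].x, cb[ib].y, cb[ib].z},
                          {cc[ic].x, cc[ic].y, cc[ic].z},
                          {cd[id].x, cd[id].y, cd[id].z}};
                      double* dv = &dblk[(size_t)w * 12];
                      for (int c = 0; c < 3; ++c) {
                        double dA = prim_eri_ladder(q1, q2, R, cm, 0, c);
                        double dB = prim_eri_ladder(q1, q2, R, cm, 1, c);
                        double dC = prim_eri_ladder(q1, q2, R, cm, 2, c);
                        dv[0 + c] += pref * dA;
                        dv[3 + c] += pref * dB;
                        dv[6 + c] += pref * dC;
                        dv[9 + c] -= pref * (dA + dB + dC);
                      }
                    }
                  }
                }
              }
            }
          }
          int atoms[4] = {sh[s1].atom, sh[s2].atom, sh[s3].atom, sh[s4].atom};
          int w = 0;
          for (int ia = 0; ia < na; ++ia)
            for (int ib = 0; ib < nb; ++ib)
              for (int ic = 0; ic < nc; ++ic)
                for (int id = 0; id < nd; ++id, ++w)
                  sink(sh[s1].off + ia, sh[s2].off + ib, sh[s3].off + ic,
                       sh[s4].off + id, atoms, &dblk[(size_t)w * 12]);
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_eri_derivs(List args) {
  std::vector<Shell> sh = parse_shells(args);
  NumericMatrix coords = args["coords"];
  int L = total_nbf(sh), nat = coords.nrow();
  NumericVector out((R_xlen_t)L * L * L * L * 3 * nat);
  double* o = out.begin();
  R_xlen_t L4 = (R_xlen_t)L * L * L * L;
  auto idx = [L](int p, int q, int r, int s) {
    return ((R_xlen_t)s * L + r) * L * L + (R_xlen_t)q * L + p;
  };
  eri_deriv_driver(sh, [&](int p, int q, int r, int s, const int* atoms,
                           const double* dv) {
    // per-atom totals for this component tuple
    for (int c = 0; c < 3; ++c) {
      double tot[4] = {0, 0, 0, 0};
      for (int k = 0; k < 4; ++k) tot[k] = dv[3 * k + c];
      // combine coinciding centers
      for (int k = 0; k < 4; ++k) {
        double val = 0.0;
        bool first = true;
        for (int m = 0; m < 4; ++m) {
          if (atoms[m] == atoms[k]) {
            if (m < k) { first = false; break; }
            val += tot[m];
          }
        }
        if (!first) continue;
        R_xlen_t coord = (R_xlen_t)(3 * atoms[k] + c) * L4;
        R_xlen_t im[8] = {idx(p, q, r, s), idx(q, p, r, s), idx(p, q, s, r),
                          idx(q, p, s, r), idx(r, s, p, q), idx(s, r, p, q),
                          idx(r, s, q, p), idx(s, r, q, p)};
        for (int t = 0; t < 8; ++t) o[coord + im[t]] = val;
      }
    }
  });
  out.attr("dim") = IntegerVector::create(L, L, L, L, 3 * nat);
  return out;
}

// Fused contraction: grad(3*nat) = sum_pqrs W_pqrs d(pq|rs)/dR for a weight
// tensor W symmetric under the full 8-fold real-integral permutation group
// (chemists' index order).
// [[Rcpp::export]]
NumericMatrix cpp_eri_deriv_contract(List args, NumericVector W) {
  std::vector<Shell> sh = parse_shells(args);
  NumericMatrix coords = args["coords"];
  int L = total_nbf(sh), nat = coords.nrow();
  NumericMatrix grad(3, nat);
  const double* w = W.begin();
  auto idx = [L](int p, int q, int r, int s) {
    return ((R_xlen_t)s * L + r) * L * L + (R_xlen_t)q * L + p;
  };
  eri_deriv_driver(sh, [&](int p, int q, int r, int s, const int* atoms,
                           const double* dv) {
    // canonical-component filter: count each distinct index tuple once
    if (q > p || s > r) return;
    R_xlen_t i12 = (R_xlen_t)p * (p + 1) / 2 + q,
             i34 = (R_xlen_t)r * (r + 1) / 2 + s;
    if (i34 > i12) return;
    double mult = (p == q ? 1.0 : 2.0) * (r == s ? 1.0 : 2.0) *
                  (i12 == i34 ? 1.0 : 2.0);
    double wv = mult * w[idx(p, q, r, s)];
    if (wv == 0.0) return;
    for (int k = 0; k < 4; ++k)
      for (int c = 0; c < 3; ++c)
        grad(c, atoms[k]) += wv * dv[3 * k + c];
  });
  return grad;
}
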