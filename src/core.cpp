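// Numerical core: Ca Go energy/forces, Gaussian density rendering,
// normalized cross-correlation gradients, and the NMMD (BAOAB Langevin)
// integration loop. Reduced units: energy in eps, length in Angstrom,
// time in ps, unit bead masses unless stated.
#include <Rcpp.h>
#include <cmath>
#include <random>
using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// ---------------------------------------------------------------------------
// Go model energy and analytic forces
// ---------------------------------------------------------------------------

struct GoTop {
  IntegerMatrix bonds;     // cols: i, j (0-based)
  NumericVector bond_r0;
  IntegerMatrix angles;    // i, j, k (j central)
  NumericVector angle_t0;
  IntegerMatrix dihedrals; // i, j, k, l
  NumericVector dih_p0;
  IntegerMatrix contacts;  // i, j
  NumericVector contact_sig;
  IntegerMatrix excl;      // i, j candidate excluded-volume pairs
  double k_bond, k_angle, k_dih1, k_dih3, eps_contact, eps_excl, r_excl;
  double excl_cut;         // truncation radius of the excluded-volume term
};

static GoTop unpack_top(const List& top) {
  GoTop t;
  t.bonds = as<IntegerMatrix>(top["bonds"]);
  t.bond_r0 = as<NumericVector>(top["bond_r0"]);
  t.angles = as<IntegerMatrix>(top["angles"]);
  t.angle_t0 = as<NumericVector>(top["angle_t0"]);
  t.dihedrals = as<IntegerMatrix>(top["dihedrals"]);
  t.dih_p0 = as<NumericVector>(top["dih_p0"]);
  t.contacts = as<IntegerMatrix>(top["contacts"]);
  t.contact_sig = as<NumericVector>(top["contact_sig"]);
  t.excl = as<IntegerMatrix>(top["excl"]);
  NumericVector p = as<NumericVector>(top["par"]);
  // par order: k_bond k_angle k_dih1 k_dih3 eps_contact eps_excl r_excl
  // excl_cut
  t.k_bond = p[0]; t.k_angle = p[1]; t.k_dih1 = p[2]; t.k_dih3 = p[3];
  t.eps_contact = p[4]; t.eps_excl = p[5]; t.r_excl = p[6];
  t.excl_cut = p[7];
  return t;
}

// coords: N x 3. forces accumulated into f (3N, atom-major x,y,z).
// Returns the 5 energy terms. throw_overlap: error on r < 1e-6.
static void go_eval(const GoTop& t, const double* x, int N,
                    double* f, double* eterms) {
  for (int i = 0; i < 3 * N; i++) f[i] = 0.0;
  for (int i = 0; i < 5; i++) eterms[i] = 0.0;

  // bonds: E = k (r - r0)^2
  for (int b = 0; b < t.bonds.nrow(); b++) {
    int i = t.bonds(b, 0), j = t.bonds(b, 1);
    double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
    double r = std::sqrt(dot3(d, d));
    if (r < 1e-6) stop("overlapping atoms in bond %d-%d", i + 1, j + 1);
    double dr = r - t.bond_r0[b];
    eterms[0] += t.k_bond * dr * dr;
    double c = -2.0 * t.k_bond * dr / r; // force on i along d
    for (int m = 0; m < 3; m++) { f[3*i+m] += c * d[m]; f[3*j+m] -= c * d[m]; }
  }

  // angles: E = k (theta - theta0)^2, j central
  for (int a = 0; a < t.angles.nrow(); a++) {
    int i = t.angles(a, 0), j = t.angles(a, 1), k = t.angles(a, 2);
    double u[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
    double v[3] = {x[3*k] - x[3*j], x[3*k+1] - x[3*j+1], x[3*k+2] - x[3*j+2]};
    double nu = std::sqrt(dot3(u, u)), nv = std::sqrt(dot3(v, v));
    if (nu < 1e-6 || nv < 1e-6) stop("overlapping atoms in angle at %d", j + 1);
    double ct = dot3(u, v) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double theta = std::acos(ct);
    double st = std::sqrt(std::max(1.0 - ct * ct, 1e-12));
    double dth = theta - t.angle_t0[a];
    eterms[1] += t.k_angle * dth * dth;
    double dEdt = 2.0 * t.k_angle * dth;
    for (int m = 0; m < 3; m++) {
      double dti = (ct * u[m] / nu - v[m] / nv) / (nu * st);
      double dtk = (ct * v[m] / nv - u[m] / nu) / (nv * st);
      f[3*i+m] -= dEdt * dti;
      f[3*k+m] -= dEdt * dtk;
      f[3*j+m] += dEdt * (dti + dtk);
    }
  }

  // dihedrals: E = k1 (1 - cos(phi - phi0)) + k3 (1 - cos(3 (phi - phi0)))
  for (int d = 0; d < t.dihedrals.nrow(); d++) {
    int i1 = t.dihedrals(d, 0), i2 = t.dihedrals(d, 1),
        i3 = t.dihedrals(d, 2), i4 = t.dihedrals(d, 3);
    double b1[3], b2[3], b3[3];
    for (int m = 0; m < 3; m++) {
      b1[m] = x[3*i2+m] - x[3*i1+m];
      b2[m] = x[3*i3+m] - x[3*i2+m];
      b3[m] = x[3*i4+m] - x[3*i3+m];
    }
    double n1[3], n2[3], m1[3];
    cross3(b1, b2, n1);
    cross3(b2, b3, n2);
    double nb2 = std::sqrt(dot3(b2, b2));
    cross3(n1, n2, m1);
    double phi = std::atan2(dot3(m1, b2) / nb2, dot3(n1, n2));
    double dphi = phi - t.dih_p0[d];
    eterms[2] += t.k_dih1 * (1.0 - std::cos(dphi)) +
                 t.k_dih3 * (1.0 - std::cos(3.0 * dphi));
    double dEdp = t.k_dih1 * std::sin(dphi) +
                  3.0 * t.k_dih3 * std::sin(3.0 * dphi);
    double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
    if (n1sq < 1e-12 || n2sq < 1e-12) continue; // collinear: zero torque
    // Blondel-Karplus gradient of phi
    double g1[3], g4[3], g2[3], g3[3];
    double c12 = dot3(b1, b2) / (nb2 * nb2);
    double c32 = dot3(b3, b2) / (nb2 * nb2);
    for (int m = 0; m < 3; m++) {
      g1[m] = -nb2 / n1sq * n1[m];
      g4[m] =  nb2 / n2sq * n2[m];
      g2[m] = -(1.0 + c12) * g1[m] + c32 * g4[m];
      g3[m] = c12 * g1[m] - (1.0 + c32) * g4[m];
      f[3*i1+m] -= dEdp * g1[m];
      f[3*i2+m] -= dEdp * g2[m];
      f[3*i3+m] -= dEdp * g3[m];
      f[3*i4+m] -= dEdp * g4[m];
    }
  }

  // native contacts: E = eps [5 (sig/r)^12 - 6 (sig/r)^10]
  for (int c = 0; c < t.contacts.nrow(); c++) {
    int i = t.contacts(c, 0), j = t.contacts(c, 1);
    double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
    double r2 = dot3(d, d);
    double r = std::sqrt(r2);
    if (r < 1e-6) stop("overlapping atoms in contact %d-%d", i + 1, j + 1);
    double s2 = t.contact_sig[c] * t.contact_sig[c] / r2;
    double s10 = s2 * s2 * s2 * s2 * s2, s12 = s10 * s2;
    eterms[3] += t.eps_contact * (5.0 * s12 - 6.0 * s10);
    // dE/dr = 60 eps (sig^10/r^11) (1 - (sig/r)^2) = 60 eps (s10 - s12)/r
    double dEdr = 60.0 * t.eps_contact * (s10 - s12) / r;
    double cc = -dEdr / r;
    for (int m = 0; m < 3; m++) { f[3*i+m] += cc * d[m]; f[3*j+m] -= cc * d[m]; }
  }

  // excluded volume: E = eps_ex [(r_excl/r)^12 - (r_excl/rc)^12] for
  // r < rc (truncated and shifted at the contact cutoff, so the native
  // structure is an exact stationary point), on non-contact pairs
  double re2 = t.r_excl * t.r_excl;
  double rc2 = t.excl_cut * t.excl_cut;
  double sc2 = re2 / rc2;
  double shift12 = sc2 * sc2 * sc2 * sc2 * sc2 * sc2;
  for (int c = 0; c < t.excl.nrow(); c++) {
    int i = t.excl(c, 0), j = t.excl(c, 1);
    double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
    double r2 = dot3(d, d);
    if (r2 < 1e-12) stop("overlapping atoms in pair %d-%d", i + 1, j + 1);
    if (r2 >= rc2) continue;
    double s2 = re2 / r2;
    double s12 = s2 * s2 * s2 * s2 * s2 * s2;
    eterms[4] += t.eps_excl * (s12 - shift12);
    double dEdr_over_r = -12.0 * t.eps_excl * s12 / r2;
    double cc = -dEdr_over_r;
    for (int m = 0; m < 3; m++) { f[3*i+m] += cc * d[m]; f[3*j+m] -= cc * d[m]; }
  }
}

// [[Rcpp::export]]
List cpp_go_energy_forces(NumericMatrix coords, List top) {
  GoTop t = unpack_top(top);
  int N = coords.nrow();
  std::vector<double> x(3 * N), f(3 * N);
  for (int i = 0; i < N; i++)
    for (int m = 0; m < 3; m++) x[3*i+m] = coords(i, m);
  double eterms[5];
  go_eval(t, x.data(), N, f.data(), eterms);
  NumericMatrix fm(N, 3);
  for (int i = 0; i < N; i++)
    for (int m = 0; m < 3; m++) fm(i, m) = f[3*i+m];
  NumericVector et = NumericVector::create(
    _["bond"] = eterms[0], _["angle"] = eterms[1], _["dihedral"] = eterms[2],
    _["contact"] = eterms[3], _["excluded"] = eterms[4]);
  return List::create(_["terms"] = et,
                      _["total"] = eterms[0] + eterms[1] + eterms[2] +
                                   eterms[3] + eterms[4],
                      _["forces"] = fm);
}

// ---------------------------------------------------------------------------
// Gaussian rendering (images and volumes), grid coordinate of index i
// (0-based) is (i - D/2) * spacing; atoms truncated at 4 sigma.
// ---------------------------------------------------------------------------

static const double TRUNC_SIG = 4.0;

// [[Rcpp::export]]
NumericMatrix cpp_render_image(NumericMatrix pos, int D, double px,
                               double sigma) {
  // pos: N x 2 positions in Angstrom (already posed/projected)
  int N = pos.nrow();
  NumericMatrix img(D, D);
  int w = (int)std::ceil(TRUNC_SIG * sigma / px);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<double> gx(2 * w + 1), gy(2 * w + 1);
  for (int a = 0; a < N; a++) {
    double pxa = pos(a, 0), pya = pos(a, 1);
    int jc = (int)std::lround(pxa / px + D / 2);
    int kc = (int)std::lround(pya / px + D / 2);
    int jlo = std::max(0, jc - w), jhi = std::min(D - 1, jc + w);
    int klo = std::max(0, kc - w), khi = std::min(D - 1, kc + w);
    if (jlo > jhi || klo > khi) continue;
    for (int j = jlo; j <= jhi; j++) {
      double dx = (j - D / 2) * px - pxa;
      gx[j - jlo] = std::exp(-dx * dx * inv2s2);
    }
    for (int k = klo; k <= khi; k++) {
      double dy = (k - D / 2) * px - pya;
      gy[k - klo] = std::exp(-dy * dy * inv2s2);
    }
    for (int k = klo; k <= khi; k++)
      for (int j = jlo; j <= jhi; j++)
        img(j, k) += gx[j - jlo] * gy[k - klo];
  }
  return img;
}

// [[Rcpp::export]]
NumericVector cpp_render_volume(NumericMatrix pos, int D, double vx,
                                double sigma) {
  // pos: N x 3 in Angstrom; returns D^3 vector, index x + D*y + D^2*z
  int N = pos.nrow();
  NumericVector vol(D * D * D);
  int w = (int)std::ceil(TRUNC_SIG * sigma / vx);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<double> gx(2 * w + 1), gy(2 * w + 1), gz(2 * w + 1);
  for (int a = 0; a < N; a++) {
    double pa[3] = {pos(a, 0), pos(a, 1), pos(a, 2)};
    int c[3], lo[3], hi[3];
    for (int m = 0; m < 3; m++) {
      c[m] = (int)std::lround(pa[m] / vx + D / 2);
      lo[m] = std::max(0, c[m] - w);
      hi[m] = std::min(D - 1, c[m] + w);
    }
    if (lo[0] > hi[0] || lo[1] > hi[1] || lo[2] > hi[2]) continue;
    for (int i = lo[0]; i <= hi[0]; i++) {
      double d = (i - D / 2) * vx - pa[0]; gx[i - lo[0]] = std::exp(-d * d * inv2s2);
    }
    for (int i = lo[1]; i <= hi[1]; i++) {
      double d = (i - D / 2) * vx - pa[1]; gy[i - lo[1]] = std::exp(-d * d * inv2s2);
    }
    for (int i = lo[2]; i <= hi[2]; i++) {
      double d = (i - D / 2) * vx - pa[2]; gz[i - lo[2]] = std::exp(-d * d * inv2s2);
    }
    for (int k = lo[2]; k <= hi[2]; k++)
      for (int j = lo[1]; j <= hi[1]; j++) {
        double gyz = gy[j - lo[1]] * gz[k - lo[2]];
        double* col = &vol[0] + D * j + D * D * k;
        for (int i = lo[0]; i <= hi[0]; i++)
          col[i] += gx[i - lo[0]] * gyz;
      }
  }
  return vol;
}

// CC between rendered density and (zero-mean) data, plus gradient of CC with
// respect to the 2-D/3-D atom positions. data must have nonzero variance.
// dim = 2 (image, data length D*D) or 3 (volume, data length D^3).
static double cc_grad(const NumericMatrix& pos, const double* data, int D,
                      double spacing, double sigma, int dim, double* grad,
                      bool nothrow = false) {
  int N = pos.nrow();
  long P = 1; for (int m = 0; m < dim; m++) P *= D;
  std::vector<double> sim(P, 0.0);
  // pass 1: render
  if (dim == 2) {
    NumericMatrix posm(const_cast<NumericMatrix&>(pos));
    NumericMatrix img = cpp_render_image(posm, D, spacing, sigma);
    for (long p = 0; p < P; p++) sim[p] = img[p];
  } else {
    NumericMatrix posm(const_cast<NumericMatrix&>(pos));
    NumericVector v = cpp_render_volume(posm, D, spacing, sigma);
    for (long p = 0; p < P; p++) sim[p] = v[p];
  }
  double ma = 0.0, mb = 0.0;
  for (long p = 0; p < P; p++) { ma += sim[p]; mb += data[p]; }
  ma /= P; mb /= P;
  double saa = 0.0, sbb = 0.0, sab = 0.0;
  for (long p = 0; p < P; p++) {
    double a = sim[p] - ma, b = data[p] - mb;
    saa += a * a; sbb += b * b; sab += a * b;
  }
  if (saa < 1e-300 || sbb < 1e-300) {
    if (nothrow) {   // e.g. model left the box mid-run: caller flags it
      for (int i = 0; i < dim * pos.nrow(); i++) grad[i] = 0.0;
      return NA_REAL;
    }
    if (saa < 1e-300) stop("zero-variance simulated density");
    stop("zero-variance data");
  }
  double na = std::sqrt(saa), nb = std::sqrt(sbb);
  double cc = sab / (na * nb);
  // weight image W_p = dCC/dI_p  (means drop out: both a and b are zero-mean)
  std::vector<double> W(P);
  for (long p = 0; p < P; p++) {
    double a = sim[p] - ma, b = data[p] - mb;
    W[p] = b / (na * nb) - cc * a / saa;
  }
  // pass 2: gradient per atom over its stencil
  int w = (int)std::ceil(TRUNC_SIG * sigma / spacing);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma), invs2 = 1.0 / (sigma * sigma);
  std::vector<double> g[3], dgr[3];
  for (int m = 0; m < dim; m++) { g[m].resize(2 * w + 1); dgr[m].resize(2 * w + 1); }
  for (int a = 0; a < N; a++) {
    double pa[3] = {0, 0, 0};
    for (int m = 0; m < dim; m++) pa[m] = pos(a, m);
    int lo[3] = {0, 0, 0}, hi[3] = {0, 0, 0};
    bool empty = false;
    for (int m = 0; m < dim; m++) {
      int c = (int)std::lround(pa[m] / spacing + D / 2);
      lo[m] = std::max(0, c - w); hi[m] = std::min(D - 1, c + w);
      if (lo[m] > hi[m]) empty = true;
      for (int i = lo[m]; i <= hi[m]; i++) {
        double d = (i - D / 2) * spacing - pa[m];
        double e = std::exp(-d * d * inv2s2);
        g[m][i - lo[m]] = e;
        dgr[m][i - lo[m]] = d * invs2 * e; // dG/dp = (c - p)/sigma^2 * G
      }
    }
    for (int m = 0; m < dim; m++) grad[a * dim + m] = 0.0;
    if (empty) continue;
    if (dim == 2) {
      for (int k = lo[1]; k <= hi[1]; k++)
        for (int j = lo[0]; j <= hi[0]; j++) {
          double Wp = W[j + (long)D * k];
          grad[a * 2]     += Wp * dgr[0][j - lo[0]] * g[1][k - lo[1]];
          grad[a * 2 + 1] += Wp * g[0][j - lo[0]] * dgr[1][k - lo[1]];
        }
    } else {
      for (int k = lo[2]; k <= hi[2]; k++)
        for (int j = lo[1]; j <= hi[1]; j++) {
          long base = (long)D * j + (long)D * D * k;
          double gy_ = g[1][j - lo[1]], gz_ = g[2][k - lo[2]];
          double dgy = dgr[1][j - lo[1]], dgz = dgr[2][k - lo[2]];
          for (int i = lo[0]; i <= hi[0]; i++) {
            double Wp = W[base + i];
            grad[a * 3]     += Wp * dgr[0][i - lo[0]] * gy_ * gz_;
            grad[a * 3 + 1] += Wp * g[0][i - lo[0]] * dgy * gz_;
            grad[a * 3 + 2] += Wp * g[0][i - lo[0]] * gy_ * dgz;
          }
        }
    }
  }
  return cc;
}

// [[Rcpp::export]]
List cpp_cc_grad_image(NumericMatrix pos2, NumericVector data, int D,
                       double px, double sigma) {
  int N = pos2.nrow();
  std::vector<double> grad(2 * N);
  double cc = cc_grad(pos2, &data[0], D, px, sigma, 2, grad.data());
  NumericMatrix g(N, 2);
  for (int i = 0; i < N; i++) { g(i, 0) = grad[2*i]; g(i, 1) = grad[2*i+1]; }
  return List::create(_["cc"] = cc, _["grad"] = g);
}

// [[Rcpp::export]]
List cpp_cc_grad_volume(NumericMatrix pos3, NumericVector data, int D,
                        double vx, double sigma) {
  int N = pos3.nrow();
  std::vector<double> grad(3 * N);
  double cc = cc_grad(pos3, &data[0], D, vx, sigma, 3, grad.data());
  NumericMatrix g(N, 3);
  for (int i = 0; i < N; i++)
    for (int m = 0; m < 3; m++) g(i, m) = grad[3*i+m];
  return List::create(_["cc"] = cc, _["grad"] = g);
}

// ---------------------------------------------------------------------------
// NMMD integration: BAOAB Langevin Velocity Verlet over atomic coordinates
// plus normal-mode amplitudes with their own inertia and time step.
// ---------------------------------------------------------------------------

struct BiasCtx {
  int kind;                  // 0 none, 1 image, 2 volume
  const double* data;
  double R[9];               // pose rotation, row-major
  double shift[3];           // Angstrom
  int D;
  double spacing, sigma, k_bias;
};

// adds k_bias * dCC/dx to f; returns CC
static double bias_eval(const BiasCtx& b, const double* x, int N, double* f,
                        std::vector<double>& pbuf, std::vector<double>& gbuf) {
  int dim = (b.kind == 1) ? 2 : 3;
  NumericMatrix pos(N, dim);
  for (int i = 0; i < N; i++) {
    double p[3];
    for (int m = 0; m < 3; m++)
      p[m] = b.R[3*m] * x[3*i] + b.R[3*m+1] * x[3*i+1] + b.R[3*m+2] * x[3*i+2];
    for (int m = 0; m < dim; m++) pos(i, m) = p[m] + b.shift[m];
  }
  gbuf.resize((size_t)dim * N);
  double cc = cc_grad(pos, b.data, b.D, b.spacing, b.sigma, dim, gbuf.data(),
                      true);
  if (ISNAN(cc)) return cc;
  // chain rule through the pose rotation: dCC/dx = R^T (rows 1..dim) * grad
  for (int i = 0; i < N; i++)
    for (int m = 0; m < 3; m++) {
      double s = 0.0;
      for (int d = 0; d < dim; d++) s += b.R[3*d+m] * gbuf[(size_t)dim*i + d];
      f[3*i+m] += b.k_bias * s;
    }
  return cc;
}

class Gauss {
  std::mt19937_64 rng;
  bool has_spare = false;
  double spare = 0.0;
public:
  explicit Gauss(uint64_t seed) : rng(seed) {}
  double operator()() {
    if (has_spare) { has_spare = false; return spare; }
    // Box-Muller on uniforms in (0,1]
    double u1, u2;
    do { u1 = (rng() >> 11) * (1.0 / 9007199254740992.0); } while (u1 <= 0.0);
    u2 = (rng() >> 11) * (1.0 / 9007199254740992.0);
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    has_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// [[Rcpp::export]]
List cpp_run_nmmd(NumericMatrix coords0, NumericMatrix vel0,
                  NumericVector masses, List top,
                  NumericMatrix modes, NumericVector q0, NumericVector qdot0,
                  int n_steps, double dt, double nm_dt, double nm_mass,
                  double temperature, double friction, double kB,
                  int bias_kind, NumericVector data, NumericMatrix rot,
                  NumericVector shift, int D, double spacing, double sigma,
                  double k_bias, int record_every, double seed,
                  bool record_coords) {
  GoTop t = unpack_top(top);
  int N = coords0.nrow();
  int M = modes.ncol();
  std::vector<double> x(3 * N), v(3 * N), f(3 * N), x0(3 * N);
  std::vector<double> q(M), qd(M), fm(M);
  for (int i = 0; i < N; i++)
    for (int m = 0; m < 3; m++) {
      x[3*i+m] = coords0(i, m); v[3*i+m] = vel0(i, m);
      x0[3*i+m] = x[3*i+m];
    }
  for (int m = 0; m < M; m++) { q[m] = q0[m]; qd[m] = qdot0[m]; }

  BiasCtx bc; bc.kind = bias_kind;
  bc.data = (data.size() > 0) ? &data[0] : nullptr;
  for (int i = 0; i < 3; i++) {
    bc.shift[i] = (i < shift.size()) ? shift[i] : 0.0;
    for (int j = 0; j < 3; j++) bc.R[3*i+j] = rot(i, j);
  }
  bc.D = D; bc.spacing = spacing; bc.sigma = sigma; bc.k_bias = k_bias;

  Gauss gauss((uint64_t)seed);
  double c1 = std::exp(-friction * dt);
  double c1q = std::exp(-friction * nm_dt);
  double kT = kB * temperature;

  std::vector<double> pbuf, gbuf;
  double eterms[5];
  auto forces = [&](double& epot, double& cc) {
    go_eval(t, x.data(), N, f.data(), eterms);
    epot = eterms[0] + eterms[1] + eterms[2] + eterms[3] + eterms[4];
    cc = NA_REAL;
    if (bc.kind != 0) cc = bias_eval(bc, x.data(), N, f.data(), pbuf, gbuf);
    for (int m = 0; m < M; m++) {
      double s = 0.0;
      for (int i = 0; i < 3 * N; i++) s += modes(i, m) * f[i];
      fm[m] = s;
    }
  };

  double epot, cc;
  forces(epot, cc);

  int n_rec = (record_every > 0) ? (n_steps / record_every + 1) : 1;
  NumericMatrix rec(n_rec, 6);            // step time epot ekin cc rmsd
  NumericMatrix qrec(n_rec, std::max(M, 1));
  NumericVector traj;
  if (record_coords) traj = NumericVector((R_xlen_t)n_rec * 3 * N);
  int ri = 0;
  bool diverged = false;
  int diverge_step = -1;

  auto record = [&](int step) {
    double ekin = 0.0;
    for (int i = 0; i < N; i++) {
      double vv = v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2];
      ekin += 0.5 * masses[i] * vv;
    }
    for (int m = 0; m < M; m++) ekin += 0.5 * nm_mass * qd[m] * qd[m];
    double sd = 0.0;
    for (int i = 0; i < 3 * N; i++) { double d = x[i] - x0[i]; sd += d * d; }
    rec(ri, 0) = step; rec(ri, 1) = step * dt; rec(ri, 2) = epot;
    rec(ri, 3) = ekin; rec(ri, 4) = cc; rec(ri, 5) = std::sqrt(sd / N);
    for (int m = 0; m < M; m++) qrec(ri, m) = q[m];
    if (record_coords)
      for (int i = 0; i < 3 * N; i++) traj[(R_xlen_t)ri * 3 * N + i] = x[i];
    ri++;
  };
  record(0);

  for (int step = 1; step <= n_steps; step++) {
    // B: half kick
    for (int i = 0; i < N; i++)
      for (int m = 0; m < 3; m++) v[3*i+m] += 0.5 * dt * f[3*i+m] / masses[i];
    for (int m = 0; m < M; m++) qd[m] += 0.5 * nm_dt * fm[m] / nm_mass;
    // A: half drift (coordinates move with both velocities and mode rates)
    for (int i = 0; i < 3 * N; i++) x[i] += 0.5 * dt * v[i];
    for (int m = 0; m < M; m++) {
      double dq = 0.5 * nm_dt * qd[m];
      q[m] += dq;
      for (int i = 0; i < 3 * N; i++) x[i] += dq * modes(i, m);
    }
    // O: Ornstein-Uhlenbeck (skipped entirely at T = 0: NVE)
    if (temperature > 0.0) {
      for (int i = 0; i < N; i++) {
        double s = std::sqrt((1.0 - c1 * c1) * kT / masses[i]);
        for (int m = 0; m < 3; m++) v[3*i+m] = c1 * v[3*i+m] + s * gauss();
      }
      double sq = std::sqrt((1.0 - c1q * c1q) * kT / nm_mass);
      for (int m = 0; m < M; m++) qd[m] = c1q * qd[m] + sq * gauss();
    }
    // A: half drift
    for (int i = 0; i < 3 * N; i++) x[i] += 0.5 * dt * v[i];
    for (int m = 0; m < M; m++) {
      double dq = 0.5 * nm_dt * qd[m];
      q[m] += dq;
      for (int i = 0; i < 3 * N; i++) x[i] += dq * modes(i, m);
    }
    // forces at new positions, then B: half kick
    bool bad = false;
    for (int i = 0; i < 3 * N && !bad; i++)
      if (!std::isfinite(x[i])) bad = true;
    if (!bad) {
      forces(epot, cc);
      if (bias_kind != 0 && ISNAN(cc)) bad = true;  // model left the box
      for (int i = 0; i < 3 * N && !bad; i++)
        if (!std::isfinite(f[i])) bad = true;
    }
    if (bad) { diverged = true; diverge_step = step; break; }
    for (int i = 0; i < N; i++)
      for (int m = 0; m < 3; m++) v[3*i+m] += 0.5 * dt * f[3*i+m] / masses[i];
    for (int m = 0; m < M; m++) qd[m] += 0.5 * nm_dt * fm[m] / nm_mass;

    if (record_every > 0 && step % record_every == 0) record(step);
  }

  NumericMatrix xout(N, 3), vout(N, 3);
  for (int i = 0; i < N; i++)
    for (int m = 0; m < 3; m++) { xout(i, m) = x[3*i+m]; vout(i, m) = v[3*i+m]; }
  if (ri < n_rec) {
    rec = rec(Range(0, std::max(ri - 1, 0)), _);
    qrec = qrec(Range(0, std::max(ri - 1, 0)), _);
  }
  List out = List::create(
    _["coords"] = xout, _["velocities"] = vout,
    _["q"] = NumericVector(q.begin(), q.end()),
    _["qdot"] = NumericVector(qd.begin(), qd.end()),
    _["records"] = rec, _["qtraj"] = qrec,
    _["diverged"] = diverged, _["diverge_step"] = diverge_step);
  if (record_coords) {
    traj.attr("dim") = IntegerVector::create(3 * N, n_rec);
    out["coord_traj"] = traj;
  }
  return out;
}
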