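// Mechanical force field for bead-spring filament networks.
//
// Units: nm, pN, pN nm (energy), seconds. A network is passed to C++ as flat
// arrays: a bead coordinate matrix, per-filament offsets, per-cylinder
// equilibrium lengths, and a spring table for bound crosslinkers / motors.
// All energy terms have analytic gradients; tests verify them against central
// finite differences.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  double norm() const { return std::sqrt(dot(*this)); }
};

inline Vec3 get_bead(const NumericMatrix& beads, int i) {
  return Vec3(beads(i, 0), beads(i, 1), beads(i, 2));
}

inline void add_grad(std::vector<double>& g, int i, const Vec3& v) {
  g[3 * i] += v.x;
  g[3 * i + 1] += v.y;
  g[3 * i + 2] += v.z;
}

// Gauss-Legendre nodes/weights on [0,1]
void gauss_legendre01(int n, std::vector<double>& x, std::vector<double>& w) {
  // Newton iteration on Legendre polynomials over [-1,1], then map to [0,1].
  x.resize(n);
  w.resize(n);
  for (int i = 0; i < n; ++i) {
    double xi = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    for (int it = 0; it < 100; ++it) {
      double p0 = 1.0, p1 = xi;
      for (int k = 2; k <= n; ++k) {
        double pk = ((2.0 * k - 1.0) * xi * p1 - (k - 1.0) * p0) / k;
        p0 = p1;
        p1 = pk;
      }
      double dp = n * (xi * p1 - p0) / (xi * xi - 1.0);
      double dx = p1 / dp;
      xi -= dx;
      if (std::fabs(dx) < 1e-15) break;
    }
    double p0 = 1.0, p1 = xi;
    for (int k = 2; k <= n; ++k) {
      double pk = ((2.0 * k - 1.0) * xi * p1 - (k - 1.0) * p0) / k;
      p0 = p1;
      p1 = pk;
    }
    double dp = n * (xi * p1 - p0) / (xi * xi - 1.0);
    x[i] = 0.5 * (xi + 1.0);
    w[i] = 1.0 / ((1.0 - xi * xi) * dp * dp); // = 0.5 * 2/((1-x^2)dp^2)
  }
}

struct Topology {
  // cylinder c: beads cyl_b0[c], cyl_b0[c]+1 ; filament cyl_fil[c]
  std::vector<int> cyl_b0, cyl_fil;
  std::vector<double> l0;
  int nbead;
};

Topology build_topology(const IntegerVector& fil_first,
                        const IntegerVector& fil_nbeads,
                        const NumericVector& l0_eq, int nbead) {
  Topology tp;
  tp.nbead = nbead;
  for (int f = 0; f < fil_first.size(); ++f) {
    for (int b = 0; b < fil_nbeads[f] - 1; ++b) {
      tp.cyl_b0.push_back(fil_first[f] + b);
      tp.cyl_fil.push_back(f);
    }
  }
  if ((int)tp.cyl_b0.size() != l0_eq.size())
    stop("l0_eq length does not match cylinder count");
  tp.l0.assign(l0_eq.begin(), l0_eq.end());
  return tp;
}

const double R_CLAMP = 1.0;   // nm; below this the 1/r^4 kernel is clamped (finite cap)

double evol_pair(const Vec3& A1, const Vec3& A2, const Vec3& B1, const Vec3& B2,
                 double kvol, const std::vector<double>& qx,
                 const std::vector<double>& qw, bool* clamped) {
  double La = (A2 - A1).norm(), Lb = (B2 - B1).norm();
  double acc = 0.0;
  int n = qx.size();
  for (int i = 0; i < n; ++i) {
    Vec3 a = A1 + (A2 - A1) * qx[i];
    for (int j = 0; j < n; ++j) {
      Vec3 b = B1 + (B2 - B1) * qx[j];
      double d = (a - b).norm();
      if (d < R_CLAMP) {
        d = R_CLAMP;
        if (clamped) *clamped = true;
      }
      acc += qw[i] * qw[j] / (d * d * d * d);
    }
  }
  return kvol * La * Lb * acc;
}

// gradient of the pair energy w.r.t. the four endpoints
void evol_pair_grad(const Vec3& A1, const Vec3& A2, const Vec3& B1, const Vec3& B2,
                    double kvol, const std::vector<double>& qx,
                    const std::vector<double>& qw,
                    Vec3& gA1, Vec3& gA2, Vec3& gB1, Vec3& gB2, double& energy) {
  Vec3 ua = A2 - A1, ub = B2 - B1;
  double La = ua.norm(), Lb = ub.norm();
  Vec3 ha = ua * (1.0 / La), hb = ub * (1.0 / Lb); // unit tangents
  int n = qx.size();
  double acc = 0.0;
  Vec3 sA1, sA2, sB1, sB2; // kernel-derivative part
  for (int i = 0; i < n; ++i) {
    Vec3 a = A1 + ua * qx[i];
    for (int j = 0; j < n; ++j) {
      Vec3 b = B1 + ub * qx[j];
      Vec3 r = a - b;
      double d = r.norm();
      double g, gp;
      if (d < R_CLAMP) {
        g = 1.0 / (R_CLAMP * R_CLAMP * R_CLAMP * R_CLAMP);
        gp = 0.0;
      } else {
        g = 1.0 / (d * d * d * d);
        gp = -4.0 * g / d;
      }
      double wij = qw[i] * qw[j];
      acc += wij * g;
      if (gp != 0.0) {
        Vec3 dir = r * (gp / d); // g'(d) * r_hat
        double si = qx[i], sj = qx[j];
        sA1 = sA1 + dir * (wij * (1.0 - si));
        sA2 = sA2 + dir * (wij * si);
        sB1 = sB1 - dir * (wij * (1.0 - sj));
        sB2 = sB2 - dir * (wij * sj);
      }
    }
  }
  energy = kvol * La * Lb * acc;
  // length-Jacobian part: d(La)/dA1 = -ha, d(La)/dA2 = +ha (same for B)
  gA1 = sA1 * (kvol * La * Lb) + ha * (-kvol * Lb * acc);
  gA2 = sA2 * (kvol * La * Lb) + ha * (kvol * Lb * acc);
  gB1 = sB1 * (kvol * La * Lb) + hb * (-kvol * La * acc);
  gB2 = sB2 * (kvol * La * Lb) + hb * (kvol * La * acc);
}

inline double seg_midpoint_dist2(const NumericMatrix& beads, int a0, int b0) {
  double mx = 0.5 * (beads(a0, 0) + beads(a0 + 1, 0)) - 0.5 * (beads(b0, 0) + beads(b0 + 1, 0));
  double my = 0.5 * (beads(a0, 1) + beads(a0 + 1, 1)) - 0.5 * (beads(b0, 1) + beads(b0 + 1, 1));
  double mz = 0.5 * (beads(a0, 2) + beads(a0 + 1, 2)) - 0.5 * (beads(b0, 2) + beads(b0 + 1, 2));
  return mx * mx + my * my + mz * mz;
}

struct EnergyBreakdown {
  double stretch = 0, bend = 0, evol = 0, spring = 0, wall = 0;
  bool clamped = false;
  double total() const { return stretch + bend + evol + spring + wall; }
};

// springs: columns b0a, b1a, fraca, b0b, b1b, fracb, k, L0  (bead indices 0-based)
EnergyBreakdown network_energy_grad(const NumericMatrix& beads, const Topology& tp,
                                    double kstr_scale, double kbend, double kvol,
                                    const NumericMatrix& springs,
                                    const NumericVector& box, double kwall,
                                    double evol_rcut, int nquad,
                                    std::vector<double>* grad) {
  EnergyBreakdown eb;
  int ncyl = tp.cyl_b0.size();
  if (grad) std::fill(grad->begin(), grad->end(), 0.0);

  // stretching: (k/2)(l - l0)^2
  for (int c = 0; c < ncyl; ++c) {
    int i = tp.cyl_b0[c];
    Vec3 d = get_bead(beads, i + 1) - get_bead(beads, i);
    double l = d.norm();
    if (l <= 1e-9) stop("degenerate cylinder (zero length)");
    double dl = l - tp.l0[c];
    eb.stretch += 0.5 * kstr_scale * dl * dl;
    if (grad) {
      Vec3 g = d * (kstr_scale * dl / l);
      add_grad(*grad, i, g * (-1.0));
      add_grad(*grad, i + 1, g);
    }
  }

  // bending: k_bend (1 - cos theta) at interior hinges
  for (int c = 0; c + 1 < ncyl; ++c) {
    if (tp.cyl_fil[c] != tp.cyl_fil[c + 1]) continue;
    int i = tp.cyl_b0[c];
    Vec3 r1 = get_bead(beads, i + 1) - get_bead(beads, i);
    Vec3 r2 = get_bead(beads, i + 2) - get_bead(beads, i + 1);
    double l1 = r1.norm(), l2 = r2.norm();
    if (l1 <= 1e-9 || l2 <= 1e-9) stop("zero-length tangent in bending term");
    double ct = r1.dot(r2) / (l1 * l2);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
    eb.bend += kbend * (1.0 - ct);
    if (grad) {
      // d(cos)/dr1 = r2/(l1 l2) - ct r1/l1^2 ; d(cos)/dr2 = r1/(l1 l2) - ct r2/l2^2
      Vec3 dc1 = r2 * (1.0 / (l1 * l2)) - r1 * (ct / (l1 * l1));
      Vec3 dc2 = r1 * (1.0 / (l1 * l2)) - r2 * (ct / (l2 * l2));
      // E = kbend (1 - ct): dE/dx = -kbend * dct/dx; r1 = x(i+1)-x(i), r2 = x(i+2)-x(i+1)
      add_grad(*grad, i, dc1 * kbend);
      add_grad(*grad, i + 1, (dc2 - dc1) * kbend);
      add_grad(*grad, i + 2, dc2 * (-kbend));
    }
  }

  // excluded volume between cylinder pairs (different filaments, or same
  // filament separated by >= 2 positions), within a midpoint cutoff
  if (kvol > 0) {
    std::vector<double> qx, qw;
    gauss_legendre01(nquad, qx, qw);
    double max_l = 0;
    for (int c = 0; c < ncyl; ++c) max_l = std::max(max_l, tp.l0[c]);
    double rc2 = (evol_rcut + max_l) * (evol_rcut + max_l);
    for (int a = 0; a < ncyl; ++a) {
      for (int b = a + 1; b < ncyl; ++b) {
        if (tp.cyl_fil[a] == tp.cyl_fil[b] && (b - a) < 2) continue;
        if (seg_midpoint_dist2(beads, tp.cyl_b0[a], tp.cyl_b0[b]) > rc2) continue;
        int ia = tp.cyl_b0[a], ib = tp.cyl_b0[b];
        if (grad) {
          Vec3 g1, g2, g3, g4;
          double e;
          evol_pair_grad(get_bead(beads, ia), get_bead(beads, ia + 1),
                         get_bead(beads, ib), get_bead(beads, ib + 1),
                         kvol, qx, qw, g1, g2, g3, g4, e);
          eb.evol += e;
          add_grad(*grad, ia, g1);
          add_grad(*grad, ia + 1, g2);
          add_grad(*grad, ib, g3);
          add_grad(*grad, ib + 1, g4);
        } else {
          eb.evol += evol_pair(get_bead(beads, ia), get_bead(beads, ia + 1),
                               get_bead(beads, ib), get_bead(beads, ib + 1),
                               kvol, qx, qw, &eb.clamped);
        }
      }
    }
  }

  // linker / motor springs: (k/2)(d - L0)^2 between fractional attachment points
  for (int s = 0; s < springs.nrow(); ++s) {
    int a0 = (int)springs(s, 0), a1 = (int)springs(s, 1);
    int b0 = (int)springs(s, 3), b1 = (int)springs(s, 4);
    double fa = springs(s, 2), fb = springs(s, 5);
    double k = springs(s, 6), L0 = springs(s, 7);
    Vec3 pa = get_bead(beads, a0) * (1.0 - fa) + get_bead(beads, a1) * fa;
    Vec3 pb = get_bead(beads, b0) * (1.0 - fb) + get_bead(beads, b1) * fb;
    Vec3 r = pa - pb;
    double d = r.norm();
    double dl = d - L0;
    eb.spring += 0.5 * k * dl * dl;
    if (grad && d > 1e-12) {
      Vec3 g = r * (k * dl / d);
      add_grad(*grad, a0, g * (1.0 - fa));
      add_grad(*grad, a1, g * fa);
      add_grad(*grad, b0, g * (-(1.0 - fb)));
      add_grad(*grad, b1, g * (-fb));
    }
  }

  // harmonic wall keeping beads inside the box
  if (kwall > 0 && box.size() == 6) {
    for (int i = 0; i < beads.nrow(); ++i) {
      for (int dim = 0; dim < 3; ++dim) {
        double lo = box[2 * dim], hi = box[2 * dim + 1];
        double x = beads(i, dim);
        double v = 0;
        if (x < lo) v = x - lo;
        else if (x > hi) v = x - hi;
        if (v != 0) {
          eb.wall += 0.5 * kwall * v * v;
          if (grad) (*grad)[3 * i + dim] += kwall * v;
        }
      }
    }
  }
  return eb;
}

} // namespace

// [[Rcpp::export]]
List net_energy_cpp(NumericMatrix beads, IntegerVector fil_first,
                    IntegerVector fil_nbeads, NumericVector l0_eq,
                    double kstr, double kbend, double kvol,
                    NumericMatrix springs, NumericVector box, double kwall,
                    double evol_rcut, int nquad) {
  Topology tp = build_topology(fil_first, fil_nbeads, l0_eq, beads.nrow());
  EnergyBreakdown eb = network_energy_grad(beads, tp, kstr, kbend, kvol, springs,
                                           box, kwall, evol_rcut, nquad, nullptr);
  return List::create(_["total"] = eb.total(), _["stretch"] = eb.stretch,
                      _["bend"] = eb.bend, _["evol"] = eb.evol,
                      _["spring"] = eb.spring, _["wall"] = eb.wall,
                      _["clamped"] = eb.clamped);
}

// [[Rcpp::export]]
NumericMatrix net_grad_cpp(NumericMatrix beads, IntegerVector fil_first,
                           IntegerVector fil_nbeads, NumericVector l0_eq,
                           double kstr, double kbend, double kvol,
                           NumericMatrix springs, NumericVector box, double kwall,
                           double evol_rcut, int nquad) {
  Topology tp = build_topology(fil_first, fil_nbeads, l0_eq, beads.nrow());
  std::vector<double> grad(3 * beads.nrow());
  network_energy_grad(beads, tp, kstr, kbend, kvol, springs, box, kwall,
                      evol_rcut, nquad, &grad);
  NumericMatrix out(beads.nrow(), 3);
  for (int i = 0; i < beads.nrow(); ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = grad[3 * i + d];
  return out;
}

// [[Rcpp::export]]
double evol_pair_cpp(NumericVector a1, NumericVector a2, NumericVector b1,
                     NumericVector b2, double kvol, int nquad) {
  std::vector<double> qx, qw;
  gauss_legendre01(nquad, qx, qw);
  bool clamped = false;
  return evol_pair(Vec3(a1[0], a1[1], a1[2]), Vec3(a2[0], a2[1], a2[2]),
                   Vec3(b1[0], b1[1], b1[2]), Vec3(b2[0], b2[1], b2[2]),
                   kvol, qx, qw, &clamped);
}

// Polak-Ribiere conjugate gradient with restarts and Armijo backtracking.
// [[Rcpp::export]]
List minimize_cpp(NumericMatrix beads, IntegerVector fil_first,
                  IntegerVector fil_nbeads, NumericVector l0_eq,
                  double kstr, double kbend, double kvol,
                  NumericMatrix springs, NumericVector box, double kwall,
                  double evol_rcut, int nquad, double ftol, int maxiter) {
  Topology tp = build_topology(fil_first, fil_nbeads, l0_eq, beads.nrow());
  int n = 3 * beads.nrow();
  NumericMatrix x = clone(beads);
  std::vector<double> g(n), gprev(n), dir(n);

  auto energy_of = [&](const NumericMatrix& b) {
    return network_energy_grad(b, tp, kstr, kbend, kvol, springs, box, kwall,
                               evol_rcut, nquad, nullptr).total();
  };
  auto grad_at = [&](const NumericMatrix& b, std::vector<double>& gg) {
    return network_energy_grad(b, tp, kstr, kbend, kvol, springs, box, kwall,
                               evol_rcut, nquad, &gg).total();
  };

  double E = grad_at(x, g);
  double maxf = 0;
  for (int i = 0; i < n; ++i) maxf = std::max(maxf, std::fabs(g[i]));
  for (int i = 0; i < n; ++i) dir[i] = -g[i];
  double step = 1e-2;
  int it = 0;
  bool converged = maxf <= ftol;

  NumericMatrix xtrial(beads.nrow(), 3);
  while (!converged && it < maxiter) {
    ++it;
    double gd = 0, gg2 = 0;
    for (int i = 0; i < n; ++i) {
      gd += g[i] * dir[i];
      gg2 += g[i] * g[i];
    }
    if (gd >= 0) { // not a descent direction: restart on steepest descent
      for (int i = 0; i < n; ++i) dir[i] = -g[i];
      gd = -gg2;
    }
    // Armijo with quadratic interpolation; initial step from the previous
    // accepted step scaled by the directional derivative
    double t = step;
    double Enew = E;
    bool accepted = false;
    for (int ls = 0; ls < 40; ++ls) {
      for (int i = 0; i < beads.nrow(); ++i)
        for (int d = 0; d < 3; ++d)
          xtrial(i, d) = x(i, d) + t * dir[3 * i + d];
      Enew = energy_of(xtrial);
      if (Enew <= E + 1e-4 * t * gd) {
        accepted = true;
        break;
      }
      // minimizer of the quadratic through (0,E), slope gd, (t,Enew)
      double denom = Enew - E - gd * t;
      double tq = (denom > 0) ? -0.5 * gd * t * t / denom : 0.5 * t;
      t = std::min(std::max(tq, 0.1 * t), 0.5 * t);
    }
    if (!accepted) { // cannot decrease along dir: restart or give up
      bool sd = true;
      for (int i = 0; i < n; ++i)
        if (dir[i] != -g[i]) { sd = false; break; }
      if (sd) break;
      for (int i = 0; i < n; ++i) dir[i] = -g[i];
      continue;
    }
    // adapt initial step for next iteration
    step = std::min(std::max(t * 2.0, 1e-6), 50.0);
    x = clone(xtrial);
    gprev = g;
    E = grad_at(x, g);
    maxf = 0;
    for (int i = 0; i < n; ++i) maxf = std::max(maxf, std::fabs(g[i]));
    if (maxf <= ftol) {
      converged = true;
      break;
    }
    // Polak-Ribiere beta with restart every 3N iterations or on negative beta
    double num = 0, den = 0;
    for (int i = 0; i < n; ++i) {
      num += g[i] * (g[i] - gprev[i]);
      den += gprev[i] * gprev[i];
    }
    double beta = (den > 0) ? std::max(0.0, num / den) : 0.0;
    if (it % (3 * n) == 0) beta = 0.0;
    for (int i = 0; i < n; ++i) dir[i] = -g[i] + beta * dir[i];
  }

  return List::create(_["beads"] = x, _["converged"] = converged,
                      _["iterations"] = it, _["max_force"] = maxf,
                      _["energy"] = E);
}

// All unordered site pairs on distinct filaments with separation in [dmin, dmax].
// sites: n x 3 coordinates; site_fil: filament id per site (any integer coding).
// [[Rcpp::export]]
IntegerMatrix eligible_pairs_cpp(NumericMatrix sites, IntegerVector site_fil,
                                 double dmin, double dmax) {
  int n = sites.nrow();
  std::vector<int> ia, ib;
  double lo2 = dmin * dmin, hi2 = dmax * dmax;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (site_fil[i] == site_fil[j]) continue;
      double dx = sites(i, 0) - sites(j, 0);
      if (std::fabs(dx) > dmax) continue;
      double dy = sites(i, 1) - sites(j, 1);
      double dz = sites(i, 2) - sites(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= lo2 && d2 <= hi2) {
        ia.push_back(i + 1); // 1-based for R
        ib.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(ia.size(), 2);
  for (size_t k = 0; k < ia.size(); ++k) {
    out(k, 0) = ia[k];
    out(k, 1) = ib[k];
  }
  return out;
}
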