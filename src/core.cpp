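#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Direction codes used throughout (columns of nbr/pspr): 0=R(+x) 1=L(-x)
// 2=U(+y) 3=D(-y). x-oriented springs live in slots 0/1, y-oriented in 2/3.

namespace {

struct Lattice {
  int n;
  const int *nbr;    // n x 4, 1-based ids, 0 = absent (column-major)
  const int *pspr;   // n x 4, spring ids
  const int *sa, *sb, *sor;
  const double *srest;
  int nspring;
  const int *constraint;   // 0 free, 1 fixed, 2 y-frozen, 3 x-frozen
  const double *fixx, *fixy;
  const int *cycle; int ncycle;  // CCW boundary, 1-based ids
  double lamx, mux, lamy, muy, pt;
  bool hinges;
};

inline int NB(const Lattice &L, int i, int d) { return L.nbr[d * L.n + i] - 1; }
inline double REST(const Lattice &L, int i, int d) {
  int s = L.pspr[d * L.n + i] - 1;
  return s >= 0 ? L.srest[s] : -1.0;
}

// synthesize the missing spring vector of a loose point from the auxiliary
// point (midpoint of the spring between next-next neighbors); rest length is
// copied from the left (missing y) or upper (missing x) neighbor
inline bool aux_vector(const Lattice &L, const std::vector<double> &X,
                       const std::vector<double> &Y, int i, int d,
                       double &vx, double &vy, double &rest) {
  int p1, p2;
  if (d <= 1) { p1 = NB(L, i, 2); p2 = NB(L, i, 3); }   // missing x: use U/D
  else        { p1 = NB(L, i, 1); p2 = NB(L, i, 0); }   // missing y: use L/R
  if (p1 < 0 || p2 < 0) return false;
  int q1 = NB(L, p1, d), q2 = NB(L, p2, d);
  if (q1 < 0 || q2 < 0) return false;
  vx = 0.5 * (X[q1] + X[q2]) - X[i];
  vy = 0.5 * (Y[q1] + Y[q2]) - Y[i];
  rest = REST(L, p1, d);              // left neighbor for missing y, upper for x
  if (rest < 0) rest = REST(L, p2, d);
  if (rest < 0) return false;
  return true;
}

struct Hinge {
  double xx, xy;   // x-side vector
  double yx, yy;   // y-side vector
  double x0, y0;   // rest lengths
  bool ok;
};

// collect up to four hinges cornered at i (auxiliary vectors for loose points)
inline int point_hinges(const Lattice &L, const std::vector<double> &X,
                        const std::vector<double> &Y, int i, Hinge h[4],
                        int dxs[4], int dys[4]) {
  double axv[2][3]; bool axok[2];   // aux for x dirs R,L
  double ayv[2][3]; bool ayok[2];   // aux for y dirs U,D
  for (int k = 0; k < 2; ++k) {
    axok[k] = ayok[k] = false;
    if (NB(L, i, k) < 0)
      axok[k] = aux_vector(L, X, Y, i, k, axv[k][0], axv[k][1], axv[k][2]);
    if (NB(L, i, 2 + k) < 0)
      ayok[k] = aux_vector(L, X, Y, i, 2 + k, ayv[k][0], ayv[k][1], ayv[k][2]);
  }
  int nh = 0;
  for (int dx = 0; dx < 2; ++dx) {
    int jx = NB(L, i, dx);
    bool xa = jx < 0 && axok[dx];
    if (jx < 0 && !xa) continue;
    for (int dy = 0; dy < 2; ++dy) {
      int jy = NB(L, i, 2 + dy);
      bool ya = jy < 0 && ayok[dy];
      if (jy < 0 && !ya) continue;
      if (xa && ya) continue;  // never synthesize both arms
      Hinge &hh = h[nh];
      if (xa) { hh.xx = axv[dx][0]; hh.xy = axv[dx][1]; hh.x0 = axv[dx][2]; }
      else    { hh.xx = X[jx] - X[i]; hh.xy = Y[jx] - Y[i]; hh.x0 = REST(L, i, dx); }
      if (ya) { hh.yx = ayv[dy][0]; hh.yy = ayv[dy][1]; hh.y0 = ayv[dy][2]; }
      else    { hh.yx = X[jy] - X[i]; hh.yy = Y[jy] - Y[i]; hh.y0 = REST(L, i, 2 + dy); }
      hh.ok = true;
      dxs[nh] = dx; dys[nh] = dy;
      ++nh;
    }
  }
  return nh;
}

// mean current area of the unit cells incident on i; quad (shoelace) area
// when the fourth corner exists, parallelogram area otherwise
inline double mean_area(const Lattice &L, const std::vector<double> &X,
                        const std::vector<double> &Y, int i) {
  Hinge h[4]; int dxs[4], dys[4];
  int nh = point_hinges(L, X, Y, i, h, dxs, dys);
  if (nh == 0) {
    // degenerate lattices (chains): fall back to rest-geometry area
    double acc = 0; int c = 0;
    for (int d = 0; d < 4; ++d) {
      double r = REST(L, i, d);
      if (r > 0) {
        double rp = -1; int po = d <= 1 ? 2 : 0;
        double rsum = 0; int rc = 0;
        for (int k = 0; k < 2; ++k) {
          double rr = REST(L, i, po + k);
          if (rr > 0) { rsum += rr; ++rc; }
        }
        rp = rc > 0 ? rsum / rc : r;
        acc += r * rp; ++c;
      }
    }
    return c > 0 ? acc / c : 0.0;
  }
  double acc = 0;
  for (int k = 0; k < nh; ++k) {
    const Hinge &hh = h[k];
    int jx = NB(L, i, dxs[k]);
    int j4 = jx >= 0 ? NB(L, jx, 2 + dys[k]) : -1;
    int jy = NB(L, i, 2 + dys[k]);
    if (j4 >= 0 && jy >= 0) {
      // perimeter i -> jx -> j4 -> jy
      double x0 = X[i], y0 = Y[i], x1 = X[jx], y1 = Y[jx];
      double x2 = X[j4], y2 = Y[j4], x3 = X[jy], y3 = Y[jy];
      double sh = 0.5 * ((x0 * y1 - x1 * y0) + (x1 * y2 - x2 * y1) +
                         (x2 * y3 - x3 * y2) + (x3 * y0 - x0 * y3));
      acc += std::fabs(sh);
    } else {
      acc += std::fabs(hh.xx * hh.yy - hh.xy * hh.yx);
    }
  }
  return acc / nh;
}

// elastic (spring + hinge) forces; also fills per-point mean cell area
void elastic_assemble(const Lattice &L, const std::vector<double> &X,
                      const std::vector<double> &Y, std::vector<double> &FX,
                      std::vector<double> &FY) {
  int n = L.n;
  std::vector<double> se(2 * n, 0.0), sr(2 * n, 0.0);
  std::vector<int> sc(2 * n, 0);
  // per-point mean strain / mean rest of incident springs, by orientation
  for (int s = 0; s < L.nspring; ++s) {
    int a = L.sa[s] - 1, b = L.sb[s] - 1, o = L.sor[s] - 1;  // o: 0=x 1=y
    double dx = X[b] - X[a], dy = Y[b] - Y[a];
    double len = std::sqrt(dx * dx + dy * dy);
    double e = (len - L.srest[s]) / L.srest[s];
    se[o * n + a] += e; se[o * n + b] += e;
    sr[o * n + a] += L.srest[s]; sr[o * n + b] += L.srest[s];
    sc[o * n + a] += 1; sc[o * n + b] += 1;
  }
  for (int i = 0; i < n; ++i) {
    double A = mean_area(L, X, Y, i);
    // direct + Poisson spring terms with the analytic strain derivatives
    for (int d = 0; d < 4; ++d) {
      int j = NB(L, i, d);
      if (j < 0) continue;
      double dx = X[j] - X[i], dy = Y[j] - Y[i];
      double len = std::sqrt(dx * dx + dy * dy);
      double x0 = REST(L, i, d);
      double e = (len - x0) / x0;
      int o = d <= 1 ? 0 : 1, po = 1 - o;
      double ebar = sc[po * n + i] > 0 ? se[po * n + i] / sc[po * n + i] : 0.0;
      double p0m = sc[po * n + i] > 0 ? sr[po * n + i] / sc[po * n + i] : x0;
      double lam = o == 0 ? L.lamx : L.lamy;
      double mu = o == 0 ? L.mux : L.muy;
      double base = A / (x0 * p0m);
      double Cdir = (lam + 2.0 * mu) * base;
      double Ccross = lam * base;
      double coef = (Cdir * e + Ccross * ebar) * A / (x0 * len);
      FX[i] += coef * dx;
      FY[i] += coef * dy;
    }
    // hinge shear term (4*stilde^2 denominator convention)
    if (L.hinges) {
      Hinge h[4]; int dxs[4], dys[4];
      int nh = point_hinges(L, X, Y, i, h, dxs, dys);
      if (nh == 0) continue;
      double mu2 = L.mux + L.muy;
      for (int k = 0; k < nh; ++k) {
        const Hinge &hh = h[k];
        double nx = std::sqrt(hh.xx * hh.xx + hh.xy * hh.xy);
        double ny = std::sqrt(hh.yx * hh.yx + hh.yy * hh.yy);
        double an = (hh.xx * hh.yx + hh.xy * hh.yy) / (nx * ny);
        if (std::fabs(an) >= 1.0 - 1e-12)
          stop("degenerate (collapsed) hinge at point %d", i + 1);
        double u = std::sqrt(1.0 - an * an);
        double taun = an / u;
        double An = std::fabs(hh.xx * hh.yy - hh.xy * hh.yx);
        double s = hh.x0 > hh.y0 ? hh.x0 / hh.y0 : hh.y0 / hh.x0;
        double st = s / (1.0 + s * s);
        double denom = (hh.x0 * hh.x0 + hh.y0 * hh.y0) * 4.0 * st * st;
        double pref = -(mu2 / (2.0 * nh)) * (An * An / denom) * taun *
                      (1.0 + taun * taun) / u;
        double vx = an * (hh.yx / (ny * ny) + hh.xx / (nx * nx)) -
                    (hh.xx + hh.yx) / (nx * ny);
        double vy = an * (hh.yy / (ny * ny) + hh.xy / (nx * nx)) -
                    (hh.xy + hh.yy) / (nx * ny);
        FX[i] += pref * vx;
        FY[i] += pref * vy;
      }
    }
  }
}

// turgor nodal forces from the CCW boundary polygon
void turgor_assemble(const Lattice &L, const std::vector<double> &X,
                     const std::vector<double> &Y, std::vector<double> &FX,
                     std::vector<double> &FY) {
  if (L.pt == 0.0 || L.ncycle < 3) return;
  int nc = L.ncycle;
  for (int k = 0; k < nc; ++k) {
    int i = L.cycle[k] - 1;
    int ip = L.cycle[(k + 1) % nc] - 1;
    int im = L.cycle[(k + nc - 1) % nc] - 1;
    FX[i] += 0.5 * L.pt * (Y[ip] - Y[im]);
    FY[i] += 0.5 * L.pt * (X[im] - X[ip]);
  }
}

struct EdgeLoad {
  std::vector<int> ids;  // 0-based, ordered along the edge
  double dx, dy, sigma;
};

// follower edge tractions: sigma per current edge length, lumped half/half
// onto segment endpoints; the end points of the edge take their incident
// segment at full weight, because the lattice carries boundary stress
// through all N+1 parallel spring lines (the uniform per-point load is the
// exact natural load of an affinely strained lattice)
void edge_assemble(const std::vector<EdgeLoad> &edges,
                   const std::vector<double> &X, const std::vector<double> &Y,
                   std::vector<double> &FX, std::vector<double> &FY) {
  for (size_t e = 0; e < edges.size(); ++e) {
    const EdgeLoad &el = edges[e];
    size_t ns = el.ids.size();
    if (ns < 2) continue;
    for (size_t k = 0; k + 1 < ns; ++k) {
      int i = el.ids[k], j = el.ids[k + 1];
      double dx = X[j] - X[i], dy = Y[j] - Y[i];
      double f = 0.5 * el.sigma * std::sqrt(dx * dx + dy * dy);
      FX[i] += f * el.dx; FY[i] += f * el.dy;
      FX[j] += f * el.dx; FY[j] += f * el.dy;
      if (k == 0) { FX[i] += f * el.dx; FY[i] += f * el.dy; }
      if (k + 2 == ns) { FX[j] += f * el.dx; FY[j] += f * el.dy; }
    }
  }
}

double residual(const Lattice &L, const std::vector<double> &FX,
                const std::vector<double> &FY) {
  double r = 0;
  for (int i = 0; i < L.n; ++i) {
    double fx = FX[i], fy = FY[i];
    int c = L.constraint[i];
    if (c == 1) continue;
    if (c == 2) fy = 0;
    if (c == 3) fx = 0;
    double f = fx * fx + fy * fy;
    if (f > r) r = f;
  }
  return std::sqrt(r);
}

Lattice make_lattice(const List &state, const List &mat) {
  Lattice L;
  IntegerMatrix nbr = state["nbr"], pspr = state["pspr"];
  IntegerVector sa = state["sa"], sb = state["sb"], sor = state["sor"];
  NumericVector srest = state["srest"];
  IntegerVector constraint = state["constraint"];
  NumericMatrix fixpos = state["fixpos"];
  IntegerVector cycle = state["cycle"];
  L.n = nbr.nrow();
  L.nbr = INTEGER(nbr); L.pspr = INTEGER(pspr);
  L.sa = INTEGER(sa); L.sb = INTEGER(sb); L.sor = INTEGER(sor);
  L.srest = REAL(srest); L.nspring = sa.size();
  L.constraint = INTEGER(constraint);
  L.fixx = REAL(fixpos); L.fixy = REAL(fixpos) + L.n;
  L.cycle = INTEGER(cycle); L.ncycle = cycle.size();
  L.lamx = as<double>(mat["lamx"]); L.mux = as<double>(mat["mux"]);
  L.lamy = as<double>(mat["lamy"]); L.muy = as<double>(mat["muy"]);
  L.pt = as<double>(mat["pt"]);
  L.hinges = as<bool>(mat["hinges"]);
  return L;
}

std::vector<EdgeLoad> make_edges(const List &loads) {
  std::vector<EdgeLoad> out;
  if (loads.size() == 0) return out;
  for (int k = 0; k < loads.size(); ++k) {
    List el = loads[k];
    EdgeLoad e;
    IntegerVector ids = el["ids"];
    NumericVector dir = el["dir"];
    e.sigma = as<double>(el["sigma"]);
    e.dx = dir[0]; e.dy = dir[1];
    e.ids.assign(ids.begin(), ids.end());
    for (size_t j = 0; j < e.ids.size(); ++j) e.ids[j] -= 1;
    out.push_back(e);
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List core_forces(List state, List mat, List edge_loads, SEXP point_forces) {
  Lattice L = make_lattice(state, mat);
  NumericMatrix pos = state["pos"];
  std::vector<double> X(REAL(pos), REAL(pos) + L.n);
  std::vector<double> Y(REAL(pos) + L.n, REAL(pos) + 2 * L.n);
  std::vector<double> FX(L.n, 0.0), FY(L.n, 0.0);
  elastic_assemble(L, X, Y, FX, FY);
  turgor_assemble(L, X, Y, FX, FY);
  std::vector<EdgeLoad> edges = make_edges(edge_loads);
  edge_assemble(edges, X, Y, FX, FY);
  if (point_forces != R_NilValue) {
    NumericMatrix pf(point_forces);
    for (int i = 0; i < L.n; ++i) { FX[i] += pf(i, 0); FY[i] += pf(i, 1); }
  }
  NumericMatrix F(L.n, 2);
  for (int i = 0; i < L.n; ++i) { F(i, 0) = FX[i]; F(i, 1) = FY[i]; }
  return List::create(_["force"] = F, _["residual"] = residual(L, FX, FY));
}

// [[Rcpp::export]]
NumericVector core_point_area(List state) {
  List mat = List::create(_["lamx"] = 0.0, _["mux"] = 0.0, _["lamy"] = 0.0,
                          _["muy"] = 0.0, _["pt"] = 0.0, _["hinges"] = false);
  Lattice L = make_lattice(state, mat);
  NumericMatrix pos = state["pos"];
  std::vector<double> X(REAL(pos), REAL(pos) + L.n);
  std::vector<double> Y(REAL(pos) + L.n, REAL(pos) + 2 * L.n);
  NumericVector A(L.n);
  for (int i = 0; i < L.n; ++i) A[i] = mean_area(L, X, Y, i);
  return A;
}

// Damped Verlet relaxation to elastostatic equilibrium. Convergence is
// tested on the static force (elastic + turgor + applied), max-norm over
// points, with constrained components projected out.
// [[Rcpp::export]]
List core_relax(List state, List mat, List edge_loads, SEXP point_forces,
                double hgamma, double mass, double eta, double thr,
                double max_steps, bool first) {
  Lattice L = make_lattice(state, mat);
  NumericMatrix pos = state["pos"], prev = state["prev"];
  int n = L.n;
  std::vector<double> X(REAL(pos), REAL(pos) + n);
  std::vector<double> Y(REAL(pos) + n, REAL(pos) + 2 * n);
  std::vector<double> PX(REAL(prev), REAL(prev) + n);
  std::vector<double> PY(REAL(prev) + n, REAL(prev) + 2 * n);
  std::vector<double> FX(n), FY(n);
  std::vector<EdgeLoad> edges = make_edges(edge_loads);
  NumericMatrix pf;
  bool haspf = point_forces != R_NilValue;
  if (haspf) pf = NumericMatrix(point_forces);

  double h2 = hgamma * hgamma;
  double res = R_PosInf;
  double best_smooth = R_PosInf, acc_smooth = 0.0;
  long steps = 0, limit = (long)max_steps;
  bool converged = false, stalled = false;
  // geometric stall detector: the corner-local hinge force is not exactly
  // conservative, so a free-floating medium can settle into a steady rigid
  // creep where the static residual equals the drag and never drops below
  // a configuration-dependent floor; when the spring lengths stop changing
  // the deformation state is at equilibrium and the run is accepted
  std::vector<double> glen(L.nspring, -1.0);
  auto spring_len = [&](int s) {
    int a = L.sa[s] - 1, b = L.sb[s] - 1;
    double dx = X[b] - X[a], dy = Y[b] - Y[a];
    return std::sqrt(dx * dx + dy * dy);
  };

  while (steps <= limit) {
    std::fill(FX.begin(), FX.end(), 0.0);
    std::fill(FY.begin(), FY.end(), 0.0);
    elastic_assemble(L, X, Y, FX, FY);
    turgor_assemble(L, X, Y, FX, FY);
    edge_assemble(edges, X, Y, FX, FY);
    if (haspf)
      for (int i = 0; i < n; ++i) { FX[i] += pf(i, 0); FY[i] += pf(i, 1); }
    res = residual(L, FX, FY);
    if (!std::isfinite(res))
      stop("relaxation diverged (non-finite forces) at step %ld", steps);
    if (res < thr) {
      // quiescence guard: require the viscous force to be below threshold
      // too, so the solver cannot stop mid-creep (overdamped motion where
      // the static force is balanced by drag) or mid-swing
      double vmax = 0.0;
      for (int i = 0; i < n; ++i) {
        double vx = X[i] - PX[i], vy = Y[i] - PY[i];
        double v = vx * vx + vy * vy;
        if (v > vmax) vmax = v;
      }
      if (eta * std::sqrt(vmax) / hgamma < thr) { converged = true; break; }
    }
    if (steps >= limit) break;

    acc_smooth += res;
    if (steps > 0 && steps % 100 == 0) {
      double sm = acc_smooth / 100.0;
      acc_smooth = 0.0;
      if (sm < best_smooth) best_smooth = sm;
      else if (steps > 2000 && sm > 100.0 * best_smooth)
        stop("relaxation diverged (residual growing) at step %ld, residual %g",
             steps, res);
    }
    if (steps > 0 && steps % 1000 == 0) {
      double dmax = 0.0;
      for (int s = 0; s < L.nspring; ++s) {
        double l = spring_len(s);
        double d = glen[s] < 0 ? R_PosInf : std::fabs(l - glen[s]);
        if (d > dmax) dmax = d;
        glen[s] = l;
      }
      if (dmax < 1e-8 && res < 1.0) { converged = true; stalled = true; break; }
    }
    double scale = first ? 0.5 * h2 / mass : h2 / mass;
    for (int i = 0; i < n; ++i) {
      double fdx = -eta * (X[i] - PX[i]) / hgamma;
      double fdy = -eta * (Y[i] - PY[i]) / hgamma;
      double nx, ny;
      if (first) {
        nx = X[i] + scale * (FX[i] + fdx);
        ny = Y[i] + scale * (FY[i] + fdy);
      } else {
        nx = 2.0 * X[i] - PX[i] + scale * (FX[i] + fdx);
        ny = 2.0 * Y[i] - PY[i] + scale * (FY[i] + fdy);
      }
      int c = L.constraint[i];
      if (c == 1) { nx = L.fixx[i]; ny = L.fixy[i]; }
      else if (c == 2) ny = L.fixy[i];
      else if (c == 3) nx = L.fixx[i];
      PX[i] = X[i]; PY[i] = Y[i];
      X[i] = nx; Y[i] = ny;
    }
    first = false;
    ++steps;
    if (steps % 2000 == 0) checkUserInterrupt();
  }

  NumericMatrix npos(n, 2), nprev(n, 2);
  for (int i = 0; i < n; ++i) {
    npos(i, 0) = X[i]; npos(i, 1) = Y[i];
    nprev(i, 0) = PX[i]; nprev(i, 1) = PY[i];
  }
  return List::create(_["pos"] = npos, _["prev"] = nprev,
                      _["steps"] = (double)steps, _["residual"] = res,
                      _["converged"] = converged, _["stalled"] = stalled);
}

// Signed point shear strain: mean over adjacent hinges of tan(phi_n),
// with the quadrant sign +1 for (R,U)/(L,D) hinges and -1 for (L,U)/(R,D),
// so that a positive simple shear yields tau > 0 everywhere.
// [[Rcpp::export]]
NumericVector core_point_shear(List state) {
  List mat = List::create(_["lamx"] = 0.0, _["mux"] = 0.0, _["lamy"] = 0.0,
                          _["muy"] = 0.0, _["pt"] = 0.0, _["hinges"] = false);
  Lattice L = make_lattice(state, mat);
  NumericMatrix pos = state["pos"];
  std::vector<double> X(REAL(pos), REAL(pos) + L.n);
  std::vector<double> Y(REAL(pos) + L.n, REAL(pos) + 2 * L.n);
  NumericVector tau(L.n);
  for (int i = 0; i < L.n; ++i) {
    Hinge h[4]; int dxs[4], dys[4];
    int nh = point_hinges(L, X, Y, i, h, dxs, dys);
    if (nh == 0) { tau[i] = NA_REAL; continue; }
    double acc = 0;
    for (int k = 0; k < nh; ++k) {
      const Hinge &hh = h[k];
      double nx = std::sqrt(hh.xx * hh.xx + hh.xy * hh.xy);
      double ny = std::sqrt(hh.yx * hh.yx + hh.yy * hh.yy);
      double an = (hh.xx * hh.yx + hh.xy * hh.yy) / (nx * ny);
      double sgn = (dxs[k] == dys[k]) ? 1.0 : -1.0;  // (R,U)/(L,D) vs mixed
      acc += sgn * an / std::sqrt(1.0 - an * an);
    }
    tau[i] = acc / nh;
  }
  return tau;
}
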