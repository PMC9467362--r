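#include <Rcpp.h>
using namespace Rcpp;

// Analytic oscillatory boundary-layer fields evaluated in closed form.
// Units: mm, s, rad. y = 0 at the substrate base, x streamwise (periodic).

struct FieldPar {
  int type;          // 0 = flat Stokes layer, 1 = ridged cavity composition
  double U0, omega, phase0, delta;
  double H, w, sg, pitch;   // ridge height, ridge width, gap (cavity width), pitch
  double A0, phase_lag, hb; // cavity streamfunction amplitude, lag, blend thickness
  double Lx, Ly;
};

struct FieldSample {
  double u, v, ux, uy, vx, vy;
};

static FieldPar as_fieldpar(const List& par) {
  FieldPar p;
  p.type = as<int>(par["type"]);
  p.U0 = as<double>(par["U0"]);
  p.omega = as<double>(par["omega"]);
  p.phase0 = as<double>(par["phase0"]);
  p.delta = as<double>(par["delta"]);
  p.H = as<double>(par["H"]);
  p.w = as<double>(par["w"]);
  p.sg = as<double>(par["sg"]);
  p.pitch = as<double>(par["pitch"]);
  p.A0 = as<double>(par["A0"]);
  p.phase_lag = as<double>(par["phase_lag"]);
  p.hb = as<double>(par["hb"]);
  p.Lx = as<double>(par["Lx"]);
  p.Ly = as<double>(par["Ly"]);
  return p;
}

// Stokes second-problem layer above a no-slip plane at yr = 0:
// u(yr,t) = U0 [sin(th) - exp(-yr/d) sin(th - yr/d)], th = omega t + phase0.
static inline void stokes_parts(const FieldPar& p, double yr, double t,
                                double& u, double& dudy, double& psi) {
  double th = p.omega * t + p.phase0;
  double yh = yr / p.delta;
  double e = std::exp(-yh);
  double sn = std::sin(th - yh), cs = std::cos(th - yh);
  double s0 = std::sin(th), c0 = std::cos(th);
  u = p.U0 * (s0 - e * sn);
  dudy = p.U0 / p.delta * e * (sn + cs);
  psi = p.U0 * (yr * s0 + 0.5 * p.delta * (e * (sn - cs) - (s0 - c0)));
}

static inline double wrapx(double x, double L) {
  double r = x - L * std::floor(x / L);
  if (r >= L) r -= L;  // guard against rounding at the seam
  return r;
}

static inline double elevation(const FieldPar& p, double x) {
  if (p.type == 0) return 0.0;
  double xm = wrapx(x, p.pitch);
  return (xm < p.w) ? p.H : 0.0;
}

static FieldSample eval_field(const FieldPar& p, double x, double y, double t) {
  FieldSample f = {0, 0, 0, 0, 0, 0};
  if (p.type == 0) {
    if (y <= 0) return f;
    double u, dudy, psi;
    stokes_parts(p, y, t, u, dudy, psi);
    f.u = u; f.uy = dudy;
    return f;
  }
  double xm = wrapx(x, p.pitch);
  double elev = (xm < p.w) ? p.H : 0.0;
  if (y <= elev) return f;
  if (y >= p.H) {
    // blended Stokes layer referenced to the crest plane:
    // psi_blend(yr) = s(yr/hb) * psi_st(yr), C1 smoothstep s.
    double yr = y - p.H;
    double u, dudy, psi;
    stokes_parts(p, yr, t, u, dudy, psi);
    double xi = yr / p.hb;
    double sb, sb1, sb2;
    if (xi >= 1.0) { sb = 1.0; sb1 = 0.0; sb2 = 0.0; }
    else {
      sb = xi * xi * (3.0 - 2.0 * xi);
      sb1 = (6.0 * xi - 6.0 * xi * xi) / p.hb;
      sb2 = (6.0 - 12.0 * xi) / (p.hb * p.hb);
    }
    f.u = sb * u + sb1 * psi;
    f.uy = sb * dudy + 2.0 * sb1 * u + sb2 * psi;
    return f;
  }
  // inside a cavity column below the crest plane
  if (xm >= p.w && y > 0.0) {
    double X = xm - p.w, Y = y;
    double A = p.A0 * std::sin(p.omega * (t - p.phase_lag) + p.phase0);
    double pis = M_PI / p.sg, pih = M_PI / p.H;
    double sx = std::sin(pis * X), s2x = std::sin(2.0 * pis * X), c2x = std::cos(2.0 * pis * X);
    double sy = std::sin(pih * Y), s2y = std::sin(2.0 * pih * Y), c2y = std::cos(2.0 * pih * Y);
    f.u  =  A * sx * sx * pih * s2y;
    f.v  = -A * pis * s2x * sy * sy;
    f.ux =  A * pis * s2x * pih * s2y;
    f.uy =  A * sx * sx * 2.0 * pih * pih * c2y;
    f.vx = -A * 2.0 * pis * pis * c2x * sy * sy;
    f.vy = -f.ux;
  }
  return f;
}

// distance from (x, y) to the nearest solid surface (floor + ridge rectangles)
static double wall_distance(const FieldPar& p, double x, double y) {
  if (p.type == 0) return std::max(y, 0.0);
  double xm = wrapx(x, p.pitch);
  double d = y; // cavity floor / floor plane
  for (int k = -1; k <= 1; ++k) {
    double x0 = k * p.pitch, x1 = k * p.pitch + p.w;
    double ddx = std::max(0.0, std::max(x0 - xm, xm - x1));
    double ddy = std::max(0.0, y - p.H);
    double db = std::sqrt(ddx * ddx + ddy * ddy);
    if (db < d) d = db;
  }
  if (y < elevation(p, x)) d = 0.0;
  return std::max(d, 0.0);
}

// [[Rcpp::export]]
NumericMatrix eval_field_cpp(List par, NumericVector x, NumericVector y, NumericVector t) {
  FieldPar p = as_fieldpar(par);
  R_xlen_t n = x.size();
  NumericMatrix out(n, 6);
  colnames(out) = CharacterVector::create("u", "v", "dudx", "dudy", "dvdx", "dvdy");
  for (R_xlen_t i = 0; i < n; ++i) {
    FieldSample f = eval_field(p, x[i], y[i], t[i]);
    out(i, 0) = f.u; out(i, 1) = f.v;
    out(i, 2) = f.ux; out(i, 3) = f.uy; out(i, 4) = f.vx; out(i, 5) = f.vy;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector wall_distance_cpp(List par, NumericVector x, NumericVector y) {
  FieldPar p = as_fieldpar(par);
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = wall_distance(p, x[i], y[i]);
  return out;
}

struct SimPar {
  double dt, max_time, u_ell, gate, alpha, b;
};

static SimPar as_simpar(const List& par) {
  SimPar s;
  s.dt = as<double>(par["dt"]);
  s.max_time = as<double>(par["max_time"]);
  s.u_ell = as<double>(par["u_ell"]);
  s.gate = as<double>(par["gate"]);
  s.alpha = as<double>(par["alpha"]);
  s.b = as<double>(par["b"]);
  return s;
}

// One explicit-Euler update; returns status (0 swim, 1 settled, 2 exited).
static inline int advance(const FieldPar& p, const SimPar& sp,
                          double& x, double& y, double& th, double& t) {
  FieldSample f = eval_field(p, x, y, t);
  double c = std::cos(th), s = std::sin(th);
  double rx = f.u + sp.u_ell * c;
  double ry = f.v + sp.u_ell * s;
  double speed = std::sqrt(rx * rx + ry * ry);
  if (wall_distance(p, x, y) <= sp.b && speed < sp.gate) return 1;
  if (y > p.Ly) return 2;
  double omz = f.vx - f.uy;
  double S12 = 0.5 * (f.uy + f.vx);
  double gdotSn = (f.vy - f.ux) * s * c + S12 * (c * c - s * s);
  double thdot = 0.5 * omz + sp.alpha * gdotSn;
  double xn = wrapx(x + sp.dt * rx, p.Lx);
  double yn = y + sp.dt * ry;
  if (yn < elevation(p, xn)) {
    if (y >= elevation(p, xn)) {
      yn = y;               // floor/top contact: drop normal (vertical) part
    } else {
      xn = x;               // ridge flank ahead: drop streamwise part
      if (yn < elevation(p, xn)) yn = y;
    }
  }
  x = xn; y = yn;
  th = wrapx(th + sp.dt * thdot, 2.0 * M_PI);
  t += sp.dt;
  return 0;
}

// [[Rcpp::export]]
NumericMatrix engine_run(NumericMatrix agents, List field_par, List sim_par) {
  FieldPar p = as_fieldpar(field_par);
  SimPar sp = as_simpar(sim_par);
  int n = agents.nrow();
  NumericMatrix out(n, 5);
  colnames(out) = CharacterVector::create("status", "t_final", "x_final", "y_final", "theta_final");
  long nmax = (long)std::ceil(sp.max_time / sp.dt - 1e-9);
  for (int i = 0; i < n; ++i) {
    double x = agents(i, 0), y = agents(i, 1), th = agents(i, 2), t = agents(i, 3);
    int status = 0;
    for (long k = 0; k < nmax; ++k) {
      status = advance(p, sp, x, y, th, t);
      if (status != 0) break;
    }
    out(i, 0) = (status == 0) ? 3.0 : (double)status; // 1 settled, 2 exited, 3 unresolved
    out(i, 1) = t; out(i, 2) = x; out(i, 3) = y; out(i, 4) = th;
  }
  return out;
}

// [[Rcpp::export]]
List engine_trajectory(NumericVector state0, List field_par, List sim_par, int save_every) {
  FieldPar p = as_fieldpar(field_par);
  SimPar sp = as_simpar(sim_par);
  double x = state0[0], y = state0[1], th = state0[2], t = state0[3];
  long nmax = (long)std::ceil(sp.max_time / sp.dt - 1e-9);
  std::vector<double> T, X, Y, TH, U, V, UX, UY, VX, VY;
  int status = 0;
  for (long k = 0; k < nmax; ++k) {
    if (k % save_every == 0) {
      FieldSample f = eval_field(p, x, y, t);
      T.push_back(t); X.push_back(x); Y.push_back(y); TH.push_back(th);
      U.push_back(f.u); V.push_back(f.v);
      UX.push_back(f.ux); UY.push_back(f.uy); VX.push_back(f.vx); VY.push_back(f.vy);
    }
    status = advance(p, sp, x, y, th, t);
    if (status != 0) break;
  }
  {
    FieldSample f = eval_field(p, x, y, t);
    T.push_back(t); X.push_back(x); Y.push_back(y); TH.push_back(th);
    U.push_back(f.u); V.push_back(f.v);
    UX.push_back(f.ux); UY.push_back(f.uy); VX.push_back(f.vx); VY.push_back(f.vy);
  }
  return List::create(
    _["status"] = (status == 0) ? 3 : status,
    _["t"] = T, _["x"] = X, _["y"] = Y, _["theta"] = TH,
    _["u"] = U, _["v"] = V,
    _["dudx"] = UX, _["dudy"] = UY, _["dvdx"] = VX, _["dvdy"] = VY);
}

// Connected-component labeling of a logical mask (4- or 8-connectivity).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nd = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int r = idx % nr, c = idx / nr;
        for (int d = 0; d < nd; ++d) {
          int rr = r + dr[d], cc = c + dc[d];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * nr);
          }
        }
      }
    }
  }
  return lab;
}
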