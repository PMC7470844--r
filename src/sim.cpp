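#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step Euler / Euler-Maruyama steppers for the 1D embryo.
// RNG draws go through R's generator (norm_rand) in column-major order
// (variable-by-variable, cell-by-cell) so that a run with a given seed is
// reproducible from R and matches the pure-R reference stepper.

struct Weights { double d, s, i; };

static inline Weights eval_weights(double g, int family, double expo,
                                   double hillK, double hillN,
                                   int ienabled, double iscale) {
  Weights w;
  if (family == 5) { // hill, normalised so theta_d(1) = 1
    double Kn = std::pow(hillK, hillN), norm = 1.0 + Kn;
    double gn = std::pow(g, hillN), hn = std::pow(1.0 - g, hillN);
    w.d = gn * norm / (gn + Kn);
    w.s = hn * norm / (hn + Kn);
  } else {
    w.d = std::pow(g, expo);
    w.s = std::pow(1.0 - g, expo);
  }
  w.i = ienabled ? iscale * g * (1.0 - g) : 0.0;
  return w;
}

static inline double front_g(double x, double t, int shape, double s,
                             double v, double x0, double gconst) {
  if (gconst >= 0.0) return gconst;
  double u = s * (x - x0 - v * t);
  double g;
  if (shape == 1) g = 1.0 / (1.0 + std::exp(-u));
  else g = u + 0.5; // piecewise linear ramp of width 1/s
  if (g < 0.0) g = 0.0;
  if (g > 1.0) g = 1.0;
  return g;
}

static inline double hill_rep(double x, double K, double h) {
  return 1.0 / (1.0 + std::pow(x / K, h));
}

// [[Rcpp::export]]
List sim_gene_cpp(NumericMatrix P0, NumericVector positions,
                  double dt, int nsteps, int save_every,
                  double bD, double Kd, double hd,
                  double bS, NumericMatrix Kstat, double hs, double deg,
                  int wfamily, double wexpo, double whillK, double whillN,
                  int wienabled, double wiscale,
                  int fshape, double fs, double fv, double fx0, double fgconst,
                  double omega, double Ddiff) {
  const int n = P0.nrow();
  const int pred[3] = {2, 0, 1};      // A <- C, B <- A, C <- B
  const int oth1[3] = {1, 2, 0};
  const int oth2[3] = {2, 0, 1};
  const bool stochastic = R_finite(omega);
  const double sqdt = std::sqrt(dt);

  int nsave = nsteps / save_every + 1;
  NumericVector states(nsave * n * 3);
  states.attr("dim") = IntegerVector::create(nsave, n, 3);
  NumericMatrix gvals(nsave, n);
  NumericVector times(nsave);

  NumericMatrix P = clone(P0);
  NumericMatrix Pnew(n, 3);
  NumericMatrix prod(n, 3), deriv(n, 3);
  int isave = 0;

  for (int step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    if (step % save_every == 0) {
      times[isave] = t;
      for (int i = 0; i < n; ++i) {
        gvals(isave, i) = front_g(positions[i], t, fshape, fs, fv, fx0, fgconst);
        for (int j = 0; j < 3; ++j)
          states[isave + nsave * (i + n * j)] = P(i, j);
      }
      ++isave;
    }
    if (step == nsteps) break;

    for (int i = 0; i < n; ++i) {
      double g = front_g(positions[i], t, fshape, fs, fv, fx0, fgconst);
      Weights w = eval_weights(g, wfamily, wexpo, whillK, whillN,
                               wienabled, wiscale);
      for (int j = 0; j < 3; ++j) {
        double D = bD * hill_rep(P(i, pred[j]), Kd, hd);
        double S = bS * hill_rep(P(i, oth1[j]), Kstat(j, oth1[j]), hs) *
                        hill_rep(P(i, oth2[j]), Kstat(j, oth2[j]), hs);
        prod(i, j) = w.d * D + w.s * S;
        deriv(i, j) = prod(i, j) - deg * P(i, j);
      }
    }
    // column-major draws to match the R reference stepper
    for (int j = 0; j < 3; ++j) {
      for (int i = 0; i < n; ++i) {
        double lap = 0.0; // no-flux ends
        if (n > 1) {
          double left  = (i > 0)     ? P(i - 1, j) : P(i, j);
          double right = (i < n - 1) ? P(i + 1, j) : P(i, j);
          lap = left - 2.0 * P(i, j) + right;
        }
        double upd = P(i, j) + dt * (deriv(i, j) + Ddiff * lap);
        if (stochastic) {
          double sigma = std::sqrt((prod(i, j) + deg * P(i, j)) / omega);
          upd += sqdt * sigma * norm_rand();
        }
        if (upd < 0.0) upd = 0.0; // tau-leaping-style clipping
        if (!R_finite(upd))
          stop("non-finite state at t = %g in cell %d", t + dt, i + 1);
        Pnew(i, j) = upd;
      }
    }
    std::copy(Pnew.begin(), Pnew.end(), P.begin());
  }
  return List::create(_["times"] = times, _["states"] = states,
                      _["g_values"] = gvals);
}

// [[Rcpp::export]]
List sim_geo_cpp(NumericMatrix P0, NumericVector positions,
                 double dt, int nsteps, int save_every,
                 double lambda, double omega0, double rho,
                 double strength, double sy1, double sy2, double uy,
                 double mu, int subvariant, double sub_nu, double sub_b,
                 double sub_c, double sub_lambda,
                 int wfamily, double wexpo, double whillK, double whillN,
                 int wienabled, double wiscale,
                 int fshape, double fs, double fv, double fx0, double fgconst,
                 double omega, double Ddiff, double noise_floor) {
  const int n = P0.nrow();
  const bool stochastic = R_finite(omega);
  const double sqdt = std::sqrt(dt);
  const double sigma = stochastic ? noise_floor / std::sqrt(omega) : 0.0;

  int nsave = nsteps / save_every + 1;
  NumericVector states(nsave * n * 2);
  states.attr("dim") = IntegerVector::create(nsave, n, 2);
  NumericMatrix gvals(nsave, n);
  NumericVector times(nsave);

  NumericMatrix P = clone(P0);
  NumericMatrix Pnew(n, 2);
  NumericMatrix deriv(n, 2);
  int isave = 0;

  for (int step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    if (step % save_every == 0) {
      times[isave] = t;
      for (int i = 0; i < n; ++i) {
        gvals(isave, i) = front_g(positions[i], t, fshape, fs, fv, fx0, fgconst);
        states[isave + nsave * i] = P(i, 0);
        states[isave + nsave * (i + n)] = P(i, 1);
      }
      ++isave;
    }
    if (step == nsteps) break;

    for (int i = 0; i < n; ++i) {
      double g = front_g(positions[i], t, fshape, fs, fv, fx0, fgconst);
      Weights w = eval_weights(g, wfamily, wexpo, whillK, whillN,
                               wienabled, wiscale);
      double y = P(i, 0), z = P(i, 1);
      double r = std::sqrt(y * y + z * z);
      double dyn_y = 0.0, dyn_z = 0.0;
      if (r > 0.0) {
        double radial = subvariant
          ? sub_lambda * (sub_nu + sub_b * r * r - sub_c * r * r * r * r)
          : lambda * (1.0 - r);
        double ang = omega0 * (1.0 - rho * y / r);
        dyn_y = radial * y - ang * z;
        dyn_z = radial * z + ang * y;
      }
      double stat_y = strength * (-(y - sy1) * (y - sy2) * (y - uy));
      double stat_z = strength * (-z);
      deriv(i, 0) = w.d * dyn_y + w.s * stat_y + w.i * mu * (-y);
      deriv(i, 1) = w.d * dyn_z + w.s * stat_z + w.i * mu * (-z);
    }
    for (int j = 0; j < 2; ++j) {
      for (int i = 0; i < n; ++i) {
        double lap = 0.0;
        if (n > 1) {
          double left  = (i > 0)     ? P(i - 1, j) : P(i, j);
          double right = (i < n - 1) ? P(i + 1, j) : P(i, j);
          lap = left - 2.0 * P(i, j) + right;
        }
        double upd = P(i, j) + dt * (deriv(i, j) + Ddiff * lap);
        if (stochastic) upd += sqdt * sigma * norm_rand();
        if (!R_finite(upd))
          stop("non-finite state at t = %g in cell %d", t + dt, i + 1);
        Pnew(i, j) = upd;
      }
    }
    std::copy(Pnew.begin(), Pnew.end(), P.begin());
  }
  return List::create(_["times"] = times, _["states"] = states,
                      _["g_values"] = gvals);
}
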