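#include <Rcpp.h>
using namespace Rcpp;

// Bilinear neuronal dynamics with balloon hemodynamics, integrated at a
// fixed sub-TR step. State per node: z (neuronal), s (vasodilatory
// signal), and log f, log v, log q (flow, venous volume, deoxyhemoglobin)
// so the physiological states stay positive. The full state vector is
// advanced with classical RK4. Inputs are piecewise constant per TR.
// Runs are integrated independently from rest (states reset at each run
// boundary) and the BOLD output is sampled on the TR grid.

struct DcmPar {
  int n;                    // nodes
  int m;                    // inputs
  const double *A;          // n x n, column-major
  const double *B;          // n x n x m
  const double *C;          // n x m
  const double *kappa, *gamma, *tau;
  double alpha, E0;
};

static inline void deriv(const DcmPar &p, const double *x, const double *u,
                         double *dx) {
  const int n = p.n;
  const double *z = x, *s = x + n, *lf = x + 2 * n, *lv = x + 3 * n,
               *lq = x + 4 * n;
  double *dz = dx, *ds = dx + n, *dlf = dx + 2 * n, *dlv = dx + 3 * n,
         *dlq = dx + 4 * n;
  // effective connectivity J = A + sum_j u_j B_j
  for (int i = 0; i < n; i++) {
    double acc = 0.0;
    for (int k = 0; k < n; k++) {
      double Jik = p.A[i + n * k];
      for (int j = 0; j < p.m; j++) {
        double uj = u[j];
        if (uj != 0.0) Jik += uj * p.B[i + n * k + n * n * j];
      }
      acc += Jik * z[k];
    }
    for (int j = 0; j < p.m; j++) acc += p.C[i + n * j] * u[j];
    dz[i] = acc;
  }
  const double ia = 1.0 / p.alpha;
  const double l1e = log(1.0 - p.E0);
  for (int i = 0; i < n; i++) {
    double f = exp(lf[i]), v = exp(lv[i]), q = exp(lq[i]);
    ds[i] = z[i] - p.kappa[i] * s[i] - p.gamma[i] * (f - 1.0);
    dlf[i] = s[i] / f;
    double fout = exp(ia * lv[i]);          // v^(1/alpha)
    dlv[i] = (f - fout) / (p.tau[i] * v);
    double E = 1.0 - exp(l1e / f);          // 1 - (1-E0)^(1/f)
    dlq[i] = (f * E / p.E0 - fout * q / v) / (p.tau[i] * q);
  }
}

// [[Rcpp::export]]
List dcm_integrate_cpp(NumericMatrix A, NumericVector Bcube,
                       NumericMatrix C, NumericMatrix U,
                       IntegerVector run_lengths,
                       NumericVector kappa, NumericVector gamma,
                       NumericVector tau, double alpha, double E0,
                       double V0, double tr, int nsub) {
  const int n = A.nrow();
  const int m = C.ncol();
  const int Ttot = U.ncol();
  if (U.nrow() != m) stop("U must be n_inputs x time");
  DcmPar p;
  p.n = n; p.m = m;
  p.A = A.begin(); p.B = Bcube.begin(); p.C = C.begin();
  p.kappa = kappa.begin(); p.gamma = gamma.begin(); p.tau = tau.begin();
  p.alpha = alpha; p.E0 = E0;

  const double k1 = 7.0 * E0, k2 = 2.0, k3 = 2.0 * E0 - 0.2;
  const double dt = tr / nsub;
  const int ns = 5 * n;
  std::vector<double> x(ns), k1v(ns), k2v(ns), k3v(ns), k4v(ns), xt(ns),
      u(m);

  NumericMatrix Y(Ttot, n), Z(Ttot, n), S(Ttot, n), F(Ttot, n),
      V(Ttot, n), Q(Ttot, n);

  int t0 = 0;
  for (int rrun = 0; rrun < run_lengths.size(); rrun++) {
    // rest state: z = s = 0, f = v = q = 1 (logs zero)
    std::fill(x.begin(), x.end(), 0.0);
    const int Trun = run_lengths[rrun];
    for (int t = 0; t < Trun; t++) {
      for (int j = 0; j < m; j++) u[j] = U(j, t0 + t);
      for (int sstep = 0; sstep < nsub; sstep++) {
        deriv(p, x.data(), u.data(), k1v.data());
        for (int i = 0; i < ns; i++) xt[i] = x[i] + 0.5 * dt * k1v[i];
        deriv(p, xt.data(), u.data(), k2v.data());
        for (int i = 0; i < ns; i++) xt[i] = x[i] + 0.5 * dt * k2v[i];
        deriv(p, xt.data(), u.data(), k3v.data());
        for (int i = 0; i < ns; i++) xt[i] = x[i] + dt * k3v[i];
        deriv(p, xt.data(), u.data(), k4v.data());
        for (int i = 0; i < ns; i++)
          x[i] += dt / 6.0 * (k1v[i] + 2.0 * k2v[i] + 2.0 * k3v[i] + k4v[i]);
      }
      for (int i = 0; i < n; i++) {
        if (!R_finite(x[i]) || fabs(x[i]) > 1e6)
          stop("state divergence at run %d, volume %d", rrun + 1, t + 1);
        double f = exp(x[2 * n + i]), v = exp(x[3 * n + i]),
               q = exp(x[4 * n + i]);
        Z(t0 + t, i) = x[i];
        S(t0 + t, i) = x[n + i];
        F(t0 + t, i) = f;
        V(t0 + t, i) = v;
        Q(t0 + t, i) = q;
        Y(t0 + t, i) =
            100.0 * V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
      }
    }
    t0 += Trun;
  }
  return List::create(_["y"] = Y, _["z"] = Z, _["s"] = S, _["f"] = F,
                      _["v"] = V, _["q"] = Q);
}
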