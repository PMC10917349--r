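// Fixed-step RK4 integrator for a three-layer gradient-frequency network of
// canonical Hopf oscillators with (optionally learned) layer-1 -> layer-2
// connections and fixed diagonal layer-2 -> layer-3 / layer-1 -> layer-3
// couplings.  States must stay inside the unit disk (the |z|^4/(1-|z|^2)
// term diverges at |z| = 1); escape aborts with the simulation time.
//
// Complex arithmetic uses a minimal inline struct (naive multiply) rather
// than std::complex: the RK4 inner loops execute ~10^8 complex multiplies
// per 16-s run and must not go through the IEEE Annex-G recovery path.

#include <Rcpp.h>
#include <vector>
#include <cmath>

struct C {
  double re, im;
};
static inline C cplx(double re, double im) { return C{re, im}; }
static inline C operator+(C a, C b) { return C{a.re + b.re, a.im + b.im}; }
static inline C operator-(C a, C b) { return C{a.re - b.re, a.im - b.im}; }
static inline C operator*(C a, C b) {
  return C{a.re * b.re - a.im * b.im, a.re * b.im + a.im * b.re};
}
static inline C operator*(double s, C a) { return C{s * a.re, s * a.im}; }
static inline C &operator+=(C &a, C b) { a.re += b.re; a.im += b.im; return a; }
static inline C conj(C a) { return C{a.re, -a.im}; }
static inline double norm2(C a) { return a.re * a.re + a.im * a.im; }

static inline C ipow(C z, int k) {
  C out = cplx(1.0, 0.0);
  for (int i = 0; i < k; ++i) out = out * z;
  return out;
}

struct LayerPar {
  double alpha, b1, b2, d1, d2;
};

struct Net {
  int N;
  std::vector<double> freqs;       // natural frequencies, Hz
  LayerPar L[3];
  bool freq_scaling;
  std::vector<int> ci, cj, ck, cm; // target (layer-2) idx, source (layer-1) idx, k, m
  bool learn;
  double lambda, mu1, mu2, kappa, tau;
  double w23, w13;
  double g[3];                     // stimulus gain per layer
};

// intrinsic flow z*(alpha + i*wterm + (b1+i d1)|z|^2 + (b2+i d2)|z|^4/(1-|z|^2))
static inline C intrinsic(C z, const LayerPar &p, double wterm) {
  double r2 = norm2(z);
  double r4 = r2 * r2;
  double den = 1.0 - r2;
  C coef = cplx(p.alpha + p.b1 * r2 + p.b2 * r4 / den,
                wterm + p.d1 * r2 + p.d2 * r4 / den);
  return z * coef;
}

// full derivative of the network state
static void deriv(const Net &net,
                  const std::vector<C> &z1, const std::vector<C> &z2,
                  const std::vector<C> &z3, const std::vector<C> &c,
                  C s,
                  std::vector<C> &dz1, std::vector<C> &dz2,
                  std::vector<C> &dz3, std::vector<C> &dc,
                  std::vector<C> &x2) {
  const int N = net.N;
  const double TWO_PI = 6.283185307179586;
  std::fill(x2.begin(), x2.end(), cplx(0.0, 0.0));
  const int M = (int)net.ci.size();
  for (int t = 0; t < M; ++t) {
    const int i = net.ci[t], j = net.cj[t];
    const int k = net.ck[t], m = net.cm[t];
    if (k == 1 && m == 1) {
      x2[i] += c[t] * z1[j];
    } else {
      x2[i] += c[t] * ipow(z1[j], k) * ipow(conj(z2[i]), m - 1);
    }
  }
  for (int i = 0; i < N; ++i) {
    double scale, w;
    if (net.freq_scaling) {
      scale = net.freqs[i];
      w = TWO_PI;
    } else {
      scale = 1.0;
      w = TWO_PI * net.freqs[i];
    }
    dz1[i] = scale * (intrinsic(z1[i], net.L[0], w) + net.g[0] * s);
    dz2[i] = scale * (intrinsic(z2[i], net.L[1], w) + x2[i] + net.g[1] * s);
    dz3[i] = scale * (intrinsic(z3[i], net.L[2], w) +
                      net.w23 * z2[i] + net.w13 * z1[i] + net.g[2] * s);
  }
  if (net.learn) {
    for (int t = 0; t < M; ++t) {
      const int i = net.ci[t], j = net.cj[t];
      const int k = net.ck[t], m = net.cm[t];
      double r2 = norm2(c[t]);
      C hebb = (k == 1 && m == 1)
        ? z2[i] * conj(z1[j])
        : ipow(z2[i], m) * ipow(conj(z1[j]), k);
      C decay = cplx(net.lambda + net.mu1 * r2 +
                     net.mu2 * r2 * r2 / (1.0 - r2), 0.0);
      dc[t] = (1.0 / net.tau) * (c[t] * decay + net.kappa * hebb);
    }
  } else {
    std::fill(dc.begin(), dc.end(), cplx(0.0, 0.0));
  }
}

static inline bool escaped(const std::vector<C> &v, double lim2) {
  for (const auto &z : v) {
    double r2 = norm2(z);
    if (!(r2 < lim2)) return true; // catches NaN too
  }
  return false;
}

// [[Rcpp::export(name = ".hopf_simulate_cpp")]]
Rcpp::List hopf_simulate_cpp(Rcpp::NumericVector freqs,
                             Rcpp::NumericMatrix layer_pars,
                             Rcpp::IntegerVector conn_i,
                             Rcpp::IntegerVector conn_j,
                             Rcpp::ComplexVector conn_c0,
                             Rcpp::IntegerVector conn_k,
                             Rcpp::IntegerVector conn_m,
                             bool learn, double lambda, double mu1, double mu2,
                             double kappa, double tau,
                             double w23, double w13,
                             Rcpp::ComplexVector stimulus,
                             Rcpp::NumericVector stim_gain,
                             double dt, bool freq_scaling,
                             Rcpp::ComplexVector z1_0,
                             Rcpp::ComplexVector z2_0,
                             Rcpp::ComplexVector z3_0,
                             Rcpp::IntegerVector track_layer,
                             Rcpp::IntegerVector track_osc) {
  const int N = freqs.size();
  const int n_steps = stimulus.size() - 1;
  if (n_steps < 1) Rcpp::stop("stimulus must contain at least two samples");

  Net net;
  net.N = N;
  net.freqs.assign(freqs.begin(), freqs.end());
  for (int l = 0; l < 3; ++l)
    net.L[l] = LayerPar{layer_pars(l, 0), layer_pars(l, 1), layer_pars(l, 2),
                        layer_pars(l, 3), layer_pars(l, 4)};
  net.freq_scaling = freq_scaling;
  net.ci.assign(conn_i.begin(), conn_i.end());
  net.cj.assign(conn_j.begin(), conn_j.end());
  net.ck.assign(conn_k.begin(), conn_k.end());
  net.cm.assign(conn_m.begin(), conn_m.end());
  net.learn = learn;
  net.lambda = lambda; net.mu1 = mu1; net.mu2 = mu2;
  net.kappa = kappa; net.tau = tau;
  net.w23 = w23; net.w13 = w13;
  for (int l = 0; l < 3; ++l) net.g[l] = stim_gain[l];

  const int M = conn_c0.size();
  std::vector<C> z1(N), z2(N), z3(N), c(M);
  for (int i = 0; i < N; ++i) {
    z1[i] = cplx(COMPLEX(z1_0)[i].r, COMPLEX(z1_0)[i].i);
    z2[i] = cplx(COMPLEX(z2_0)[i].r, COMPLEX(z2_0)[i].i);
    z3[i] = cplx(COMPLEX(z3_0)[i].r, COMPLEX(z3_0)[i].i);
  }
  for (int t = 0; t < M; ++t)
    c[t] = cplx(COMPLEX(conn_c0)[t].r, COMPLEX(conn_c0)[t].i);

  std::vector<C> stim(n_steps + 1);
  for (int t = 0; t <= n_steps; ++t)
    stim[t] = cplx(COMPLEX(stimulus)[t].r, COMPLEX(stimulus)[t].i);

  // outputs
  Rcpp::ComplexMatrix mf(3, n_steps + 1);
  const int n_track = track_layer.size();
  Rcpp::ComplexMatrix tracked(n_track > 0 ? n_track : 1, n_steps + 1);

  auto record = [&](int step) {
    C m1 = cplx(0, 0), m2 = cplx(0, 0), m3 = cplx(0, 0);
    for (int i = 0; i < N; ++i) { m1 += z1[i]; m2 += z2[i]; m3 += z3[i]; }
    const double inv = 1.0 / N;
    mf(0, step) = Rcomplex{inv * m1.re, inv * m1.im};
    mf(1, step) = Rcomplex{inv * m2.re, inv * m2.im};
    mf(2, step) = Rcomplex{inv * m3.re, inv * m3.im};
    for (int t = 0; t < n_track; ++t) {
      const int l = track_layer[t], o = track_osc[t];
      const C &z = (l == 0) ? z1[o] : (l == 1) ? z2[o] : z3[o];
      tracked(t, step) = Rcomplex{z.re, z.im};
    }
  };
  record(0);

  // RK4 workspaces
  std::vector<C> k1z1(N), k1z2(N), k1z3(N), k1c(M);
  std::vector<C> k2z1(N), k2z2(N), k2z3(N), k2c(M);
  std::vector<C> k3z1(N), k3z2(N), k3z3(N), k3c(M);
  std::vector<C> k4z1(N), k4z2(N), k4z3(N), k4c(M);
  std::vector<C> t1(N), t2(N), t3(N), tc(M), x2ws(N);

  const double lim2 = 0.9999 * 0.9999;
  for (int n = 0; n < n_steps; ++n) {
    const C s0 = stim[n];
    const C sh = 0.5 * (stim[n] + stim[n + 1]);
    const C s1 = stim[n + 1];

    deriv(net, z1, z2, z3, c, s0, k1z1, k1z2, k1z3, k1c, x2ws);
    for (int i = 0; i < N; ++i) {
      t1[i] = z1[i] + 0.5 * dt * k1z1[i];
      t2[i] = z2[i] + 0.5 * dt * k1z2[i];
      t3[i] = z3[i] + 0.5 * dt * k1z3[i];
    }
    for (int t = 0; t < M; ++t) tc[t] = c[t] + 0.5 * dt * k1c[t];
    deriv(net, t1, t2, t3, tc, sh, k2z1, k2z2, k2z3, k2c, x2ws);
    for (int i = 0; i < N; ++i) {
      t1[i] = z1[i] + 0.5 * dt * k2z1[i];
      t2[i] = z2[i] + 0.5 * dt * k2z2[i];
      t3[i] = z3[i] + 0.5 * dt * k2z3[i];
    }
    for (int t = 0; t < M; ++t) tc[t] = c[t] + 0.5 * dt * k2c[t];
    deriv(net, t1, t2, t3, tc, sh, k3z1, k3z2, k3z3, k3c, x2ws);
    for (int i = 0; i < N; ++i) {
      t1[i] = z1[i] + dt * k3z1[i];
      t2[i] = z2[i] + dt * k3z2[i];
      t3[i] = z3[i] + dt * k3z3[i];
    }
    for (int t = 0; t < M; ++t) tc[t] = c[t] + dt * k3c[t];
    deriv(net, t1, t2, t3, tc, s1, k4z1, k4z2, k4z3, k4c, x2ws);

    const double h6 = dt / 6.0;
    for (int i = 0; i < N; ++i) {
      z1[i] += h6 * (k1z1[i] + 2.0 * k2z1[i] + 2.0 * k3z1[i] + k4z1[i]);
      z2[i] += h6 * (k1z2[i] + 2.0 * k2z2[i] + 2.0 * k3z2[i] + k4z2[i]);
      z3[i] += h6 * (k1z3[i] + 2.0 * k2z3[i] + 2.0 * k3z3[i] + k4z3[i]);
    }
    for (int t = 0; t < M; ++t)
      c[t] += h6 * (k1c[t] + 2.0 * k2c[t] + 2.0 * k3c[t] + k4c[t]);

    if (escaped(z1, lim2) || escaped(z2, lim2) || escaped(z3, lim2) ||
        escaped(c, lim2))
      Rcpp::stop("oscillator state or connection escaped the unit disk at t = %.4f s",
                 (n + 1) * dt);
    record(n + 1);
  }

  Rcpp::ComplexMatrix zf(3, N);
  for (int i = 0; i < N; ++i) {
    zf(0, i) = Rcomplex{z1[i].re, z1[i].im};
    zf(1, i) = Rcomplex{z2[i].re, z2[i].im};
    zf(2, i) = Rcomplex{z3[i].re, z3[i].im};
  }
  Rcpp::ComplexVector cf(M);
  for (int t = 0; t < M; ++t) cf[t] = Rcomplex{c[t].re, c[t].im};

  return Rcpp::List::create(Rcpp::Named("mean_fields") = mf,
                            Rcpp::Named("tracked") = tracked,
                            Rcpp::Named("z_final") = zf,
                            Rcpp::Named("c_final") = cf);
}
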