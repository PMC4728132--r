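#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Advance the membrane-cytosol reaction-diffusion system.
//
// Layout: `fields` is an N x N x 4 array (column-major), species order
// Cdc42T, Cdc42Dm, BemGEF42, BemGEFm; concentrations in uM (membrane shell
// convention). Cytosol pools Dc (GDP-Cdc42) and Bc (Bem1-GEF) are scalars.
//
// One macro step of size dt does, in order:
//   1. explicit 5-point periodic-Laplacian diffusion of all four fields
//      (Dm is small, so the diffusive bound dt <= h^2/(4 Dm) is loose);
//   2. if noise is on, an Euler-Maruyama increment s*sqrt(dt)/h * N(0,1) on
//      BemGEFm at every grid point, with the area-integrated increment
//      removed from BemGEFc so Bem1-GEF mass is conserved exactly;
//   3. pointwise reaction integration with the cytosol pools frozen: each
//      point takes ceil(dt * Lmax / theta) forward-Euler substeps, where
//      Lmax is the largest local per-species loss coefficient (stiffness
//      lives in the peak interior where k4a*Cdc42T is large); membrane <->
//      cytosol transfer is accumulated per substep and applied to the pools
//      afterwards, so both conservation laws hold to rounding error.
//
// With adaptive = false, step 3 uses a single forward-Euler step (the plain
// explicit Euler-Maruyama scheme kept for validation); dt must then satisfy
// the reaction stability bound itself.
//
// [[Rcpp::export]]
List advance_rd(NumericVector fields, double Dc, double Bc,
                List params, double h, double dt, int nsteps,
                bool noise, bool adaptive, double theta = 0.2) {
  IntegerVector dims = fields.attr("dim");
  const int N = dims[0];
  if (dims[1] != N || dims[2] != 4) stop("fields must be N x N x 4");
  const int M = N * N;

  const double k1a = params["k1a"], k1b = params["k1b"], s = params["s"];
  const double k2a = params["k2a"], k2b = params["k2b"], k3 = params["k3"];
  const double k4a = params["k4a"], k4b = params["k4b"];
  const double k5a = params["k5a"], k5b = params["k5b"], k7 = params["k7"];
  const double Dmdiff = params["Dm"], eta = params["eta"];

  NumericVector out = clone(fields);
  double *T  = out.begin();
  double *D  = out.begin() + M;
  double *G  = out.begin() + 2 * M;
  double *Bm = out.begin() + 3 * M;
  double *f4[4] = {T, D, G, Bm};

  std::vector<double> lap(M);
  std::vector<int> ip(N), im(N);
  for (int i = 0; i < N; ++i) {
    ip[i] = (i + 1) % N;
    im[i] = (i + N - 1) % N;
  }
  const double alpha = dt * Dmdiff / (h * h);
  if (alpha > 0.25)
    stop("dt exceeds the explicit diffusion stability bound h^2/(4 Dm)");
  const double noise_amp = s * std::sqrt(dt) / h;

  RNGScope scope;

  for (int step = 0; step < nsteps; ++step) {
    // 1. diffusion
    for (int sp = 0; sp < 4; ++sp) {
      double *f = f4[sp];
      for (int j = 0; j < N; ++j) {
        const int jN = j * N, jpN = ip[j] * N, jmN = im[j] * N;
        for (int i = 0; i < N; ++i)
          lap[i + jN] = f[ip[i] + jN] + f[im[i] + jN] +
                        f[i + jpN] + f[i + jmN] - 4.0 * f[i + jN];
      }
      for (int k = 0; k < M; ++k) f[k] += alpha * lap[k];
    }

    // 2. mass-neutral noise on Bem1-GEF membrane attachment
    if (noise && s > 0) {
      double tot = 0.0;
      for (int k = 0; k < M; ++k) {
        double inc = noise_amp * norm_rand();
        Bm[k] += inc;
        tot += inc;
      }
      Bc -= eta * tot / M;
      if (Bc < 0) {
        if (Bc < -1e-9) stop("noise drove cytosolic BemGEFc negative");
        Bc = 0;
      }
    }

    // 3. reactions, cytosol frozen, per-point adaptive substeps
    double cyt_c = 0.0, cyt_b = 0.0;  // time-integrated flow to cytosol
    const double gainD = k5a * Dc;    // constant within the macro step
    const double gainBm = k1a * Bc;
    for (int k = 0; k < M; ++k) {
      double t = T[k], d = D[k], g = G[k], bm = Bm[k];
      int nsub = 1;
      if (adaptive) {
        double LT = k2b + k4a * bm + k7 * Bc;
        double LD = k2a * bm + k3 * g + k5b;
        double LBm = k1b + k4a * t;
        double Lmax = std::max(std::max(LT, LD), std::max(k4b, LBm));
        nsub = (int)std::ceil(dt * Lmax / theta);
        if (nsub < 1) nsub = 1;
        if (nsub > 2000000) stop("reaction substep count exploded");
      }
      const double dts = dt / nsub;
      double acc_c = 0.0, acc_b = 0.0;
      for (int u = 0; u < nsub; ++u) {
        const double exch = (k2a * bm + k3 * g) * d;
        const double bindT = (k4a * bm + k7 * Bc) * t;
        const double rT = exch - k2b * t - bindT + k4b * g;
        const double rD = k2b * t - exch - k5b * d + gainD;
        const double rG = bindT - k4b * g;
        const double rBm = gainBm - k1b * bm + k4b * g - k4a * bm * t;
        acc_c += dts * (k5b * d - gainD);
        acc_b += dts * (k1b * bm - gainBm - k7 * Bc * t);
        t += dts * rT; d += dts * rD; g += dts * rG; bm += dts * rBm;
      }
      T[k] = t; D[k] = d; G[k] = g; Bm[k] = bm;
      cyt_c += acc_c; cyt_b += acc_b;
    }
    Dc += eta * cyt_c / M;
    Bc += eta * cyt_b / M;

    // sanity: clamp rounding-level negatives, abort on real ones
    for (int sp = 0; sp < 4; ++sp) {
      double *f = f4[sp];
      for (int k = 0; k < M; ++k) {
        if (f[k] < 0) {
          if (f[k] < -1e-9)
            stop("negative membrane concentration (%.3g) at step %d: "
                 "dt too large", f[k], step);
          f[k] = 0;
        }
        if (!std::isfinite(f[k]))
          stop("non-finite membrane concentration at step %d", step);
      }
    }
    if (Dc < 0) { if (Dc < -1e-9) stop("cytosolic Cdc42Dc negative"); Dc = 0; }
  }

  return List::create(_["fields"] = out, _["Cdc42Dc"] = Dc,
                      _["BemGEFc"] = Bc);
}
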