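// Finite-volume core for the nonlocal adhesion-repulsion-attraction models.
//
// Densities are cell averages on an N x N periodic grid over (-L, L)^2; the
// first matrix index is the x direction.  The nonlocal drift
//   K_i(x) = sum_j \int_{|y|<=1} u_j(x+y) w_ij(|y|) (y/|y|) dy
// is discretised as a fixed Cartesian stencil sampled at cell centres and
// applied either by FFT (circular cross-correlation, FFTW backend) or by
// direct summation.  The stencils are built on the R side; each carries the
// two components of the vector weight w(y) = w(|y|) * (y/|y|) * dx^2,
// offset-indexed with wraparound so that
// K[a,b] = sum_m u[(a+m1)%N, (b+m2)%N] * w[m1,m2].
//
// For real stencils wx, wy the two cross-correlation components are obtained
// together:  Kx + i*Ky = ifft2( fft2(u) * conj(fft2(wx - i*wy)) ).
// Plans use FFTW_ESTIMATE so plan selection (and hence rounding) is
// reproducible run to run.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <fftw3.h>
#include <complex>
#include <vector>
using namespace Rcpp;

namespace {

typedef std::complex<double> cplx;

// one-size c2c FFT pair with its own aligned buffer
struct FFT {
  int N = 0;
  fftw_complex* buf = nullptr;
  fftw_plan fwd = nullptr, bwd = nullptr;

  void init(int n) {
    N = n;
    buf = fftw_alloc_complex((size_t)N * N);
    // in-place transforms; ESTIMATE keeps planning deterministic and cheap
    fwd = fftw_plan_dft_2d(N, N, buf, buf, FFTW_FORWARD, FFTW_ESTIMATE);
    bwd = fftw_plan_dft_2d(N, N, buf, buf, FFTW_BACKWARD, FFTW_ESTIMATE);
  }
  ~FFT() {
    if (fwd) fftw_destroy_plan(fwd);
    if (bwd) fftw_destroy_plan(bwd);
    if (buf) fftw_free(buf);
  }
  cplx* data() { return reinterpret_cast<cplx*>(buf); }

  // forward transform of a real array into out
  void forward_real(const double* re, cplx* out) {
    cplx* b = data();
    const size_t M = (size_t)N * N;
    for (size_t q = 0; q < M; ++q) b[q] = cplx(re[q], 0.0);
    fftw_execute(fwd);
    std::copy(b, b + M, out);
  }
  // forward transform of a complex array into out
  void forward_cplx(const cplx* z, cplx* out) {
    cplx* b = data();
    const size_t M = (size_t)N * N;
    std::copy(z, z + M, b);
    fftw_execute(fwd);
    std::copy(b, b + M, out);
  }
  // unnormalised inverse transform of z, split into re/im parts scaled 1/N^2
  void backward_split(const cplx* z, double* re, double* im) {
    cplx* b = data();
    const size_t M = (size_t)N * N;
    std::copy(z, z + M, b);
    fftw_execute(bwd);
    const double s = 1.0 / (double)M;
    for (size_t q = 0; q < M; ++q) {
      re[q] = b[q].real() * s;
      im[q] = b[q].imag() * s;
    }
  }
};

// Workspace for one model configuration (grid + stencils), reused across
// steps.  All arrays are arma column-major; the grid is square so the FFT
// treats the memory layout consistently for fields and stencils alike.
struct Stepper {
  int N, ns;
  double dx;
  FFT fft;
  std::vector<std::vector<cplx>> P;     // ns*ns Fourier multipliers
  std::vector<std::vector<cplx>> Uhat;  // per-species spectra
  std::vector<cplx> acc;
  arma::mat sig, sat;
  std::vector<arma::mat> Kx, Ky, vfx, vfy;
  arma::mat Fx, Fy, unew;
  double vmax = 0, outmax = 0, maxsig = 0;

  Stepper(const List& stencils, int N_, int ns_, double dx_)
      : N(N_), ns(ns_), dx(dx_) {
    fft.init(N);
    const size_t M = (size_t)N * N;
    P.resize(ns * ns);
    std::vector<cplx> wc(M);
    for (int idx = 0; idx < ns * ns; ++idx) {
      List st = stencils[idx];
      NumericMatrix wx = st["wx"], wy = st["wy"];
      for (size_t q = 0; q < M; ++q) wc[q] = cplx(wx[q], -wy[q]);
      P[idx].resize(M);
      fft.forward_cplx(wc.data(), P[idx].data());
      for (size_t q = 0; q < M; ++q) P[idx][q] = std::conj(P[idx][q]);
    }
    Uhat.assign(ns, std::vector<cplx>(M));
    acc.resize(M);
    sig.set_size(N, N); sat.set_size(N, N);
    Kx.assign(ns, arma::mat(N, N)); Ky.assign(ns, arma::mat(N, N));
    vfx.assign(ns, arma::mat(N, N)); vfy.assign(ns, arma::mat(N, N));
    Fx.set_size(N, N); Fy.set_size(N, N); unew.set_size(N, N);
  }

  void nonlocal(const arma::cube& U) {
    const size_t M = (size_t)N * N;
    for (int j = 0; j < ns; ++j)
      fft.forward_real(U.slice(j).memptr(), Uhat[j].data());
    for (int i = 0; i < ns; ++i) {
      std::fill(acc.begin(), acc.end(), cplx(0.0, 0.0));
      for (int j = 0; j < ns; ++j) {
        const cplx* u = Uhat[j].data();
        const cplx* p = P[i * ns + j].data();
        for (size_t q = 0; q < M; ++q) acc[q] += u[q] * p[q];
      }
      fft.backward_split(acc.data(), Kx[i].memptr(), Ky[i].memptr());
    }
  }

  // face velocities (nonlinear-diffusion + saturated advective part) and the
  // quantities entering the admissible step.  vfx[s](a,b) sits between cells
  // (a,b) and (a+1,b); vfy between (a,b) and (a,b+1).
  void face_velocities(const arma::cube& U) {
    sig = arma::sum(U, 2);
    maxsig = sig.max();
    nonlocal(U);
    sat = arma::clamp(1.0 - sig, 0.0, arma::datum::inf);
    vmax = 0.0;
    for (int s = 0; s < ns; ++s) {
      const arma::mat& kx = Kx[s];
      const arma::mat& ky = Ky[s];
      arma::mat& fx = vfx[s];
      arma::mat& fy = vfy[s];
      for (int b = 0; b < N; ++b) {
        int bp = (b + 1) % N;
        for (int a = 0; a < N; ++a) {
          int ap = (a + 1) % N;
          double vx = -(sig(ap, b) - sig(a, b)) / dx +
                      0.5 * (sat(a, b) * kx(a, b) + sat(ap, b) * kx(ap, b));
          double vy = -(sig(a, bp) - sig(a, b)) / dx +
                      0.5 * (sat(a, b) * ky(a, b) + sat(a, bp) * ky(a, bp));
          fx(a, b) = vx;
          fy(a, b) = vy;
          double av = std::max(std::fabs(vx), std::fabs(vy));
          if (av > vmax) vmax = av;
        }
      }
    }
    // strict donor-cell positivity bound: total outflow speed per cell
    outmax = 0.0;
    for (int s = 0; s < ns; ++s) {
      const arma::mat& fx = vfx[s];
      const arma::mat& fy = vfy[s];
      for (int b = 0; b < N; ++b) {
        int bm = (b + N - 1) % N;
        for (int a = 0; a < N; ++a) {
          int am = (a + N - 1) % N;
          double out = std::max(fx(a, b), 0.0) + std::max(-fx(am, b), 0.0) +
                       std::max(fy(a, b), 0.0) + std::max(-fy(a, bm), 0.0);
          if (out > outmax) outmax = out;
        }
      }
    }
  }

  double admissible_dt() const {
    const double inf = arma::datum::inf;
    double d1 = maxsig > 0 ? dx * dx / (4.0 * maxsig) : inf;
    double d2 = vmax > 0 ? dx / (2.0 * vmax) : inf;
    double d3 = outmax > 0 ? dx / outmax : inf;
    return std::min(d1, std::min(d2, d3));
  }

  // conservative upwind donor-cell update
  void apply_fluxes(arma::cube& U, double dt) {
    for (int s = 0; s < ns; ++s) {
      arma::mat& u = U.slice(s);
      const arma::mat& fx = vfx[s];
      const arma::mat& fy = vfy[s];
      for (int b = 0; b < N; ++b) {
        int bp = (b + 1) % N;
        for (int a = 0; a < N; ++a) {
          int ap = (a + 1) % N;
          double vx = fx(a, b), vy = fy(a, b);
          Fx(a, b) = vx * (vx > 0 ? u(a, b) : u(ap, b));
          Fy(a, b) = vy * (vy > 0 ? u(a, b) : u(a, bp));
        }
      }
      for (int b = 0; b < N; ++b) {
        int bm = (b + N - 1) % N;
        for (int a = 0; a < N; ++a) {
          int am = (a + N - 1) % N;
          unew(a, b) = u(a, b) - dt / dx * (Fx(a, b) - Fx(am, b) +
                                            Fy(a, b) - Fy(a, bm));
        }
      }
      u = unew;
    }
  }
};

arma::cube fields_to_cube(const List& fields) {
  int ns = fields.size();
  arma::mat f0 = as<arma::mat>(fields[0]);
  arma::cube U(f0.n_rows, f0.n_cols, ns);
  U.slice(0) = f0;
  for (int s = 1; s < ns; ++s) U.slice(s) = as<arma::mat>(fields[s]);
  return U;
}

List cube_to_fields(const arma::cube& U) {
  List out(U.n_slices);
  for (arma::uword s = 0; s < U.n_slices; ++s) out[s] = wrap(U.slice(s));
  return out;
}

}  // namespace

// [[Rcpp::export]]
List nonlocal_fft_cpp(List fields, List stencils) {
  arma::cube U = fields_to_cube(fields);
  const int ns = U.n_slices, N = U.n_rows;
  Stepper w(stencils, N, ns, 1.0);
  w.nonlocal(U);
  List out(ns);
  for (int i = 0; i < ns; ++i)
    out[i] = List::create(_["Kx"] = wrap(w.Kx[i]), _["Ky"] = wrap(w.Ky[i]));
  return out;
}

// [[Rcpp::export]]
List nonlocal_direct_cpp(List fields, List stencils) {
  arma::cube U = fields_to_cube(fields);
  const int ns = U.n_slices, N = U.n_rows;
  List out(ns);
  for (int i = 0; i < ns; ++i) {
    arma::mat Kx(N, N, arma::fill::zeros), Ky(N, N, arma::fill::zeros);
    for (int j = 0; j < ns; ++j) {
      List st = stencils[i * ns + j];
      arma::mat wx = as<arma::mat>(st["wx"]);
      arma::mat wy = as<arma::mat>(st["wy"]);
      const arma::mat& u = U.slice(j);
      std::vector<int> m1s, m2s;
      std::vector<double> vx, vy;
      for (int m2 = 0; m2 < N; ++m2)
        for (int m1 = 0; m1 < N; ++m1)
          if (wx(m1, m2) != 0.0 || wy(m1, m2) != 0.0) {
            m1s.push_back(m1); m2s.push_back(m2);
            vx.push_back(wx(m1, m2)); vy.push_back(wy(m1, m2));
          }
      const int M = m1s.size();
      for (int b = 0; b < N; ++b)
        for (int a = 0; a < N; ++a) {
          double sx = 0.0, sy = 0.0;
          for (int m = 0; m < M; ++m) {
            double uv = u((a + m1s[m]) % N, (b + m2s[m]) % N);
            sx += uv * vx[m];
            sy += uv * vy[m];
          }
          Kx(a, b) += sx;
          Ky(a, b) += sy;
        }
    }
    out[i] = List::create(_["Kx"] = wrap(Kx), _["Ky"] = wrap(Ky));
  }
  return out;
}

// [[Rcpp::export]]
List ara_step_cpp(List fields, List stencils, double L, double dt, double cfl) {
  arma::cube U = fields_to_cube(fields);
  const int ns = U.n_slices, N = U.n_rows;
  const double dx = 2.0 * L / N;
  Stepper w(stencils, N, ns, dx);
  w.face_velocities(U);
  double adm = w.admissible_dt();
  if (dt <= 0) {
    dt = cfl * adm;
    if (!std::isfinite(dt)) dt = 1e-3;  // fully degenerate (zero) state
  } else if (dt > adm) {
    stop("time step dt = %g violates the stability restriction; admissible dt = %g",
         dt, adm);
  }
  w.apply_fluxes(U, dt);
  return List::create(_["fields"] = cube_to_fields(U), _["dt"] = dt,
                      _["dt_admissible"] = adm);
}

// [[Rcpp::export]]
List ara_run_cpp(List fields, List stencils, double L, double tol, double t0,
                 double t_max, double cfl, double check_interval, int max_steps,
                 double dt_max) {
  arma::cube U = fields_to_cube(fields);
  const int ns = U.n_slices, N = U.n_rows;
  const double dx = 2.0 * L / N;
  Stepper w(stencils, N, ns, dx);
  arma::cube prev = U;
  double t = t0;
  double next_check = t0 + check_interval;
  bool converged = false;
  int steps = 0;
  double dt = 0.0;
  std::vector<double> res_t, res_v;
  while (t < t_max - 1e-12 && steps < max_steps) {
    w.face_velocities(U);
    dt = cfl * w.admissible_dt();
    if (!std::isfinite(dt)) dt = check_interval;  // degenerate static state
    if (dt > dt_max) dt = dt_max;
    if (t + dt > next_check) dt = next_check - t;
    if (t + dt > t_max) dt = t_max - t;
    if (dt <= 1e-13) break;
    w.apply_fluxes(U, dt);
    t += dt;
    ++steps;
    if (t >= next_check - 1e-12) {
      double res = std::sqrt(arma::accu(arma::square(U - prev)) * dx * dx);
      res_t.push_back(t);
      res_v.push_back(res);
      if (res < tol) { converged = true; break; }
      prev = U;
      next_check += check_interval;
    }
    if (steps % 256 == 0) checkUserInterrupt();
  }
  return List::create(_["fields"] = cube_to_fields(U), _["t"] = t,
                      _["converged"] = converged, _["steps"] = steps,
                      _["res_times"] = wrap(res_t), _["res_values"] = wrap(res_v),
                      _["dt_last"] = dt);
}
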