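// Local atomic-environment descriptors: element-channelled Gaussian radial
// basis plus a spherical-harmonic power spectrum (2- and 3-body invariants),
// evaluated on overlap-tolerant transformed distances d~ = max(r, r_min)
// inside a smooth cosine cutoff envelope. Every term depends on the raw
// distance only through d~, so descriptors (and their analytic Jacobians)
// plateau exactly when atoms overlap below r_min and vanish smoothly at
// r_cut. Vectors are normalised to unit Euclidean length; the Jacobian
// includes the normalisation.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

// real orthonormal spherical harmonics up to l = 3 and their Cartesian
// gradients, via homogeneous solid harmonics S_lm: Y = S/r^l,
// grad Y = grad S / r^l - l S r_vec / r^(l+2)
static void sph_harm(const double v[3], double r, int lmax,
                     double* Y, double (*dY)[3], bool want_grad) {
  const double x = v[0], y = v[1], z = v[2];
  const int nY = (lmax + 1) * (lmax + 1);
  std::vector<double> S(nY), dS(nY * 3, 0.0);
  int k = 0;
  S[k] = 0.28209479177387814; // l=0
  ++k;
  if (lmax >= 1) {
    const double c1 = 0.4886025119029199;
    S[k] = c1 * y; dS[3 * k + 1] = c1; ++k;
    S[k] = c1 * z; dS[3 * k + 2] = c1; ++k;
    S[k] = c1 * x; dS[3 * k + 0] = c1; ++k;
  }
  if (lmax >= 2) {
    const double ca = 1.0925484305920792, c20 = 0.31539156525252005,
                 c22 = 0.5462742152960396;
    S[k] = ca * x * y; dS[3*k] = ca * y; dS[3*k+1] = ca * x; ++k;
    S[k] = ca * y * z; dS[3*k+1] = ca * z; dS[3*k+2] = ca * y; ++k;
    S[k] = c20 * (2*z*z - x*x - y*y);
    dS[3*k] = -2*c20*x; dS[3*k+1] = -2*c20*y; dS[3*k+2] = 4*c20*z; ++k;
    S[k] = ca * x * z; dS[3*k] = ca * z; dS[3*k+2] = ca * x; ++k;
    S[k] = c22 * (x*x - y*y); dS[3*k] = 2*c22*x; dS[3*k+1] = -2*c22*y; ++k;
  }
  if (lmax >= 3) {
    const double c3a = 0.5900435899266435, c3b = 2.890611442640554,
                 c3c = 0.4570457994644658, c30 = 0.3731763325901154,
                 c32 = 1.445305721320277;
    S[k] = c3a * y * (3*x*x - y*y);
    dS[3*k] = 6*c3a*x*y; dS[3*k+1] = 3*c3a*(x*x - y*y); ++k;
    S[k] = c3b * x * y * z;
    dS[3*k] = c3b*y*z; dS[3*k+1] = c3b*x*z; dS[3*k+2] = c3b*x*y; ++k;
    S[k] = c3c * y * (4*z*z - x*x - y*y);
    dS[3*k] = -2*c3c*x*y; dS[3*k+1] = c3c*(4*z*z - x*x - 3*y*y);
    dS[3*k+2] = 8*c3c*y*z; ++k;
    S[k] = c30 * z * (2*z*z - 3*x*x - 3*y*y);
    dS[3*k] = -6*c30*x*z; dS[3*k+1] = -6*c30*y*z;
    dS[3*k+2] = c30*(6*z*z - 3*x*x - 3*y*y); ++k;
    S[k] = c3c * x * (4*z*z - x*x - y*y);
    dS[3*k] = c3c*(4*z*z - 3*x*x - y*y); dS[3*k+1] = -2*c3c*x*y;
    dS[3*k+2] = 8*c3c*x*z; ++k;
    S[k] = c32 * z * (x*x - y*y);
    dS[3*k] = 2*c32*x*z; dS[3*k+1] = -2*c32*y*z; dS[3*k+2] = c32*(x*x - y*y); ++k;
    S[k] = c3a * x * (x*x - 3*y*y);
    dS[3*k] = 3*c3a*(x*x - y*y); dS[3*k+1] = -6*c3a*x*y; ++k;
  }
  // convert solid harmonics to surface harmonics
  double rl = 1.0; // r^l
  int idx = 0;
  for (int l = 0; l <= lmax; ++l) {
    const double inv_rl = 1.0 / rl;
    const double fac = l / (r * r * rl); // l / r^(l+2)
    for (int m = -l; m <= l; ++m, ++idx) {
      Y[idx] = S[idx] * inv_rl;
      if (want_grad) {
        for (int a = 0; a < 3; ++a) {
          dY[idx][a] = dS[3*idx + a] * inv_rl - fac * S[idx] * v[a];
        }
      }
    }
    rl *= r;
  }
}

// [[Rcpp::export]]
List cpp_descriptors(NumericMatrix pos, IntegerVector channel, int n_channel,
                     double r_cut, double r_min, int n_radial, int l_max,
                     double ang_delta, bool jacobian) {
  const int N = pos.nrow();
  const int E = n_channel;
  if (l_max > 3) stop("l_max > 3 is not supported");
  const int nY = (l_max + 1) * (l_max + 1);
  const int n_pair = E * (E + 1) / 2;
  const int d = E + E * n_radial + n_pair * (l_max + 1);

  NumericMatrix desc(N, d);
  NumericVector jac; // flat (d, 3, N, N); reshaped to an array on the R side
  if (jacobian) {
    jac = NumericVector((R_xlen_t)d * 3 * N * N);
  }
  if (N == 0) return List::create(_["desc"] = desc, _["jac"] = jac);

  // radial grid
  const double spacing = (n_radial > 1) ? (r_cut - r_min) / (n_radial - 1)
                                        : (r_cut - r_min);
  // basis width equal to the grid spacing: adjacent bumps overlap, which
  // keeps kernel distances smooth in r (narrower widths alias into
  // oscillatory pair forces)
  const double width = 1.0 * spacing;
  std::vector<double> mu(n_radial);
  for (int n = 0; n < n_radial; ++n) mu[n] = r_min + n * spacing;
  const double inv_w2 = 1.0 / (width * width);

  // pair index lookup for channel pairs (za <= zb)
  std::vector<int> pidx(E * E);
  {
    int c = 0;
    for (int a = 0; a < E; ++a)
      for (int b = a; b < E; ++b) { pidx[a * E + b] = c; pidx[b * E + a] = c; ++c; }
  }

  std::vector<double> v(d), dv; // raw vector and its gradient (d x 3N)
  std::vector<double> A(E * nY), dA;
  double Yv[16]; double dYv[16][3];

  for (int i = 0; i < N; ++i) {
    std::fill(v.begin(), v.end(), 0.0);
    std::fill(A.begin(), A.end(), 0.0);
    if (jacobian) {
      dv.assign((size_t)d * 3 * N, 0.0);
      dA.assign((size_t)E * nY * 3 * N, 0.0);
    }
    v[channel[i]] = 1.0; // element one-hot block

    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      double rv[3] = { pos(j,0) - pos(i,0), pos(j,1) - pos(i,1),
                       pos(j,2) - pos(i,2) };
      double r = std::sqrt(rv[0]*rv[0] + rv[1]*rv[1] + rv[2]*rv[2]);
      double dt = (r > r_min) ? r : r_min; // transformed distance
      if (dt >= r_cut) continue;
      const int zj = channel[j];
      const bool grad_active = jacobian && (r > r_min);
      double ur[3] = {0.0, 0.0, 0.0};
      if (r > 1e-12) { ur[0] = rv[0]/r; ur[1] = rv[1]/r; ur[2] = rv[2]/r; }

      // cutoff envelope on the transformed distance
      const double env = 0.5 * (std::cos(PI_ * dt / r_cut) + 1.0);
      const double denv = -0.5 * PI_ / r_cut * std::sin(PI_ * dt / r_cut);

      // radial block
      for (int n = 0; n < n_radial; ++n) {
        const double g = std::exp(-0.5 * (dt - mu[n]) * (dt - mu[n]) * inv_w2);
        const int f = E + zj * n_radial + n;
        v[f] += g * env;
        if (grad_active) {
          const double dT = (-(dt - mu[n]) * inv_w2 * g * env + g * denv);
          for (int a = 0; a < 3; ++a) {
            dv[(size_t)f + (size_t)d * (3*j + a)] += dT * ur[a];
            dv[(size_t)f + (size_t)d * (3*i + a)] -= dT * ur[a];
          }
        }
      }

      // angular block: switched on smoothly above the overlap plateau so the
      // (direction-dependent) harmonics never see an ill-defined r-hat
      double xs = (dt - r_min) / ang_delta;
      if (xs <= 0.0 || r <= 1e-12) continue;
      if (xs > 1.0) xs = 1.0;
      const double s = xs * xs * (3.0 - 2.0 * xs);
      const double dsw = (xs < 1.0) ? 6.0 * xs * (1.0 - xs) / ang_delta : 0.0;
      const double q = s * env;
      const double dq = dsw * env + s * denv;

      sph_harm(rv, r, l_max, Yv, dYv, grad_active);
      for (int m = 0; m < nY; ++m) {
        A[zj * nY + m] += q * Yv[m];
        if (grad_active) {
          for (int a = 0; a < 3; ++a) {
            const double g = dq * ur[a] * Yv[m] + q * dYv[m][a];
            dA[((size_t)zj * nY + m) * 3 * N + 3*j + a] += g;
            dA[((size_t)zj * nY + m) * 3 * N + 3*i + a] -= g;
          }
        }
      }
    }

    // power-spectrum block
    const int off = E + E * n_radial;
    for (int za = 0; za < E; ++za) {
      for (int zb = za; zb < E; ++zb) {
        const int pc = pidx[za * E + zb];
        int m0 = 0;
        for (int l = 0; l <= l_max; ++l) {
          double p = 0.0;
          const int f = off + pc * (l_max + 1) + l;
          for (int m = m0; m < m0 + 2*l + 1; ++m) {
            p += A[za * nY + m] * A[zb * nY + m];
            if (jacobian) {
              for (int c = 0; c < 3 * N; ++c) {
                dv[(size_t)f + (size_t)d * c] +=
                  A[za * nY + m] * dA[((size_t)zb * nY + m) * 3 * N + c] +
                  A[zb * nY + m] * dA[((size_t)za * nY + m) * 3 * N + c];
              }
            }
          }
          v[f] += p;
          m0 += 2*l + 1;
        }
      }
    }

    // unit normalisation (one-hot block guarantees a nonzero norm)
    double nv = 0.0;
    for (int f = 0; f < d; ++f) nv += v[f] * v[f];
    nv = std::sqrt(nv);
    for (int f = 0; f < d; ++f) desc(i, f) = v[f] / nv;
    if (jacobian) {
      for (int c = 0; c < 3 * N; ++c) {
        double proj = 0.0;
        for (int f = 0; f < d; ++f) proj += desc(i, f) * dv[(size_t)f + (size_t)d * c];
        for (int f = 0; f < d; ++f) {
          jac[(size_t)f + (size_t)d * c + (size_t)d * 3 * N * i] =
            (dv[(size_t)f + (size_t)d * c] - desc(i, f) * proj) / nv;
        }
      }
    }
  }
  return List::create(_["desc"] = desc, _["jac"] = jac);
}
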