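// Eigenfield resonance search for field-swept CW-EPR.
//
// For a fixed orientation of the static field B0 the Hamiltonian is linear in
// the field magnitude, H(B) = H0 + B * Hz1.  Eigenvalues are computed on an
// ascending field ladder; resonances are the roots of dE_ij(B) - h*nu for
// ordered level pairs (i < j), located by linear interpolation within the
// bracketing ladder segment and optionally refined by a safeguarded secant
// using values-only diagonalizations.  Transition intensity combines the
// squared magnetic-dipole moment perpendicular to B0 (g folded into the
// Zeeman derivative operators), the Boltzmann population difference, and the
// 1/|d(dE)/dB| frequency-to-field conversion.
//
// Ordered (sorted) eigenvalue pairs are tracked so that level anticrossings
// leave dE_ij(B) continuous.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static const double KB_CM_PER_K = 0.695034800; // Boltzmann constant, cm^-1/K

struct Root {
  double B, amp, slope;
  int i, j;
};

static void perp_frame(const vec& n, vec& u, vec& v) {
  vec e = {1.0, 0.0, 0.0};
  if (std::abs(n(0)) > 0.9) e = {0.0, 1.0, 0.0};
  u = cross(n, e);
  u /= norm(u);
  v = cross(n, u);
}

// Values-only level difference E_j - E_i at field B (sorted index tracking).
static double level_gap(const cx_mat& H0, const cx_mat& Hz1, double B,
                        int i, int j) {
  vec ev = eig_sym(cx_mat(H0 + B * Hz1));
  return ev(j) - ev(i);
}

static void orientation_roots(const cx_mat& H0, const cx_mat& Gx,
                              const cx_mat& Gy, const cx_mat& Gz,
                              const vec& n, const vec& ladder, double nu_cm,
                              double kT_cm, int vec_stride,
                              double refine_tol_G,
                              std::vector<Root>& out) {
  const int dim = H0.n_rows;
  const int K = ladder.n_elem;
  cx_mat Hz1 = n(0) * Gx + n(1) * Gy + n(2) * Gz;

  mat E(dim, K);
  std::vector<cx_mat> V;
  std::vector<int> vidx(K, -1);
  for (int k = 0; k < K; ++k) {
    cx_mat Hk = H0 + ladder(k) * Hz1;
    if (k % vec_stride == 0 || k == K - 1) {
      vec ev;
      cx_mat vk;
      eig_sym(ev, vk, Hk, "dc");
      E.col(k) = ev;
      vidx[k] = (int)V.size();
      V.push_back(vk);
    } else {
      E.col(k) = eig_sym(Hk);
    }
  }

  vec u, v;
  perp_frame(n, u, v);
  cx_mat O1 = u(0) * Gx + u(1) * Gy + u(2) * Gz;
  cx_mat O2 = v(0) * Gx + v(1) * Gy + v(2) * Gz;

  for (int k = 0; k < K - 1; ++k) {
    const double Ba = ladder(k), Bb = ladder(k + 1), dB = Bb - Ba;
    for (int i = 0; i < dim - 1; ++i) {
      for (int j = i + 1; j < dim; ++j) {
        double a = E(j, k) - E(i, k) - nu_cm;
        double b = E(j, k + 1) - E(i, k + 1) - nu_cm;
        if (a > 0 && b > 0) break; // gaps grow with j: no further roots
        // half-open bracketing so a root on a knot is counted once
        if (!((a <= 0 && b > 0) || (a >= 0 && b < 0))) continue;

        double slope = (b - a) / dB;
        if (std::abs(slope) < 1e-14) continue;
        double t = a / (a - b);
        double Bstar = Ba + t * dB;

        if (refine_tol_G > 0) {
          // safeguarded regula falsi on f(B) = dE(B) - h*nu
          double lo = Ba, hi = Bb, flo = a, fhi = b;
          for (int it = 0; it < 40; ++it) {
            double f = level_gap(H0, Hz1, Bstar, i, j) - nu_cm;
            if (std::abs(f / slope) <= refine_tol_G) break;
            if ((flo <= 0 && f > 0) || (flo >= 0 && f < 0)) {
              hi = Bstar;
              fhi = f;
            } else {
              lo = Bstar;
              flo = f;
            }
            slope = (fhi - flo) / (hi - lo);
            double Bn = (flo == fhi) ? 0.5 * (lo + hi)
                                     : lo - flo * (hi - lo) / (fhi - flo);
            if (Bn <= lo || Bn >= hi) Bn = 0.5 * (lo + hi);
            Bstar = Bn;
          }
        }

        // amplitude and populations from the nearest eigenvector knot
        int kn = (int)std::lround((k + t) / vec_stride) * vec_stride;
        if (kn < 0) kn = 0;
        if (kn > K - 1) kn = K - 1;
        if (vidx[kn] < 0) kn = K - 1;
        const cx_mat& Vm = V[vidx[kn]];
        cx_vec vi = Vm.col(i), vj = Vm.col(j);
        double moment = 0.5 * (std::norm(cdot(vj, O1 * vi)) +
                               std::norm(cdot(vj, O2 * vi)));

        double pop = 1.0;
        if (kT_cm > 0) {
          vec Ek = E.col(kn);
          vec w = exp(-(Ek - Ek.min()) / kT_cm);
          pop = (w(i) - w(j)) / accu(w);
          if (pop < 0) pop = 0;
        }

        Root r;
        r.B = Bstar;
        r.amp = moment * pop / std::abs(slope);
        r.slope = slope;
        r.i = i;
        r.j = j;
        if (r.amp > 0) out.push_back(r);
      }
    }
  }
}

// [[Rcpp::export(name = ".powder_sticks_cpp")]]
arma::mat powder_sticks_cpp(const arma::cx_mat& H0, const arma::cx_mat& Gx,
                            const arma::cx_mat& Gy, const arma::cx_mat& Gz,
                            const arma::mat& orientations,
                            const arma::vec& weights, const arma::vec& ladder,
                            double nu_cm, double temperature_K, int vec_stride,
                            double refine_tol_G) {
  const double kT = (std::isfinite(temperature_K) && temperature_K > 0)
                        ? KB_CM_PER_K * temperature_K
                        : -1.0;
  std::vector<double> Bs, As;
  std::vector<Root> roots;
  for (uword o = 0; o < orientations.n_rows; ++o) {
    if (o % 16 == 0) Rcpp::checkUserInterrupt();
    roots.clear();
    vec n = orientations.row(o).t();
    orientation_roots(H0, Gx, Gy, Gz, n, ladder, nu_cm, kT, vec_stride,
                      refine_tol_G, roots);
    for (const Root& r : roots) {
      Bs.push_back(r.B);
      As.push_back(r.amp * weights(o));
    }
  }
  mat out(Bs.size(), 2);
  for (size_t r = 0; r < Bs.size(); ++r) {
    out(r, 0) = Bs[r];
    out(r, 1) = As[r];
  }
  return out;
}

// [[Rcpp::export(name = ".resonances_cpp")]]
arma::mat resonances_cpp(const arma::cx_mat& H0, const arma::cx_mat& Gx,
                         const arma::cx_mat& Gy, const arma::cx_mat& Gz,
                         const arma::vec& orientation, const arma::vec& ladder,
                         double nu_cm, double temperature_K,
                         double refine_tol_G) {
  const double kT = (std::isfinite(temperature_K) && temperature_K > 0)
                        ? KB_CM_PER_K * temperature_K
                        : -1.0;
  std::vector<Root> roots;
  // eigenvectors at every knot for single-orientation searches
  orientation_roots(H0, Gx, Gy, Gz, orientation, ladder, nu_cm, kT, 1,
                    refine_tol_G, roots);
  mat out(roots.size(), 5);
  for (size_t r = 0; r < roots.size(); ++r) {
    out(r, 0) = roots[r].B;
    out(r, 1) = roots[r].amp;
    out(r, 2) = roots[r].i + 1; // 1-based level indices for R
    out(r, 3) = roots[r].j + 1;
    out(r, 4) = roots[r].slope;
  }
  return out;
}
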