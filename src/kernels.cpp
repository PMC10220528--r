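#include <Rcpp.h>
using namespace Rcpp;

static inline double min_image_1d(double d, double L) {
  return d - L * std::round(d / L);
}

// Histogram of minimum-image ref->target distances.
// counts[k] accumulates distances with k*dr < d <= (k+1)*dr is NOT the
// convention here; we use floor(d/dr), i.e. [k*dr, (k+1)*dr).
// [[Rcpp::export]]
IntegerVector cpp_dist_hist_pbc(NumericMatrix ref, NumericMatrix target,
                                NumericVector box, double dr, int nbins,
                                bool exclude_same_index) {
  IntegerVector counts(nbins);
  const double rmax = dr * nbins;
  const double rmax2 = rmax * rmax;
  for (int i = 0; i < ref.nrow(); ++i) {
    for (int j = 0; j < target.nrow(); ++j) {
      double dx = min_image_1d(ref(i, 0) - target(j, 0), box[0]);
      double dy = min_image_1d(ref(i, 1) - target(j, 1), box[1]);
      double dz = min_image_1d(ref(i, 2) - target(j, 2), box[2]);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= rmax2) continue;
      if (d2 == 0.0 && exclude_same_index) continue;
      int k = (int)std::floor(std::sqrt(d2) / dr);
      if (k >= 0 && k < nbins) counts[k]++;
    }
  }
  return counts;
}

// All (i, j) pairs (1-based) between point sets a and b with distance <=
// cutoff under minimum image; brute force O(n*m), fast enough for the frame
// sizes this package targets.
// [[Rcpp::export]]
IntegerMatrix cpp_pairs_within(NumericMatrix a, NumericMatrix b,
                               NumericVector box, double cutoff, bool use_pbc) {
  std::vector<int> ii, jj;
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < a.nrow(); ++i) {
    for (int j = 0; j < b.nrow(); ++j) {
      double dx = a(i, 0) - b(j, 0);
      double dy = a(i, 1) - b(j, 1);
      double dz = a(i, 2) - b(j, 2);
      if (use_pbc) {
        dx = min_image_1d(dx, box[0]);
        dy = min_image_1d(dy, box[1]);
        dz = min_image_1d(dz, box[2]);
      }
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= c2) { ii.push_back(i + 1); jj.push_back(j + 1); }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) { out(k, 0) = ii[k]; out(k, 1) = jj[k]; }
  return out;
}

// Overdamped Langevin (Euler-Maruyama) bead-spring polymer in explicit
// solvent, NVT, periodic orthorhombic box, reduced units (kB = 1, m = 1).
// Pair potentials: WCA (eps = 1, sigma) between all beads; an additional
// full Lennard-Jones well of depth eps_t (cut at 2.5 sigma) replaces WCA for
// solvent <-> terminal-bead pairs. Bonds are harmonic springs between
// consecutive polymer beads. Noise is drawn from R's RNG so set.seed()
// controls the trajectory bit-for-bit.
// [[Rcpp::export]]
List cpp_toy_langevin(NumericMatrix coords0, int n_polymer,
                      LogicalVector is_terminal, NumericVector box,
                      double bond_k, double bend_k, double sigma, double eps_t,
                      double backbone_sigma_factor,
                      double temperature, double gamma, double dt,
                      int n_steps, int n_equil, int stride) {
  const int n = coords0.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = coords0(i, 0); y[i] = coords0(i, 1); z[i] = coords0(i, 2); }
  const double rc_wca = std::pow(2.0, 1.0 / 6.0) * sigma;
  const double rc_wca2 = rc_wca * rc_wca;
  const double rc_lj = 2.5 * sigma;
  const double rc_lj2 = rc_lj * rc_lj;
  const double mob = dt / gamma;                       // mobility * dt
  const double noise = std::sqrt(2.0 * temperature * dt / gamma);
  const double max_disp = 0.3 * sigma;                 // clamp against rare overlaps
  std::vector<double> fx(n), fy(n), fz(n);
  List frames;
  RNGScope scope;

  for (int step = 0; step < n_steps; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    // bonds along the polymer backbone
    for (int i = 0; i + 1 < n_polymer; ++i) {
      double dx = min_image_1d(x[i + 1] - x[i], box[0]);
      double dy = min_image_1d(y[i + 1] - y[i], box[1]);
      double dz = min_image_1d(z[i + 1] - z[i], box[2]);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      double fmag = bond_k * (r - sigma) / r;          // pulls toward rest length sigma
      fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
      fx[i + 1] -= fmag * dx; fy[i + 1] -= fmag * dy; fz[i + 1] -= fmag * dz;
    }
    // bending stiffness: U = bend_k * (1 + cos theta) at each interior bead,
    // zero for a straight chain; keeps the occlusion geometry of terminal
    // beads well defined at desk-scale sampling
    if (bend_k > 0.0) {
      for (int j = 1; j + 1 < n_polymer; ++j) {
        double ux = min_image_1d(x[j - 1] - x[j], box[0]);
        double uy = min_image_1d(y[j - 1] - y[j], box[1]);
        double uz = min_image_1d(z[j - 1] - z[j], box[2]);
        double vx = min_image_1d(x[j + 1] - x[j], box[0]);
        double vy = min_image_1d(y[j + 1] - y[j], box[1]);
        double vz = min_image_1d(z[j + 1] - z[j], box[2]);
        double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
        double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
        if (nu < 1e-9 || nv < 1e-9) continue;
        double ct = (ux * vx + uy * vy + uz * vz) / (nu * nv);
        // grad of cos(theta) wrt the end beads
        double g1x = vx / (nu * nv) - ct * ux / (nu * nu);
        double g1y = vy / (nu * nv) - ct * uy / (nu * nu);
        double g1z = vz / (nu * nv) - ct * uz / (nu * nu);
        double g3x = ux / (nu * nv) - ct * vx / (nv * nv);
        double g3y = uy / (nu * nv) - ct * vy / (nv * nv);
        double g3z = uz / (nu * nv) - ct * vz / (nv * nv);
        fx[j - 1] -= bend_k * g1x; fy[j - 1] -= bend_k * g1y; fz[j - 1] -= bend_k * g1z;
        fx[j + 1] -= bend_k * g3x; fy[j + 1] -= bend_k * g3y; fz[j + 1] -= bend_k * g3z;
        fx[j] += bend_k * (g1x + g3x); fy[j] += bend_k * (g1y + g3y);
        fz[j] += bend_k * (g1z + g3z);
      }
    }
    // nonbonded pairs
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        bool bonded_pair = (j < n_polymer && j == i + 1);
        if (bonded_pair) continue;                     // bonded neighbours: spring only
        double dx = min_image_1d(x[i] - x[j], box[0]);
        double dy = min_image_1d(y[i] - y[j], box[1]);
        double dz = min_image_1d(z[i] - z[j], box[2]);
        double r2 = dx * dx + dy * dy + dz * dz;
        bool sticky = (i >= n_polymer && j < n_polymer && is_terminal[j]) ||
                      (j >= n_polymer && i < n_polymer && is_terminal[i]);
        // bulky non-terminal polymer beads: enlarged WCA radius toward the
        // solvent only, shielding the terminal beads' hydration shell
        bool bulky = (i >= n_polymer && j < n_polymer && !is_terminal[j]) ||
                     (j >= n_polymer && i < n_polymer && !is_terminal[i]);
        double sig = bulky ? backbone_sigma_factor * sigma : sigma;
        double cut2 = sticky ? rc_lj2 : std::pow(2.0, 1.0 / 3.0) * sig * sig;
        if (r2 >= cut2 || r2 < 1e-12) continue;
        double sr2 = sig * sig / r2;
        double sr6 = sr2 * sr2 * sr2;
        double eps = sticky ? eps_t : 1.0;
        // f/r = 24 eps (2 sr12 - sr6) / r2 ; WCA is LJ truncated at the minimum
        double fr = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / r2;
        fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
        fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
      }
    }
    for (int i = 0; i < n; ++i) {
      double ddx = fx[i] * mob + noise * norm_rand();
      double ddy = fy[i] * mob + noise * norm_rand();
      double ddz = fz[i] * mob + noise * norm_rand();
      double dmag = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      if (dmag > max_disp) { double s = max_disp / dmag; ddx *= s; ddy *= s; ddz *= s; }
      x[i] += ddx; y[i] += ddy; z[i] += ddz;
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i]))
        stop("toy Langevin integration became non-finite at step %d", step + 1);
      x[i] -= box[0] * std::floor(x[i] / box[0]);
      y[i] -= box[1] * std::floor(y[i] / box[1]);
      z[i] -= box[2] * std::floor(z[i] / box[2]);
    }
    if (step >= n_equil && ((step - n_equil) % stride == 0)) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i) { fr(i, 0) = x[i]; fr(i, 1) = y[i]; fr(i, 2) = z[i]; }
      frames.push_back(fr);
    }
  }
  return frames;
}
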