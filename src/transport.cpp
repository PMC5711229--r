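// Analog photon Monte Carlo transport in a homogeneous cylindrical phantom
// with track-length fluence estimation in thin cylindrical shell tallies on
// the source transverse plane.  Photons only (kerma approximation); free
// path from the total mass attenuation coefficient; interaction channels
// photoelectric (termination), incoherent (free-electron Klein-Nishina),
// coherent (form-factor-weighted Thomson via inverse-CDF sampling of the
// squared form factor), pair (termination plus two back-to-back 0.511 MeV
// photons).  Uses R's RNG so set.seed() gives bit-identical runs.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double MEC2 = 0.51099895;   // MeV
static const double HC_KEV_A = 12.3984193;

// linear interpolation in log(E) of pre-logged coefficient columns
struct CoefGrid {
  const double *logE;
  const double *col[4];   // log photoelectric, incoherent, coherent, pair
  int n;
  inline void lookup(double E, double out[4]) const {
    double le = std::log(E);
    if (le <= logE[0]) le = logE[0];
    if (le >= logE[n - 1]) le = logE[n - 1];
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) { int m = (lo + hi) >> 1; if (logE[m] <= le) lo = m; else hi = m; }
    double f = (le - logE[lo]) / (logE[lo + 1] - logE[lo]);
    for (int k = 0; k < 4; ++k) {
      double a = col[k][lo], b = col[k][lo + 1];
      double v = a + f * (b - a);
      out[k] = (v < -700.0) ? 0.0 : std::exp(v);
    }
  }
};

static inline double unif() {
  double u;
  do { u = R::unif_rand(); } while (u <= 0.0 || u >= 1.0);
  return u;
}

// Klein-Nishina sampling by rejection on cos(theta) with envelope 2
static inline void kn_sample(double E, double &Eprime, double &cost) {
  double alpha = E / MEC2;
  double c, f, x;
  do {
    c = 1.0 - 2.0 * unif();
    x = 1.0 / (1.0 + alpha * (1.0 - c));       // E'/E
    f = x * x * (x + 1.0 / x - (1.0 - c * c));
  } while (2.0 * unif() > f);
  cost = c;
  Eprime = E * x;
}

// rotate direction (u,v,w) by polar angle with cosine `cost` and uniform azimuth
static inline void rotate_dir(double &u, double &v, double &w, double cost) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double phi = 2.0 * M_PI * unif();
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(w) > 0.999999) {
    u = sint * cp; v = sint * sp; w = (w > 0 ? cost : -cost);
  } else {
    double den = std::sqrt(1.0 - w * w);
    double un = u * cost + sint * (u * w * cp - v * sp) / den;
    double vn = v * cost + sint * (v * w * cp + u * sp) / den;
    double wn = w * cost - sint * cp * den;
    double norm = std::sqrt(un * un + vn * vn + wn * wn);
    u = un / norm; v = vn / norm; w = wn / norm;
  }
}

struct Photon { double x, y, z, u, v, w, E; };

// [[Rcpp::export(name = ".simulate_cpp")]]
NumericVector simulate_cpp(NumericVector src_E, NumericVector src_cum,
                           NumericVector logE,
                           NumericVector log_pe, NumericVector log_inc,
                           NumericVector log_coh, NumericVector log_pair,
                           double density, double radius, double half_height,
                           NumericVector ring_r, double ring_dr, double ring_dz,
                           double e_cutoff, double e_binw, int nbins,
                           NumericVector hist_per_batch,
                           NumericVector coh_x2, NumericVector coh_cum,
                           bool use_coherent) {
  const int nring = ring_r.size(), nbatch = hist_per_batch.size();
  const int nsrc = src_E.size(), ncoh = coh_x2.size();
  CoefGrid grid;
  grid.logE = logE.begin(); grid.n = logE.size();
  grid.col[0] = log_pe.begin(); grid.col[1] = log_inc.begin();
  grid.col[2] = log_coh.begin(); grid.col[3] = log_pair.begin();

  NumericVector tall(nring * nbins * nbatch);  // raw chord-length sums
  std::vector<double> r2hi(nring), r2lo(nring);
  for (int j = 0; j < nring; ++j) {
    double rhi = ring_r[j] + 0.5 * ring_dr, rlo = ring_r[j] - 0.5 * ring_dr;
    r2hi[j] = rhi * rhi; r2lo[j] = (rlo > 0 ? rlo * rlo : 0.0);
  }
  const double dz2 = 0.5 * ring_dz;
  const double R2 = radius * radius;

  Photon stack[16];

  for (int b = 0; b < nbatch; ++b) {
    double nh = hist_per_batch[b];
    double *tb = tall.begin() + (size_t)b * nring * nbins;
    for (double h = 0; h < nh; h += 1.0) {
      if (((long long)h & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
      int nstk = 0;
      // primary emission: isotropic from the centre
      {
        double uu = unif();
        int li = 0;
        while (li < nsrc - 1 && uu > src_cum[li]) ++li;
        double w0 = 2.0 * unif() - 1.0;
        double s0 = std::sqrt(std::max(0.0, 1.0 - w0 * w0));
        double ph = 2.0 * M_PI * unif();
        stack[nstk++] = { 0.0, 0.0, 0.0, s0 * std::cos(ph), s0 * std::sin(ph),
                          w0, src_E[li] };
      }
      while (nstk > 0) {
        Photon p = stack[--nstk];
        for (;;) {
          if (p.E < e_cutoff) break;
          double part[4];
          grid.lookup(p.E, part);
          double mu = (part[0] + part[1] + part[2] + part[3]) * density; // 1/cm
          double sfree = (mu > 0) ? -std::log(unif()) / mu : 1e30;
          // distance to cylinder boundary
          double dexit = 1e30;
          double a = p.u * p.u + p.v * p.v;
          double bq = 2.0 * (p.x * p.u + p.y * p.v);
          double c0 = p.x * p.x + p.y * p.y;
          if (a > 1e-14) {
            double disc = bq * bq - 4.0 * a * (c0 - R2);
            if (disc > 0) {
              double t = (-bq + std::sqrt(disc)) / (2.0 * a);
              if (t > 0 && t < dexit) dexit = t;
            }
          }
          if (p.w > 1e-14)       { double t = (half_height - p.z) / p.w;  if (t < dexit) dexit = t; }
          else if (p.w < -1e-14) { double t = (-half_height - p.z) / p.w; if (t < dexit) dexit = t; }
          double seg = (sfree < dexit) ? sfree : dexit;
          // --- track-length tally over [0, seg] ---
          if (seg > 0) {
            double t0 = 0.0, t1 = seg;
            if (std::fabs(p.w) < 1e-14) {
              if (std::fabs(p.z) > dz2) t1 = -1.0;
            } else {
              double ta = (-dz2 - p.z) / p.w, tbnd = (dz2 - p.z) / p.w;
              if (ta > tbnd) { double tmp = ta; ta = tbnd; tbnd = tmp; }
              if (ta > t0) t0 = ta;
              if (tbnd < t1) t1 = tbnd;
            }
            if (t1 > t0) {
              int ib = (int)((p.E - e_cutoff) / e_binw);
              if (ib >= nbins) ib = nbins - 1;
              if (ib >= 0) {
                // radial range over [t0,t1] for quick ring rejection
                double q0 = a * t0 * t0 + bq * t0 + c0;
                double q1 = a * t1 * t1 + bq * t1 + c0;
                double qmin = (q0 < q1 ? q0 : q1), qmax = (q0 > q1 ? q0 : q1);
                if (a > 1e-14) {
                  double tv = -bq / (2.0 * a);
                  if (tv > t0 && tv < t1) {
                    double qv = a * tv * tv + bq * tv + c0;
                    if (qv < qmin) qmin = qv;
                  }
                }
                for (int j = 0; j < nring; ++j) {
                  if (r2hi[j] < qmin || r2lo[j] > qmax) continue;
                  double chord = 0.0;
                  // length inside disk rho^2 <= r2 minus inner disk
                  for (int side = 0; side < 2; ++side) {
                    double r2 = side == 0 ? r2hi[j] : r2lo[j];
                    double len = 0.0;
                    if (a <= 1e-14) {
                      if (c0 <= r2) len = t1 - t0;
                    } else {
                      double disc = bq * bq - 4.0 * a * (c0 - r2);
                      if (disc > 0) {
                        double sq = std::sqrt(disc);
                        double ta = (-bq - sq) / (2.0 * a);
                        double tbq = (-bq + sq) / (2.0 * a);
                        double lo = (ta > t0 ? ta : t0);
                        double hi = (tbq < t1 ? tbq : t1);
                        if (hi > lo) len = hi - lo;
                      }
                    }
                    chord += (side == 0 ? len : -len);
                  }
                  if (chord > 0) tb[(size_t)ib * nring + j] += chord;
                }
              }
            }
          }
          // --- end tally ---
          if (sfree >= dexit) break;  // escapes the phantom
          p.x += sfree * p.u; p.y += sfree * p.v; p.z += sfree * p.w;
          // select interaction channel
          double tot = part[0] + part[1] + part[2] + part[3];
          double xi = unif() * tot;
          if (xi < part[0]) break;                    // photoelectric
          xi -= part[0];
          if (xi < part[1]) {                         // incoherent
            double Ep, ct;
            kn_sample(p.E, Ep, ct);
            rotate_dir(p.u, p.v, p.w, ct);
            p.E = Ep;
            if (p.E < e_cutoff) break;
            continue;
          }
          xi -= part[1];
          if (xi < part[2]) {                         // coherent
            if (!use_coherent || ncoh < 2) continue;  // no deflection available
            double x2q = p.E * 1e3 / HC_KEV_A; x2q *= x2q;  // x^2 at theta=pi
            double x2max = coh_x2[ncoh - 1] < x2q ? coh_x2[ncoh - 1] : x2q;
            // Amax = cum at x2max (linear interp)
            int lo = 0, hi = ncoh - 1;
            while (hi - lo > 1) { int m = (lo + hi) >> 1; if (coh_x2[m] <= x2max) lo = m; else hi = m; }
            double f = (x2max - coh_x2[lo]) / (coh_x2[lo + 1] - coh_x2[lo]);
            double Amax = coh_cum[lo] + f * (coh_cum[lo + 1] - coh_cum[lo]);
            double ct;
            for (;;) {
              double Au = unif() * Amax;
              int l2 = 0, h2 = ncoh - 1;
              while (h2 - l2 > 1) { int m = (l2 + h2) >> 1; if (coh_cum[m] <= Au) l2 = m; else h2 = m; }
              double dc = coh_cum[l2 + 1] - coh_cum[l2];
              double g = dc > 0 ? (Au - coh_cum[l2]) / dc : 0.0;
              double x2 = coh_x2[l2] + g * (coh_x2[l2 + 1] - coh_x2[l2]);
              ct = 1.0 - 2.0 * x2 / x2q;
              if (ct < -1.0) ct = -1.0;
              if (2.0 * unif() <= 1.0 + ct * ct) break;
            }
            rotate_dir(p.u, p.v, p.w, ct);
            continue;
          }
          // pair production: local termination + two annihilation photons
          if (p.E > 2.0 * MEC2 && nstk < 14) {
            double w0 = 2.0 * unif() - 1.0;
            double s0 = std::sqrt(std::max(0.0, 1.0 - w0 * w0));
            double ph = 2.0 * M_PI * unif();
            double du = s0 * std::cos(ph), dv = s0 * std::sin(ph);
            stack[nstk++] = { p.x, p.y, p.z,  du,  dv,  w0, MEC2 };
            stack[nstk++] = { p.x, p.y, p.z, -du, -dv, -w0, MEC2 };
          }
          break;
        }
      }
    }
  }
  tall.attr("dim") = IntegerVector::create(nring, nbins, nbatch);
  return tall;
}

// [[Rcpp::export(name = ".sample_compton_cpp")]]
NumericMatrix sample_compton_cpp(double energy, int n) {
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double Ep, ct;
    kn_sample(energy, Ep, ct);
    out(i, 0) = Ep; out(i, 1) = ct;
  }
  colnames(out) = CharacterVector::create("energy_MeV", "cos_theta");
  return out;
}
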