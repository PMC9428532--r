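#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Image-source model for a shoebox room with uniform, frequency-dependent
// wall absorption (Allen & Berkley 1979 geometry).  All six surfaces share
// one reflection coefficient per octave band, beta = sqrt(1 - alpha), so an
// image reached after e wall hits carries amplitude beta^e / d with d the
// travel distance (1/r spherical spreading; the 1/(4*pi) constant is dropped
// because RIRs are energy-normalized downstream).
//
// Each arrival is injected at its exact fractional delay as a Hann-windowed
// sinc (Peterson 1986).  Nearest-sample rounding is NOT acceptable here: it
// adds the many late all-positive arrivals sharing one bin coherently at all
// frequencies, which inflates the late tail energy and stretches the decay.
//
// Returns an n_samples x n_bands matrix of band impulse trains; the band
// responses are recombined through a zero-phase octave filterbank in R.
//
// [[Rcpp::export(name = ".cpp_image_source")]]
NumericMatrix cpp_image_source(NumericVector room,      // Lx, Ly, Lz (m)
                               NumericVector src,       // source xyz (m)
                               NumericVector rcv,       // receiver xyz (m)
                               NumericVector beta,      // per-band reflection coeff
                               double fs,
                               double duration,         // seconds
                               double c,                // speed of sound (m/s)
                               IntegerVector max_order, // per-dimension |m| cap
                               NumericVector air_db_m)  // per-band air absorption, dB/m
{
  const int nb = beta.size();
  if (nb > 16) stop("at most 16 frequency bands supported");
  const int HW = 20; // half-width of the sinc injection kernel, samples
  const int n  = (int) std::ceil(duration * fs);
  const double rmax = c * duration; // images beyond this arrive after the tail

  NumericMatrix h(n, nb);

  // beta^e lookup; e is bounded by total wall hits along the three axes
  const int emax = 2 * (max_order[0] + max_order[1] + max_order[2]) + 3;
  std::vector< std::vector<double> > bpow(nb, std::vector<double>(emax + 1));
  for (int b = 0; b < nb; ++b) {
    bpow[b][0] = 1.0;
    for (int e = 1; e <= emax; ++e) bpow[b][e] = bpow[b][e - 1] * beta[b];
  }

  const double Lx = room[0], Ly = room[1], Lz = room[2];
  std::vector<double> lair(nb); // per-metre log attenuation
  for (int b = 0; b < nb; ++b) lair[b] = -std::log(10.0) / 20.0 * air_db_m[b];

  for (int mx = -max_order[0]; mx <= max_order[0]; ++mx) {
    const double tx = 2.0 * mx * Lx;
    for (int px = 0; px <= 1; ++px) {
      const double xi = (1 - 2 * px) * src[0] + tx - rcv[0];
      const int ex = std::abs(mx - px) + std::abs(mx);
      // quick reject: even the closest y/z images are too far
      if (std::abs(xi) > rmax) continue;
      for (int my = -max_order[1]; my <= max_order[1]; ++my) {
        const double ty = 2.0 * my * Ly;
        for (int py = 0; py <= 1; ++py) {
          const double yi = (1 - 2 * py) * src[1] + ty - rcv[1];
          const double dxy2 = xi * xi + yi * yi;
          if (dxy2 > rmax * rmax) continue;
          const int exy = ex + std::abs(my - py) + std::abs(my);
          for (int mz = -max_order[2]; mz <= max_order[2]; ++mz) {
            const double tz = 2.0 * mz * Lz;
            for (int pz = 0; pz <= 1; ++pz) {
              const double zi = (1 - 2 * pz) * src[2] + tz - rcv[2];
              const double d = std::sqrt(dxy2 + zi * zi);
              if (d < 1e-9) continue; // degenerate geometry guarded in R
              const double tau = d / c * fs;       // delay in samples
              const int bin0 = (int) std::floor(tau);
              if (bin0 >= n) continue;
              const int e = exy + std::abs(mz - pz) + std::abs(mz);
              const double g = 1.0 / d;
              double amp[16];
              for (int b = 0; b < nb; ++b)
                amp[b] = bpow[b][e] * g * std::exp(lair[b] * d);
              // windowed sinc at fractional delay: sin(pi*(k - frac)) =
              // -(-1)^k * sin(pi*frac), so one sin() per image suffices
              const double frac = tau - bin0;
              const double spf = std::sin(M_PI * frac);
              for (int k = -HW; k <= HW; ++k) {
                const int bin = bin0 + k;
                if (bin < 0 || bin >= n) continue;
                const double x = M_PI * (k - frac);
                double s;
                if (std::fabs(x) < 1e-8) s = 1.0;
                else s = ((k & 1) ? spf : -spf) / x; // = sin(x)/x
                const double w = 0.5 * (1.0 + std::cos(M_PI * (k - frac) / (HW + 1)));
                const double sw = s * w;
                for (int b = 0; b < nb; ++b)
                  h(bin, b) += amp[b] * sw;
              }
            }
          }
        }
      }
    }
  }
  return h;
}
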