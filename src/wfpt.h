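#ifndef VPLDDM_WFPT_H
#define VPLDDM_WFPT_H

#include <cmath>
#include <algorithm>

// Wiener first-passage-time density at the LOWER boundary for a diffusion
// with drift v, boundary separation a, relative start z in (0,1), diffusion
// coefficient 1.  Series evaluation follows the complementary small-time
// (Gaussian image) and large-time (sine) expansions; whichever needs fewer
// terms for truncation error <= err (in the a^2-scaled domain) is used.
//
// u is decision time (t - t0), u > 0.
inline double wfpt_flower(double u, double v, double a, double z, double err) {
    if (u <= 0.0) return 0.0;
    const double pi = M_PI;
    double tt = u / (a * a);  // scaled time

    // terms needed by each series
    double ks, kl;
    if (2.0 * std::sqrt(2.0 * pi * tt) * err < 1.0) {
        ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * err * std::sqrt(2.0 * pi * tt)));
        ks = std::max(ks, std::sqrt(tt) + 1.0);
    } else {
        ks = 2.0;
    }
    if (pi * tt * err < 1.0) {
        kl = std::sqrt(-2.0 * std::log(pi * tt * err) / (pi * pi * tt));
        kl = std::max(kl, 1.0 / (pi * std::sqrt(tt)));
    } else {
        kl = 1.0 / (pi * std::sqrt(tt));
    }

    double p;
    if (ks < kl) {  // small-time expansion
        int K = (int)std::ceil(ks);
        int lo = -(int)std::floor((K - 1) / 2.0);
        int hi = (int)std::ceil((K - 1) / 2.0);
        p = 0.0;
        for (int k = lo; k <= hi; ++k) {
            double w = z + 2.0 * k;
            p += w * std::exp(-w * w / (2.0 * tt));
        }
        p /= std::sqrt(2.0 * pi * tt * tt * tt);
    } else {        // large-time expansion
        int K = (int)std::ceil(kl);
        p = 0.0;
        for (int k = 1; k <= K; ++k) {
            p += k * std::exp(-k * k * pi * pi * tt / 2.0) * std::sin(k * pi * z);
        }
        p *= pi;
    }
    if (p < 0.0) p = 0.0;  // truncation can leave tiny negatives

    // unscale and apply the drift factor
    double dens = p * std::exp(-v * a * z - v * v * u / 2.0) / (a * a);
    return dens >= 0.0 ? dens : 0.0;
}

// Density at either boundary: upper-boundary passage is the lower-boundary
// passage of the sign-flipped, start-reflected process.
inline double wfpt_density_raw(double t, double v, double a, double t0, double z,
                               bool upper, double err) {
    double u = t - t0;
    if (u <= 0.0) return 0.0;
    if (upper) return wfpt_flower(u, -v, a, 1.0 - z, err);
    return wfpt_flower(u, v, a, z, err);
}

// P(absorb at upper boundary) for drift v, separation a, relative start z.
inline double absorb_upper_raw(double v, double a, double z) {
    if (v == 0.0) return z;
    double x = -2.0 * v * a;
    // P = (1 - e^{xz}) / (1 - e^x); guard against exp overflow for |x| large
    if (x > 50.0) return std::exp(x * (z - 1.0));   // both terms dominated by exponentials
    if (x < -50.0) return -std::expm1(x * z);       // denominator ~ 1
    return std::expm1(x * z) / std::expm1(x);
}

#endif
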