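#include <Rcpp.h>
#include <vector>
#include <functional>
#include "wfpt.h"
using namespace Rcpp;

// Hierarchical DDM sampler: single-parameter Gaussian random-walk
// Metropolis updates sweeping group-level then subject-level parameters,
// with proposal scales adapted toward 0.2-0.5 acceptance during burn-in
// and frozen afterwards.
//
// Parameter layout (flattened, must match the R-side parameter table):
//   group means   : for type in (v, a, t, z): one per factor cell
//   group sds     : same order            (hierarchical runs only)
//   subject values: for each subject, for type in (v, a, t, z): one per cell
//                                         (hierarchical runs only)
// z-type parameters live on the logit scale throughout.

static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

namespace {

struct Layout {
    int ncell[4];      // cells per type (v, a, t, z); z may be 0 (fixed 0.5)
    int off[4];        // offset of each type within a G-block
    int G;             // total cells across types
    int n_subj;
    bool hier;
    int P;             // total parameter count
    int mu_idx(int type, int c) const { return off[type] + c; }
    int sg_idx(int type, int c) const { return G + off[type] + c; }
    int x_idx(int j, int type, int c) const { return 2 * G + j * G + off[type] + c; }
};

// group-mean prior constants: v, a, t, logit-z
const double MU_M[4]  = {2.0, 1.5, 0.4, 0.0};
const double MU_S[4]  = {3.0, 1.0, 0.25, 0.5};
const double MU_LO[4] = {-INFINITY, 0.1, 0.0, -INFINITY};
// half-normal scales for group sds
const double SG_S[4]  = {1.0, 0.3, 0.3, 0.25};
// support floor for subject-level values
const double X_LO[4]  = {-INFINITY, 0.01, 0.0, -INFINITY};

inline double log_mu_prior(int type, double mu) {
    double d = (mu - MU_M[type]) / MU_S[type];
    return -0.5 * d * d;  // truncation constant fixed; support checked by caller
}

inline double log_sg_prior(int type, double sg) {
    double d = sg / SG_S[type];
    return -0.5 * d * d;
}

// subject-level prior: normal (v, logit-z) or lower-truncated normal (a, t);
// the truncation normalizer depends on (mu, sg) and must enter their updates
inline double log_x_prior(int type, double x, double mu, double sg) {
    double d = (x - mu) / sg;
    double lp = -0.5 * d * d - std::log(sg);
    if (std::isfinite(X_LO[type]))
        lp -= R::pnorm((mu - X_LO[type]) / sg, 0.0, 1.0, 1, 1);
    return lp;
}

}  // namespace

// [[Rcpp::export]]
List hddm_gibbs_cpp(NumericVector rt, IntegerVector resp_upper,
                    NumericVector drift_sign, IntegerVector subj,
                    IntegerVector cv, IntegerVector ca,
                    IntegerVector ct, IntegerVector cz,
                    int n_subj, IntegerVector ncell,
                    int n_sweeps, int n_burn, int thin,
                    double err, double lfloor,
                    NumericVector fixed) {
    // fixed: length 4 (v, a, t, logit-z); a non-NA entry clamps every cell
    // of that parameter type at the given value (no updates, no hierarchy)
    bool is_fixed[4];
    for (int ty = 0; ty < 4; ++ty) is_fixed[ty] = !NumericVector::is_na(fixed[ty]);
    const int n_tr = rt.size();
    Layout L;
    L.n_subj = n_subj;
    L.hier = n_subj > 1;
    L.G = 0;
    for (int ty = 0; ty < 4; ++ty) {
        L.ncell[ty] = ncell[ty];
        L.off[ty] = L.G;
        L.G += ncell[ty];
    }
    L.P = L.hier ? L.G * (2 + n_subj) : L.G;
    const bool has_z = L.ncell[3] > 0;
    const double log_lfloor = std::log(lfloor);

    // per-trial cell pointers by type
    const IntegerVector* cell[4] = {&cv, &ca, &ct, &cz};

    // affected-trial lists: for each (subject, type, cell) in hierarchical
    // runs, or each (type, cell) otherwise
    int n_units = (L.hier ? n_subj : 1) * L.G;
    std::vector< std::vector<int> > aff(n_units);
    for (int i = 0; i < n_tr; ++i) {
        int j = L.hier ? subj[i] : 0;
        for (int ty = 0; ty < 4; ++ty) {
            if (L.ncell[ty] == 0) continue;
            int c = (*cell[ty])[i];
            aff[j * L.G + L.off[ty] + c].push_back(i);
        }
    }

    std::vector<double> theta(L.P);
    double min_rt = n_tr > 0 ? *std::min_element(rt.begin(), rt.end()) : 1.0;

    // overdispersed initial values drawn through R's RNG
    for (int ty = 0; ty < 4; ++ty) {
        for (int c = 0; c < L.ncell[ty]; ++c) {
            if (is_fixed[ty]) {
                theta[L.mu_idx(ty, c)] = fixed[ty];
                if (L.hier) {
                    theta[L.sg_idx(ty, c)] = 1e-3;
                    for (int j = 0; j < n_subj; ++j)
                        theta[L.x_idx(j, ty, c)] = fixed[ty];
                }
                continue;
            }
            double m;
            switch (ty) {
            case 0: m = 2.0 + 0.7 * norm_rand(); break;
            case 1: m = std::max(0.3, 1.5 + 0.3 * norm_rand()); break;
            case 2: m = std::max(0.02, std::min(0.35, 0.7 * min_rt) +
                                 0.05 * norm_rand()); break;
            default: m = 0.2 * norm_rand(); break;
            }
            theta[L.mu_idx(ty, c)] = m;
            if (L.hier) {
                double s = 0.25 * SG_S[ty] * (1.0 + 0.5 * unif_rand());
                theta[L.sg_idx(ty, c)] = s;
                for (int j = 0; j < n_subj; ++j) {
                    double x = m + 0.3 * s * norm_rand();
                    if (std::isfinite(X_LO[ty]) && x <= X_LO[ty])
                        x = X_LO[ty] + 0.01;
                    theta[L.x_idx(j, ty, c)] = x;
                }
            }
        }
    }

    // per-trial loglik from the value level (subject level if hierarchical)
    std::vector<double> lltr(n_tr);
    int floored_total = 0;
    auto value_of = [&](int j, int ty, int c) -> double {
        return L.hier ? theta[L.x_idx(j, ty, c)] : theta[L.mu_idx(ty, c)];
    };
    auto trial_ll = [&](int i, int ty_changed, double newval) -> double {
        int j = L.hier ? subj[i] : 0;
        double xv = (ty_changed == 0) ? newval : value_of(j, 0, cv[i]);
        double xa = (ty_changed == 1) ? newval : value_of(j, 1, ca[i]);
        double xt = (ty_changed == 2) ? newval : value_of(j, 2, ct[i]);
        double zz = 0.5;
        if (has_z) {
            double xz = (ty_changed == 3) ? newval : value_of(j, 3, cz[i]);
            zz = invlogit(xz);
        }
        double v = drift_sign[i] * xv;
        double d = wfpt_density_raw(rt[i], v, xa, xt, zz, resp_upper[i] != 0, err);
        return (d < lfloor) ? log_lfloor : std::log(d);
    };
    for (int i = 0; i < n_tr; ++i) lltr[i] = trial_ll(i, -1, 0.0);

    // adaptive proposal machinery
    std::vector<double> scale(L.P), base(4);
    base[0] = 0.3; base[1] = 0.1; base[2] = 0.03; base[3] = 0.1;
    for (int ty = 0; ty < 4; ++ty)
        for (int c = 0; c < L.ncell[ty]; ++c) {
            scale[L.mu_idx(ty, c)] = base[ty];
            if (L.hier) {
                scale[L.sg_idx(ty, c)] = 0.5 * base[ty];
                for (int j = 0; j < n_subj; ++j)
                    scale[L.x_idx(j, ty, c)] = base[ty];
            }
        }
    std::vector<int> att(L.P, 0), acc(L.P, 0);
    std::vector<long> att_post(L.P, 0), acc_post(L.P, 0);

    auto mh_step = [&](int k, double lo,
                       const std::function<double(double, double)>& logtarget_delta,
                       const std::function<void(double)>& commit,
                       bool post_burn) {
        double cur = theta[k];
        double prop = cur + scale[k] * norm_rand();
        ++att[k];
        if (post_burn) ++att_post[k];
        if (prop <= lo) return;
        double delta = logtarget_delta(cur, prop);
        if (delta >= 0.0 || std::log(unif_rand()) < delta) {
            theta[k] = prop;
            commit(prop);
            ++acc[k];
            if (post_burn) ++acc_post[k];
        }
    };

    int kept_n = (n_sweeps - n_burn + thin - 1) / thin;
    NumericMatrix draws(kept_n, L.P);
    NumericVector deviance(kept_n);
    int kept = 0;
    std::vector<double> scratch;
    scratch.reserve(n_tr);

    for (int s = 0; s < n_sweeps; ++s) {
        bool post = s >= n_burn;

        for (int ty = 0; ty < 4; ++ty) {
            if (is_fixed[ty]) continue;
            for (int c = 0; c < L.ncell[ty]; ++c) {
                // ---- group mean ----
                int k = L.mu_idx(ty, c);
                if (L.hier) {
                    double sg = theta[L.sg_idx(ty, c)];
                    mh_step(k, MU_LO[ty],
                        [&](double cur, double prop) {
                            double d = log_mu_prior(ty, prop) - log_mu_prior(ty, cur);
                            for (int j = 0; j < n_subj; ++j) {
                                double x = theta[L.x_idx(j, ty, c)];
                                d += log_x_prior(ty, x, prop, sg)
                                   - log_x_prior(ty, x, cur, sg);
                            }
                            return d;
                        },
                        [](double) {}, post);
                } else {
                    const std::vector<int>& tr = aff[L.off[ty] + c];
                    mh_step(k, X_LO[ty] > MU_LO[ty] ? X_LO[ty] : MU_LO[ty],
                        [&](double cur, double prop) {
                            double d = log_mu_prior(ty, prop) - log_mu_prior(ty, cur);
                            scratch.clear();
                            for (int i : tr) {
                                double l = trial_ll(i, ty, prop);
                                scratch.push_back(l);
                                d += l - lltr[i];
                            }
                            return d;
                        },
                        [&](double) {
                            const std::vector<int>& tr2 = aff[L.off[ty] + c];
                            for (size_t q = 0; q < tr2.size(); ++q)
                                lltr[tr2[q]] = scratch[q];
                        }, post);
                }
                if (!L.hier) continue;

                // ---- group sd ----
                int ks = L.sg_idx(ty, c);
                double mu_now = theta[L.mu_idx(ty, c)];
                mh_step(ks, 1e-4,
                    [&](double cur, double prop) {
                        double d = log_sg_prior(ty, prop) - log_sg_prior(ty, cur);
                        for (int j = 0; j < n_subj; ++j) {
                            double x = theta[L.x_idx(j, ty, c)];
                            d += log_x_prior(ty, x, mu_now, prop)
                               - log_x_prior(ty, x, mu_now, cur);
                        }
                        return d;
                    },
                    [](double) {}, post);

                // ---- subject values ----
                double mu_c = theta[L.mu_idx(ty, c)];
                double sg_c = theta[L.sg_idx(ty, c)];
                for (int j = 0; j < n_subj; ++j) {
                    int kx = L.x_idx(j, ty, c);
                    const std::vector<int>& tr = aff[j * L.G + L.off[ty] + c];
                    mh_step(kx, X_LO[ty],
                        [&](double cur, double prop) {
                            double d = log_x_prior(ty, prop, mu_c, sg_c)
                                     - log_x_prior(ty, cur, mu_c, sg_c);
                            scratch.clear();
                            for (int i : tr) {
                                double l = trial_ll(i, ty, prop);
                                scratch.push_back(l);
                                d += l - lltr[i];
                            }
                            return d;
                        },
                        [&](double) {
                            for (size_t q = 0; q < tr.size(); ++q)
                                lltr[tr[q]] = scratch[q];
                        }, post);
                }
            }
        }

        // adapt proposal scales in batches of 50 during burn-in
        if (!post && (s + 1) % 50 == 0) {
            for (int k = 0; k < L.P; ++k) {
                if (att[k] == 0) continue;
                double rate = (double)acc[k] / att[k];
                scale[k] *= std::exp(rate - 0.35);
                scale[k] = std::min(5.0, std::max(1e-5, scale[k]));
                att[k] = acc[k] = 0;
            }
        }

        if (post && (s - n_burn) % thin == 0) {
            for (int k = 0; k < L.P; ++k) draws(kept, k) = theta[k];
            double ll = 0.0;
            for (int i = 0; i < n_tr; ++i) ll += lltr[i];
            deviance[kept] = -2.0 * ll;
            ++kept;
        }
    }

    NumericVector acc_rate(L.P);
    for (int k = 0; k < L.P; ++k)
        acc_rate[k] = att_post[k] > 0 ? (double)acc_post[k] / att_post[k] : NA_REAL;

    for (int i = 0; i < n_tr; ++i)
        if (lltr[i] <= log_lfloor + 1e-12) ++floored_total;

    return List::create(_["draws"] = draws,
                        _["deviance"] = deviance,
                        _["accept_rate"] = acc_rate,
                        _["scales"] = NumericVector(scale.begin(), scale.end()),
                        _["n_floored_final"] = floored_total);
}
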