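// Metropolis-within-Gibbs sampler for the hierarchical multispecies
// occupancy model with data augmentation.
//
// Latent binary states (supercommunity membership w, site occupancy z)
// and the inclusion probability omega have closed-form full conditionals;
// species-level parameters are updated by adaptive Gaussian random-walk
// Metropolis in two blocks per taxon (occupancy block, detection block);
// community means and SDs are updated by scalar adaptive random walks,
// with SDs proposed on the log scale and rejected outside their uniform
// prior support. To break the hierarchical funnel between community
// hyperparameters and species effects, each parameter column also gets
// interweaved group moves: a joint translation of the community mean
// with every species effect, and a joint rescaling of the community SD
// with the species deviations from the mean. Proposal adaptation is
// frozen at the end of burn-in.

#include <Rcpp.h>
using namespace Rcpp;

static inline double inv_logit_c(double l) {
  if (l > 0.0) return 1.0 / (1.0 + std::exp(-l));
  double e = std::exp(l);
  return e / (1.0 + e);
}

struct AdaptScale {
  double ls;       // log proposal scale
  int accepts;
  int tries;
  AdaptScale() : ls(std::log(0.5)), accepts(0), tries(0) {}
};

static inline void adapt(AdaptScale &a, double target, int batch_len,
                         int batch_no) {
  if (a.tries < batch_len) return;
  double rate = (double)a.accepts / (double)a.tries;
  double delta = std::min(0.05, 1.0 / std::sqrt((double)batch_no));
  a.ls += (rate > target ? delta : -delta);
  if (a.ls > 3.0) a.ls = 3.0;
  if (a.ls < -8.0) a.ls = -8.0;
  a.accepts = 0;
  a.tries = 0;
}

// [[Rcpp::export]]
List msom_chain_cpp(IntegerMatrix y,          // M x ncell
                    IntegerVector cell_site,  // ncell, 0-based, sorted
                    IntegerVector site_start, // J+1 offsets
                    NumericMatrix Xpsi,       // J x Dpsi
                    NumericMatrix Xdet,       // ncell x Ddet
                    IntegerVector mu_kind,    // Dall: 0 logit-unif, 1 normal
                    NumericVector mu_var,     // Dall (normal variance)
                    NumericVector sd_upper,   // Dall
                    double omega_a, double omega_b,
                    int n_iter, int burn, int thin,
                    NumericMatrix theta_init, // M x Dall
                    IntegerVector w_init,
                    IntegerMatrix z_init,     // M x J
                    double omega_init,
                    NumericVector mu_init, NumericVector sd_init,
                    bool fix_species, bool fix_omega, bool update_hyper) {
  const int M = y.nrow(), ncell = y.ncol();
  const int J = Xpsi.nrow(), Dpsi = Xpsi.ncol(), Ddet = Xdet.ncol();
  const int Dall = Dpsi + Ddet;
  const int batch_len = 50;

  NumericMatrix theta(clone(theta_init));
  IntegerVector w(clone(w_init));
  IntegerMatrix z(clone(z_init));
  double omega = omega_init;
  NumericVector mu(clone(mu_init)), sdv(clone(sd_init));

  // row-major caches: [i * stride + idx]
  std::vector<double> psi_lin((size_t)M * J), psi_p((size_t)M * J);
  std::vector<double> det_lin((size_t)M * ncell), det_p((size_t)M * ncell);
  // row-major copy of y for cache-friendly likelihood loops
  std::vector<int> yrow((size_t)M * ncell);
  for (int i = 0; i < M; ++i)
    for (int c = 0; c < ncell; ++c) yrow[(size_t)i * ncell + c] = y(i, c);

  std::vector<int> detected((size_t)M * J, 0);
  for (int i = 0; i < M; ++i)
    for (int c = 0; c < ncell; ++c)
      if (y(i, c) == 1) detected[(size_t)i * J + cell_site[c]] = 1;

  auto refresh_taxon = [&](int i) {
    for (int j = 0; j < J; ++j) {
      double l = 0.0;
      for (int q = 0; q < Dpsi; ++q) l += Xpsi(j, q) * theta(i, q);
      psi_lin[(size_t)i * J + j] = l;
      psi_p[(size_t)i * J + j] = inv_logit_c(l);
    }
    for (int c = 0; c < ncell; ++c) {
      double l = 0.0;
      for (int d = 0; d < Ddet; ++d) l += Xdet(c, d) * theta(i, Dpsi + d);
      det_lin[(size_t)i * ncell + c] = l;
      det_p[(size_t)i * ncell + c] = inv_logit_c(l);
    }
  };
  for (int i = 0; i < M; ++i) refresh_taxon(i);

  auto occ_ll_of = [&](int i, const double *ps) {
    if (w[i] == 0) return 0.0;
    double ll = 0.0;
    for (int j = 0; j < J; ++j)
      ll += (z(i, j) == 1) ? std::log(ps[j]) : std::log1p(-ps[j]);
    return ll;
  };
  auto det_ll_of = [&](int i, const double *pc) {
    double ll = 0.0;
    const int *yr = &yrow[(size_t)i * ncell];
    for (int j = 0; j < J; ++j) {
      if (z(i, j) != 1) continue;
      for (int c = site_start[j]; c < site_start[j + 1]; ++c)
        ll += (yr[c] == 1) ? std::log(pc[c]) : std::log1p(-pc[c]);
    }
    return ll;
  };

  // current-state log-likelihood caches (refreshed after latent updates)
  std::vector<double> occ_ll(M), det_ll(M);

  std::vector<AdaptScale> sc_occ(M), sc_det(M), sc_mu(Dall), sc_sd(Dall),
      sc_tr(Dall), sc_sc(Dall);
  for (int i = 0; i < M; ++i) { sc_occ[i].ls = std::log(0.3);
                                sc_det[i].ls = std::log(0.3); }
  for (int c = 0; c < Dall; ++c) { sc_tr[c].ls = std::log(0.3);
                                   sc_sc[c].ls = std::log(0.3); }

  const int n_ret = (n_iter > burn) ? (n_iter - burn) / thin : 0;
  NumericMatrix out_hyper(n_ret, 1 + 2 * Dall);
  NumericMatrix out_theta(n_ret, M * Dall);
  IntegerMatrix out_w(n_ret, M);
  IntegerMatrix out_z(n_ret, M * J);
  int row = 0, batch_no = 0;

  std::vector<double> th_new(Dall);
  const int buf = std::max(J, ncell);
  std::vector<double> prop_lin(buf), prop_p(buf);
  // proposal buffers for group moves (all taxa)
  std::vector<double> grp_lin((size_t)M * buf), grp_p((size_t)M * buf);
  std::vector<double> grp_ll(M);

  for (int iter = 1; iter <= n_iter; ++iter) {
    bool adapting = iter <= burn;

    // --- z | w, theta, y ------------------------------------------------
    for (int i = 0; i < M; ++i) {
      const double *pc = &det_p[(size_t)i * ncell];
      const double *ps = &psi_p[(size_t)i * J];
      for (int j = 0; j < J; ++j) {
        if (detected[(size_t)i * J + j]) { z(i, j) = 1; continue; }
        if (w[i] == 0) { z(i, j) = 0; continue; }
        double logq = 0.0;
        for (int c = site_start[j]; c < site_start[j + 1]; ++c)
          logq += std::log1p(-pc[c]);
        double num = ps[j] * std::exp(logq);
        double pr = num / (num + 1.0 - ps[j]);
        z(i, j) = (unif_rand() < pr) ? 1 : 0;
      }
    }

    // --- w | z, omega ---------------------------------------------------
    for (int i = 0; i < M; ++i) {
      bool anyz = false;
      for (int j = 0; j < J; ++j) if (z(i, j)) { anyz = true; break; }
      if (anyz) { w[i] = 1; continue; }
      const double *ps = &psi_p[(size_t)i * J];
      double logq = 0.0;
      for (int j = 0; j < J; ++j) logq += std::log1p(-ps[j]);
      double num = omega * std::exp(logq);
      double pr = num / (num + 1.0 - omega);
      w[i] = (unif_rand() < pr) ? 1 : 0;
    }

    // --- omega | w (conjugate) -----------------------------------------
    if (!fix_omega) {
      int sw = 0;
      for (int i = 0; i < M; ++i) sw += w[i];
      omega = R::rbeta(omega_a + sw, omega_b + M - sw);
    }

    if (!fix_species) {
      // refresh likelihood caches for the new latent states
      for (int i = 0; i < M; ++i) {
        occ_ll[i] = occ_ll_of(i, &psi_p[(size_t)i * J]);
        det_ll[i] = det_ll_of(i, &det_p[(size_t)i * ncell]);
      }

      // --- species parameters (two blocks per taxon) --------------------
      for (int i = 0; i < M; ++i) {
        // occupancy block
        {
          double s = std::exp(sc_occ[i].ls);
          double prior_cur = 0.0, prior_new = 0.0;
          for (int q = 0; q < Dpsi; ++q) {
            th_new[q] = theta(i, q) + s * norm_rand();
            prior_cur += R::dnorm(theta(i, q), mu[q], sdv[q], 1);
            prior_new += R::dnorm(th_new[q], mu[q], sdv[q], 1);
          }
          for (int j = 0; j < J; ++j) {
            double l = 0.0;
            for (int q = 0; q < Dpsi; ++q) l += Xpsi(j, q) * th_new[q];
            prop_lin[j] = l;
            prop_p[j] = inv_logit_c(l);
          }
          double lp_new = occ_ll_of(i, prop_p.data());
          sc_occ[i].tries++;
          if (std::log(unif_rand()) < (lp_new + prior_new) -
                                      (occ_ll[i] + prior_cur)) {
            for (int q = 0; q < Dpsi; ++q) theta(i, q) = th_new[q];
            std::copy(prop_lin.begin(), prop_lin.begin() + J,
                      psi_lin.begin() + (size_t)i * J);
            std::copy(prop_p.begin(), prop_p.begin() + J,
                      psi_p.begin() + (size_t)i * J);
            occ_ll[i] = lp_new;
            sc_occ[i].accepts++;
          }
        }
        // detection block
        {
          double s = std::exp(sc_det[i].ls);
          double prior_cur = 0.0, prior_new = 0.0;
          for (int d = 0; d < Ddet; ++d) {
            int cc = Dpsi + d;
            th_new[cc] = theta(i, cc) + s * norm_rand();
            prior_cur += R::dnorm(theta(i, cc), mu[cc], sdv[cc], 1);
            prior_new += R::dnorm(th_new[cc], mu[cc], sdv[cc], 1);
          }
          for (int c = 0; c < ncell; ++c) {
            double l = 0.0;
            for (int d = 0; d < Ddet; ++d) l += Xdet(c, d) * th_new[Dpsi + d];
            prop_lin[c] = l;
            prop_p[c] = inv_logit_c(l);
          }
          double lp_new = det_ll_of(i, prop_p.data());
          sc_det[i].tries++;
          if (std::log(unif_rand()) < (lp_new + prior_new) -
                                      (det_ll[i] + prior_cur)) {
            for (int d = 0; d < Ddet; ++d) theta(i, Dpsi + d) = th_new[Dpsi + d];
            std::copy(prop_lin.begin(), prop_lin.begin() + ncell,
                      det_lin.begin() + (size_t)i * ncell);
            std::copy(prop_p.begin(), prop_p.begin() + ncell,
                      det_p.begin() + (size_t)i * ncell);
            det_ll[i] = lp_new;
            sc_det[i].accepts++;
          }
        }
      }
    }

    // --- community hyperparameters --------------------------------------
    if (update_hyper) {
      for (int c = 0; c < Dall; ++c) {
        // mean: scalar random walk
        {
          double s = std::exp(sc_mu[c].ls);
          double mu_new = mu[c] + s * norm_rand();
          double lp_cur = 0.0, lp_new = 0.0;
          for (int i = 0; i < M; ++i) {
            lp_cur += R::dnorm(theta(i, c), mu[c], sdv[c], 1);
            lp_new += R::dnorm(theta(i, c), mu_new, sdv[c], 1);
          }
          if (mu_kind[c] == 0) {
            lp_cur += R::dlogis(mu[c], 0.0, 1.0, 1);
            lp_new += R::dlogis(mu_new, 0.0, 1.0, 1);
          } else {
            double sdp = std::sqrt(mu_var[c]);
            lp_cur += R::dnorm(mu[c], 0.0, sdp, 1);
            lp_new += R::dnorm(mu_new, 0.0, sdp, 1);
          }
          sc_mu[c].tries++;
          if (std::log(unif_rand()) < lp_new - lp_cur) {
            mu[c] = mu_new;
            sc_mu[c].accepts++;
          }
        }
        // SD: scalar log-scale random walk
        {
          double s = std::exp(sc_sd[c].ls);
          double sd_new = sdv[c] * std::exp(s * norm_rand());
          sc_sd[c].tries++;
          if (sd_new > 0.0 && sd_new < sd_upper[c]) {
            double lp_cur = std::log(sdv[c]);   // log-scale RW Jacobian
            double lp_new = std::log(sd_new);
            for (int i = 0; i < M; ++i) {
              lp_cur += R::dnorm(theta(i, c), mu[c], sdv[c], 1);
              lp_new += R::dnorm(theta(i, c), mu[c], sd_new, 1);
            }
            if (std::log(unif_rand()) < lp_new - lp_cur) {
              sdv[c] = sd_new;
              sc_sd[c].accepts++;
            }
          }
        }
      }

      // --- interweaved group moves (mean translation, SD rescale) -------
      if (!fix_species) {
        for (int c = 0; c < Dall; ++c) {
          const bool is_det = c >= Dpsi;
          const int n_out = is_det ? ncell : J;
          const std::vector<double> &lin_cache = is_det ? det_lin : psi_lin;
          const std::vector<double> &ll_cache = is_det ? det_ll : occ_ll;
          auto xval = [&](int k) {
            return is_det ? Xdet(k, c - Dpsi) : Xpsi(k, c);
          };
          // (a) translate mu[c] and the whole theta column by delta;
          // species-level normal terms cancel, only the data likelihood
          // and the mu prior change
          {
            double s = std::exp(sc_tr[c].ls);
            double delta = s * norm_rand();
            double lp_cur = 0.0, lp_new = 0.0;
            for (int i = 0; i < M; ++i) {
              lp_cur += ll_cache[i];
              double *gl = &grp_lin[(size_t)i * buf];
              double *gp = &grp_p[(size_t)i * buf];
              const double *lc = &lin_cache[(size_t)i * n_out];
              for (int k = 0; k < n_out; ++k) {
                gl[k] = lc[k] + delta * xval(k);
                gp[k] = inv_logit_c(gl[k]);
              }
              grp_ll[i] = is_det ? det_ll_of(i, gp) : occ_ll_of(i, gp);
              lp_new += grp_ll[i];
            }
            double mu_new = mu[c] + delta;
            if (mu_kind[c] == 0) {
              lp_cur += R::dlogis(mu[c], 0.0, 1.0, 1);
              lp_new += R::dlogis(mu_new, 0.0, 1.0, 1);
            } else {
              double sdp = std::sqrt(mu_var[c]);
              lp_cur += R::dnorm(mu[c], 0.0, sdp, 1);
              lp_new += R::dnorm(mu_new, 0.0, sdp, 1);
            }
            sc_tr[c].tries++;
            if (std::log(unif_rand()) < lp_new - lp_cur) {
              mu[c] = mu_new;
              for (int i = 0; i < M; ++i) {
                theta(i, c) += delta;
                double *gl = &grp_lin[(size_t)i * buf];
                double *gp = &grp_p[(size_t)i * buf];
                if (is_det) {
                  std::copy(gl, gl + ncell, det_lin.begin() + (size_t)i * ncell);
                  std::copy(gp, gp + ncell, det_p.begin() + (size_t)i * ncell);
                  det_ll[i] = grp_ll[i];
                } else {
                  std::copy(gl, gl + J, psi_lin.begin() + (size_t)i * J);
                  std::copy(gp, gp + J, psi_p.begin() + (size_t)i * J);
                  occ_ll[i] = grp_ll[i];
                }
              }
              sc_tr[c].accepts++;
            }
          }
          // (b) rescale sd[c] and the species deviations about mu[c];
          // the normal terms and transform Jacobians cancel except for
          // one log(factor) from the log-scale proposal
          {
            double s = std::exp(sc_sc[c].ls);
            double fac = std::exp(s * norm_rand());
            double sd_new = sdv[c] * fac;
            sc_sc[c].tries++;
            if (sd_new > 0.0 && sd_new < sd_upper[c]) {
              double lp_cur = 0.0, lp_new = std::log(fac);
              for (int i = 0; i < M; ++i) {
                lp_cur += ll_cache[i];
                double shift = (fac - 1.0) * (theta(i, c) - mu[c]);
                double *gl = &grp_lin[(size_t)i * buf];
                double *gp = &grp_p[(size_t)i * buf];
                const double *lc = &lin_cache[(size_t)i * n_out];
                for (int k = 0; k < n_out; ++k) {
                  gl[k] = lc[k] + shift * xval(k);
                  gp[k] = inv_logit_c(gl[k]);
                }
                grp_ll[i] = is_det ? det_ll_of(i, gp) : occ_ll_of(i, gp);
                lp_new += grp_ll[i];
              }
              if (std::log(unif_rand()) < lp_new - lp_cur) {
                sdv[c] = sd_new;
                for (int i = 0; i < M; ++i) {
                  theta(i, c) = mu[c] + fac * (theta(i, c) - mu[c]);
                  double *gl = &grp_lin[(size_t)i * buf];
                  double *gp = &grp_p[(size_t)i * buf];
                  if (is_det) {
                    std::copy(gl, gl + ncell,
                              det_lin.begin() + (size_t)i * ncell);
                    std::copy(gp, gp + ncell,
                              det_p.begin() + (size_t)i * ncell);
                    det_ll[i] = grp_ll[i];
                  } else {
                    std::copy(gl, gl + J, psi_lin.begin() + (size_t)i * J);
                    std::copy(gp, gp + J, psi_p.begin() + (size_t)i * J);
                    occ_ll[i] = grp_ll[i];
                  }
                }
                sc_sc[c].accepts++;
              }
            }
          }
        }
      }
    }

    // --- adaptation ------------------------------------------------------
    if (adapting && iter % batch_len == 0) {
      ++batch_no;
      for (int i = 0; i < M; ++i) {
        adapt(sc_occ[i], 0.234, batch_len, batch_no);
        adapt(sc_det[i], 0.234, batch_len, batch_no);
      }
      for (int c = 0; c < Dall; ++c) {
        adapt(sc_mu[c], 0.44, batch_len, batch_no);
        adapt(sc_sd[c], 0.44, batch_len, batch_no);
        adapt(sc_tr[c], 0.234, batch_len, batch_no);
        adapt(sc_sc[c], 0.234, batch_len, batch_no);
      }
    }

    // --- record ----------------------------------------------------------
    if (iter > burn && (iter - burn) % thin == 0 && row < n_ret) {
      out_hyper(row, 0) = omega;
      for (int c = 0; c < Dall; ++c) {
        out_hyper(row, 1 + c) = mu[c];
        out_hyper(row, 1 + Dall + c) = sdv[c];
      }
      for (int c = 0; c < Dall; ++c)
        for (int i = 0; i < M; ++i)
          out_theta(row, c * M + i) = theta(i, c);
      for (int i = 0; i < M; ++i) out_w(row, i) = w[i];
      for (int j = 0; j < J; ++j)
        for (int i = 0; i < M; ++i)
          out_z(row, j * M + i) = z(i, j);
      ++row;
    }
  }

  NumericVector acc_occ(M), acc_det(M);
  for (int i = 0; i < M; ++i) {
    acc_occ[i] = sc_occ[i].tries ? (double)sc_occ[i].accepts / sc_occ[i].tries
                                 : NA_REAL;
    acc_det[i] = sc_det[i].tries ? (double)sc_det[i].accepts / sc_det[i].tries
                                 : NA_REAL;
  }

  return List::create(_["hyper"] = out_hyper, _["theta"] = out_theta,
                      _["w"] = out_w, _["z"] = out_z,
                      _["accept_occ"] = acc_occ, _["accept_det"] = acc_det);
}
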