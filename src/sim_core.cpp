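#include <Rcpp.h>
using namespace Rcpp;

// One-dimensional overdamped force-balance model of the fission-yeast
// metaphase/anaphase spindle.  All elements (two poles, N_ch chromosomes
// each with two sister centromeres carrying M attachment sites) live on the
// spindle axis; inertia is neglected so drag * velocity = sum of forces.
//
// Force-velocity terms of the form A*(1 - v_toward/V) are linear in the
// element's own velocity, so each per-element balance is solved exactly for
// v instead of lagging the velocity one step behind.
//
// Randomness comes from R's RNG (unif_rand), so set.seed() on the R side
// makes runs reproducible.  Attachment-pole choices are expressed as
// "correct vs erroneous" rather than "left vs right", which makes the
// stochastic process exactly equivariant under mirror reflection of the
// initial state with the same random stream.

static inline double ldep_factor(double d_sp, double alpha, double d_mean,
                                 bool enabled, bool proportional) {
  if (!enabled) return 1.0;
  double f = proportional ? alpha * d_sp / d_mean
                          : 1.0 + alpha * (d_sp / d_mean - 1.0);
  return f > 0.0 ? f : 0.0;
}

// [[Rcpp::export]]
List sim_core(List par, List init, int n_meta, int n_ana, int out_every) {
  const double F_k   = as<double>(par["F_k"]);
  const double V_k   = as<double>(par["V_k"]);
  const double k_a   = as<double>(par["k_a"]);
  const double k_d   = as<double>(par["k_d"]);
  const double d_alpha = as<double>(par["d_alpha"]);
  const double beta  = as<double>(par["beta"]);
  const double K_c   = as<double>(par["K_c"]);
  const double d_0   = as<double>(par["d_0"]);
  const double K_k   = as<double>(par["K_k"]);
  const double mu_k  = as<double>(par["mu_k"]);
  const double F_mz  = as<double>(par["F_mz"]);
  const double V_mz  = as<double>(par["V_mz"]);
  const double mu_spb  = as<double>(par["mu_spb"]);
  const double mu_ch   = as<double>(par["mu_ch"]);
  const double mu_site = as<double>(par["mu_site"]);
  const double alpha   = as<double>(par["alpha"]);
  const double d_mean  = as<double>(par["d_mean"]);
  const bool   ldep_on = as<bool>(par["ldep_enabled"]);
  const bool   ldep_prop = as<std::string>(par["ldep_form"]) == "proportional";
  const double dt      = as<double>(par["dt"]);
  const double d_floor = as<double>(par["d_floor"]);
  const int N = as<int>(par["N_ch"]);
  const int M = as<int>(par["M_sites"]);
  const bool start_anaphase = as<bool>(init["anaphase"]);
  const double t0 = as<double>(init["t"]);

  double xL = as<double>(init["x_spbL"]);
  double xR = as<double>(init["x_spbR"]);
  NumericMatrix cen0 = init["x_cen"];     // N x 2
  NumericVector site0 = init["x_site"];   // N*2*M, index (c,s,m) -> (c*2+s)*M+m
  IntegerVector att0 = init["att"];       // -1 left pole, 0 detached, +1 right
  IntegerVector pi0 = init["pi"];         // -1 erroneous, 0, +1 correct

  const int nSis = N * 2, nSite = nSis * M;
  std::vector<double> cen(nSis), site(nSite);
  std::vector<int> att(nSite), pi(nSite);
  for (int c = 0; c < N; ++c)
    for (int s = 0; s < 2; ++s) cen[c * 2 + s] = cen0(c, s);
  for (int i = 0; i < nSite; ++i) {
    site[i] = site0[i];
    att[i] = att0[i];
    pi[i] = pi0[i];
  }
  std::vector<double> v_site(nSite, 0.0), v_cen(nSis, 0.0);
  std::vector<double> v_site_prev(nSite, 0.0), v_cen_prev(nSis, 0.0);
  std::vector<double> f_site(nSite, 0.0); // realised axial pulling force

  const int n_tot = n_meta + n_ana;
  const int n_out = n_tot / out_every + 1;
  // columns: t, anaphase, xL, xR, cen (2N), site (nSite), pi (nSite)
  const int ncol = 4 + nSis + 2 * nSite;
  NumericMatrix out(n_out, ncol);

  double attach_events = 0, detach_events = 0;
  double exp_attach = 0, exp_detach = 0;

  int row = 0;
  for (int step = 0; step <= n_tot; ++step) {
    bool anaphase = start_anaphase || step >= n_meta;
    if (step % out_every == 0) {
      out(row, 0) = t0 + step * dt;
      out(row, 1) = anaphase ? 1.0 : 0.0;
      out(row, 2) = xL;
      out(row, 3) = xR;
      for (int i = 0; i < nSis; ++i) out(row, 4 + i) = cen[i];
      for (int i = 0; i < nSite; ++i) out(row, 4 + nSis + i) = site[i];
      for (int i = 0; i < nSite; ++i) out(row, 4 + nSis + nSite + i) = pi[i];
      ++row;
    }
    if (step == n_tot) break;

    // ---- mechanics -------------------------------------------------------
    // attachment sites: mu_site * v = -K_k (x_s - x_c) - mu_k (vs - vc)_prev
    //                                + A*u - (A/V_k) v        (if attached)
    for (int c = 0; c < N; ++c) {
      for (int s = 0; s < 2; ++s) {
        int ic = c * 2 + s;
        for (int m = 0; m < M; ++m) {
          int i = ic * M + m;
          double f = -K_k * (site[i] - cen[ic]) -
                     mu_k * (v_site_prev[i] - v_cen_prev[ic]);
          double denom = mu_site;
          double A = 0.0;
          int u = 0;
          if (att[i] != 0) {
            double xp = att[i] > 0 ? xR : xL;
            double d_sp = std::fabs(xp - site[i]);
            A = F_k * ldep_factor(d_sp, alpha, d_mean, ldep_on && !anaphase,
                                  ldep_prop);
            u = (xp > site[i]) ? 1 : (xp < site[i] ? -1 : 0);
            f += A * u;
            denom += A / V_k;
          }
          double v = f / denom;
          v_site[i] = v;
          // realised axial force transmitted along the kMT (reaction on pole)
          f_site[i] = (att[i] != 0 && u != 0) ? A * (1.0 - u * v / V_k) * u : 0.0;
        }
      }
    }

    // centromeres: mu_ch * v = site springs/dampers + cohesin (metaphase)
    for (int c = 0; c < N; ++c) {
      for (int s = 0; s < 2; ++s) {
        int ic = c * 2 + s;
        double f = 0.0;
        for (int m = 0; m < M; ++m) {
          int i = ic * M + m;
          f += K_k * (site[i] - cen[ic]) +
               mu_k * (v_site_prev[i] - v_cen_prev[ic]);
        }
        if (!anaphase) {
          int io = c * 2 + (1 - s);
          double delta = cen[io] - cen[ic];
          double dist = std::fabs(delta);
          if (dist > 0)
            f += K_c * (dist - d_0) * (delta > 0 ? 1.0 : -1.0);
        }
        v_cen[ic] = f / mu_ch;
      }
    }

    // poles: mu_spb * v = +/- F_mz (1 - v_out/V_mz) + kMT reactions
    double reacL = 0.0, reacR = 0.0;
    for (int i = 0; i < nSite; ++i) {
      if (att[i] > 0) reacR += -f_site[i];
      else if (att[i] < 0) reacL += -f_site[i];
    }
    double vR = (F_mz + reacR) / (mu_spb + F_mz / V_mz);
    double vL = (reacL - F_mz) / (mu_spb + F_mz / V_mz);

    // ---- advance ---------------------------------------------------------
    xL += vL * dt;
    xR += vR * dt;
    // keep a residual spindle even when the midzone generator is overpowered
    if (xR - xL < 0.2) {
      double c = 0.5 * (xL + xR);
      xL = c - 0.1;
      xR = c + 0.1;
    }
    for (int i = 0; i < nSis; ++i) {
      cen[i] += v_cen[i] * dt;
      if (cen[i] < xL) cen[i] = xL;
      if (cen[i] > xR) cen[i] = xR;
    }
    for (int i = 0; i < nSite; ++i) {
      site[i] += v_site[i] * dt;
      if (site[i] < xL) site[i] = xL;
      if (site[i] > xR) site[i] = xR;
    }
    v_site_prev = v_site;
    v_cen_prev = v_cen;

    // ---- stochastic attachment / detachment ------------------------------
    for (int c = 0; c < N; ++c) {
      double m_pair = 0.5 * (cen[c * 2] + cen[c * 2 + 1]);
      int n_att_pair = 0;
      for (int k = 0; k < 2 * M; ++k)
        if (att[c * 2 * M + k] != 0) ++n_att_pair;
      for (int s = 0; s < 2; ++s) {
        int ic = c * 2 + s;
        // correct pole = the pole on this sister's side of the pair midpoint
        int correct;
        if (cen[ic] < m_pair) correct = -1;
        else if (cen[ic] > m_pair) correct = 1;
        else correct = (s == 0) ? -1 : 1;
        for (int m = 0; m < M; ++m) {
          int i = ic * M + m;
          if (att[i] == 0) {
            double p = k_a * dt;
            if (p > 1) p = 1;
            exp_attach += p;
            if (unif_rand() < p) {
              // new attachment: correct vs erroneous
              double p_corr = (n_att_pair > 0) ? (1.0 + beta) / 2.0 : 0.5;
              int newpi = (unif_rand() < p_corr) ? 1 : -1;
              pi[i] = newpi;
              att[i] = newpi * correct;
              ++n_att_pair;
              ++attach_events;
            }
          } else {
            double d_sc = std::fabs(site[i] - m_pair);
            if (d_sc < d_floor) d_sc = d_floor;
            double rate = k_d * d_alpha / d_sc;
            double p = rate * dt;
            if (p > 1) p = 1;
            exp_detach += p;
            if (unif_rand() < p) {
              att[i] = 0;
              pi[i] = 0;
              --n_att_pair;
              ++detach_events;
            }
          }
        }
      }
    }
  }

  NumericMatrix cen_end(N, 2);
  for (int c = 0; c < N; ++c)
    for (int s = 0; s < 2; ++s) cen_end(c, s) = cen[c * 2 + s];

  return List::create(
      _["snapshots"] = out,
      _["x_spbL"] = xL, _["x_spbR"] = xR, _["x_cen"] = cen_end,
      _["x_site"] = NumericVector(site.begin(), site.end()),
      _["att"] = IntegerVector(att.begin(), att.end()),
      _["pi"] = IntegerVector(pi.begin(), pi.end()),
      _["attach_events"] = attach_events,
      _["detach_events"] = detach_events,
      _["expected_attach"] = exp_attach,
      _["expected_detach"] = exp_detach);
}
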