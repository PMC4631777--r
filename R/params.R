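#' Model parameters for the spindle force-balance simulation
#'
#' Builds the full parameter set of the one-dimensional stochastic
#' force-balance model of the fission-yeast spindle.  Forces are expressed in
#' units of the attachment-site stall force `F_k` (nondimensional, default 1),
#' lengths in micrometres and times in seconds, so velocities are um/s, spring
#' constants force/um and drag coefficients force.s/um.
#'
#' @param F_k Stall force of a single attached site (force units).
#' @param V_k Maximum (unloaded) poleward velocity of an attachment site,
#'   um/s.  Sets the depolymerisation-limited speed of kinetochore movement.
#' @param k_a Attachment rate per detached site, 1/s.
#' @param k_d Baseline detachment rate, 1/s.  The effective rate is modulated
#'   by the distance between a site and the centre of its sister pair (see
#'   [detachment_rate()]), emulating Aurora-B-like destabilisation of
#'   low-tension attachments.
#' @param d_alpha Spatial range of the Aurora-B-like activity, um.  A site at
#'   distance `d_alpha` from the pair centre detaches at exactly `k_d`.
#' @param beta Orientation-effect parameter in \[0, 1\]: a new attachment on a
#'   pair that already has at least one attached site goes to the correct pole
#'   with probability `(1 + beta)/2` (see [choose_attachment_pole()]).
#' @param K_c Cohesin spring constant linking the two sister centromeres,
#'   force/um.
#' @param d_0 Cohesin rest length, um.  Together with `K_c` and the typical
#'   opposing pulling forces it sets the metaphase inter-sister distance
#'   (about 0.5 um with defaults).
#' @param K_k,mu_k Spring constant and damping of the centromere-site
#'   coupling.
#' @param F_mz,V_mz Stall force and maximum sliding velocity of the
#'   interdigitated-microtubule midzone force generator pushing the poles
#'   apart.
#' @param mu_spb,mu_ch,mu_site Drag coefficients of spindle poles,
#'   centromeres and attachment sites.
#' @param N_ch Number of chromosomes (3 in fission yeast).
#' @param M_sites Attachment sites per kinetochore (3).
#' @param alpha Strength of the length-dependent pulling-force prefactor
#'   (fractional force change per fractional site-pole distance change).
#' @param d_mean Mean in vivo site-pole distance, um, the reference at which
#'   the prefactor equals 1.
#' @param ldep_enabled Logical, whether the length-dependent prefactor is
#'   active during metaphase (it is always off in anaphase).
#' @param ldep_form Either `"offset"` (the default,
#'   `1 + alpha * (d/d_mean - 1)`) or `"proportional"`
#'   (`alpha * d/d_mean`, see [length_dep_factor()]).
#' @param dt Integration time step, s.
#' @param out_dt Snapshot interval, s (must be a multiple of `dt`).
#' @param t_meta Metaphase duration before the anaphase trigger, s.
#' @param t_ana Simulated anaphase duration, s.
#' @param L0 Initial spindle length, um.
#' @param d_floor Lower clamp on the site-to-pair-centre distance in the
#'   detachment-rate modulation, um.
#' @param seed Optional default RNG seed, used by [simulate_mitosis()] when no
#'   seed argument is given.
#' @param ... Unused; present so that configuration lists can be spliced in
#'   with `do.call()`.  Unknown names raise an error.
#'
#' @return An object of class `spindle_params`: a validated named list.
#' @examples
#' p <- spindle_params()
#' p$alpha
#' spindle_params(ldep_enabled = FALSE, t_meta = 120)
#' @export
spindle_params <- function(F_k = 1, V_k = 0.042,
                           k_a = 0.048, k_d = 0.048,
                           d_alpha = 0.25, beta = 0.9,
                           K_c = 4, d_0 = 0.25,
                           K_k = 10, mu_k = 0.5,
                           F_mz = 50, V_mz = 0.00135,
                           mu_spb = 200, mu_ch = 25, mu_site = 2,
                           N_ch = 3, M_sites = 3,
                           alpha = 0.2, d_mean = 1, ldep_enabled = TRUE,
                           ldep_form = c("offset", "proportional"),
                           dt = 0.05, out_dt = 1,
                           t_meta = 600, t_ana = 240,
                           L0 = 1.5, d_floor = 0.01, seed = NULL, ...) {
  dots <- list(...)
  if (length(dots) > 0) {
    abort(paste0("unknown model parameter(s): ",
                 paste(names(dots), collapse = ", ")))
  }
  ldep_form <- match.arg(ldep_form)
  p <- list(F_k = F_k, V_k = V_k, k_a = k_a, k_d = k_d,
            d_alpha = d_alpha, beta = beta, K_c = K_c, d_0 = d_0,
            K_k = K_k, mu_k = mu_k, F_mz = F_mz, V_mz = V_mz,
            mu_spb = mu_spb, mu_ch = mu_ch, mu_site = mu_site,
            N_ch = as.integer(N_ch), M_sites = as.integer(M_sites),
            alpha = alpha, d_mean = d_mean,
            ldep_enabled = isTRUE(ldep_enabled), ldep_form = ldep_form,
            dt = dt, out_dt = out_dt, t_meta = t_meta, t_ana = t_ana,
            L0 = L0, d_floor = d_floor, seed = seed)
  class(p) <- "spindle_params"
  validate_spindle_params(p)
}

#' Validate a spindle_params object
#'
#' Checks every invariant of the model parameter set and aborts with the
#' offending field name otherwise.
#'
#' @param p A `spindle_params` object (or plain named list with the same
#'   fields).
#' @return `p`, invisibly classed as `spindle_params`.
#' @export
validate_spindle_params <- function(p) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) abort(paste0("invalid parameter `", field, "`: ", msg))
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in c("F_k", "k_a", "k_d", "K_c", "d_0", "K_k", "mu_k", "F_mz",
              "alpha", "d_mean", "L0")) {
    chk(num1(p[[f]]) && p[[f]] >= 0, f, "must be a nonnegative number")
  }
  for (f in c("V_k", "V_mz", "mu_spb", "mu_ch", "mu_site", "d_alpha",
              "dt", "out_dt", "d_floor")) {
    chk(num1(p[[f]]) && p[[f]] > 0, f, "must be a positive number")
  }
  chk(num1(p$beta) && p$beta >= 0 && p$beta <= 1, "beta", "must lie in [0, 1]")
  chk(p$N_ch >= 1, "N_ch", "must be >= 1")
  chk(p$M_sites >= 1, "M_sites", "must be >= 1")
  chk(num1(p$t_meta) && p$t_meta >= 0, "t_meta", "must be >= 0")
  chk(num1(p$t_ana) && p$t_ana >= 0, "t_ana", "must be >= 0")
  chk(p$ldep_form %in% c("offset", "proportional"), "ldep_form",
      "must be 'offset' or 'proportional'")
  # the explicit Euler scheme needs per-step event probabilities well below 1
  chk(p$k_a * p$dt < 0.1, "dt", "k_a * dt must be < 0.1")
  chk(p$k_d * p$dt < 0.1, "dt", "k_d * dt must be < 0.1")
  steps_out <- p$out_dt / p$dt
  chk(abs(steps_out - round(steps_out)) < 1e-8, "out_dt",
      "must be a multiple of dt")
  invisible(structure(p, class = "spindle_params"))
}

#' @export
print.spindle_params <- function(x, ...) {
  cat("<spindle_params>\n")
  cat(sprintf("  %d chromosomes x 2 sisters x %d sites; L_dep %s (alpha=%g, d_mean=%g um)\n",
              x$N_ch, x$M_sites,
              if (x$ldep_enabled) "on" else "off", x$alpha, x$d_mean))
  cat(sprintf("  rates: k_a=%g/s k_d=%g/s d_alpha=%g um beta=%g\n",
              x$k_a, x$k_d, x$d_alpha, x$beta))
  cat(sprintf("  forces: F_k=%g V_k=%g um/s F_mz=%g V_mz=%g um/s K_c=%g K_k=%g\n",
              x$F_k, x$V_k, x$F_mz, x$V_mz, x$K_c, x$K_k))
  cat(sprintf("  schedule: dt=%gs, metaphase %gs + anaphase %gs, L0=%g um\n",
              x$dt, x$t_meta, x$t_ana, x$L0))
  invisible(x)
}
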