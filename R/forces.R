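#' Length-dependent pulling-force prefactor
#'
#' Multiplicative prefactor on the kinetochore pulling force that encodes the
#' kinesin-8-like length dependence: microtubules reaching further from their
#' pole pull harder.  The default ("offset") form is
#' `L_dep = 1 + alpha * (d_site_pole / d_mean - 1)`, clamped at 0, so that the
#' prefactor is exactly 1 at the mean site-pole distance and `alpha` is the
#' fractional force change per fractional length change.  The alternative
#' "proportional" form is `alpha * d_site_pole / d_mean`.
#'
#' @param d_site_pole Distance between the attachment site and its attached
#'   pole, um (vectorised, must be nonnegative).
#' @param alpha Strength of the length dependence (>= 0).
#' @param d_mean Reference site-pole distance, um.
#' @param enabled If `FALSE` the prefactor is identically 1.
#' @param form `"offset"` (default) or `"proportional"`.
#' @return Numeric vector of nonnegative prefactors, nondecreasing in
#'   `d_site_pole`.
#' @examples
#' length_dep_factor(1, alpha = 0.2, d_mean = 1)    # 1
#' length_dep_factor(2, alpha = 0.2, d_mean = 1)    # 1.2
#' length_dep_factor(2, enabled = FALSE)            # 1
#' @export
length_dep_factor <- function(d_site_pole, alpha = 0.2, d_mean = 1,
                              enabled = TRUE,
                              form = c("offset", "proportional")) {
  form <- match.arg(form)
  if (any(!is.finite(d_site_pole)) || any(d_site_pole < 0)) {
    abort("`d_site_pole` must be finite and nonnegative")
  }
  if (alpha < 0) abort("`alpha` must be >= 0")
  if (!enabled) return(rep(1, length(d_site_pole)))
  f <- if (form == "proportional") alpha * d_site_pole / d_mean
       else 1 + alpha * (d_site_pole / d_mean - 1)
  pmax(f, 0)
}

#' Pulling force on a single attachment site
#'
#' Linear force-velocity law of the kinetochore-microtubule force generator:
#' `F = ldep * F_k * (1 - v / V_k) * pi`, where `pi` is +1 when the site is
#' attached to the correct pole, -1 when attached to the opposite pole and 0
#' when detached.  `v` is the site velocity signed towards the attached pole,
#' so the force stalls at `ldep * F_k` and vanishes at `v = V_k`.
#'
#' @param v Site velocity towards the attached pole, um/s (vectorised).
#' @param pi Attachment state, in \{-1, 0, +1\}.
#' @param ldep Length-dependent prefactor (see [length_dep_factor()]).
#' @param F_k Stall force.
#' @param V_k Maximum velocity, um/s (> 0).
#' @return Signed force, 0 for detached sites.
#' @examples
#' pulling_force(0, pi = 1)        # stall force
#' pulling_force(0.05, pi = 1)     # zero at maximum velocity
#' pulling_force(0, pi = 0)        # detached
#' @export
pulling_force <- function(v, pi, ldep = 1, F_k = 1, V_k = 0.05) {
  if (V_k <= 0) abort("`V_k` must be > 0")
  if (!all(pi %in% c(-1, 0, 1))) abort("`pi` must be in {-1, 0, 1}")
  ldep * F_k * (1 - v / V_k) * pi
}

#' Distance-modulated detachment rate
#'
#' Effective detachment rate of an attached site as a function of its distance
#' to the centre of the sister-kinetochore pair, emulating an Aurora-B-like
#' activity concentrated at the pair centre that destabilises nearby (i.e.
#' low-tension) attachments: `rate = k_d * d_alpha / max(d, d_floor)`.  At
#' `d = d_alpha` the rate equals the baseline `k_d`, and it decreases with
#' distance; the clamp `d_floor` keeps it finite at the pair centre.
#'
#' @param d_site_center Distance between the site and the pair centre, um
#'   (vectorised, >= 0).
#' @param k_d Baseline detachment rate, 1/s.
#' @param d_alpha Spatial range of the Aurora-B-like activity, um (> 0).
#' @param d_floor Clamp distance, um (> 0).
#' @return Detachment rates, 1/s.
#' @examples
#' detachment_rate(0.25, k_d = 0.06, d_alpha = 0.25)   # k_d
#' detachment_rate(0.50, k_d = 0.06, d_alpha = 0.25)   # k_d / 2
#' @export
detachment_rate <- function(d_site_center, k_d = 0.06, d_alpha = 0.25,
                            d_floor = 0.01) {
  if (d_alpha <= 0) abort("`d_alpha` must be > 0")
  if (d_floor <= 0) abort("`d_floor` must be > 0")
  if (any(!is.finite(d_site_center)) || any(d_site_center < 0)) {
    abort("`d_site_center` must be finite and nonnegative")
  }
  k_d * d_alpha / pmax(d_site_center, d_floor)
}

#' Pole choice for a newly attaching site
#'
#' Samples the attachment state of a site that is about to attach.  If the
#' sister pair already has at least one attached site the new attachment is
#' correct (towards the sister's own pole) with probability `(1 + beta)/2`,
#' linearly interpolating between equiprobable (`beta = 0`) and error-free
#' (`beta = 1`).  A fully unattached pair attaches to either pole with
#' probability 1/2.
#'
#' @param pair_attached Logical (or count): does the pair currently have any
#'   attached site?
#' @param beta Orientation-effect parameter in \[0, 1\].
#' @param n Number of independent draws.
#' @return Integer vector of `n` attachment states: +1 (correct pole) or -1
#'   (erroneous pole).
#' @examples
#' set.seed(1)
#' choose_attachment_pole(TRUE, beta = 1, n = 5)   # all +1
#' @export
choose_attachment_pole <- function(pair_attached, beta = 0.9, n = 1) {
  if (beta < 0 || beta > 1) abort("`beta` must lie in [0, 1]")
  p_correct <- if (as.integer(pair_attached) > 0) (1 + beta) / 2 else 0.5
  ifelse(runif(n) < p_correct, 1L, -1L)
}
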