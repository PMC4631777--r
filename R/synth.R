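#' Parameters of the synthetic trajectory generator
#'
#' Defaults emulate the phenomenology of metaphase kinetochore trajectories
#' in fission yeast: square-wave-like oscillations of the sister-pair
#' midpoint (piecewise-linear poleward / anti-poleward runs with stochastic
#' reversals), inter-event midline drifts, sister "breathing" around an
#' inter-sister distance of ~0.5 um, Gaussian localisation noise, and
#' (optionally) transient detachment excursions towards a pole labelled with
#' a checkpoint-signal burst.  Presets carry the published wild-type,
#' kinesin-8-deletion and low-dose-TBZ measurements: amplitude 0.23 / 0.35 /
#' 0.14 um, half-period 63 / 76 / 64 s, drift 0.1 / 0.2 / 0.06 um, spindle
#' length at anaphase onset 2.95 / 4.68 / 2.95 um.
#'
#' @param preset `"wt"`, `"klp6"` or `"tbz"`.
#' @param amplitude Oscillation amplitude of the pair midpoint, um.
#' @param half_period Mean semi-period of the oscillation, s.
#' @param drift_sd Standard deviation of the midline step applied at each
#'   reversal event, um.
#' @param detach_rate Rate of detachment excursions, 1/s (0 disables them).
#' @param detach_excursion Excursion distance towards the nearest pole, um.
#' @param detach_speed Excursion speed, um/min.
#' @param spindle_length Pole-to-pole distance, um.
#' @param spindle_growth Spindle elongation rate, um/s (0 = constant).
#' @param breathing_mean,breathing_sd Mean and slow-fluctuation sd of the
#'   inter-sister distance, um.
#' @param noise_sd Localisation noise added to every reported position, um.
#' @param duration Trace duration, s.
#' @param dt Frame interval, s.
#' @param waveform `"ramp"` (piecewise-linear, the default: oscillations are
#'   depolymerisation-driven runs) or `"sine"` (for closed-form Fourier
#'   checks).
#' @param deterministic_reversal If `TRUE` reversals occur exactly every
#'   `half_period`; otherwise waiting times are exponential with that mean,
#'   truncated at 3x the mean.
#' @param anaphase_speed Poleward speed used by
#'   [synth_anaphase_trajectory()], um/min.
#' @param seed Optional default seed.
#' @param ... Unknown names are an error.
#' @return A `synth_params` list.
#' @export
synth_params <- function(preset = c("wt", "klp6", "tbz"),
                         amplitude = NULL, half_period = NULL,
                         drift_sd = NULL, detach_rate = NULL,
                         detach_excursion = 1, detach_speed = 2.5,
                         spindle_length = NULL, spindle_growth = 0,
                         breathing_mean = 0.5, breathing_sd = 0.05,
                         noise_sd = 0.02, duration = 600, dt = 0.5,
                         waveform = c("ramp", "sine"),
                         deterministic_reversal = FALSE,
                         anaphase_speed = 2, seed = NULL, ...) {
  dots <- list(...)
  if (length(dots) > 0) {
    abort(paste0("unknown synthetic parameter(s): ",
                 paste(names(dots), collapse = ", ")))
  }
  preset <- match.arg(preset)
  def <- switch(preset,
    wt   = list(amplitude = 0.23, half_period = 63, drift_sd = 0.1,
                detach_rate = 0, spindle_length = 2.95),
    klp6 = list(amplitude = 0.35, half_period = 76, drift_sd = 0.2,
                detach_rate = 0.005, spindle_length = 4.68),
    tbz  = list(amplitude = 0.14, half_period = 64, drift_sd = 0.06,
                detach_rate = 0, spindle_length = 2.95))
  p <- list(preset = preset,
            amplitude = amplitude %||% def$amplitude,
            half_period = half_period %||% def$half_period,
            drift_sd = drift_sd %||% def$drift_sd,
            detach_rate = detach_rate %||% def$detach_rate,
            detach_excursion = detach_excursion,
            detach_speed = detach_speed,
            spindle_length = spindle_length %||% def$spindle_length,
            spindle_growth = spindle_growth,
            breathing_mean = breathing_mean, breathing_sd = breathing_sd,
            noise_sd = noise_sd, duration = duration, dt = dt,
            waveform = match.arg(waveform),
            deterministic_reversal = isTRUE(deterministic_reversal),
            anaphase_speed = anaphase_speed, seed = seed)
  for (f in c("drift_sd", "breathing_sd", "noise_sd", "detach_rate",
              "spindle_growth")) {
    if (p[[f]] < 0) abort(paste0("invalid parameter `", f, "`: must be >= 0"))
  }
  for (f in c("amplitude", "half_period", "spindle_length", "duration",
              "dt", "breathing_mean", "anaphase_speed")) {
    if (p[[f]] <= 0) abort(paste0("invalid parameter `", f, "`: must be > 0"))
  }
  structure(p, class = "synth_params")
}

#' Synthetic metaphase trajectory
#'
#' Generates one experimental-style tracked trajectory according to a
#' [synth_params()] stated world: alternating poleward/anti-poleward midline
#' ramps (or a sinusoid) with reversal events, a Gaussian midline drift step
#' at each reversal, slowly fluctuating sister breathing, localisation
#' noise, and optional detachment excursions flagged in the `burst` column.
#'
#' @param p A [synth_params()] object.
#' @param seed RNG seed (defaults to `p$seed` or 1).
#' @return A `kt_trajectory` tibble (`t`, `pole1`, `pole2`, `cenA`, `cenB`,
#'   `burst`) with the `"anaphase_onset"` attribute set to `duration`.
#' @examples
#' tr <- synth_metaphase_trajectory(synth_params("wt"), seed = 2)
#' head(tr)
#' @export
synth_metaphase_trajectory <- function(p, seed = NULL) {
  stopifnot(inherits(p, "synth_params"))
  set.seed(seed %||% p$seed %||% 1)
  t <- seq(0, p$duration, by = p$dt)
  n <- length(t)
  L <- p$spindle_length + p$spindle_growth * t
  mid <- numeric(n)
  burst <- logical(n)
  if (p$waveform == "sine") {
    phase <- runif(1, 0, 2 * pi)
    mid <- p$amplitude * sin(2 * pi * t / (2 * p$half_period) + phase)
  } else {
    draw_wait <- function() {
      if (p$deterministic_reversal) p$half_period
      else min(rexp(1, 1 / p$half_period), 3 * p$half_period)
    }
    baseline <- 0
    # oscillatory displacement about the baseline, random initial phase
    z <- runif(1, -p$amplitude, p$amplitude)
    dir <- sample(c(-1, 1), 1)
    slope <- 2 * p$amplitude / p$half_period
    next_rev <- draw_wait()
    # detachment bookkeeping: phase 0 none, 1 outbound, 2 return
    det_phase <- 0L
    det_target <- 0
    v_det <- p$detach_speed / 60
    for (i in seq_len(n)) {
      mid[i] <- baseline + z
      burst[i] <- det_phase > 0L
      if (i == n) break
      if (det_phase == 0L) {
        z <- z + dir * slope * p$dt
        z <- max(min(z, p$amplitude), -p$amplitude)
        if (t[i + 1] >= next_rev) {
          dir <- -dir
          baseline <- baseline + rnorm(1, 0, p$drift_sd)
          baseline <- max(min(baseline, L[i] / 2 - 0.3), -L[i] / 2 + 0.3)
          next_rev <- next_rev + draw_wait()
        }
        if (p$detach_rate > 0 && runif(1) < p$detach_rate * p$dt) {
          det_phase <- 1L
          pole_sign <- if (mid[i] >= 0) 1 else -1
          det_target <- mid[i] + pole_sign *
            min(p$detach_excursion, L[i] / 2 - 0.2 - pole_sign * mid[i])
        }
      } else if (det_phase == 1L) {
        stp <- sign(det_target - (baseline + z)) * v_det * p$dt
        z <- z + stp
        if (abs(baseline + z - det_target) <= v_det * p$dt) det_phase <- 2L
      } else {
        stp <- sign(baseline - (baseline + z)) * v_det * p$dt
        z <- z + stp
        if (abs(z) <= max(v_det * p$dt, p$amplitude)) {
          if (abs(z) <= p$amplitude) det_phase <- 0L
        }
      }
    }
  }
  # slowly fluctuating inter-sister breathing (AR(1))
  br <- numeric(n)
  br[1] <- 0
  phi <- 0.95
  innov <- rnorm(n, 0, p$breathing_sd * sqrt(1 - phi^2))
  for (i in 2:n) br[i] <- phi * br[i - 1] + innov[i]
  d_is <- pmax(p$breathing_mean + br, 0.05)
  out <- tibble(
    t = t,
    pole1 = -L / 2 + rnorm(n, 0, p$noise_sd),
    pole2 = L / 2 + rnorm(n, 0, p$noise_sd),
    cenA = mid - d_is / 2 + rnorm(n, 0, p$noise_sd),
    cenB = mid + d_is / 2 + rnorm(n, 0, p$noise_sd),
    burst = burst)
  attr(out, "anaphase_onset") <- p$duration
  class(out) <- c("kt_trajectory", class(out))
  out
}

#' Synthetic anaphase trajectory
#'
#' Sisters separate from the spindle centre and move to opposite poles at
#' constant speed, one of them delayed by `lag` seconds; with `noise_sd = 0`
#' the [lagging_time()] analyser recovers the lag exactly.  Setting
#' `same_pole = TRUE` sends both sisters to the same pole (a mis-segregation
#' event).
#'
#' @param p A [synth_params()] object (`spindle_length`, `breathing_mean`,
#'   `anaphase_speed`, `noise_sd`, `dt` are used).
#' @param lag Delay of sister B's departure, s.
#' @param duration Trace duration after onset, s (default long enough for
#'   both arrivals).
#' @param same_pole Send both sisters to the upper pole.
#' @param seed RNG seed.
#' @return A `kt_trajectory` tibble with `"anaphase_onset"` attribute 0.
#' @export
synth_anaphase_trajectory <- function(p, lag = 0, duration = NULL,
                                      same_pole = FALSE, seed = NULL) {
  stopifnot(inherits(p, "synth_params"))
  set.seed(seed %||% p$seed %||% 1)
  v <- p$anaphase_speed / 60
  travel <- (p$spindle_length - p$breathing_mean) / 2
  duration <- duration %||% (travel / v + lag + 60)
  t <- seq(0, duration, by = p$dt)
  pos <- function(start, target, t0) {
    x <- start + sign(target - start) * v * pmax(t - t0, 0)
    if (target >= start) pmin(x, target) else pmax(x, target)
  }
  pA <- -p$spindle_length / 2
  pB <- p$spindle_length / 2
  cenA <- pos(-p$breathing_mean / 2, if (same_pole) pB else pA,
              if (same_pole) lag else 0)
  cenB <- pos(p$breathing_mean / 2, pB, if (same_pole) 0 else lag)
  n <- length(t)
  out <- tibble(
    t = t,
    pole1 = pA + rnorm(n, 0, p$noise_sd),
    pole2 = pB + rnorm(n, 0, p$noise_sd),
    cenA = cenA + rnorm(n, 0, p$noise_sd),
    cenB = cenB + rnorm(n, 0, p$noise_sd),
    burst = FALSE)
  attr(out, "anaphase_onset") <- 0
  class(out) <- c("kt_trajectory", class(out))
  out
}

#' Synthetic microtubule intensity profiles
#'
#' Generates 1-D fluorescence profiles along microtubules: baseline 1 plus an
#' exponential plus-end accumulation whose tip-window mean scales linearly
#' with microtubule length (`tip_gain` per um), plus Gaussian noise.  On
#' noiseless output, [klp5_profile_stats()] recovers a tip-intensity versus
#' length slope of `tip_gain`.
#'
#' @param n Number of profiles (0 gives an empty tibble).
#' @param lengths Microtubule lengths, um; defaults to `n` draws uniform on
#'   0.6-3.4 um.
#' @param tip_gain Increase of the (median-normalized) tip intensity per um
#'   of microtubule length.
#' @param noise_sd Additive Gaussian noise, intensity units.
#' @param tip_frac Plus-end window used to calibrate the accumulation (match
#'   the analysis setting).
#' @param seed RNG seed.
#' @return A tibble with columns `profile_id`, `position`, `intensity`,
#'   `mt_length`.
#' @export
synth_intensity_profiles <- function(n, lengths = NULL, tip_gain = 1,
                                     noise_sd = 0, tip_frac = 0.1,
                                     seed = NULL) {
  set.seed(seed %||% 1)
  if (n == 0) {
    return(tibble(profile_id = character(0), position = numeric(0),
                  intensity = numeric(0), mt_length = numeric(0)))
  }
  lengths <- lengths %||% runif(n, 0.6, 3.4)
  if (length(lengths) != n) abort("`lengths` must have `n` values")
  w <- 0.05
  purrr::map_dfr(seq_len(n), function(i) {
    L <- lengths[i]
    npts <- max(12, round(L / 0.05))
    s <- seq(0, 1, length.out = npts)
    shape <- exp((s - 1) / w)
    cal <- mean(shape[s >= 1 - tip_frac])   # tip-window mean of the shape
    intensity <- 1 + tip_gain * L * shape / cal + rnorm(npts, 0, noise_sd)
    tibble(profile_id = sprintf("mt%03d", i), position = seq_len(npts),
           intensity = intensity, mt_length = L)
  })
}
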