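#' Tidy a simulation ensemble
#'
#' @param x A `sim_ensemble` from [run_ensemble()].
#' @param ... Unused.
#' @return The per-run, per-chromosome summary tibble.
#' @method tidy sim_ensemble
#' @export
tidy.sim_ensemble <- function(x, ...) x$summary

#' One-row ensemble summary
#'
#' @param x A `sim_ensemble`.
#' @param ... Unused.
#' @return A tibble with the grand mean and sem of the anaphase-onset
#'   normalized distance, the mean inter-sister distance and spindle length,
#'   the mis-segregation rate, the median lagging time and run counts.
#' @method glance sim_ensemble
#' @export
glance.sim_ensemble <- function(x, ...) {
  s <- x$summary
  tibble(mean_nd = mean(s$nd_onset),
         sem_nd = sd(s$nd_onset) / sqrt(nrow(s)),
         mean_intersister = mean(s$intersister_mean),
         mean_spindle_length = mean(s$spindle_length_onset),
         missegregation_rate = mean(s$missegregated),
         median_lagging = median(s$lagging_time, na.rm = TRUE),
         lagging_censored = sum(s$lagging_censored),
         n_runs = max(s$run), n = nrow(s),
         ldep = x$params$ldep_enabled)
}

#' @method tidy sim_trajectory
#' @export
tidy.sim_trajectory <- function(x, ...) sim_states(x)

#' @method glance sim_trajectory
#' @export
glance.sim_trajectory <- function(x, ...) {
  m <- run_metrics(x)
  tibble(mean_nd_onset = mean(m$nd_onset),
         spindle_length_onset = m$spindle_length_onset[1],
         mean_intersister = mean(m$intersister_mean),
         missegregated = sum(m$missegregated),
         seed = x$seed, ldep = x$params$ldep_enabled)
}

#' Tidy oscillation metrics
#'
#' @param x An `oscillation_metrics` object.
#' @param ... Unused.
#' @return The semi-period segment table (extrema method) or the spectral
#'   peak table (FFT method).
#' @method tidy oscillation_metrics
#' @export
tidy.oscillation_metrics <- function(x, ...) {
  if (x$method == "extrema") x$segments else x$peaks
}

#' @method glance oscillation_metrics
#' @export
glance.oscillation_metrics <- function(x, ...) {
  tibble(amplitude = x$amplitude, half_period = x$half_period,
         period = x$period, method = x$method,
         n_segments = if (is.null(x$segments)) NA_integer_
                      else nrow(x$segments),
         disagrees_with_fft = x$disagrees_with_fft)
}

#' @method tidy profile_stats
#' @export
tidy.profile_stats <- function(x, ...) x$tips

#' @method glance profile_stats
#' @export
glance.profile_stats <- function(x, ...) {
  fit <- stats::lm(tip_mean ~ mid_length, data = x$tips)
  tibble(n_bins = nrow(x$tips), n_profiles = sum(x$tips$n),
         tip_slope = unname(stats::coef(fit)[2]),
         tip_monotonic = !is.unsorted(x$tips$tip_mean))
}

#' @method tidy group_summary
#' @export
tidy.group_summary <- function(x, ...) x$summary

#' @method glance group_summary
#' @export
glance.group_summary <- function(x, ...) {
  tibble(n_groups = nrow(x$summary), n_tests = nrow(x$tests),
         min_p = min(x$tests$p.value))
}
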