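new_oscillation_metrics <- function(amplitude, half_period, method,
                                    peaks = NULL, segments = NULL, n = NA_integer_,
                                    disagrees_with_fft = NA) {
  structure(list(amplitude = amplitude, half_period = half_period,
                 period = 2 * half_period, method = method,
                 peaks = peaks, segments = segments, n = n,
                 disagrees_with_fft = disagrees_with_fft),
            class = "oscillation_metrics")
}

#' @export
print.oscillation_metrics <- function(x, ...) {
  cat(sprintf("<oscillation_metrics/%s>", x$method))
  if (is.na(x$amplitude)) {
    cat(" no qualifying oscillation\n")
  } else {
    cat(sprintf(" amplitude %.3f um, half-period %.1f s\n",
                x$amplitude, x$half_period))
  }
  if (!is.null(x$segments)) {
    cat(sprintf("  %d semi-period segment(s)\n", nrow(x$segments)))
  }
  invisible(x)
}

#' Oscillation amplitude and half-period by Fourier analysis
#'
#' Characterises a kinetochore (midpoint) trajectory by its discrete Fourier
#' spectrum.  The magnitude spectrum is normalized by the signal length and
#' multiplied by two (only half the spectrum is kept, so energy must be
#' preserved), which makes the peak height of a pure sinusoid equal its
#' amplitude in um.  Local spectral maxima at frequencies below 5e-3 Hz are
#' excluded (high-pass filter); the highest remaining peak defines the
#' amplitude and the half-period `1/(2 f_peak)`.
#'
#' @param x Uniformly sampled position series, um (mean-detrended
#'   internally); at least 64 samples.
#' @param dt Sampling interval, s.
#' @param min_freq High-pass cutoff, Hz.
#' @param min_amplitude Absolute floor (um) below which spectral maxima are
#'   treated as numerical noise rather than oscillation peaks.
#' @return An `oscillation_metrics` object (method `"fft"`).  When no local
#'   maximum survives the cutoff, `amplitude` and `half_period` are `NA` (an
#'   empty result, not an error).  `tidy()` returns the peak table,
#'   `glance()` the summary row.
#' @details A finite recording leaks a sinusoid's energy into the bins
#'   neighbouring its true frequency; the reported amplitude is therefore the
#'   root-sum-square of the scaled magnitudes over the peak bin +/- 2
#'   neighbours, which keeps the worst-case underestimate below 5%.
#' @examples
#' t <- seq(0, 600, by = 0.5)
#' m <- fft_oscillation_metrics(0.23 * sin(2 * pi * t / 126), dt = 0.5)
#' glance(m)
#' @export
fft_oscillation_metrics <- function(x, dt, min_freq = 5e-3,
                                    min_amplitude = 1e-8) {
  if (length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    abort("`dt` must be a single positive number (uniform sampling)")
  }
  n <- length(x)
  if (n < 64) abort("series must have at least 64 samples")
  if (any(!is.finite(x))) abort("`x` must be finite")
  amp <- 2 * Mod(fft(x - mean(x))) / n
  kmax <- floor(n / 2)
  amp <- amp[2:(kmax + 1)]          # drop DC, keep positive frequencies
  freq <- (1:kmax) / (n * dt)
  k <- 2:(kmax - 1)
  is_peak <- c(FALSE, amp[k] > amp[k - 1] & amp[k] >= amp[k + 1], FALSE)
  keep <- is_peak & freq >= min_freq & amp > min_amplitude
  peaks <- tibble(frequency = freq[keep], amplitude = amp[keep])
  if (nrow(peaks) == 0) {
    return(new_oscillation_metrics(NA_real_, NA_real_, "fft",
                                   peaks = peaks, n = n))
  }
  best <- which.max(peaks$amplitude)
  kbest <- which(freq == peaks$frequency[best])[1]
  win <- max(1, kbest - 2):min(kmax, kbest + 2)
  amp_best <- sqrt(sum(amp[win]^2))
  new_oscillation_metrics(amp_best,
                          1 / (2 * peaks$frequency[best]),
                          "fft", peaks = peaks, n = n)
}

locate_extrema <- function(xs) {
  d <- diff(xs)
  s <- sign(d)
  s[s == 0] <- NA
  s <- zoo_na_locf(s)
  idx <- which(diff(s) != 0) + 1
  idx[!is.na(idx)]
}

# drop alternating extrema pairs whose excursion is below `thr` (spline
# ringing, localisation noise); removing an adjacent pair always preserves
# the max/min alternation of the remainder
prune_extrema <- function(idx, xs, thr) {
  while (length(idx) >= 2) {
    exc <- abs(diff(xs[idx]))
    j <- which.min(exc)
    if (exc[j] >= thr) break
    idx <- idx[-c(j, j + 1)]
  }
  idx
}

# minimal last-observation-carried-forward (both directions) for sign runs
zoo_na_locf <- function(v) {
  if (all(is.na(v))) return(v)
  for (i in seq_along(v)) if (is.na(v[i]) && i > 1) v[i] <- v[i - 1]
  for (i in rev(seq_along(v))) if (is.na(v[i]) && i < length(v)) v[i] <- v[i + 1]
  v
}

#' Oscillation metrics from spline-smoothed local extrema
#'
#' The second, independent characterisation of kinetochore oscillations: the
#' trajectory is smoothed with a cubic smoothing spline (generalised
#' cross-validated smoothing parameter by default), local extrema of the
#' smoothed curve are located, and the midpoints between consecutive extrema
#' delimit the semi-period segments.  Each segment's amplitude is half the
#' mean peak-to-trough excursion of the two runs it straddles; the summary
#' amplitude and half-period are means over segments.  When a uniformly
#' sampled series long enough for Fourier analysis is given, the result is
#' cross-checked against [fft_oscillation_metrics()] and flagged when the two
#' amplitudes disagree by more than 50%.
#'
#' @param x Position series, um.
#' @param t Time stamps, s (strictly increasing).
#' @param spar Optional smoothing parameter for [stats::smooth.spline()];
#'   `NULL` selects it by generalised cross-validation.
#' @param min_excursion Minimum peak-to-trough excursion (um) for a pair of
#'   extrema to count as an oscillation event; smaller wiggles (spline
#'   ringing, localisation noise) are pruned.  Defaults to 10% of the range
#'   of the smoothed series.
#' @return An `oscillation_metrics` object (method `"extrema"`) with a
#'   `segments` tibble (`start`, `end`, `t_extremum`, `extremum`,
#'   `duration`, `amplitude`).  Fewer than 3 extrema give an empty result.
#' @export
extrema_oscillation_metrics <- function(x, t, spar = NULL,
                                        min_excursion = NULL) {
  if (length(x) != length(t)) abort("`x` and `t` must have the same length")
  if (any(diff(t) <= 0)) abort("`t` must be strictly increasing")
  fit <- if (is.null(spar)) smooth.spline(t, x) else smooth.spline(t, x, spar = spar)
  xs <- predict(fit, t)$y
  idx <- locate_extrema(xs)
  thr <- min_excursion %||% max(0.1 * diff(range(xs)), 1e-6)
  idx <- prune_extrema(idx, xs, thr)
  if (length(idx) < 3) {
    return(new_oscillation_metrics(NA_real_, NA_real_, "extrema",
                                   segments = tibble(), n = length(x)))
  }
  te <- t[idx]; xe <- xs[idx]
  mids <- (te[-length(te)] + te[-1]) / 2
  k <- length(idx)
  j <- seq_len(k - 2)
  segments <- tibble(start = mids[j], end = mids[j + 1],
                     t_extremum = te[j + 1], extremum = xe[j + 1],
                     duration = mids[j + 1] - mids[j],
                     amplitude = (abs(xe[j + 1] - xe[j]) +
                                  abs(xe[j + 2] - xe[j + 1])) / 4)
  m <- new_oscillation_metrics(mean(segments$amplitude),
                               mean(segments$duration),
                               "extrema", segments = segments, n = length(x))
  dts <- diff(t)
  if (length(x) >= 64 && max(abs(dts - dts[1])) < 1e-8 * max(dts)) {
    f <- fft_oscillation_metrics(x, dt = dts[1])
    if (!is.na(f$amplitude) && !is.na(m$amplitude)) {
      m$disagrees_with_fft <-
        abs(m$amplitude - f$amplitude) / f$amplitude > 0.5
    }
  }
  m
}

#' Inter-event drift amplitudes
#'
#' Midline drift between consecutive oscillation events.  Each semi-period
#' segment boundary (the midpoint in time between two consecutive extrema,
#' from [extrema_oscillation_metrics()]) sits where a symmetric oscillation
#' crosses its midline, so the series value there estimates the local
#' oscillation baseline; the drift between two consecutive events is the
#' absolute difference of these boundary values.  A strictly stationary
#' oscillation therefore gives drifts at the noise floor of the smoother
#' rather than inheriting the oscillation amplitude.
#'
#' @param x Position series, um.
#' @param t Time stamps, s.
#' @param segments Segment table (needs a `start` column), e.g.
#'   `extrema_oscillation_metrics(x, t)$segments`.
#' @return Numeric vector of drift amplitudes (um), one per consecutive
#'   segment pair; length 0 when fewer than 2 segments.
#' @export
drift_amplitudes <- function(x, t, segments) {
  if (is.null(segments) || nrow(segments) < 2) return(numeric(0))
  base <- approx(t, x, xout = segments$start)$y
  abs(diff(base))
}

#' Maximum poleward speed
#'
#' Maximum absolute velocity of a kinetochore over an interval, from a
#' centered finite difference on a rolling-mean-smoothed series.  Used to
#' compare anaphase-A poleward speed with the speed of detachment
#' excursions.
#'
#' @param x Position series, um.
#' @param t Time stamps, s (uniformly increasing).
#' @param window Odd smoothing window length in samples (>= 3).
#' @return Maximum speed in um/min.
#' @examples
#' t <- seq(0, 60, 1)
#' max_poleward_speed(t / 30, t)  # 2 um over 60 s -> 2 um/min
#' @export
max_poleward_speed <- function(x, t, window = 5) {
  if (window %% 2 != 1 || window < 3) abort("`window` must be odd and >= 3")
  if (length(x) < window + 2) abort("interval shorter than the smoothing window")
  xs <- stats::filter(x, rep(1 / window, window), sides = 2)
  i <- seq(2, length(x) - 1)
  v <- (xs[i + 1] - xs[i - 1]) / (t[i + 1] - t[i - 1])
  60 * max(abs(v), na.rm = TRUE)
}
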