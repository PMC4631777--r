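test_that("spot assignment picks the most distant pair as poles and projects", {
  spots <- data.frame(t = 0, x = c(0, 3, 1.4, 1.6), y = 0)
  fr <- assign_and_project(spots)
  expect_equal(fr$pole1, -1.5)
  expect_equal(fr$pole2, 1.5)
  expect_equal(fr$cenA, -0.1)
  expect_equal(fr$cenB, 0.1)
  # assignment is by distance, not order: a centromere beyond a pole
  spots2 <- data.frame(t = 0, x = c(0, 3, 3.1, 1.5), y = 0)
  fr2 <- assign_and_project(spots2)
  expect_equal(fr2$pole2 - fr2$pole1, 3.1)   # 0 and 3.1 are most distant
  # off-axis spots are orthogonally projected
  spots3 <- data.frame(t = 0, x = c(0, 2, 1, 1), y = c(0, 0, 0.4, -0.4))
  fr3 <- assign_and_project(spots3)
  expect_equal(fr3$cenA, 0)
  expect_equal(fr3$cenB, 0)
  # frames with the wrong spot count are dropped with a message
  bad <- data.frame(t = c(0, 0, 0, 1, 1, 1, 1),
                    x = c(0, 3, 1.5, 0, 3, 1.4, 1.6), y = 0)
  expect_message(out <- assign_and_project(bad), "dropped 1 frame")
  expect_equal(nrow(out), 1)
  expect_equal(out$t, 1)
})

test_that("normalized distance has the documented anchors and invariances", {
  expect_equal(normalized_distance(0, -1.5, 1.5), 0)     # centre
  expect_equal(normalized_distance(1.5, -1.5, 1.5), 0.5) # pole
  expect_equal(normalized_distance(0.33, -1.5, 1.5), 0.11)
  expect_error(normalized_distance(0, 1, 1), "zero spindle length")
  expect_warning(normalized_distance(2, -1.5, 1.5), "exceed 0.5")
  # invariance under translation, reflection and pole relabeling
  set.seed(3)
  for (i in 1:20) {
    p1 <- runif(1, -3, 0); p2 <- runif(1, 0.5, 3); m <- runif(1, p1, p2)
    nd <- normalized_distance(m, p1, p2)
    a <- runif(1, -5, 5)
    expect_equal(normalized_distance(m + a, p1 + a, p2 + a), nd)
    expect_equal(normalized_distance(-m, -p1, -p2), nd)
    expect_equal(normalized_distance(m, p2, p1), nd)
  }
})

test_that("ensemble time-courses average absolute centre distances", {
  tr <- tibble::tibble(t = 0:10, pole1 = -1.5, pole2 = 1.5,
                       cenA = 0.2, cenB = 0.4)
  attr(tr, "anaphase_onset") <- 5
  tc <- center_distance_timecourse(list(tr, tr))
  expect_equal(unique(tc$cen_mean), 0.3)
  expect_equal(unique(tc$cen_sd), 0)
  expect_equal(unique(tc$pole_mean), 1.5)
  expect_equal(tc$time, -5:5)
  # mirrored trajectories: absolute value is taken before averaging
  tr2 <- tr; tr2$cenA <- -0.2; tr2$cenB <- -0.4
  attr(tr2, "anaphase_onset") <- 5
  tc2 <- center_distance_timecourse(list(tr, tr2))
  expect_equal(unique(tc2$cen_mean), 0.3)
  expect_equal(unique(tc2$cen_sd), 0)
  expect_error(center_distance_timecourse(list()), "empty")
  expect_error(center_distance_timecourse(list(tibble::tibble(t = 1:3))),
               "anaphase-onset")
})

test_that("FFT metrics recover a constructed sinusoid", {
  t <- seq(0, 600, by = 0.1); t <- t[-length(t)]
  x <- 0.23 * sin(2 * pi * t / 126)
  m <- fft_oscillation_metrics(x, dt = 0.1)
  expect_equal(m$amplitude, 0.23, tolerance = 0.05)
  # half-period within 2 frequency bins of 63 s
  f_peak <- 1 / (2 * m$half_period)
  expect_lt(abs(f_peak - 1 / 126), 2 / 600)
  expect_equal(m$period, 2 * m$half_period)
  # amplitude is linear in signal scale, half-period invariant
  m3 <- fft_oscillation_metrics(3 * x, dt = 0.1)
  expect_equal(m3$amplitude, 3 * m$amplitude, tolerance = 1e-9)
  expect_equal(m3$half_period, m$half_period)
})

test_that("FFT high-pass excludes slow components and empty results are signalled", {
  expect_true(is.na(fft_oscillation_metrics(rep(1, 128), dt = 1)$amplitude))
  # 300-s period = 3.3e-3 Hz, below the 5e-3 Hz cutoff
  t <- seq(0, 599.5, by = 0.5)
  slow <- 0.3 * sin(2 * pi * t / 300)
  m <- fft_oscillation_metrics(slow, dt = 0.5)
  expect_true(is.na(m$amplitude))
  expect_true(is.na(glance(m)$half_period))
  expect_error(fft_oscillation_metrics(1:10, dt = 1), "64")
  expect_error(fft_oscillation_metrics(rnorm(128), dt = -1), "dt")
})

test_that("extrema metrics recover a triangle wave and agree with the FFT", {
  t <- seq(0, 600, by = 0.5)
  tri <- 0.2 * (2 / pi) * asin(sin(2 * pi * t / 120))
  m <- extrema_oscillation_metrics(tri, t)
  expect_lt(abs(m$amplitude - 0.2), 0.02)
  expect_lt(abs(m$half_period - 60), 6)
  expect_gt(nrow(m$segments), 3)
  expect_false(isTRUE(m$disagrees_with_fft))
  # monotone ramp: no extrema, empty result rather than a crash
  ramp <- extrema_oscillation_metrics(seq(0, 1, length.out = 100), 1:100)
  expect_true(is.na(ramp$amplitude))
  expect_equal(nrow(ramp$segments), 0)
  # method equivalence on a pure sinusoid: 10% amplitude, 15% half-period
  x <- 0.23 * sin(2 * pi * t / 126)
  me <- extrema_oscillation_metrics(x, t)
  mf <- fft_oscillation_metrics(x, dt = 0.5)
  expect_lt(abs(me$amplitude - mf$amplitude) / mf$amplitude, 0.10)
  expect_lt(abs(me$half_period - mf$half_period) / mf$half_period, 0.15)
})

test_that("drift amplitudes difference consecutive segment means", {
  x <- c(rep(0, 100), rep(0.2, 100))
  t <- seq_len(200)
  seg <- tibble::tibble(start = c(1, 101), end = c(100, 200))
  expect_equal(drift_amplitudes(x, t, seg), 0.2)
  expect_length(drift_amplitudes(x, t, seg[1, ]), 0)     # single segment
  expect_length(drift_amplitudes(x, t, NULL), 0)
  # stationary oscillation: drifts at the smoother's noise floor
  ts <- seq(0, 600, by = 0.5)
  osc <- 0.2 * sin(2 * pi * ts / 120)
  m <- extrema_oscillation_metrics(osc, ts)
  expect_lt(max(drift_amplitudes(osc, ts, m$segments)), 0.02)
})

test_that("lagging time measures the sister arrival delay symmetrically", {
  p <- synth_params("wt", noise_sd = 0)
  tr <- synth_anaphase_trajectory(p, lag = 30, seed = 1)
  lt <- lagging_time(tr)
  expect_equal(lt$lagging_time, 30)
  expect_false(lt$censored)
  # symmetric in sister labels
  tr_sw <- tr
  tr_sw$cenA <- tr$cenB; tr_sw$cenB <- tr$cenA
  attr(tr_sw, "anaphase_onset") <- 0
  expect_equal(lagging_time(tr_sw)$lagging_time, 30)
  expect_equal(lagging_time(synth_anaphase_trajectory(p, lag = 0,
                                                      seed = 2))$lagging_time, 0)
  # a sister that never reaches its pole is censored
  short <- synth_anaphase_trajectory(p, lag = 500, duration = 40, seed = 3)
  lt2 <- lagging_time(short)
  expect_true(lt2$censored)
  expect_true(is.na(lt2$lagging_time))
  expect_error(lagging_time(tibble::tibble(t = 1, pole1 = -1, pole2 = 1,
                                           cenA = 0, cenB = 0)),
               "anaphase-onset")
})

test_that("mis-segregation is both sisters on one side, ties excused", {
  tr <- tibble::tibble(t = 0, pole1 = -1.5, pole2 = 1.5,
                       cenA = -1.4, cenB = 1.3)
  expect_false(missegregation_flag(tr))
  tr2 <- tr; tr2$cenA <- 1.2; tr2$cenB <- 1.4
  expect_true(missegregation_flag(tr2))
  tr3 <- tr; tr3$cenA <- 0; tr3$cenB <- 1.4   # exactly at the centre
  expect_false(missegregation_flag(tr3))
})

test_that("maximum poleward speed reads off constructed slopes in um/min", {
  t <- seq(0, 60, by = 1)
  expect_equal(max_poleward_speed(t * (2 / 60), t), 2)    # 2 um over 60 s
  expect_equal(max_poleward_speed(rep(1, 61), t), 0)      # static
  saw <- (1.2 / 60) * abs((t %% 80) - 40)   # triangle with slope 1.2 um/min
  expect_equal(max_poleward_speed(saw, t, window = 3), 1.2, tolerance = 0.05)
  expect_error(max_poleward_speed(t, t, window = 4), "odd")
  expect_error(max_poleward_speed(1:4, 1:4, window = 5), "shorter")
})

test_that("group summaries report means, sems and Student's t-tests", {
  d <- data.frame(g = rep(c("a", "b"), each = 4),
                  y = c(1, 2, 1, 2, 1, 2, 1, 2))
  gs <- summarize_groups(d, y, g)
  expect_equal(gs$tests$statistic, 0)
  expect_equal(gs$tests$p.value, 1)
  expect_equal(tidy(gs)$sem, rep(sd(c(1, 2, 1, 2)) / 2, 2))
  # sem of {1, 2, 3} = sd/sqrt(n) = 0.5774
  d2 <- data.frame(g = c(rep("a", 3), rep("b", 3)),
                   y = c(1, 2, 3, 11, 12, 13))
  gs2 <- summarize_groups(d2, y, g)
  expect_equal(tidy(gs2)$sem[1], 0.5774, tolerance = 1e-4)
  # cleanly separated groups with tiny jitter
  set.seed(2)
  d3 <- data.frame(g = rep(c("a", "b"), each = 4),
                   y = rep(c(0, 1), each = 4) + rnorm(8, 0, 0.01))
  expect_lt(summarize_groups(d3, y, g)$tests$p.value, 1e-4)
  expect_error(summarize_groups(data.frame(g = c("a", "b"), y = c(1, 2)),
                                y, g), "at least 2")
})

test_that("profile statistics normalize by the median and window the tip", {
  # flat profile: identity under median normalization
  flat <- tibble::tibble(profile_id = "p1", position = 1:10,
                         intensity = 1, mt_length = 1.2)
  ps <- klp5_profile_stats(flat, bins = c(1, 2))
  expect_equal(ps$tips$tip_mean, 1)
  expect_equal(unique(ps$profile$mean), 1)
  # median 1, last-decile tip = 3
  five <- tibble::tibble(profile_id = "p1", position = 1:5,
                         intensity = c(1, 1, 1, 1, 3), mt_length = 1.2)
  expect_equal(klp5_profile_stats(five, bins = c(1, 2))$tips$tip_mean, 3)
  # invariance under scaling any single profile by a positive constant
  two <- dplyr::bind_rows(five,
    tibble::tibble(profile_id = "p2", position = 1:5,
                   intensity = 7 * c(1, 1, 2, 1, 5), mt_length = 1.7))
  two_scaled <- two
  two_scaled$intensity[two_scaled$profile_id == "p2"] <-
    two_scaled$intensity[two_scaled$profile_id == "p2"] / 7
  s1 <- klp5_profile_stats(two, bins = c(1, 1.5, 2))
  s2 <- klp5_profile_stats(two_scaled, bins = c(1, 1.5, 2))
  expect_equal(s1$tips, s2$tips)
  expect_equal(s1$profile, s2$profile)
  # zero-median profiles are excluded and reported
  zm <- dplyr::bind_rows(five,
    tibble::tibble(profile_id = "z", position = 1:5,
                   intensity = 0, mt_length = 1.3))
  expect_message(out <- klp5_profile_stats(zm, bins = c(1, 2)), "zero median")
  expect_equal(sum(out$tips$n), 1)
  # empty bins are absent from the output
  expect_false(any(is.na(s1$tips$tip_mean)))
  expect_s3_class(autoplot(s1), "ggplot")
})
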