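test_that("detached chromosomes feel no force while poles drift apart", {
  p <- fast_params(k_a = 0, k_d = 0)
  set.seed(1)
  st <- init_spindle_state(p, mode = "centered", jitter = 0)
  st1 <- step_dynamics(st, p)
  expect_equal(st1$x_cen, st$x_cen, tolerance = 1e-12)
  expect_equal(st1$x_site, st$x_site, tolerance = 1e-12)
  expect_gt(st1$x_spbR, st$x_spbR)   # midzone pushes poles outward
  expect_lt(st1$x_spbL, st$x_spbL)
  expect_equal(st1$t, st$t + p$dt)
})

test_that("with all force generators off, positions are constant", {
  p <- fast_params(k_a = 0, k_d = 0, F_mz = 0, t_meta = 10, t_ana = 0)
  set.seed(1)
  st <- init_spindle_state(p, mode = "centered", jitter = 0)
  sim <- simulate_mitosis(p, seed = 2, init = st)
  s <- sim$states
  for (col in colnames(s)) {
    if (col %in% c("t", "anaphase")) next
    expect_lt(max(abs(s[, col] - s[1, col])), 1e-12)
  }
})

test_that("no attachment ever forms when k_a = 0", {
  p <- fast_params(k_a = 0)
  set.seed(1)
  st <- init_spindle_state(p, mode = "centered", jitter = 0.05)
  sim <- simulate_mitosis(p, seed = 3, init = st)
  pis <- sim$states[, grep("^pi_", colnames(sim$states))]
  expect_true(all(pis == 0))
  expect_equal(sim$counters$attach_events, 0)
  # and the centromeres never move
  cen <- sim$states[, grep("^cen_", colnames(sim$states))]
  expect_lt(max(abs(sweep(cen, 2, cen[1, ]))), 1e-9)
})

test_that("identical seeds give bit-identical trajectories", {
  p <- fast_params()
  s1 <- simulate_mitosis(p, seed = 11)
  s2 <- simulate_mitosis(p, seed = 11)
  expect_identical(s1$states, s2$states)
  s3 <- simulate_mitosis(p, seed = 12)
  expect_false(identical(s3$states, s1$states))
})

test_that("attachment states stay in {-1, 0, 1} and events match the rates", {
  p <- spindle_params(t_meta = 300, t_ana = 0)
  sim <- simulate_mitosis(p, seed = 5)
  pis <- sim$states[, grep("^pi_", colnames(sim$states))]
  expect_true(all(pis %in% c(-1, 0, 1)))
  # realised event counts within 3 Monte-Carlo standard errors of the
  # integrated per-step probabilities
  ct <- sim$counters
  expect_lt(abs(ct$attach_events - ct$expected_attach),
            3 * sqrt(ct$expected_attach))
  expect_lt(abs(ct$detach_events - ct$expected_detach),
            3 * sqrt(ct$expected_detach))
})

test_that("mirror-reflected initial states give mirror trajectories under the same seed", {
  p <- fast_params()
  set.seed(42)
  st <- init_spindle_state(p, mode = "prophase")
  st$x_cen <- st$x_cen + 0.07   # break any accidental symmetry
  st$x_site <- st$x_site + 0.07
  sim1 <- simulate_mitosis(p, seed = 99, init = st)
  sim2 <- simulate_mitosis(p, seed = 99, init = mirror_state(st))
  s1 <- sim1$states; s2 <- sim2$states
  expect_equal(s2[, "x_spbL"], -s1[, "x_spbR"], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(s2[, "x_spbR"], -s1[, "x_spbL"], tolerance = 1e-12,
               ignore_attr = TRUE)
  for (col in grep("^cen_|^site_", colnames(s1), value = TRUE)) {
    expect_equal(s2[, col], -s1[, col], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  for (col in grep("^pi_", colnames(s1), value = TRUE)) {
    expect_identical(s2[, col], s1[, col])
  }
})

test_that("an isolated attached site never exceeds V_k and approaches it as drag vanishes", {
  # single chromosome, single site, decoupled from its centromere
  p <- spindle_params(N_ch = 1, M_sites = 1, K_k = 0, mu_k = 0, K_c = 0,
                      mu_site = 1e-8, t_meta = 5, t_ana = 0, out_dt = 0.05)
  set.seed(1)
  st <- init_spindle_state(p, mode = "centered", jitter = 0)
  st$att <- c(1L, 0L)   # sister A attached to the right pole
  st$pi <- c(1L, 0L)
  st$x_site[] <- st$x_cen[1, ]
  stp <- step_dynamics(st, p)
  v <- (stp$x_site[1] - st$x_site[1]) / p$dt
  # mu_site -> 0 limit of the force-velocity balance
  expect_equal(v, p$V_k, tolerance = 1e-4)
  # over a longer stretch the site speed never exceeds V_k
  sim <- simulate_mitosis(spindle_params(N_ch = 1, M_sites = 1, K_k = 0,
                                         mu_k = 0, K_c = 0, k_d = 0,
                                         t_meta = 20, t_ana = 0,
                                         out_dt = 0.05),
                          seed = 4, init = st)
  xs <- sim$states[, "site_c1A_1"]
  expect_lt(max(abs(diff(xs)) / 0.05), p$V_k * (1 + 1e-6))
})

test_that("metaphase statistics reproduce the calibrated anchors on a small ensemble", {
  ens <- run_ensemble(spindle_params(), n_runs = 25, base_seed = 101)
  g <- glance(ens)
  # spindle grows from 1.5 um to about the wild-type 2.95 um at onset
  expect_gt(g$mean_spindle_length, 2.6)
  expect_lt(g$mean_spindle_length, 3.3)
  # metaphase inter-sister distance near the 0.5 um in vivo anchor
  expect_gt(g$mean_intersister, 0.35)
  expect_lt(g$mean_intersister, 0.65)
  expect_true(all(tidy(ens)$nd_onset >= 0))
})

test_that("ensemble bookkeeping and seed-block stability hold", {
  p <- fast_params()
  e1 <- run_ensemble(p, n_runs = 1, base_seed = 7)
  expect_equal(nrow(tidy(e1)), p$N_ch)   # one row per chromosome
  expect_error(run_ensemble(p, n_runs = 0), "n_runs")
  # disjoint seed blocks agree within Monte-Carlo error (4 pooled sems)
  a <- glance(run_ensemble(p, 60, base_seed = 1))
  b <- glance(run_ensemble(p, 60, base_seed = 5001))
  expect_lt(abs(a$mean_nd - b$mean_nd),
            4 * sqrt(a$sem_nd^2 + b$sem_nd^2))
})

test_that("parameter sweep validates factors and keeps baseline rows", {
  p <- fast_params()
  expect_error(parameter_sweep(p, factors = list(bogus = c(low = 0.5)),
                               n_runs = 2), "bogus")
  sw <- parameter_sweep(p, factors = list(), n_runs = 3)
  expect_equal(sw$condition, c("ldep_on", "baseline_off"))
  sw2 <- parameter_sweep(p, factors = list(K_c = c(low = 0.5)), n_runs = 3)
  expect_true("K_c_low" %in% sw2$condition)
  expect_s3_class(autoplot(sw2), "ggplot")
})

test_that("anaphase releases cohesin and segregates sisters to opposite poles", {
  sim <- simulate_mitosis(spindle_params(t_ana = 300), seed = 21)
  tr <- as_tracked(sim, 1)
  expect_s3_class(tr, "kt_trajectory")
  expect_equal(attr(tr, "anaphase_onset"), 600)
  last <- tr[nrow(tr), ]
  ctr <- (last$pole1 + last$pole2) / 2
  # sisters end on opposite sides in this seed and far apart
  expect_gt(abs(last$cenA - last$cenB), 1)
  expect_false(missegregation_flag(tr))
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(autoplot(tr), "ggplot")
})
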