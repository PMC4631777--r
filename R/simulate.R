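#' Initial spindle state
#'
#' Constructs the state of the spindle at mitosis onset: the two poles at
#' `-L0/2` and `+L0/2` (the origin is the initial spindle centre), every
#' sister pair placed near the centre with a small random offset, sisters
#' separated by the cohesin rest length, attachment sites at their centromere,
#' and all sites detached.
#'
#' @param params A [spindle_params()] object.
#' @param mode `"prophase"` (default): each sister pair starts adjacent to a
#'   randomly chosen pole, mono-oriented, with the pole-proximal sister's
#'   sites attached to that pole - the capture-by-the-nearest-pole geometry
#'   of early mitosis, from which congression must be achieved actively.
#'   `"centered"`: pairs start detached near the spindle centre with a
#'   uniform offset of half-width `jitter` (useful for symmetry and
#'   regression tests).
#' @param jitter Half-width (um) of the uniform random placement; set to 0
#'   for a deterministic start.  Uses the current RNG state.
#' @return A `spindle_state` list with fields `t`, `x_spbL`, `x_spbR`,
#'   `x_cen` (N_ch x 2 matrix), `x_site` (length `N_ch * 2 * M_sites`, index
#'   order chromosome, sister, site), `att` (-1 left pole, 0 detached,
#'   +1 right pole), `pi` (-1 erroneous, 0 detached, +1 correct) and
#'   `anaphase`.
#' @export
init_spindle_state <- function(params, mode = c("prophase", "centered"),
                               jitter = 0.05) {
  p <- validate_spindle_params(params)
  mode <- match.arg(mode)
  N <- p$N_ch; M <- p$M_sites
  lim <- max(p$L0 / 2 - p$d_0 / 2, 0)
  att <- integer(2 * N * M)
  pi <- integer(2 * N * M)
  if (mode == "centered") {
    offs <- if (jitter > 0) runif(N, -jitter, jitter) else rep(0, N)
    offs <- pmax(pmin(offs, lim), -lim)
  } else {
    pole <- ifelse(runif(N) < 0.5, -1L, 1L)
    inward <- if (jitter > 0) runif(N, 0, jitter) else rep(0, N)
    offs <- pole * pmax(pmin(lim - inward, lim), 0)
    for (c in seq_len(N)) {
      near <- if (pole[c] > 0) 2L else 1L   # sister on the pole side
      idx <- ((c - 1L) * 2L + (near - 1L)) * M + seq_len(M)
      att[idx] <- pole[c]
      pi[idx] <- 1L
    }
  }
  x_cen <- cbind(offs - p$d_0 / 2, offs + p$d_0 / 2)
  x_site <- as.numeric(t(x_cen))[rep(seq_len(2 * N), each = M)]
  st <- list(t = 0, x_spbL = -p$L0 / 2, x_spbR = p$L0 / 2,
             x_cen = x_cen, x_site = x_site,
             att = att, pi = pi,
             anaphase = FALSE)
  structure(st, class = "spindle_state")
}

check_spindle_state <- function(state, params) {
  N <- params$N_ch; M <- params$M_sites
  if (!is.matrix(state$x_cen) || !all(dim(state$x_cen) == c(N, 2))) {
    abort("`state$x_cen` must be an N_ch x 2 matrix")
  }
  if (length(state$x_site) != 2 * N * M) abort("`state$x_site` has wrong length")
  if (!all(state$pi %in% c(-1L, 0L, 1L))) abort("`state$pi` must be in {-1,0,1}")
  if (!all(state$att %in% c(-1L, 0L, 1L))) abort("`state$att` must be in {-1,0,1}")
  if (any((state$att == 0) != (state$pi == 0))) {
    abort("`att` and `pi` must be detached (0) together")
  }
  if (state$x_spbL >= state$x_spbR) abort("x_spbL must be < x_spbR")
  invisible(state)
}

core_par <- function(p) {
  p[c("F_k", "V_k", "k_a", "k_d", "d_alpha", "beta", "K_c", "d_0", "K_k",
      "mu_k", "F_mz", "V_mz", "mu_spb", "mu_ch", "mu_site", "alpha",
      "d_mean", "ldep_enabled", "ldep_form", "dt", "d_floor", "N_ch",
      "M_sites")]
}

core_init <- function(state) {
  list(t = state$t, x_spbL = state$x_spbL, x_spbR = state$x_spbR,
       x_cen = state$x_cen, x_site = as.numeric(state$x_site),
       att = as.integer(state$att), pi = as.integer(state$pi),
       anaphase = isTRUE(state$anaphase))
}

#' Advance the spindle state by one time step
#'
#' One explicit overdamped update: per-element force balance (midzone
#' force-velocity generator on the poles, pulling forces with the
#' length-dependent prefactor on attached sites, spring-damper coupling
#' between sites and centromeres, cohesin spring between sisters), followed by
#' stochastic attachment (probability `k_a * dt` per detached site) and
#' detachment (probability `detachment_rate * dt` per attached site) events.
#'
#' @param state A `spindle_state`, see [init_spindle_state()].
#' @param params A [spindle_params()] object.
#' @return The updated `spindle_state` with `t` advanced by `dt`.
#' @export
step_dynamics <- function(state, params) {
  p <- validate_spindle_params(params)
  check_spindle_state(state, p)
  res <- sim_core(core_par(p), core_init(state),
                  n_meta = if (isTRUE(state$anaphase)) 0L else 1L,
                  n_ana = if (isTRUE(state$anaphase)) 1L else 0L,
                  out_every = 1L)
  st <- list(t = state$t + p$dt, x_spbL = res$x_spbL, x_spbR = res$x_spbR,
             x_cen = res$x_cen, x_site = res$x_site,
             att = res$att, pi = res$pi, anaphase = isTRUE(state$anaphase))
  structure(st, class = "spindle_state")
}

#' Simulate one mitosis
#'
#' Runs the stochastic force-balance model through metaphase (`t_meta`
#' seconds) and anaphase (`t_ana` seconds).  At the anaphase trigger the
#' cohesin spring is removed, the length-dependent prefactor is forced to 1
#' (kinesin-8 relocalises to the midzone at anaphase), and existing
#' attachments - including erroneous ones - are kept; stochastic attachment
#' and detachment continue so that free chromatids can still be captured.
#'
#' @param params A [spindle_params()] object.
#' @param seed Integer RNG seed; defaults to `params$seed` or 1.  Identical
#'   seeds give bit-identical trajectories.
#' @param init Optional initial `spindle_state`; by default
#'   [init_spindle_state()] is drawn after seeding.
#' @return A `sim_trajectory` object: list with `states` (snapshot matrix),
#'   `params`, `seed` and the attach/detach event `counters`.  Use
#'   [sim_states()] for a tidy tibble, [as_tracked()] for the
#'   experimental-style per-chromosome table, and [tidy()] / [glance()] /
#'   [autoplot()] methods.
#' @examples
#' p <- spindle_params(t_meta = 60, t_ana = 30)
#' sim <- simulate_mitosis(p, seed = 7)
#' sim
#' @export
simulate_mitosis <- function(params, seed = NULL, init = NULL) {
  p <- validate_spindle_params(params)
  seed <- seed %||% p$seed %||% 1L
  set.seed(seed)
  if (is.null(init)) init <- init_spindle_state(p)
  check_spindle_state(init, p)
  out_every <- as.integer(round(p$out_dt / p$dt))
  n_meta <- out_every * round(p$t_meta / (p$dt * out_every))
  n_ana <- out_every * round(p$t_ana / (p$dt * out_every))
  res <- sim_core(core_par(p), core_init(init),
                  n_meta = n_meta, n_ana = n_ana, out_every = out_every)
  colnames(res$snapshots) <- snapshot_names(p$N_ch, p$M_sites)
  structure(list(states = res$snapshots, params = p, seed = seed,
                 counters = res[c("attach_events", "detach_events",
                                  "expected_attach", "expected_detach")]),
            class = "sim_trajectory")
}

snapshot_names <- function(N, M) {
  sis <- c("A", "B")
  cen <- as.vector(outer(sis, seq_len(N),
                         function(s, c) paste0("cen_c", c, s)))
  site <- as.vector(sapply(seq_len(N), function(c)
    sapply(sis, function(s) paste0("site_c", c, s, "_", seq_len(M)))))
  c("t", "anaphase", "x_spbL", "x_spbR", cen, site, paste0("pi_", site))
}

#' @export
print.sim_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf("<sim_trajectory> %d snapshots, %g s metaphase + %g s anaphase, seed %s\n",
              n, x$params$t_meta, x$params$t_ana, format(x$seed)))
  cat(sprintf("  final spindle length %.2f um; L_dep %s\n",
              x$states[n, "x_spbR"] - x$states[n, "x_spbL"],
              if (x$params$ldep_enabled) "on" else "off"))
  invisible(x)
}

#' Snapshot table of a simulated trajectory
#'
#' @param sim A `sim_trajectory` from [simulate_mitosis()].
#' @return A tibble with one row per snapshot: `t`, `anaphase`, pole
#'   positions, per-sister centromere positions, per-site positions and
#'   attachment states.
#' @export
sim_states <- function(sim) {
  as_tibble(as.data.frame(sim$states))
}

#' Experimental-style tracked table of one chromosome
#'
#' Extracts one chromosome from a simulated trajectory in the same layout the
#' trajectory analysers (and the trajectory CSV dialect) use: time, the two
#' pole positions, the two sister-centromere positions, plus a `burst` label
#' that is `TRUE` whenever at least one sister of the pair is fully detached
#' (the in vivo correlate of a Mad2 burst).
#'
#' @param sim A `sim_trajectory`.
#' @param chromosome Chromosome index in `1:N_ch`.
#' @return A `kt_trajectory` tibble with columns `t`, `pole1`, `pole2`,
#'   `cenA`, `cenB`, `burst`, `anaphase`, and an `"anaphase_onset"` attribute
#'   (seconds).
#' @export
as_tracked <- function(sim, chromosome = 1) {
  s <- sim$states
  N <- sim$params$N_ch; M <- sim$params$M_sites
  if (chromosome < 1 || chromosome > N) abort("`chromosome` out of range")
  cenA <- s[, paste0("cen_c", chromosome, "A")]
  cenB <- s[, paste0("cen_c", chromosome, "B")]
  piA <- s[, paste0("pi_site_c", chromosome, "A_", seq_len(M)), drop = FALSE]
  piB <- s[, paste0("pi_site_c", chromosome, "B_", seq_len(M)), drop = FALSE]
  burst <- rowSums(piA != 0) == 0 | rowSums(piB != 0) == 0
  out <- tibble(t = s[, "t"], pole1 = s[, "x_spbL"], pole2 = s[, "x_spbR"],
                cenA = cenA, cenB = cenB, burst = burst,
                anaphase = s[, "anaphase"] == 1)
  attr(out, "anaphase_onset") <- sim$params$t_meta
  class(out) <- c("kt_trajectory", class(out))
  out
}

## ---- per-run summary metrics ----------------------------------------------

run_metrics <- function(sim, epsilon = 0.2) {
  s <- sim$states
  p <- sim$params
  N <- p$N_ch
  meta <- s[, "anaphase"] == 0
  onset <- which(s[, "anaphase"] == 1)[1]
  if (is.na(onset)) onset <- nrow(s)
  last <- nrow(s)
  L_on <- s[onset, "x_spbR"] - s[onset, "x_spbL"]
  ctr_on <- (s[onset, "x_spbR"] + s[onset, "x_spbL"]) / 2
  ctr_end <- (s[last, "x_spbR"] + s[last, "x_spbL"]) / 2
  rows <- lapply(seq_len(N), function(c) {
    cA <- s[, paste0("cen_c", c, "A")]
    cB <- s[, paste0("cen_c", c, "B")]
    mid <- (cA + cB) / 2
    nd <- abs(mid[onset] - ctr_on) / L_on
    d_is <- mean(abs(cA - cB)[meta | seq_len(last) == onset])
    # anaphase segregation: each sister's target pole is the one on its side
    # of the spindle centre at the end of the run
    arr <- function(x) {
      tgt <- if (x[last] >= ctr_end) s[, "x_spbR"] else s[, "x_spbL"]
      hit <- which(abs(x - tgt) <= epsilon & s[, "anaphase"] == 1)
      if (length(hit) == 0) NA_real_ else s[hit[1], "t"]
    }
    tA <- arr(cA); tB <- arr(cB)
    misseg <- sign(cA[last] - ctr_end) == sign(cB[last] - ctr_end) &&
      (cA[last] != ctr_end) && (cB[last] != ctr_end)
    tibble(chromosome = c,
           nd_onset = nd,
           spindle_length_onset = L_on,
           intersister_mean = d_is,
           lagging_time = abs(tA - tB),
           lagging_censored = is.na(tA) || is.na(tB),
           missegregated = misseg)
  })
  dplyr::bind_rows(rows)
}

#' Run an ensemble of simulations
#'
#' Repeats [simulate_mitosis()] `n_runs` times with seeds
#' `base_seed + 0:(n_runs-1)` and summarises each run per chromosome:
#' normalized distance of the sister-pair midpoint to the spindle centre at
#' anaphase onset (`nd_onset`, 0 = centre, 0.5 = pole), spindle length at
#' onset, time-averaged metaphase inter-sister distance, anaphase lagging
#' time (delay between the two sisters' pole arrivals, arrival being the
#' first time within `epsilon` of the tracked pole) and a mis-segregation
#' flag (both sisters on the same side of the spindle centre at the end of
#' anaphase A).
#'
#' @param params A [spindle_params()] object.
#' @param n_runs Number of independent runs (>= 1).
#' @param base_seed First seed; run `i` uses `base_seed + i - 1`.
#' @param epsilon Pole-arrival tolerance, um.
#' @param keep_trajectories If `TRUE`, the individual `sim_trajectory`
#'   objects are retained in the result (memory!).
#' @return A `sim_ensemble` object; `tidy()` returns the per-run,
#'   per-chromosome summary tibble and `glance()` the ensemble means.
#' @examples
#' p <- spindle_params(t_meta = 60, t_ana = 30)
#' ens <- run_ensemble(p, n_runs = 3, base_seed = 1)
#' tidy(ens)
#' @export
run_ensemble <- function(params, n_runs, base_seed = 1, epsilon = 0.2,
                         keep_trajectories = FALSE) {
  p <- validate_spindle_params(params)
  if (n_runs < 1) abort("`n_runs` must be >= 1")
  sims <- vector("list", if (keep_trajectories) n_runs else 0)
  summ <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    sim <- simulate_mitosis(p, seed = base_seed + i - 1)
    m <- run_metrics(sim, epsilon = epsilon)
    m$run <- i
    m$seed <- base_seed + i - 1
    summ[[i]] <- m
    if (keep_trajectories) sims[[i]] <- sim
  }
  out <- list(summary = dplyr::bind_rows(summ)[, c("run", "seed", "chromosome",
                                                   "nd_onset",
                                                   "spindle_length_onset",
                                                   "intersister_mean",
                                                   "lagging_time",
                                                   "lagging_censored",
                                                   "missegregated")],
              params = p, base_seed = base_seed,
              trajectories = if (keep_trajectories) sims else NULL)
  class(out) <- "sim_ensemble"
  out
}

#' @export
print.sim_ensemble <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<sim_ensemble> %d runs x %d chromosomes (L_dep %s)\n",
              max(x$summary$run), x$params$N_ch,
              if (x$params$ldep_enabled) "on" else "off"))
  cat(sprintf("  mean nd at anaphase onset: %.3f (sem %.3f)\n",
              g$mean_nd, g$sem_nd))
  cat(sprintf("  mean inter-sister distance: %.2f um; spindle at onset: %.2f um\n",
              g$mean_intersister, g$mean_spindle_length))
  cat(sprintf("  mis-segregation rate: %.2f%%; median lagging time: %.0f s\n",
              100 * g$missegregation_rate, g$median_lagging))
  invisible(x)
}

#' Sweep model parameters and measure centering
#'
#' Re-runs [run_ensemble()] for low/high variations of selected parameters
#' with the length-dependent prefactor turned off, alongside the unmodified
#' off-baseline and the on-reference, and reports the mean normalized
#' anaphase-onset distance per condition.  This is the in-silico control
#' asking whether any ordinary parameter change can substitute for the
#' length-dependent mechanism.
#'
#' @param params Baseline [spindle_params()].
#' @param factors Named list mapping parameter names to multipliers, e.g.
#'   `list(k_a = c(low = 0.5, high = 2))`.  Defaults to low = x0.5 /
#'   high = x2 for `k_a`, `k_d`, `d_alpha`, `K_c`, `F_mz`, `V_k`.
#' @param n_runs Runs per condition.
#' @param base_seed Seed of the first run of every condition.
#' @return A tibble with one row per condition (`condition`, `parameter`,
#'   `level`, `factor`, `ldep`, `mean_nd`, `sem_nd`, `mean_intersister`,
#'   `n`), classed `sweep_result` for [autoplot()].
#' @export
parameter_sweep <- function(params, factors = NULL, n_runs = 100,
                            base_seed = 1) {
  p <- validate_spindle_params(params)
  if (is.null(factors)) {
    factors <- setNames(
      rep(list(c(low = 0.5, high = 2)), 6),
      c("k_a", "k_d", "d_alpha", "K_c", "F_mz", "V_k"))
  }
  bad <- setdiff(names(factors), names(p))
  if (length(bad) > 0) {
    abort(paste0("unknown parameter(s) in `factors`: ",
                 paste(bad, collapse = ", ")))
  }
  one <- function(pp, cond, parameter, level, fac) {
    ens <- run_ensemble(pp, n_runs = n_runs, base_seed = base_seed)
    g <- glance(ens)
    tibble(condition = cond, parameter = parameter, level = level,
           factor = fac, ldep = pp$ldep_enabled,
           mean_nd = g$mean_nd, sem_nd = g$sem_nd,
           mean_intersister = g$mean_intersister, n = n_runs)
  }
  p_on <- p; p_on$ldep_enabled <- TRUE
  p_off <- p; p_off$ldep_enabled <- FALSE
  out <- list(one(p_on, "ldep_on", "ldep", "reference", 1),
              one(p_off, "baseline_off", "none", "baseline", 1))
  for (nm in names(factors)) {
    for (lev in names(factors[[nm]])) {
      fac <- factors[[nm]][[lev]]
      pp <- p_off
      pp[[nm]] <- pp[[nm]] * fac
      pp <- validate_spindle_params(pp)
      out[[length(out) + 1]] <-
        one(pp, paste0(nm, "_", lev), nm, lev, fac)
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("sweep_result", class(res))
  res
}
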