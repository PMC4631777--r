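# short-schedule parameter sets used across the unit tests; the defaults
# themselves are exercised in test-acceptance.R
fast_params <- function(...) {
  args <- utils::modifyList(list(t_meta = 60, t_ana = 30), list(...))
  do.call(spindle_params, args)
}

# mirror image of a spindle state about the spindle centre (origin)
mirror_state <- function(st) {
  out <- st
  out$x_spbL <- -st$x_spbR
  out$x_spbR <- -st$x_spbL
  out$x_cen <- -st$x_cen
  out$x_site <- -st$x_site
  out$att <- -st$att
  out$pi <- st$pi
  out
}

# noiseless deterministic synthetic oscillation parameters
clean_synth <- function(...) {
  synth_params("wt", noise_sd = 0, drift_sd = 0, breathing_sd = 0,
               detach_rate = 0, deterministic_reversal = TRUE, ...)
}
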