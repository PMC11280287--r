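# Shared fixtures: the study-default Franz cell and simulator truths.

paper_cfg <- function() default_scenario()$cfg
paper_times <- function() default_scenario()$times

# truth with a prescribed lag (h) and steady flux (ug/sq.cm/h) under the
# study-default cell
truth_from_lag_flux <- function(lag, flux, cfg = paper_cfg(), seed = 1L) {
  h <- cfg$skin_thickness
  D <- h^2 / (6 * lag)
  K <- flux * h / (cfg$donor_concentration * D)
  simulation_truth(D = D, K = K, h = h, C = cfg$donor_concentration,
                   seed = seed)
}

# noiseless simulated profile for a given truth
simulated_profile <- function(truth, cfg = paper_cfg(),
                              times = paper_times(), ...) {
  sim <- simulate_franz(truth, cfg, times, ...)
  cumulative_permeation(sim$series, cfg)
}
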