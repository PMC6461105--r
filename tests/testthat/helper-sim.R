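# shared fixtures built in code

# small, fast ensemble for smoke-level checks
small_ensemble <- function(k_active = 2.1, k_inactive = 2.4,
                           n_molecules = 40, seed = 101, ...) {
  simulate_ensemble(sim_config(two_state_rates(k_active, k_inactive),
                               n_molecules = n_molecules, seed = seed,
                               ...))
}

# pooled intensities drawn straight from a two-log-normal mixture with
# known area fractions -- the generative oracle for the histogram fit
mixture_sample <- function(n, frac_low, mode_low = 1, mode_high = 10,
                           shape = 0.2, seed = 1) {
  set.seed(seed)
  n_low <- rbinom(1, n, frac_low)
  c(rlnorm(n_low, log(mode_low) + shape^2, shape),
    rlnorm(n - n_low, log(mode_high) + shape^2, shape))
}

# the printed occupancy table's population ratios (unrounded)
keq_phos <- 23 / 77
keq_unphos <- 52 / 46
keq_phos_tpx2 <- 14 / 86
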