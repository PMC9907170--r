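# Shared fixtures built in code.

# Noiseless logistic culture: N(t) = K / (1 + (K/N0 - 1) exp(-r t)).
# Its log-ratio slope is r (1 - N/K), so the per-capita rate decays from
# ~r to 0 as the culture saturates.
logistic_curve <- function(N0 = 0.05, K = 5, r = 0.01,
                           times = seq(0, 2500, by = 10)) {
  N <- K / (1 + (K / N0 - 1) * exp(-r * times))
  log_transform(N, times, init_cycles = 1)
}

# Small two-genotype toxic screen used by the pipeline tests.
small_screen <- function(seed = 7, doses = c(0, 0.5, 1, 2),
                         replicates = 3,
                         treatment = treatment_model(
                           "toxic", on_lambda = c(1, 1, 2),
                           on_mu = c(0.6, 1, 2), on_kappa = c(0.4, 1, 2)),
                         noise = noise_spec()) {
  genos <- list(empty = well_sim_spec(0.05, 300, 0.012, 3),
                pip = well_sim_spec(0.05, 330, 0.011, 3))
  simulate_screen(genos, treatment, doses = doses,
                  replicates = replicates, noise = noise, seed = seed)
}
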