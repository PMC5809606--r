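# shorthand constructors used across the suite
leuk_m1 <- function(a, p, d = 2.3, ...) {
  model_params(lineage_params(a, p, d), variant = "model1", ...)
}
leuk_m2 <- function(a, p, d = 2.3, ...) {
  model_params(lineage_params(a, p, d), variant = "model2", ...)
}

# seeded state: healthy equilibrium plus leukemic mitotic cells
seeded_state <- function(params, lsc = 1) {
  st <- healthy_equilibrium(params)
  st["l1"] <- st["l1"] + lsc
  st
}

# observation table sampled without noise from a simulated trajectory
obs_from_trajectory <- function(params, init, times) {
  tr <- simulate_model(params, init = init, t_end = max(times),
                       times = sort(unique(c(0, times))))
  bf <- tr$blast_fraction[match(times, tr$t)]
  observation_table(t = times, kind = "exact", value = bf)
}
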