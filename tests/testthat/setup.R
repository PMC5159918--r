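# one moderate synthetic population shared across test files
shared_sim <- generate_population(
  simulation_config(seed = 42, n_population_sites = 600,
                    n_sampled_sites = 120))
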