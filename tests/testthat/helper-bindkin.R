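## Shared fixtures: reference truth systems and quiet instrument configs.

ref_system <- function() binding_system(4.1e4, 2.5e-3, R_max = 100,
                                        label = "reference")

noiseless <- function(interval = 0.4, assoc = 360, dissoc = 600) {
  instrument_config(noise_sd = 0, sampling_interval = interval,
                    association_window = assoc,
                    dissociation_window = dissoc)
}

noisy <- function(sd = 0.5, interval = 0.4, assoc = 360, dissoc = 600) {
  instrument_config(noise_sd = sd, sampling_interval = interval,
                    association_window = assoc,
                    dissociation_window = dissoc)
}

with_seed_test <- function(seed, code) withr::with_seed(seed, code)

## analytic association curve, for oracle comparisons
closed_form_association <- function(system, concentration, times, R0 = 0) {
  kon <- system$k_ass * concentration + system$k_diss
  Req <- system$R_max * concentration / (system$K_D + concentration)
  (Req - R0) * (1 - exp(-kon * times)) + R0
}
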