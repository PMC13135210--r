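# Example generator configuration overriding a few defaults.
# Load with: read_synth_config_yaml(system.file("extdata",
#   "synth_config_example.yaml", package = "teleabx"))
n_practices: 50
mean_patients_per_practice: 80
practice_intercept_sd: 0.4
true_ate_knob: -0.07
missingness_rates:
  race_ethnicity: 0.0615
  census_division: 0.0615
seed: 20230101
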