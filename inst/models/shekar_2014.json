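{
  "name": "shekar_2014",
  "label": "Shekar et al. 2014",
  "n_compartments": 2,
  "parameterization": "clearance-volume",
  "thetas": {"CL": 5.1, "V1": 22.7, "Q": 7.3, "V2": 18.1},
  "theta_units": {"CL": "L/h", "V1": "L", "Q": "L/h", "V2": "L"},
  "covariate_effects": [],
  "iiv_parameters": ["CL", "V1"],
  "omega": [[0.14, 0.0], [0.0, 0.25]],
  "residual_error": {
    "proportional": {
      "kind": "proportional",
      "sd_additive": 0,
      "sd_proportional": 0.25,
      "variant_label": "proportional"
    }
  },
  "population_medians": {},
  "provenance": "Two-compartment meropenem model developed in critically ill patients on extracorporeal support, after Shekar et al. 2014. Typical clearance anchored to the published 5.1 L/h. Variability magnitudes set to representative values where the source tabulation was not available."
}
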