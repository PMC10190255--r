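{
  "name": "grensemann_2020",
  "label": "Grensemann et al. 2020",
  "n_compartments": 2,
  "parameterization": "clearance-volume",
  "thetas": {"CL": 5.06, "V1": 17.4, "Q": 7.2, "V2": 16.8},
  "theta_units": {"CL": "L/h", "V1": "L", "Q": "L/h", "V2": "L"},
  "covariate_effects": [],
  "iiv_parameters": ["CL", "V1"],
  "omega": [[0.11, 0.0422], [0.0422, 0.18]],
  "residual_error": {
    "combined": {
      "kind": "combined",
      "sd_additive": 0.5,
      "sd_proportional": 0.15,
      "variant_label": "combined"
    }
  },
  "population_medians": {},
  "provenance": "Two-compartment meropenem model without covariates, after Grensemann et al. 2020. Typical clearance anchored to the published 5.06 L/h. Variability magnitudes set to representative values where the source tabulation was not available."
}
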