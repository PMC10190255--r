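{
  "name": "onichimowski_2020",
  "label": "Onichimowski et al. 2020",
  "n_compartments": 1,
  "parameterization": "clearance-volume",
  "thetas": {"CL": 15, "V1": 39.7},
  "theta_units": {"CL": "L/h", "V1": "L"},
  "covariate_effects": [],
  "iiv_parameters": ["CL", "V1"],
  "omega": [[0.16, 0.0], [0.0, 0.22]],
  "residual_error": {
    "proportional": {
      "kind": "proportional",
      "sd_additive": 0,
      "sd_proportional": 0.35,
      "variant_label": "proportional"
    }
  },
  "population_medians": {},
  "provenance": "One-compartment meropenem model without covariates, after Onichimowski et al. 2020. Typical clearance anchored to the published 15 L/h (a high value relative to other candidates; the source population differed systematically). Variability magnitudes set to representative values where the source tabulation was not available."
}
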