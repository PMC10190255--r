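{
  "name": "ojeanson_2021",
  "label": "O'Jeanson et al. 2021",
  "n_compartments": 2,
  "parameterization": "clearance-volume",
  "thetas": {"CL": 5.78, "V1": 21.9, "Q": 4.3, "V2": 13.7},
  "theta_units": {"CL": "L/h", "V1": "L", "Q": "L/h", "V2": "L"},
  "covariate_effects": [
    {
      "parameter": "CL",
      "covariate": "residual_diuresis",
      "form": "linear",
      "coefficients": [0.00154],
      "reference_value": 0
    }
  ],
  "iiv_parameters": ["CL", "V1"],
  "omega": [[0.09, 0.0], [0.0, 0.16]],
  "residual_error": {
    "proportional": {
      "kind": "proportional",
      "sd_additive": 0,
      "sd_proportional": 0.21,
      "variant_label": "proportional"
    }
  },
  "population_medians": {"residual_diuresis": 845},
  "provenance": "Two-compartment meropenem model for critically ill CRRT patients with residual diuresis (mL/24 h) as a linear covariate on clearance, after O'Jeanson et al. 2021. Typical clearance anchored to the published 5.78 L/h at zero residual diuresis; development-population median residual diuresis 845 mL/24 h. Distribution, variability, and residual-error magnitudes set to representative values where the source tabulation was not available."
}
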