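{
  "name": "burger_2018",
  "label": "Burger et al. 2018",
  "n_compartments": 2,
  "parameterization": "clearance-volume",
  "thetas": {"CL": 4.7, "V1": 29.6, "Q": 6.6, "V2": 22.4},
  "theta_units": {"CL": "L/h", "V1": "L", "Q": "L/h", "V2": "L"},
  "covariate_effects": [
    {
      "parameter": "CL",
      "covariate": "total_flow_rate",
      "form": "linear",
      "coefficients": [0.0011],
      "reference_value": 2000
    }
  ],
  "iiv_parameters": ["CL", "V1"],
  "omega": [[0.12, 0.0], [0.0, 0.2]],
  "residual_error": {
    "proportional": {
      "kind": "proportional",
      "sd_additive": 0,
      "sd_proportional": 0.18,
      "variant_label": "proportional"
    },
    "combined": {
      "kind": "combined",
      "sd_additive": 0.45,
      "sd_proportional": 0.14,
      "variant_label": "combined"
    },
    "additive": {
      "kind": "additive",
      "sd_additive": 1.7,
      "sd_proportional": 0,
      "variant_label": "additive"
    }
  },
  "population_medians": {"total_flow_rate": 2000},
  "provenance": "Two-compartment meropenem model with total CRRT flow rate (mL/h) as a structural linear covariate on clearance, after Burger et al. 2018. Typical clearance anchored to the published 4.7 L/h at the 2,000 mL/h reference flow. Three residual-error variants are published for this model and each is evaluated as a separate arm. Variability magnitudes set to representative values where the source tabulation was not available."
}
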