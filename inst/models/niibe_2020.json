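{
  "name": "niibe_2020",
  "label": "Niibe et al. 2020",
  "n_compartments": 2,
  "parameterization": "clearance-volume",
  "thetas": {"CL": 4.4, "V1": 14.8, "Q": 5.9, "V2": 11.2},
  "theta_units": {"CL": "L/h", "V1": "L", "Q": "L/h", "V2": "L"},
  "covariate_effects": [
    {
      "parameter": "CL",
      "covariate": "egfr_cg",
      "form": "power",
      "coefficients": [0.45],
      "reference_value": 31
    }
  ],
  "iiv_parameters": ["CL", "V1"],
  "omega": [[0.1, 0.0], [0.0, 0.15]],
  "residual_error": {
    "combined": {
      "kind": "combined",
      "sd_additive": 0.3,
      "sd_proportional": 0.2,
      "variant_label": "combined"
    }
  },
  "population_medians": {"egfr_cg": 31},
  "provenance": "Two-compartment meropenem model with Cockcroft-Gault eGFR as a power covariate on clearance, after Niibe et al. 2020. Typical clearance anchored to the published 4.4 L/h at the reference eGFR of 31 (reported per 1.73 m^2 in the source; the unindexed Table-1-style eGFR is used unchanged here, an ambiguity inherited from the sources). Variability magnitudes set to representative values where the source tabulation was not available."
}
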