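{
  "name": "hanberg_2018",
  "label": "Hanberg et al. 2018",
  "n_compartments": 2,
  "parameterization": "clearance-volume",
  "thetas": {"CL": 1.9, "V1": 9.6, "Q": 8.0, "V2": 12.1},
  "theta_units": {"CL": "L/h", "V1": "L", "Q": "L/h", "V2": "L"},
  "covariate_effects": [
    {
      "parameter": "CL",
      "covariate": "egfr_ckdepi",
      "form": "power",
      "coefficients": [0.6],
      "reference_value": 41
    }
  ],
  "iiv_parameters": ["CL", "V1"],
  "omega": [[0.2, 0.0], [0.0, 0.3]],
  "residual_error": {
    "proportional": {
      "kind": "proportional",
      "sd_additive": 0,
      "sd_proportional": 0.3,
      "variant_label": "proportional"
    }
  },
  "population_medians": {"egfr_ckdepi": 41},
  "provenance": "Two-compartment meropenem model developed in ECMO patients with CKD-EPI eGFR as a power covariate on clearance, after Hanberg et al. 2018. Typical clearance anchored to the published 1.9 L/h at the reference eGFR of 41 mL/min/1.73 m^2 (a low value relative to other candidates; the source population differed systematically). Variability magnitudes set to representative values where the source tabulation was not available."
}
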