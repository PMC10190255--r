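{
  "name": "ulldemolins_2015",
  "label": "Ulldemolins et al. 2015",
  "n_compartments": 1,
  "parameterization": "clearance-volume",
  "thetas": {"CL": 3.2, "V1": 40.5},
  "theta_units": {"CL": "L/h", "V1": "L"},
  "covariate_effects": [
    {
      "parameter": "CL",
      "covariate": "residual_diuresis",
      "form": "linear",
      "coefficients": [0.0012],
      "reference_value": 0
    }
  ],
  "iiv_parameters": ["CL", "V1"],
  "omega": [[0.13, 0.0], [0.0, 0.21]],
  "residual_error": {
    "combined": {
      "kind": "combined",
      "sd_additive": 1.0,
      "sd_proportional": 0.25,
      "variant_label": "combined"
    }
  },
  "population_medians": {"residual_diuresis": 500},
  "provenance": "One-compartment meropenem model for CRRT patients with residual diuresis (mL/24 h) as a linear covariate on clearance, after Ulldemolins et al. 2015. Parameter values set to representative magnitudes consistent with the covariate structure reported for this model; no typical clearance was printed for it in the evaluation the package emulates."
}
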