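{
  "t_hole_eV": 0.0146,
  "t_elec_eV": 0.0293,
  "lambda_eV": 0.37,
  "temperature_K": 298,
  "z0_A": 3.10,
  "r0_A": 13,
  "area_A2": 30.0,
  "length_A": null,
  "rho_per_m3": 4.0e26
}
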