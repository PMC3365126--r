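{
  "geometry": "cylinder",
  "mechanical": {"C11": 0.06, "C12": 0.04, "C22": 0.08,
                 "eta": 6.5e-06, "nu": 0.7},
  "electrical": {"tau_e": 5, "C_sp": 0.01},
  "coupling": {"alpha1_Csp": -0.08, "alpha2_Csp": 0.03},
  "cell": {"r_c": 5e-06},
  "units": {"tau_e": "us"}
}
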