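# prestinmem JSON config schema

Top-level keys:

- `geometry` (required): `"cylinder"` (outer hair cell, orthotropic wall) or
  `"sphere"` (prestin-transfected cell, isotropic membrane).
- `mechanical` (required):
  - cylinder: `C11`, `C12`, `C22` (N/m, positive-definite matrix), `eta`
    (N s^nu / m, >= 0), `nu` (dimensionless, in (0, 1)).
  - sphere: `K` (N/m, > 0), `eta`, `nu` as above.
- `electrical` (required): `tau_e` (prestin RC time; seconds unless `units`
  says otherwise), `C_sp` (specific capacitance, F/m^2).
- `coupling` (required):
  - cylinder: `alpha1_Csp`, `alpha2_Csp` (products alpha_i * C_sp, 1/V).
  - sphere: `alpha_Csp` (1/V).
- `cell` (required): `r_c` (radius, m).
- `units` (optional): `{"tau_e": "s" | "ms" | "us"}`. All other quantities
  are SI.

Example (`default_ohc.json`, the package defaults):

```json
{
  "geometry": "cylinder",
  "mechanical": {"C11": 0.06, "C12": 0.04, "C22": 0.08,
                 "eta": 6.5e-06, "nu": 0.7},
  "electrical": {"tau_e": 5, "C_sp": 0.01},
  "coupling": {"alpha1_Csp": -0.08, "alpha2_Csp": 0.03},
  "cell": {"r_c": 5e-06},
  "units": {"tau_e": "us"}
}
```

Sweep CSV schema (`prestinmem fit force --data`): header row
`freq_hz,amplitude_norm[,phase_rad]`; frequencies in Hz, strictly
increasing; amplitudes normalized to the low-frequency value. Lines
starting with `#` are comments.

Charge time-course CSV: header `t_s,q_C_per_m2` (SI units), signed charge.
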