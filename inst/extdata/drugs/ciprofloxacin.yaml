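name: ciprofloxacin
logP: 0.95
fu_p: 0.67
mw: 331.3
pka:
- value: 6.09
  type: acid
- value: 8.62
  type: base
solubility:
- mg_mL: 38.4
  ph: 7.0
  prandial: any
distribution: pksim
p_int: 1.57
saef_overrides:
  caecum: 26.24
  colon_ascendens: 0.0
  colon_transversum: 0.0
  colon_descendens: 0.0
  colon_sigmoid: 0.0
  rectum: 0.0
renal:
  cl_spec: 1.61
  gfr_fraction: 1.0
hepatic:
  pathway: CYP1A2
  cl_spec: 0.043
biliary:
  cl_spec: 0.096
comment: cl_spec 1/min normalized to organ volume; caecal surface enhancement 26.24, other large intestine 0
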