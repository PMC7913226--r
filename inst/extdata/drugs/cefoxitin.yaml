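name: cefoxitin
logP: 0.84
fu_p: 0.48
mw: 427.45
pka:
- value: 3.58
  type: acid
solubility:
- mg_mL: 0.2
  ph: 7.0
  prandial: any
distribution: rodgers_rowland
p_int: 0.161
renal:
  cl_spec: 3.8
  gfr_fraction: 1.0
comment: renal cl_spec 1/min normalized to kidney volume, plus glomerular filtration
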