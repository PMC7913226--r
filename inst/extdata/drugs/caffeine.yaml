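name: caffeine
logP: 0.87
fu_p: 0.7
mw: 194.2
pka:
- value: 0.8
  type: base
solubility:
- mg_mL: 21.6
  ph: 7.0
  prandial: any
distribution: pksim
p_int: 223.0
renal:
  cl_spec: 0.00246
  gfr_fraction: 0.0
hepatic:
  pathway: CYP1A2
  vmax: 73.1
  km: 14.7
comment: vmax pmol/min/mg microsomal protein, km uM, renal cl_spec 1/min (2.46e-3)
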