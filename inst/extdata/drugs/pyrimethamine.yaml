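name: pyrimethamine
logP: 3.14
fu_p: 0.095
mw: 248.71
pka:
- value: 6.9
  type: base
solubility:
- mg_mL: 0.12
  ph: 5.0
  prandial: any
distribution: rodgers_rowland
p_int: 6370.0
renal:
  gfr_fraction: 1.0
hepatic:
  pathway: unspecific_hepatic
  cl_spec: 0.089
erythrocyte:
  vf_proteins: 0.19
  vf_lipid: 0.0
dissolution:
  any:
    t50_min: 10.0
    shape: 1.0
comment: hepatic cl_spec 1/min normalized to liver volume; erythrocyte fractions set the whole-blood to plasma ratio
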