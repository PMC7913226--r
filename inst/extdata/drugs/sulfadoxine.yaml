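name: sulfadoxine
logP: 3.74
fu_p: 0.036
mw: 310.33
pka:
- value: 6.2
  type: acid
solubility:
- mg_mL: 0.474
  ph: 5.0
  prandial: any
distribution: rodgers_rowland
p_int: 1690.0
renal:
  gfr_fraction: 0.21
erythrocyte:
  vf_proteins: 0.06
  vf_lipid: 0.0
dissolution:
  any:
    t50_min: 10.0
    shape: 1.0
comment: net renal elimination as a fraction of glomerular filtration (tubular reabsorption)
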