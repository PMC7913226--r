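name: lumefantrine
logP: 3.09
fu_p: 0.0029
mw: 528.9
pka:
- value: 9.35
  type: base
solubility:
- mg_mL: 0.0097
  ph: 6.5
  prandial: fasted
- mg_mL: 0.18
  ph: 5.0
  prandial: fed_high_fat
- mg_mL: 0.05
  ph: 5.0
  prandial: fed
distribution: pksim
p_int: 24.4
hepatic:
  pathway: CYP3A4
  cl_int: 93.7
dissolution:
  fasted:
    t50_min: 270.0
    shape: 6.9
  fed:
    t50_min: 217.0
    shape: 1.9
comment: cl_int uL/min/mg microsomal protein; fed solubility is the milk value used for the nutritional drink
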