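compartment,mild,intermediate,severe,provenance
bone,0.947,0.913,0.869,interpolated
brain,0.918,0.865,0.797,measured
fat,0.817,0.822,0.624,adjusted
gonads,0.936,0.894,0.84,surrogate
intestines,0.936,0.894,0.84,surrogate
lung,0.936,0.894,0.84,surrogate
stomach,0.936,0.894,0.84,surrogate
heart,0.902,0.839,0.758,measured
kidney,0.874,0.792,0.686,measured
liver,0.872,0.789,0.682,measured
muscle,0.893,0.771,0.715,adjusted
pancreas,0.936,0.894,0.84,surrogate
skin,0.954,0.922,0.879,measured
spleen,0.844,0.743,0.612,measured
blood_arterial,1.03,0.992,0.833,fixture
blood_venous,1.02,0.979,0.822,fixture
blood_portal,1.02,0.982,0.825,fixture
plasma_proteins,0.894,0.706,0.494,measured
hematocrit,0.945,0.791,0.681,measured
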