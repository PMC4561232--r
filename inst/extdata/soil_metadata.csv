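parameter,value,unit
sand,69.41,percent
silt,27.71,percent
clay,2.88,percent
pH_KCl,7,-
HAC,6.4,mmol(+)/kg
TEB,165.9,mmol(+)/kg
C_org,14.3,g/kg
N_total,0.98,g/kg
K,180,mg/kg
Ca,2571.4,mg/kg
Na,20,mg/kg
Mg,59.5,mg/kg
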