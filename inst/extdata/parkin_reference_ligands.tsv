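ligand	kd_uM	dissociation_half_life_s	concentrations_uM
DTT	1.4	1737	62.5,31.25,15.62,7.8,3.9,1.95,0.98
UblD	5.4	120	140,46.7,15.6,5.2,1.7,0.6
UbcH7	4.7	30	140,46.7,15.6,5.2,1.7,0.6
Ubq	82	NA	500,250,125,62.5,31.25,15.62
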