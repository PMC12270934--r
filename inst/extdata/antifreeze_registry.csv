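name,mw_g_per_mol,dissociation_degree
glucose,180,1
sucrose,342,1
maltodextrin,800,1
ethanol,46.5,1
xylitol,152,1
NaCl,58.4,2
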