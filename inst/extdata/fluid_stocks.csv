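# Electrolyte stock solutions for the simulated digestive fluids, at 1.25x
# the working concentration (mmol/L). NA = constituent absent from that fluid.
constituent,oral,gastric,intestinal
KCl,15.1,6.90,6.80
KH2PO4,3.70,0.90,0.80
NaHCO3,13.6,25.0,85.0
NaCl,NA,47.2,38.4
MgCl2_6H2O,0.15,0.10,0.33
NH4_2CO3,0.06,0.50,NA
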