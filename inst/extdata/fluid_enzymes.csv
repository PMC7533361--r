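# Enzymatic components of the simulated digestion fluids at working (1x)
# strength, dosed by pre-defined activity, plus working CaCl2 and pH.
# stock_u_per_ml is the activity of the enzyme stock solution used when
# allocating volumes in working_fluid(); adjust to the batch in hand.
phase,enzyme,activity_u_per_ml,stock_u_per_ml,cacl2_mmol_l,ph
oral,alpha-amylase,75,1500,0.75,7
gastric,pepsin,2000,40000,0.075,3
intestinal,alpha-chymotrypsin,25,1000,0.3,7
intestinal,trypsin,100,4000,0.3,7
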