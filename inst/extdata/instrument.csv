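# Orbitrap instrument parameter set used for PRM of gluten peptides
# (stored verbatim from the shipped method; acquisition metadata only).
parameter,value
spray_voltage,35 kV
spray_current,17 uA
aux_gas_flow_rate,10
sheath_gas_flow_rate,45
scan_range,108-4015 m/z
resolving_power,70000
capillary_temperature,320 C
normalised_collision_energy,stepped 18-27
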