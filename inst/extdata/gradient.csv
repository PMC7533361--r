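# Reversed-phase chromatography schedule for the quantitative PRM runs.
# percent_b is the acetonitrile mobile phase; the run ends at 15.07 min.
time_min,percent_b,flow_ml_min,event
0.00,3,0.30,inject
1.00,7,0.30,
3.00,25,0.30,
3.90,40,0.30,
8.00,95,0.40,
9.50,95,0.40,
12.00,95,0.30,
12.50,7,0.30,
15.07,3,0.30,end
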