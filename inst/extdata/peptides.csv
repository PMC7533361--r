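# Marker immunogenic gluten peptides monitored by the shipped PRM method.
# P1H is the heavy internal standard: L-phenylalanine(13C9,15N) at residue 6.
# Its label_delta overrides the composition-derived +10.027 Da with the value
# most consistent with the printed P1H transition m/z (+6.006 Da); remove the
# override to use the composition delta.
name,sequence,charges,label_position,label_13c,label_15n,label_delta,rt_min
P1,LQLQPFPQPQLPY,2,,,,,6.11
P1H,LQLQPFPQPQLPY,2,6,9,1,6.006,6.11
P2,LQLQPFPQPQLPYPQPQPF,3,,,,,6.59
P3,LQLQPFPQPQLPYPQPHLPYPQPQPF,3,,,,,7.12
P4,LQLQPFPQPQLPYPQPQLPYPQPQPF,3,,,,,6.43
P5,LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF,4,,,,,7.29
P6,RPQQPYPQPQPQY,2,,,,,3.48
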