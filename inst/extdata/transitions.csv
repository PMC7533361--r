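# Shipped PRM transition list, one row per fragment ion, values as printed in
# the source method (stored verbatim; validate_config() reports where they
# disagree with recomputation from the sequences).
peptide,sequence,precursor_mz,charge,fragment_label,fragment_mz,rt_min,window_min
P1,LQLQPFPQPQLPY,784.927,2,y2,279.134,6.11,0.5
P1,LQLQPFPQPQLPY,784.927,2,b4,483.293,6.11,0.5
P1,LQLQPFPQPQLPY,784.927,2,b6,470.240,6.11,0.5
P1,LQLQPFPQPQLPY,784.927,2,b11,1290.719,6.11,0.5
P1H,LQLQPFPQPQLPY,787.927,2,y2,279.134,6.11,0.5
P1H,LQLQPFPQPQLPY,787.927,2,b4,483.293,6.11,0.5
P1H,LQLQPFPQPQLPY,787.927,2,b6,476.254,6.11,0.5
P1H,LQLQPFPQPQLPY,787.927,2,b11,1296.731,6.11,0.5
P2,LQLQPFPQPQLPYPQPQPF,755.068,3,y4,488.251,6.59,0.5
P2,LQLQPFPQPQLPYPQPQPF,755.068,3,b8,952.526,6.59,0.5
P2,LQLQPFPQPQLPYPQPQPF,755.068,3,b9,1049.544,6.59,0.5
P3,LQLQPFPQPQLPYPQPHLPYPQPQPF,1029.543,3,y2,263.139,7.12,0.5
P3,LQLQPFPQPQLPYPQPHLPYPQPQPF,1029.543,3,b7,824.429,7.12,0.5
P3,LQLQPFPQPQLPYPQPHLPYPQPQPF,1029.543,3,y6,713.357,7.12,0.5
P3,LQLQPFPQPQLPYPQPHLPYPQPQPF,1029.543,3,b8,952.527,7.12,0.5
P3,LQLQPFPQPQLPYPQPHLPYPQPQPF,1029.543,3,b11,1290.722,7.12,0.5
P4,LQLQPFPQPQLPYPQPQLPYPQPQPF,1032.543,3,y2,263.139,6.43,0.5
P4,LQLQPFPQPQLPYPQPQLPYPQPQPF,1032.543,3,y4,488.250,6.43,0.5
P4,LQLQPFPQPQLPYPQPQLPYPQPQPF,1032.543,3,y6,713.358,6.43,0.5
P4,LQLQPFPQPQLPYPQPQLPYPQPQPF,1032.543,3,y8,973.479,6.43,0.5
P5,LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF,978.264,4,y4,488.252,7.29,0.5
P5,LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF,978.264,4,b21,824.429,7.29,0.5
P5,LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF,978.264,4,y8,973.480,7.29,0.5
P5,LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF,978.264,4,b11,1290.726,7.29,0.5
P6,RPQQPYPQPQPQY,813.905,2,y3,407.194,3.48,0.5
P6,RPQQPYPQPQPQY,813.905,2,a8,967.513,3.48,0.5
P6,RPQQPYPQPQPQY,813.905,2,b9,995.508,3.48,0.5
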