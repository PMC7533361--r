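# HLA-DQ2.5-restricted gluten T-cell epitope 9-mer cores (native, not
# deamidated), as curated in the standard celiac epitope registry
# (Sollid et al. nomenclature). The glia-a3 entry is the native 9-mer carried
# by peptide P6 (the canonical register starts one residue earlier with F,
# which P6 does not contain). Editable: motif scanning uses exact overlapping
# matches against these cores.
epitope,core
DQ2.5-glia-a1a,PFPQPQLPY
DQ2.5-glia-a1b,PYPQPQLPY
DQ2.5-glia-a2,PQPQLPYPQ
DQ2.5-glia-a3,RPQQPYPQP
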