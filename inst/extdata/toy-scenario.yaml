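# Example CLI scenario: a fast five-chromosome toy cohort.
chrom_lengths:
  chr1: 6000
  chr2: 5000
  chr3: 4000
  chrX: 3000
  chrY: 2000
telomere_length: 100
centromere_length: 200
par_length: 300
repeat_block: 150
sample_depth: 40
control_depth: 15
n_controls: 1
n_reference: 20
n_euploid_test: 2
n_trisomic_test: 1
trisomy_chrom: chr3
fetal_fraction: 20
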