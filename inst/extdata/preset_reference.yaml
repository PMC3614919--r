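# Reference power-study scenario: 100 founders, 200 RILs, three 100 cM
# chromosomes with markers every 10 cM, one 3-allele QTL at 50 cM of each
# chromosome, five categories in ratio 1:2:4:2:1.
nFounders: 100
nNonfounders: 200
chromosomes:
  - {length_cM: 100, spacing_cM: 10}
  - {length_cM: 100, spacing_cM: 10}
  - {length_cM: 100, spacing_cM: 10}
nAlleles: 3
qtl:
  - {chromosome: 1, position_cM: 50, h2: 0.05}
  - {chromosome: 2, position_cM: 50, h2: 0.10}
  - {chromosome: 3, position_cM: 50, h2: 0.15}
categoryFreqs: [1, 2, 4, 2, 1]
nReplicates: 100
lodThreshold: 2.0
seed: 1
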