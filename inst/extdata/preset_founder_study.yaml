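# Founder-number power study: 200 RILs from a variable founder pool,
# three 1000 cM chromosomes (101 markers each at 10 cM), 18 QTL.
nFounders: 50
nNonfounders: 200
chromosomes:
  - {length_cM: 1000, spacing_cM: 10}
  - {length_cM: 1000, spacing_cM: 10}
  - {length_cM: 1000, spacing_cM: 10}
nAlleles: 3
qtl:
  - {chromosome: 1, position_cM: 90, h2: 0.01}
  - {chromosome: 1, position_cM: 240, h2: 0.01}
  - {chromosome: 1, position_cM: 390, h2: 0.01}
  - {chromosome: 1, position_cM: 540, h2: 0.01}
  - {chromosome: 1, position_cM: 690, h2: 0.01}
  - {chromosome: 1, position_cM: 840, h2: 0.03}
  - {chromosome: 2, position_cM: 80, h2: 0.03}
  - {chromosome: 2, position_cM: 230, h2: 0.03}
  - {chromosome: 2, position_cM: 380, h2: 0.03}
  - {chromosome: 2, position_cM: 530, h2: 0.03}
  - {chromosome: 2, position_cM: 680, h2: 0.05}
  - {chromosome: 2, position_cM: 830, h2: 0.05}
  - {chromosome: 3, position_cM: 120, h2: 0.05}
  - {chromosome: 3, position_cM: 270, h2: 0.05}
  - {chromosome: 3, position_cM: 420, h2: 0.05}
  - {chromosome: 3, position_cM: 570, h2: 0.05}
  - {chromosome: 3, position_cM: 720, h2: 0.10}
  - {chromosome: 3, position_cM: 870, h2: 0.15}
categoryFreqs: [1, 2, 4, 2, 1]
nReplicates: 100
lodThreshold: 2.0
seed: 1
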