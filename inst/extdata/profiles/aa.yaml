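# Generation profile: African-American prostate-cancer patient stratum.
# Note the race-reversed minor alleles relative to the EA profile:
# rs4652 (minor A here, C in EA) and DHFR-19bp (minor ins here, del in EA).
# All same-chromosome r2 < 0.2 in this stratum, so no LD pair is declared.
# Ancestry = African-ancestry proportion.
stratum: AA
n_samples: 604
target_prevalence: 0.306
age_mean: 61.8
age_sd: 7.8
site_prob: 0.555
ancestry_mean: 0.906
ancestry_sd: 0.155
ld: null
variants:
  - {variant_id: rs2274976, chromosome: "1", position: 11790870, gene: MTHFR, allele_a: A, allele_b: G, minor_allele: A, maf: 0.03}
  - {variant_id: rs1801131, chromosome: "1", position: 11794419, gene: MTHFR, allele_a: C, allele_b: A, minor_allele: C, maf: 0.17}
  - {variant_id: rs1801133, chromosome: "1", position: 11796321, gene: MTHFR, allele_a: A, allele_b: G, minor_allele: A, maf: 0.13}
  - {variant_id: rs1805087, chromosome: "1", position: 236885200, gene: MTR, allele_a: G, allele_b: A, minor_allele: G, maf: 0.29}
  - {variant_id: rs7587117, chromosome: "2", position: 74221528, gene: SLC4A5, allele_a: C, allele_b: T, minor_allele: C, maf: 0.16}
  - {variant_id: rs10380, chromosome: "5", position: 7897078, gene: MTRR, allele_a: T, allele_b: C, minor_allele: T, maf: 0.34}
  - {variant_id: rs4644, chromosome: "14", position: 55138217, gene: LGALS3, allele_a: A, allele_b: C, minor_allele: A, maf: 0.26}
  - {variant_id: rs4652, chromosome: "14", position: 55138318, gene: LGALS3, allele_a: C, allele_b: A, minor_allele: A, maf: 0.16}
  - {variant_id: rs2236225, chromosome: "14", position: 64442127, gene: MTHFD1, allele_a: T, allele_b: C, minor_allele: T, maf: 0.22}
  - {variant_id: rs622506, chromosome: "15", position: 79846853, gene: MTHFS, allele_a: C, allele_b: A, minor_allele: C, maf: 0.18}
  - {variant_id: DHFR-19bp, chromosome: "19", position: .na, gene: DHFR, allele_a: del, allele_b: ins, minor_allele: ins, maf: 0.45}
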