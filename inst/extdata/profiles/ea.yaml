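# Generation profile: European-American prostate-cancer patient stratum.
# Sample size, high-aggressiveness prevalence, covariate distributions,
# per-variant minor-allele frequencies and the one strong LD pair
# (rs4644-rs4652, r2 = 0.86). Ancestry = European-ancestry proportion.
stratum: EA
n_samples: 690
target_prevalence: 0.214
age_mean: 64.0
age_sd: 7.7
site_prob: 0.538
ancestry_mean: 0.967
ancestry_sd: 0.073
ld:
  variant_1: rs4644
  variant_2: rs4652
  r2: 0.86
variants:
  - {variant_id: rs2274976, chromosome: "1", position: 11790870, gene: MTHFR, allele_a: A, allele_b: G, minor_allele: A, maf: 0.05}
  - {variant_id: rs1801131, chromosome: "1", position: 11794419, gene: MTHFR, allele_a: C, allele_b: A, minor_allele: C, maf: 0.33}
  - {variant_id: rs1801133, chromosome: "1", position: 11796321, gene: MTHFR, allele_a: A, allele_b: G, minor_allele: A, maf: 0.33}
  - {variant_id: rs1805087, chromosome: "1", position: 236885200, gene: MTR, allele_a: G, allele_b: A, minor_allele: G, maf: 0.20}
  - {variant_id: rs7587117, chromosome: "2", position: 74221528, gene: SLC4A5, allele_a: C, allele_b: T, minor_allele: C, maf: 0.32}
  - {variant_id: rs10380, chromosome: "5", position: 7897078, gene: MTRR, allele_a: T, allele_b: C, minor_allele: T, maf: 0.10}
  - {variant_id: rs4644, chromosome: "14", position: 55138217, gene: LGALS3, allele_a: A, allele_b: C, minor_allele: A, maf: 0.39}
  - {variant_id: rs4652, chromosome: "14", position: 55138318, gene: LGALS3, allele_a: C, allele_b: A, minor_allele: C, maf: 0.42}
  - {variant_id: rs2236225, chromosome: "14", position: 64442127, gene: MTHFD1, allele_a: T, allele_b: C, minor_allele: T, maf: 0.43}
  - {variant_id: rs622506, chromosome: "15", position: 79846853, gene: MTHFS, allele_a: C, allele_b: A, minor_allele: C, maf: 0.35}
  # chromosome kept as listed in the source metadata panel ("19") even
  # though DHFR maps to 5q14.1; position unavailable for the 19-bp indel.
  - {variant_id: DHFR-19bp, chromosome: "19", position: .na, gene: DHFR, allele_a: del, allele_b: ins, minor_allele: del, maf: 0.43}
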