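# Programmatic fixtures: tiny cohorts, genotype tables and VCF text built
# in code at test time.

fix_variants <- function(k = 2) {
  data.frame(
    variant_id = paste0("rsV", seq_len(k)),
    chromosome = rep("1", k),
    position = seq_len(k) * 1000L,
    gene = paste0("GENE", seq_len(k)),
    allele_a = rep("A", k), allele_b = rep("G", k),
    minor_allele = rep("A", k),
    stringsAsFactors = FALSE)
}

# small random cohort: two HWE variants, covariates, Bernoulli(0.3) outcome
fix_random_cohort <- function(seed, n = 200, maf1 = 0.3, maf2 = 0.4,
                              prev = 0.3) {
  g1 <- sipiScan::simulateGenotypes(maf1, n, seed = seed)
  g2 <- sipiScan::simulateGenotypes(maf2, n, seed = seed + 100000L)
  cv <- sipiScan::simulateCovariates(
    list(age_mean = 64, age_sd = 7.7, site_prob = 0.5,
         ancestry_mean = 0.9, ancestry_sd = 0.05),
    n = n, seed = seed + 200000L)
  y <- sipiScan::simulateOutcome(g1, g2, cv, NULL, prev,
                                 seed = seed + 300000L)
  sipiScan::SnpCohort(rbind(rsV1 = g1, rsV2 = g2), fix_variants(2),
                      phenotype = y, age = cv$age, site = cv$site,
                      ancestry = cv$ancestry, stratum = "SIM")
}

# cohort with a planted interaction effect on its two variants
fix_effect_cohort <- function(seed, n, pattern, beta, maf1 = 0.33,
                              maf2 = 0.43, prev = 0.214,
                              covariate_betas = c(age = 0, site = 0,
                                                  ancestry = 0)) {
  g1 <- sipiScan::simulateGenotypes(maf1, n, seed = seed)
  g2 <- sipiScan::simulateGenotypes(maf2, n, seed = seed + 100000L)
  cv <- sipiScan::simulateCovariates(
    list(age_mean = 64, age_sd = 7.7, site_prob = 0.538,
         ancestry_mean = 0.967, ancestry_sd = 0.073),
    n = n, seed = seed + 200000L)
  eff <- sipiScan::effectSpec(pattern, beta,
                              covariate_betas = covariate_betas)
  y <- sipiScan::simulateOutcome(g1, g2, cv, eff, prev,
                                 seed = seed + 300000L)
  sipiScan::SnpCohort(rbind(rsV1 = g1, rsV2 = g2), fix_variants(2),
                      phenotype = y, age = cv$age, site = cv$site,
                      ancestry = cv$ancestry, stratum = "SIM")
}

fix_write_genotype_table <- function(path, sep = "\t") {
  lines <- c(
    paste(c("sample_id", "phenotype", "age", "site", "ancestry",
            "rsV1", "rsV2"), collapse = sep),
    paste(c("s1", "0", "61.2", "1", "0.95", "0", "A/G"), collapse = sep),
    paste(c("s2", "1", "70.5", "0", "0.99", "1", "G/G"), collapse = sep),
    paste(c("s3", "0", "58.0", "1", "0.91", "2", "A/A"), collapse = sep),
    paste(c("s4", "1", "66.3", "0", "0.97", "NA", "G/A"),
          collapse = sep))
  writeLines(lines, path)
  path
}

fix_write_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    paste(c("1", "1000", "rsV1", "A", "G", ".", ".", ".", "GT",
            "0/0", "0/1", "1/1", "./."), collapse = "\t"),
    paste(c("1", "2000", "rsV2", "C", "T", ".", ".", ".", "GT",
            "0|1", "./1", "1/1", "0/0"), collapse = "\t"),
    paste(c("1", "3000", "rsTri", "C", "T,G", ".", ".", ".", "GT",
            "0/1", "0/2", "0/0", "0/0"), collapse = "\t"))
  writeLines(lines, path)
  path
}
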