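#!/usr/bin/env Rscript
# Build one synthetic mapping cohort: a phased SNP panel with block LD, an
# embedded recessive fertility haplotype (frequency 0.18, homozygote effect
# -0.8 SD, h2 = 0.10), and sequence variants around it. Writes the phased
# VCF, phenotype and variant tables used by the downstream steps.

suppressPackageStartupMessages(library(haplorec))
dir.create("results", showWarnings = FALSE)

seed <- 20260930L
cfg <- sim_config(n_individuals = 2000,
                  chrom_sizes = c("1" = 1500, "2" = 1000),
                  seed = seed)
panel <- simulate_panel(cfg)
cs <- embed_recessive_qtl(panel, "1", c(701, 780), target_freq = 0.18,
                          tolerance = 0.02, seed = seed + 1L)
panel <- cs$panel
message("embedded causal haplotype on BTA-like chromosome 1, SNPs 701-780, ",
        "realized frequency ", round(cs$realized_frequency, 3),
        ", homozygotes ", sum(causal_copies(cs) == 2L))

ph <- simulate_fertility(panel, cs, beta_hom = -0.8, h2 = 0.1,
                         seed = seed + 2L)
vt <- simulate_sequence_variants(panel, cs, n_variants = 200,
                                 seed = seed + 3L)

write_phased_vcf(panel, "results/cohort.vcf")
write_tsv(ph, "results/phenotypes.tsv")
write_tsv(vt$info, "results/variants_info.tsv")
write_tsv(data.frame(id = panel$ids, copies = causal_copies(cs)),
          "results/causal_status.tsv")
writeLines(c(paste("causal_chrom", cs$chromosome, sep = "\t"),
             paste("causal_start", cs$window["start"], sep = "\t"),
             paste("causal_end", cs$window["end"], sep = "\t"),
             paste("allele_string", cs$allele_string, sep = "\t"),
             paste("realized_frequency", cs$realized_frequency, sep = "\t")),
           "results/causal_spec.tsv")
message("wrote results/cohort.vcf (+ phenotype, variant, status tables)")
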