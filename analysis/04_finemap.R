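#!/usr/bin/env Rscript
# Fine-mapping around the top haplotype: carrier-compatibility filter on
# sequence variants within +/- 3 Mb (allele frequency > 0.8 in homozygous
# carriers, 0.4-0.6 in heterozygous carriers, < 0.05 in non-carriers),
# recessive variant association (MAF > 0.05, imputation r2 > 0.4), LD with
# the causal variant, and conditional dissection.

suppressPackageStartupMessages(library(haplorec))

panel <- read_phased_vcf("results/cohort.vcf")
ph <- read_table("results/phenotypes.tsv",
                 c(id = "character", y = "double", cohort = "character"))
spec <- read.delim("results/causal_spec.tsv", header = FALSE,
                   row.names = 1)
cs_call <- list(chrom = spec["causal_chrom", 1],
                start = as.integer(spec["causal_start", 1]),
                end = as.integer(spec["causal_end", 1]),
                allele_string = spec["allele_string", 1])
status <- read_table("results/causal_status.tsv",
                     c(id = "character", copies = "integer"))

# regenerate the cohort's variants (deterministic seed from step 01)
cfg <- sim_config(2000, c("1" = 1500, "2" = 1000), seed = 20260930L)
cs <- embed_recessive_qtl(simulate_panel(cfg), cs_call$chrom,
                          c(cs_call$start, cs_call$end), 0.18, 0.02,
                          seed = 20260931L)
vt <- simulate_sequence_variants(cs$panel, cs, n_variants = 200,
                                 seed = 20260933L)

region <- finemap_region(list(chrom = cs_call$chrom,
                              start_bp = cs$start_bp, end_bp = cs$end_bp))
cmp <- compatibility_filter(vt, status, region)
message(sum(cmp$compatible), " of ", nrow(cmp),
        " regional variants compatible with recessive inheritance ",
        "(designated causal variant compatible: ",
        cmp$compatible[cmp$variant_id == vt$causal_variant_id], ")")
write_tsv(cmp, "results/compatibility.tsv")

va <- variant_recessive_assoc(vt, ph)
best <- va$results[which.min(va$results$p), ]
message(sprintf("recessive variant association: %d tested, top %s p %.3g",
                va$n_tests, best$variant_id, best$p))
write_tsv(va$results, "results/variant_assoc.tsv")

causal_g <- vt$geno[vt$causal_variant_id, ]
r2_top <- ld_r2(causal_g, vt$geno[best$variant_id, ])
message(sprintf("LD between top variant and designated causal: r2 = %.3f",
                r2_top))

cond <- as.numeric(causal_g == 2L)
va_cond <- variant_recessive_assoc(vt, ph, conditional = cond)
res1 <- subset(va_cond$results, variant_id != vt$causal_variant_id)
message(sprintf(
  "conditional on causal variant: min regional p %.3g (threshold %.3g)%s",
  min(res1$p), bonferroni_threshold(va_cond$n_tests),
  if (min(res1$p) > bonferroni_threshold(va_cond$n_tests))
    " -- QTL signal absent" else ""))
write_tsv(va_cond$results, "results/variant_assoc_conditional.tsv")
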