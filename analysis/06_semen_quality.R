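#!/usr/bin/env Rscript
# Semen-quality pipeline: the ejaculate filter cascade with per-step bull
# and ejaculate counts, per-bull mean fresh-semen traits, sperm-morphology
# trait derivation (16 defect categories), and breeding-suitability rates
# for homozygous carriers vs other bulls.

suppressPackageStartupMessages(library(haplorec))

bulls <- sprintf("bull%03d", 1:250)
ej <- simulate_ejaculates(bulls, seed = 61)
flt <- filter_ejaculates(ej)
message("filter cascade:")
for (i in seq_len(nrow(flt$steps)))
  message(sprintf("  %-52s %4d bulls %6d ejaculates",
                  flt$steps$step[i], flt$steps$n_bulls[i],
                  flt$steps$n_ejaculates[i]))
write_tsv(flt$steps, "results/filter_cascade.tsv")

traits <- bull_mean_traits(flt$records)
message(nrow(traits), " bulls with >= 8 surviving ejaculates; mean motility ",
        round(mean(traits$motility_pct), 1), "%")
write_tsv(traits, "results/semen_traits.tsv")

# morphology: first 50 bulls homozygous for the head-shape-raising haplotype
status <- data.frame(id = bulls, copies = c(rep(2L, 50), rep(0L, 200)))
ex <- simulate_morphology(bulls, status, seed = 62)
mo <- derive_morphology_traits(ex)
mo <- mo[mo$n_exams_assessed > 0, ] # proportions undefined otherwise
suit <- breeding_suitability(mo$pct_normal, mo$pct_non_compensatory)
hom <- mo$bull %in% bulls[1:50]
message(sprintf(
  "head-shape anomalies: %.2f%% (homozygous) vs %.2f%% (others), ratio %.2f",
  mean(mo$pct_head_shape[hom]), mean(mo$pct_head_shape[!hom]),
  mean(mo$pct_head_shape[hom]) / mean(mo$pct_head_shape[!hom])))
message(sprintf(
  "passed morphology examination: %.1f%% of homozygous vs %.1f%% of others",
  100 * mean(suit$passed[hom]), 100 * mean(suit$passed[!hom])))
write_tsv(cbind(mo[c("bull", "n_exams", "n_exams_assessed", "pct_normal",
                     "pct_non_compensatory", "pct_head_shape")],
                category = suit$category, passed = suit$passed),
          "results/morphology_traits.tsv")
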