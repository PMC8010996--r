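# Generators: determinism, mosaic structure, causal embedding, phenotype
# scale, sequence variants, insemination and semen record simulation.

test_that("panel simulation is seed-deterministic and mosaic-structured", {
  cfg <- sim_config(40, c("1" = 120, "2" = 80), seed = 5)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$chroms, p2$chroms)
  expect_identical(p1$ids, p2$ids)
  # positions strictly increasing, alleles complete
  for (ch in p1$chroms) {
    expect_true(all(diff(ch$map$pos) > 0))
    expect_false(anyNA(ch$H))
  }
  # single founder: every SNP monomorphic
  mono <- simulate_panel(sim_config(30, c("1" = 50), n_founders = 1, seed = 2))
  expect_true(all(apply(mono$chroms[[1]]$H, 2, function(col)
    length(unique(col)) == 1)))
  # switch_rate = 0: every haplotype equals one founder template exactly
  frozen <- simulate_panel(sim_config(25, c("1" = 60), n_founders = 4,
                                      switch_rate = 0, seed = 7))
  founders <- attr(frozen, "founders")[["1"]]
  H <- frozen$chroms[[1]]$H
  matches_founder <- apply(H, 1, function(h)
    any(colSums(abs(t(founders) - h)) == 0))
  expect_true(all(matches_founder))
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(0, c(10)), "positive")
  expect_error(sim_config(10, c(0)), "positive")
  expect_error(sim_config(10, c(10), switch_rate = 1.5), "switch_rate")
})

test_that("embedded recessive haplotype hits its target frequency with
           Hardy-Weinberg homozygote counts", {
  cfg <- sim_config(1000, c("1" = 200), seed = 11)
  panel <- simulate_panel(cfg)
  cs <- embed_recessive_qtl(panel, "1", c(51, 100), target_freq = 0.18,
                            tolerance = 0.02, seed = 3)
  expect_gte(cs$realized_frequency, 0.16)
  expect_lte(cs$realized_frequency, 0.20)
  expect_equal(nchar(cs$allele_string), 50)
  # realised frequency equals the panel count of the allele string
  call <- list(chrom = "1", start = 51, end = 100,
               allele_string = cs$allele_string)
  hd <- haplotype_dosage(cs$panel, call, mode = "additive")
  expect_equal(sum(hd$copies) / (2 * 1000), cs$realized_frequency)
  # homozygote count within exact binomial bounds of q^2 N
  cs2 <- embed_recessive_qtl(panel, "1", c(51, 100), target_freq = 0.2,
                             tolerance = 0.02, seed = 9)
  n_hom <- sum(causal_copies(cs2) == 2L)
  bounds <- qbinom(c(1e-4, 1 - 1e-4), 1000, 0.2^2)
  expect_gte(n_hom, bounds[1])
  expect_lte(n_hom, bounds[2])
})

test_that("unattainable embedding targets raise errors", {
  panel <- simulate_panel(sim_config(10, c("1" = 30), seed = 1))
  # tolerance 0 and target not a multiple of 1/(2N)
  expect_error(embed_recessive_qtl(panel, "1", c(1, 10), 0.123,
                                   tolerance = 0, seed = 1), "unattainable")
  expect_error(embed_recessive_qtl(panel, "1", c(25, 35), 0.2, seed = 1),
               "window")
})

test_that("fertility phenotype sits on the phenotypic-SD scale and carries
           the homozygote effect", {
  cfg <- sim_config(2000, c("1" = 400), seed = 21)
  panel <- simulate_panel(cfg)
  cs <- embed_recessive_qtl(panel, "1", c(101, 180), 0.18, 0.02, seed = 4)
  # beta = 0, h2 = 0: unit variance within 3 SE (SE of var ~ sqrt(2/(n-1)))
  ph0 <- simulate_fertility(cs$panel, cs, beta_hom = 0, h2 = 0, seed = 8)
  expect_lt(abs(var(ph0$y) - 1), 3 * sqrt(2 / 1999))
  # homozygote contrast near the generating effect
  ph <- simulate_fertility(cs$panel, cs, beta_hom = -0.8, h2 = 0.1, seed = 9)
  hom <- causal_copies(cs) == 2L
  diff <- mean(ph$y[hom]) - mean(ph$y[!hom])
  se <- sqrt(var(ph$y[hom]) / sum(hom) + var(ph$y[!hom]) / sum(!hom))
  expect_lt(abs(diff - (-0.8)), 2 * se)
  expect_error(simulate_fertility(cs$panel, cs, h2 = 1), "h2")
  # determinism
  expect_identical(ph, simulate_fertility(cs$panel, cs, beta_hom = -0.8,
                                          h2 = 0.1, seed = 9))
})

test_that("sequence variants include a perfectly concordant causal variant
           and unlinked variants decay to independence", {
  cfg <- sim_config(800, c("1" = 300, "2" = 100), seed = 31)
  panel <- simulate_panel(cfg)
  cs <- embed_recessive_qtl(panel, "1", c(101, 160), 0.18, 0.02, seed = 5)
  panel <- cs$panel
  vt <- simulate_sequence_variants(panel, cs, n_variants = 120, seed = 6)
  expect_identical(vt, simulate_sequence_variants(panel, cs,
                                                  n_variants = 120, seed = 6))
  copies <- causal_copies(cs)
  cv <- vt$geno[vt$causal_variant_id, ]
  expect_equal(ld_r2(cv, copies), 1)
  expect_true(all(vt$info$impute_r2 >= 0 & vt$info$impute_r2 <= 1))
  # designated causal variant passes the compatibility filter by construction
  status <- data.frame(id = panel$ids, copies = copies)
  cmp <- compatibility_filter(vt, status, finemap_region(cs))
  expect_true(cmp$compatible[cmp$variant_id == vt$causal_variant_id])
  # variants on another chromosome are unlinked
  vt2 <- simulate_sequence_variants(panel, cs, n_variants = 40, seed = 7,
                                    chromosome = "2")
  r2 <- apply(vt2$geno, 1, ld_r2, b = copies)
  expect_true(all(r2 < 0.1, na.rm = TRUE))
})

test_that("insemination outcomes follow the logistic factor model", {
  eff <- setNames(rep(0, 40), paste0("b", 1:40))
  zero_sds <- c(month = 0, parity = 0, price = 0, breed = 0,
                technician = 0, herd = 0)
  rec <- simulate_inseminations(eff, n_per_bull = 250, base_rate = 0.65,
                                factor_sds = zero_sds, seed = 13)
  expect_equal(nrow(rec), 40 * 250)
  se <- sqrt(0.65 * 0.35 / nrow(rec))
  expect_lt(abs(mean(rec$y) - 0.65), 3 * se)
  # a bull with a -1 logit deviation falls below the base rate
  eff2 <- c(low = -1, setNames(rep(0, 9), paste0("b", 1:9)))
  rec2 <- simulate_inseminations(eff2, n_per_bull = 10000, base_rate = 0.65,
                                 factor_sds = zero_sds, seed = 14)
  expect_lt(mean(rec2$y[rec2$bull == "low"]), 0.65)
  expect_error(simulate_inseminations(numeric(0), 10), "empty")
})

test_that("morphology exams are multinomial with a doubled homozygote
           head-shape probability", {
  bulls <- paste0("b", 1:200)
  status <- data.frame(id = bulls,
                       copies = rep(c(2L, 0L), each = 100))
  ex <- simulate_morphology(bulls, status, seed = 17)
  dcols <- paste0("defect_", 0:15)
  expect_true(all(rowSums(ex[dcols]) <= ex$assessed))
  # head-shape enrichment in homozygotes
  prop_head <- ex$defect_0 / ex$assessed
  hom <- ex$bull %in% bulls[1:100]
  ratio <- mean(prop_head[hom]) / mean(prop_head[!hom])
  expect_gte(ratio, 1.6)
  expect_lte(ratio, 2.4)
  # all-defect probabilities zero: every exam fully normal
  clean <- simulate_morphology(bulls[1:5], status[1:5, ],
                               params = list(defect_probs = rep(0, 16)),
                               seed = 18)
  expect_true(all(clean[dcols] == 0))
  expect_error(simulate_morphology(bulls[1:2], status[1:2, ],
                                   params = list(defect_probs = rep(0.1, 3))),
               "16")
})

test_that("ejaculate records populate every filter field deterministically", {
  rec <- simulate_ejaculates(paste0("b", 1:30), seed = 19)
  expect_identical(rec, simulate_ejaculates(paste0("b", 1:30), seed = 19))
  needed <- c("bull", "day", "time_s", "age_days", "interval_days",
              "volume_ml", "mixed", "processed", "motility_pct",
              "head_score", "tail_score", "sperm_per_straw", "sex_sorted",
              "collector", "handler", "genotyped", "concentration")
  expect_true(all(needed %in% names(rec)))
  # first ejaculate per bull has unknown interval
  firsts <- !duplicated(rec$bull)
  expect_true(all(is.na(rec$interval_days[firsts])))
  expect_error(simulate_ejaculates("b1", params = list(volume_sd = -1)),
               "dispersion")
})
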