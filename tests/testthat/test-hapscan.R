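# Window geometry, haplotype tallying, dosage coding, OLS association,
# genome scan behaviour, thresholds and genomic inflation.

test_that("window enumeration drops trailing partial windows", {
  w <- enumerate_windows(c("1" = 110), window_size = 50, step = 15)
  expect_equal(w$start, c(1L, 16L, 31L, 46L, 61L))
  expect_equal(w$end - w$start + 1L, rep(50L, 5))
  expect_equal(nrow(enumerate_windows(c("1" = 50))), 1L)
  expect_equal(nrow(enumerate_windows(c("1" = 49))), 0L)
  # windows never span chromosomes
  w2 <- enumerate_windows(c("1" = 65, "2" = 50))
  expect_equal(nrow(w2), 3L)
  expect_true(all(w2$end[w2$chrom == "2"] <= 50))
})

test_that("window haplotype tallies give exact frequencies and honour the
           frequency filter", {
  # 8 haplotypes over 2 SNPs: "00" x5, "01" x2, "10" x1
  panel <- panel_from_strings(list("1" = c("00", "00", "00", "01",
                                           "00", "01", "00", "10")))
  win <- list(chrom = "1", start = 1, end = 2)
  calls <- window_haplotypes(panel, win, min_freq = 0.01)
  expect_equal(calls$allele_string, c("00", "01", "10"))
  expect_equal(calls$frequency, c(0.625, 0.25, 0.125))
  expect_equal(sum(calls$frequency), 1)
  calls2 <- window_haplotypes(panel, win, min_freq = 0.2)
  expect_setequal(calls2$allele_string, c("00", "01"))
  # n_hom: only individual 1 is 00/00
  expect_equal(calls$n_hom[calls$allele_string == "00"], 1L)
  # monomorphic window
  mono <- panel_from_strings(list("1" = rep("11", 8)))
  cm <- window_haplotypes(mono, list(chrom = "1", start = 1, end = 2))
  expect_equal(cm$frequency, 1)
  expect_equal(cm$n_hom, 4L)
  # pre-filter frequencies always sum to one
  rnd <- simulate_panel(sim_config(30, c("1" = 40), seed = 71))
  cr <- window_haplotypes(rnd, list(chrom = "1", start = 5, end = 14),
                          min_freq = 0)
  expect_equal(sum(cr$frequency), 1)
})

test_that("haplotype dosage codes additive and recessive modes with the
           homozygote eligibility rule", {
  panel <- panel_from_strings(list("1" = c("01", "01",   # hom target
                                           "01", "00",   # het
                                           "00", "00"))) # non-carrier
  call <- list(chrom = "1", start = 1, end = 2, allele_string = "01")
  add <- haplotype_dosage(panel, call, "additive")
  rec <- haplotype_dosage(panel, call, "recessive", min_hom_frac = 0.005)
  expect_equal(add$dosage, c(2, 1, 0))
  expect_equal(rec$dosage, c(1, 0, 0))
  # additive = 2 * recessive + heterozygote indicator
  expect_equal(add$dosage, 2 * rec$dosage + as.numeric(add$copies == 1L))
  # 3 homozygotes of 1000 individuals (0.3%) -> ineligible
  haps <- c(rep("01", 6), rep("00", 2 * 997))
  big <- panel_from_strings(list("1" = haps))
  rec_big <- haplotype_dosage(big, call, "recessive", min_hom_frac = 0.005)
  expect_false(rec_big$eligible)
  expect_null(rec_big$dosage)
  expect_error(fit_association(rnorm(1000), rec_big), "ineligible")
  expect_error(haplotype_dosage(panel, list(chrom = "1", start = 1, end = 2,
                                            allele_string = "011"), "additive"),
               "length")
})

test_that("carrier status equals brute-force string matching on random
           panels and additive identity holds", {
  for (s in 1:5) {
    panel <- simulate_panel(sim_config(25, c("1" = 30), seed = 80 + s))
    calls <- window_haplotypes(panel, list(chrom = "1", start = 3, end = 9),
                               min_freq = 0)
    call <- calls[sample.int(nrow(calls), 1), ]
    st <- carrier_status(panel, call)
    # brute force: compare each haplotype's string
    H <- panel$chroms[[1]]$H
    strs <- apply(H[, 3:9, drop = FALSE], 1, paste, collapse = "")
    bf <- as.integer(strs[seq(1, 50, 2)] == call$allele_string) +
      as.integer(strs[seq(2, 50, 2)] == call$allele_string)
    expect_equal(st$copies, bf)
    expect_equal(sum(st$copies == 2L), call$n_hom)
    add <- haplotype_dosage(panel, call, "additive")
    expect_equal(add$dosage, 2 * as.numeric(bf == 2) + as.numeric(bf == 1))
  }
})

test_that("association fit matches hand normal equations and a pseudo-inverse
           oracle", {
  fit <- fit_association(c(0, 1, 1, 2, 2, 3), c(0, 0, 1, 1, 2, 2))
  expect_equal(fit$beta, 1.0)
  # random instances with covariates vs SVD pseudo-inverse
  set.seed(91)
  for (i in 1:8) {
    n <- sample(20:50, 1)
    C <- matrix(rnorm(n * 3), n)
    d <- rbinom(n, 2, 0.3)
    y <- 0.3 * d + C %*% rnorm(3) + rnorm(n)
    fit <- fit_association(as.numeric(y), as.numeric(d), covariates = C)
    oracle <- pinv_ols(as.numeric(y), cbind(1, C, d))
    expect_equal(fit$beta, oracle$beta, tolerance = 1e-8)
    expect_equal(fit$se, oracle$se, tolerance = 1e-8)
    expect_equal(fit$p_value, oracle$p, tolerance = 1e-8)
  }
  # constant dosage: degenerate, no crash
  degen <- fit_association(rnorm(10), rep(1, 10))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$p_value))
  # perfect fit handled without crash
  perfect <- fit_association(c(0, 0, 1, 1, 2, 2), c(0, 0, 1, 1, 2, 2))
  expect_true(is.na(perfect$p_value) || perfect$p_value >= 0)
  expect_error(fit_association(rnorm(10), rbinom(10, 2, .5),
                               covariates = cbind(1:10, 2 * (1:10))),
               "rank")
})

test_that("the genome scan finds an embedded recessive QTL, is permutation
           invariant, and prefers the recessive coding", {
  cfg <- sim_config(800, c("1" = 700, "2" = 400), seed = 95)
  panel <- simulate_panel(cfg)
  cs <- embed_recessive_qtl(panel, "1", c(301, 380), 0.18, 0.02, seed = 96)
  panel <- cs$panel
  ph <- simulate_fertility(panel, cs, -0.8, 0.1, seed = 97)
  sc <- hap_scan(panel, ph, mode = "recessive", min_freq = 0.01)
  top <- top_hit(sc)
  expect_equal(top$chrom, "1")
  expect_true(top$start <= 380 && top$end >= 301)
  # additive p at the same haplotype is larger
  add_fit <- fit_association(ph, haplotype_dosage(panel, top, "additive"),
                             ids = panel$ids)
  expect_lt(top$p, add_fit$p_value)
  # permutation invariance of the result table
  perm <- sample(800)
  scp <- hap_scan(permute_panel(panel, perm),
                  ph[match(panel$ids[perm], ph$id), ],
                  mode = "recessive", min_freq = 0.01)
  expect_equal(scp$results, sc$results)
  # id mismatch errors
  bad <- ph; bad$id[1] <- "nobody"
  expect_error(hap_scan(panel, bad, mode = "recessive"), "mismatch")
})

test_that("conditioning on the causal recessive status removes the causal
           window from significance", {
  cfg <- sim_config(1000, c("1" = 700), seed = 98)
  panel <- simulate_panel(cfg)
  cs <- embed_recessive_qtl(panel, "1", c(301, 380), 0.18, 0.02, seed = 99)
  panel <- cs$panel
  ph <- simulate_fertility(panel, cs, -0.8, 0.1, seed = 100)
  rec_status <- as.numeric(causal_copies(cs) == 2L)
  sc0 <- hap_scan(panel, ph, mode = "recessive")
  sc1 <- hap_scan(panel, ph, mode = "recessive", conditional = rec_status)
  in_causal <- function(r) r$start <= 380 & r$end >= 301
  p0 <- min(sc0$results$p[in_causal(sc0$results)])
  p1 <- min(sc1$results$p[in_causal(sc1$results)])
  expect_lt(p0, bonferroni_threshold(sc0$n_tests))
  expect_gt(p1, bonferroni_threshold(sc1$n_tests))
  expect_gt(p1 / p0, 100)
})

test_that("Bonferroni thresholds and the inflation factor follow their
           definitions", {
  expect_equal(bonferroni_threshold(10), 0.005)
  expect_error(bonferroni_threshold(0), "positive")
  expect_equal(genomic_lambda(rep(0.5, 7)), 1.0)
  set.seed(101)
  p <- runif(10000)
  expect_gt(genomic_lambda(p), 0.95)
  expect_lt(genomic_lambda(p), 1.05)
  expect_gt(genomic_lambda(p / 2), genomic_lambda(p))
  expect_error(genomic_lambda(numeric(0)), "no p-values")
  expect_error(genomic_lambda(c(0.5, 0)), "0, 1")
})
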