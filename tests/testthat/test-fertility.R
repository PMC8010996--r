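# Mixed-model fertility derivation, standardization, cohort merging and the
# carrier contrasts.

small_records <- function(n = 30, seed = 5) {
  set.seed(seed)
  data.frame(bull = sample(c("b1", "b2", "b3"), n, TRUE),
             month = sample(c("M01", "M02"), n, TRUE),
             parity = sample(c("heifer", "cow"), n, TRUE),
             herd = sample(paste0("H", 1:4), n, TRUE),
             y = rbinom(n, 1, 0.65),
             stringsAsFactors = FALSE)
}

test_that("mixed-model equations reproduce generalized least squares on
           small instances", {
  rec <- small_records()
  fit <- solve_nrr_mme(rec, c(herd = 9, bull = 19))
  X <- model.matrix(~ month + parity, rec)
  bulls <- sort(unique(rec$bull)); herds <- sort(unique(rec$herd))
  Zs <- 1 * outer(rec$bull, bulls, "==")
  Zh <- 1 * outer(rec$herd, herds, "==")
  V <- diag(nrow(rec)) + Zh %*% t(Zh) / 9 + Zs %*% t(Zs) / 19
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% rec$y)
  u_bull <- (1 / 19) * t(Zs) %*% Vi %*% (rec$y - X %*% b)
  u_herd <- (1 / 9) * t(Zh) %*% Vi %*% (rec$y - X %*% b)
  expect_equal(fit$estimates$effect, as.vector(u_bull), tolerance = 1e-8)
  expect_equal(fit$herd_effects$effect, as.vector(u_herd), tolerance = 1e-8)
  expect_equal(unname(fit$fixed_effects), as.vector(b), tolerance = 1e-8)
  expect_equal(fit$estimates$n_inseminations,
               as.integer(table(rec$bull)[bulls]))
})

test_that("bull solutions shrink with the variance ratio and recover
           per-bull means as it vanishes", {
  rec <- small_records()[, c("bull", "y")]
  big <- solve_nrr_mme(rec, c(herd = 9, bull = 1e8))
  expect_lt(max(abs(big$estimates$effect)), 1e-6)
  tiny <- solve_nrr_mme(rec, c(herd = 9, bull = 1e-8))
  pm <- tapply(rec$y, rec$bull, mean)
  expect_equal(tiny$estimates$effect,
               as.vector(pm) - unname(tiny$fixed_effects[1]),
               tolerance = 1e-6)
  expect_error(solve_nrr_mme(rec, c(herd = 9, bull = 0)), "positive")
})

test_that("the mixed model recovers simulated bull fertility rankings", {
  set.seed(141)
  true_eff <- rnorm(80, sd = 0.3)
  names(true_eff) <- sprintf("b%03d", 1:80)
  rec <- simulate_inseminations(true_eff, n_per_bull = 500, seed = 142)
  fit <- solve_nrr_mme(rec)
  est <- fit$estimates
  expect_gt(cor(true_eff[est$bull], est$effect, method = "spearman"), 0.8)
})

test_that("aliased fixed effects are reported by name", {
  rec <- small_records()
  rec$price <- rec$month # perfectly confounded factor
  expect_error(solve_nrr_mme(rec), "aliased.*price|aliased.*month")
})

test_that("standardization hits 100 +/- 12 exactly, idempotently, with the
           5-SD rule strict", {
  set.seed(151)
  est <- data.frame(bull = sprintf("b%02d", 1:50), effect = rnorm(50, 0, 3))
  std <- standardize_fertility(est)
  expect_equal(mean(std$fertility), 100, tolerance = 1e-9)
  expect_equal(sd(std$fertility), 12, tolerance = 1e-9)
  expect_equal(standardize_fertility(std)$fertility, std$fertility)
  # outlier boundary: the -5 SD rule is strict ("more than")
  base <- rnorm(100, 100, 12)
  bound_gap <- function(x) {
    v <- c(base, x)
    x - (mean(v) - 5 * sd(v))
  }
  x5 <- uniroot(bound_gap, c(0, 99), tol = 1e-12)$root # sits at -5 SD
  at_bound <- data.frame(bull = sprintf("c%03d", 1:101),
                         fertility = c(base, x5 + 1e-8))
  expect_true("c101" %in% remove_low_outliers(at_bound, k = 5)$bull)
  below <- at_bound
  below$fertility[101] <- x5 - 1
  expect_message(dropped <- remove_low_outliers(below, k = 5), "c101")
  expect_false("c101" %in% dropped$bull)
  expect_error(standardize_fertility(data.frame(bull = 1:2,
                                                effect = c(1, 1))), "variance")
})

test_that("cohort merging z-standardizes within cohort and rejects
           singletons", {
  est <- data.frame(bull = sprintf("b%02d", 1:40),
                    fertility = c(rnorm(25, 100, 12), rnorm(15, 50, 3)),
                    cohort = rep(c("CH", "DE-AT"), c(25, 15)))
  ph <- merge_cohorts(est)
  for (cn in c("CH", "DE-AT")) {
    expect_equal(mean(ph$y[ph$cohort == cn]), 0, tolerance = 1e-12)
    expect_equal(sd(ph$y[ph$cohort == cn]), 1, tolerance = 1e-12)
  }
  # permuting rows leaves each bull's value unchanged
  perm <- sample(40)
  ph_perm <- merge_cohorts(est[perm, ])
  expect_equal(ph_perm$y[match(ph$id, ph_perm$id)], ph$y)
  single <- merge_cohorts(est[est$cohort == "CH", ])
  expect_equal(single$y, as.vector(scale(est$fertility[1:25])))
  est_bad <- rbind(est, data.frame(bull = "x", fertility = 1, cohort = "XX"))
  expect_error(merge_cohorts(est_bad), "singleton")
})

test_that("homozygous load counts and tallies are conserved", {
  ids <- sprintf("b%02d", 1:10)
  st <- function(copies) data.frame(id = ids, copies = copies)
  statuses <- list(st(c(2, 2, 0, 0, 0, 1, 1, 0, 0, 0)),
                   st(c(2, 0, 2, 0, 0, 0, 0, 1, 0, 0)),
                   st(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0)))
  hl <- homozygous_load(statuses)
  expect_equal(hl$load$load[1:3], c(2L, 1L, 1L))
  expect_equal(sum(hl$tally), 10L)
  expect_equal(unname(hl$tally["0"]), 7L)
  all0 <- homozygous_load(list(st(rep(0, 10))))
  expect_true(all(all0$load$load == 0))
  st_bad <- st(rep(0, 10)); st_bad$id[1] <- "zz"
  expect_error(homozygous_load(list(statuses[[1]], st_bad)), "mismatch")
})

test_that("the Welch contrast matches a permutation oracle and handles
           degenerate groups", {
  ident <- load_contrast_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p_value, 1, tolerance = 1e-12)
  set.seed(161)
  a <- rnorm(12, 1.2); b <- rnorm(12, 0)
  w <- load_contrast_ttest(a, b)
  pooled <- c(a, b)
  perm_stat <- replicate(20000, {
    s <- sample(24)
    mean(pooled[s[1:12]]) - mean(pooled[s[13:24]])
  })
  p_perm <- mean(abs(perm_stat) >= abs(mean(a) - mean(b)))
  expect_lt(abs(w$p_value - p_perm), 0.02)
  expect_error(load_contrast_ttest(c(1, 1), c(2, 2)), "zero variance")
  expect_error(load_contrast_ttest(1, c(1, 2)), ">= 2")
})

test_that("heterozygote vs non-carrier contrast is null for recessive and
           powered for additive architectures", {
  n <- 3736; q <- 0.18
  # recessive: null calibration over replicates
  hits <- 0L
  for (s in 1:200) {
    set.seed(1000 + s)
    copies <- rbinom(n, 2, q)
    y <- -0.8 * (copies == 2) + rnorm(n)
    st <- data.frame(id = as.character(1:n), copies = copies)
    p <- het_vs_noncarrier_test(data.frame(id = st$id, y = y), st)$p_value
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, qbinom(0.0005, 200, 0.05))
  expect_lte(hits, qbinom(0.9995, 200, 0.05))
  # additive architecture (het effect -0.4): powered
  sig <- 0L
  for (s in 1:20) {
    set.seed(2000 + s)
    copies <- rbinom(n, 2, q)
    y <- -0.4 * (copies == 1) - 0.8 * (copies == 2) + rnorm(n)
    st <- data.frame(id = as.character(1:n), copies = copies)
    p <- het_vs_noncarrier_test(data.frame(id = st$id, y = y), st)$p_value
    if (p < 0.05) sig <- sig + 1L
  }
  expect_gte(sig, 18L)
  st_nz <- data.frame(id = c("a", "b"), copies = c(1L, 2L))
  expect_error(het_vs_noncarrier_test(data.frame(id = c("a", "b"), y = 1:2),
                                      st_nz), "non-carriers")
})
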