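# Synthetic breeding-population generator.
#
# The generators emulate the statistical structure the mapping pipeline
# assumes: phased SNP panels with block LD (founder-mosaic copying), a causal
# recessive haplotype at a configurable frequency, a polygenic background
# with given SNP heritability, fertility on the phenotypic-SD scale,
# per-insemination binary non-return outcomes, and ejaculate / sperm
# morphology records. All generators are seed-deterministic.

#' Simulation configuration
#'
#' @param n_individuals number of diploid individuals.
#' @param chrom_sizes integer vector of SNP counts per chromosome; names are
#'   chromosome labels (defaults to `"1"`, `"2"`, ...).
#' @param n_founders number of founder haplotype templates per chromosome.
#' @param switch_rate per-SNP probability that a simulated haplotype switches
#'   to a different founder template; controls LD block length.
#' @param maf_floor lower bound for the founder allele frequency from which
#'   founder templates are drawn (realised panel MAF can drift below it).
#' @param seed integer seed.
#'
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_individuals, chrom_sizes, n_founders = 10,
                       switch_rate = 0.01, maf_floor = 0.05, seed = 1) {
  if (length(n_individuals) != 1 || n_individuals < 1)
    stop("invalid config: n_individuals must be a positive count")
  if (length(chrom_sizes) < 1 || any(chrom_sizes < 1))
    stop("invalid config: chrom_sizes must be positive counts")
  if (n_founders < 1) stop("invalid config: n_founders must be positive")
  if (switch_rate < 0 || switch_rate > 1)
    stop("invalid config: switch_rate must lie in [0, 1]")
  if (maf_floor < 0 || maf_floor >= 0.5)
    stop("invalid config: maf_floor must lie in [0, 0.5)")
  if (is.null(names(chrom_sizes)))
    names(chrom_sizes) <- as.character(seq_along(chrom_sizes))
  structure(list(n_individuals = as.integer(n_individuals),
                 chrom_sizes = stats::setNames(as.integer(chrom_sizes),
                                               names(chrom_sizes)),
                 n_founders = as.integer(n_founders),
                 switch_rate = switch_rate,
                 maf_floor = maf_floor,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a phased haplotype panel
#'
#' Haplotypes are mosaics of founder templates: each simulated haplotype
#' starts by copying a random founder and, with probability `switch_rate` per
#' SNP, switches to a (possibly different) founder template, so nearby SNPs
#' are in linkage disequilibrium. Founder alleles are Bernoulli draws around
#' per-SNP frequencies uniform on `[maf_floor, 1 - maf_floor]`. Physical
#' positions are strictly increasing with random inter-SNP gaps (mean about
#' 3.5 kb, mimicking a dense genotyping array).
#'
#' @param config a [sim_config()].
#' @return A [hap_panel()].
#' @export
simulate_panel <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- config$n_individuals
  n2 <- 2L * n
  F <- config$n_founders
  bases <- c("A", "C", "G", "T")
  chroms <- lapply(names(config$chrom_sizes), function(cn) {
    m <- config$chrom_sizes[[cn]]
    p <- stats::runif(m, config$maf_floor, 1 - config$maf_floor)
    founders <- matrix(stats::rbinom(F * m, 1L, rep(p, each = F)), F, m)
    if (config$switch_rate == 0 || m == 1L) {
      H <- founders[sample.int(F, n2, replace = TRUE), , drop = FALSE]
    } else {
      # one template-switch stream over all haplotypes laid end to end:
      # a forced switch at each haplotype start, Bernoulli(switch_rate)
      # switches elsewhere; each segment copies one founder template
      L <- n2 * m
      k <- stats::rbinom(1L, L, config$switch_rate)
      ev <- sort(unique(c(seq(1, L, by = m), sample(L, k))))
      fid <- rep.int(sample.int(F, length(ev), replace = TRUE),
                     diff(c(ev, L + 1)))
      snp <- rep.int(seq_len(m), n2)
      H <- t(matrix(founders[fid + (snp - 1L) * F], nrow = m))
    }
    pos <- cumsum(sample(500:6500, m, replace = TRUE))
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    map <- data.frame(snp_id = paste0("snp", cn, "_", pos), pos = pos,
                      ref = ref, alt = unname(alt),
                      stringsAsFactors = FALSE)
    list(map = map, H = H, founders = founders)
  })
  names(chroms) <- names(config$chrom_sizes)
  founders <- lapply(chroms, `[[`, "founders")
  chroms <- lapply(chroms, function(ch) ch[c("map", "H")])
  panel <- hap_panel(sprintf("ind%04d", seq_len(n)), chroms, validate = FALSE)
  attr(panel, "founders") <- founders
  panel
}

#' Embed a recessive causal haplotype
#'
#' Designates a causal allele string over a SNP window and rewrites the panel
#' so that the string segregates at (close to) a target haplotype frequency.
#' Carrier haplotypes are drawn independently with probability `target_freq`
#' (redrawn until the realised frequency falls within `tolerance`), so
#' homozygote counts are approximately Hardy-Weinberg; exact HWE is not
#' forced. Non-carrier haplotypes that happen to match the causal string have
#' one allele flipped so the realised frequency is exact.
#'
#' @param panel a [hap_panel()].
#' @param chromosome chromosome name.
#' @param window integer vector `c(start, end)` of SNP indices (1-based,
#'   inclusive) on that chromosome.
#' @param target_freq target haplotype frequency in (0, 1).
#' @param tolerance admissible absolute deviation of the realised frequency.
#' @param seed integer seed.
#'
#' @return A `causal_spec` list: `chromosome`, `window`, `allele_string`,
#'   `realized_frequency`, `carrier` (logical per haplotype row),
#'   `effect_hom_sd` (filled by [simulate_fertility()]), `causal_variant_id`
#'   (filled by [simulate_sequence_variants()]), and the modified `panel`.
#' @export
embed_recessive_qtl <- function(panel, chromosome, window, target_freq,
                                tolerance = 0.02, seed = 1) {
  stopifnot(inherits(panel, "hap_panel"), chromosome %in% names(panel$chroms))
  ch <- panel$chroms[[chromosome]]
  if (window[1] < 1 || window[2] > nrow(ch$map) || window[1] > window[2])
    stop("window does not lie on chromosome '", chromosome, "'")
  if (target_freq <= 0 || target_freq >= 1)
    stop("target_freq must lie in (0, 1)")
  n2 <- nrow(ch$H)
  # counts k/2N achievable within tolerance
  k_lo <- ceiling((target_freq - tolerance) * n2)
  k_hi <- floor((target_freq + tolerance) * n2)
  if (k_lo > k_hi)
    stop("target frequency ", target_freq, " unattainable within tolerance ",
         tolerance, " for ", n2, " haplotypes")
  set.seed(seed)
  cols <- window[1]:window[2]
  # causal allele string: copy one existing haplotype's window, then flip two
  # positions so it is distinguishable from common background haplotypes
  template <- ch$H[sample.int(n2, 1L), cols]
  flip <- sample(seq_along(cols), min(2L, length(cols)))
  template[flip] <- 1L - template[flip]
  for (try in 1:1000) {
    carrier <- stats::runif(n2) < target_freq
    if (sum(carrier) >= k_lo && sum(carrier) <= k_hi) break
    if (try == 1000)
      stop("failed to realise target frequency within tolerance")
  }
  W <- ch$H[, cols, drop = FALSE]
  W[carrier, ] <- rep(template, each = sum(carrier))
  # break accidental matches among non-carriers (flip one allele)
  bg <- which(!carrier)
  acc <- bg[colSums(abs(t(W[bg, , drop = FALSE]) - template)) == 0]
  if (length(acc)) W[acc, flip[1]] <- 1L - template[flip[1]]
  ch$H[, cols] <- W
  panel$chroms[[chromosome]] <- ch
  structure(list(chromosome = chromosome,
                 window = c(start = window[1], end = window[2]),
                 start_bp = ch$map$pos[window[1]],
                 end_bp = ch$map$pos[window[2]],
                 allele_string = paste(template, collapse = ""),
                 realized_frequency = mean(carrier),
                 carrier = carrier,
                 effect_hom_sd = NA_real_,
                 causal_variant_id = NA_character_,
                 panel = panel),
            class = "causal_spec")
}

#' Simulate a fertility phenotype on the phenotypic-SD scale
#'
#' `y = beta_hom * I(homozygous causal) + g + e`, where the polygenic term
#' `g` sums i.i.d. effects over a fraction of panel SNPs scaled to sample
#' variance `h2`, and `e` is Gaussian with variance `1 - h2`, so the marginal
#' variance before the QTL effect is (approximately) 1: the latent scale is
#' phenotypic standard deviations.
#'
#' @param panel a [hap_panel()] (use `causal$panel` so the embedded haplotype
#'   is present).
#' @param causal a `causal_spec` from [embed_recessive_qtl()].
#' @param beta_hom homozygote effect in phenotypic SD units.
#' @param h2 SNP heritability of the background, in `[0, 1)`.
#' @param seed integer seed.
#' @param causal_fraction fraction of SNPs contributing to the polygenic term.
#' @param dosage optional precomputed [dosage_matrix()] of the panel.
#' @return A `data.frame` phenotype table: `id`, `y`, `cohort`.
#' @export
simulate_fertility <- function(panel, causal, beta_hom = -0.8, h2 = 0.1,
                               seed = 1, causal_fraction = 0.1,
                               dosage = NULL) {
  if (h2 >= 1) stop("h2 must be < 1")
  if (h2 < 0) stop("h2 must be >= 0")
  set.seed(seed)
  n <- n_individuals(panel)
  hom <- causal_copies(causal) == 2L
  g <- 0
  if (h2 > 0) {
    D <- if (is.null(dosage)) dosage_matrix(panel) else dosage
    m_c <- max(1L, round(ncol(D) * causal_fraction))
    j <- sort(sample.int(ncol(D), m_c))
    u <- stats::rnorm(m_c)
    g <- as.vector(scale(D[, j, drop = FALSE] %*% u)) * sqrt(h2)
  }
  e <- stats::rnorm(n, sd = sqrt(1 - h2))
  data.frame(id = panel$ids,
             y = beta_hom * as.numeric(hom) + g + e,
             cohort = "sim",
             stringsAsFactors = FALSE)
}

#' Copies of the embedded causal haplotype per individual
#'
#' @param causal a `causal_spec` from [embed_recessive_qtl()].
#' @return integer vector of copy counts (0/1/2), in panel individual order.
#' @export
causal_copies <- function(causal) {
  cr <- causal$carrier
  n <- length(cr) %/% 2L
  as.integer(cr[seq(1L, 2L * n, by = 2L)]) +
    as.integer(cr[seq(2L, 2L * n, by = 2L)])
}

#' Simulate imputed sequence variants around the causal window
#'
#' Places variants within `region_margin` of the embedded causal window. One
#' designated variant carries the alternate allele exactly on causal-carrier
#' haplotypes (dosage r-squared of 1 with the causal haplotype). The other
#' variants are either linked -- carrier indicator flipped per haplotype with
#' an error rate growing with distance, so LD decays -- or unlinked
#' background variants at a random frequency. Each variant carries a
#' simulated imputation quality in `[0, 1]`.
#'
#' @param panel a [hap_panel()].
#' @param causal a `causal_spec`.
#' @param region_margin margin in bp on both sides of the causal window.
#' @param n_variants number of variants to simulate.
#' @param seed integer seed.
#' @param decay_bp LD decay scale in bp for linked variants.
#' @param chromosome chromosome to place variants on; when it differs from
#'   the causal chromosome all variants are unlinked.
#' @return A `variant_table`: list with `info` (data.frame: `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `af`, `impute_r2`), `geno` (integer
#'   matrix variants x individuals, alt dosage 0/1/2), `ids`, and
#'   `causal_variant_id`.
#' @export
simulate_sequence_variants <- function(panel, causal, region_margin = 3e6,
                                       n_variants = 300, seed = 1,
                                       decay_bp = 1e6,
                                       chromosome = causal$chromosome) {
  stopifnot(inherits(causal, "causal_spec"), n_variants >= 1)
  set.seed(seed)
  n <- n_individuals(panel)
  n2 <- 2L * n
  linked_chrom <- identical(chromosome, causal$chromosome)
  lo <- max(1, causal$start_bp - region_margin)
  hi <- causal$end_bp + region_margin
  pos <- sort(sample(seq(lo, hi), n_variants))
  mid <- (causal$start_bp + causal$end_bp) / 2
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_variants, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  i_causal <- if (linked_chrom) which.min(abs(pos - mid)) else NA_integer_
  A <- matrix(0L, n_variants, n2)
  carrier <- causal$carrier
  for (v in seq_len(n_variants)) {
    if (linked_chrom && v == i_causal) {
      A[v, ] <- as.integer(carrier)
    } else if (linked_chrom && stats::runif(1) < 0.5) {
      eps <- 0.5 * (1 - exp(-abs(pos[v] - mid) / decay_bp))
      flip <- stats::runif(n2) < eps
      A[v, ] <- as.integer(xor(carrier, flip))
    } else {
      A[v, ] <- stats::rbinom(n2, 1L, stats::runif(1, 0.02, 0.98))
    }
  }
  idx <- .hap_rows(n)
  geno <- A[, idx$first, drop = FALSE] + A[, idx$second, drop = FALSE]
  storage.mode(geno) <- "integer"
  colnames(geno) <- panel$ids
  impute_r2 <- stats::runif(n_variants, 0.2, 1)
  vid <- paste0(chromosome, ":", pos)
  if (linked_chrom) impute_r2[i_causal] <- 0.99
  info <- data.frame(variant_id = vid, chrom = chromosome, pos = pos,
                     ref = ref, alt = unname(alt),
                     af = rowMeans(A), impute_r2 = impute_r2,
                     stringsAsFactors = FALSE)
  rownames(geno) <- vid
  structure(list(info = info, geno = geno, ids = panel$ids,
                 causal_variant_id = if (linked_chrom) vid[i_causal]
                                     else NA_character_),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$info), "variants x", length(x$ids),
      "individuals; causal:", x$causal_variant_id, "\n")
  invisible(x)
}

#' Simulate first-insemination records
#'
#' Outcomes are Bernoulli with success probability
#' `logistic(logit(base_rate) + bull + herd + fixed-factor effects)`; a
#' success (1) means no re-insemination was recorded within 56 days
#' (non-return). Factor-level effects are drawn Gaussian on the logit scale
#' with the standard deviations in `factor_sds`.
#'
#' @param bull_effects named numeric vector of per-bull deviations on the
#'   logit scale; names are bull ids.
#' @param n_per_bull integer count of inseminations per bull (recycled).
#' @param base_rate baseline 56-day non-return probability.
#' @param factor_sds named list/vector of logit-scale effect SDs with entries
#'   `month`, `parity`, `price`, `breed`, `technician`, `herd`.
#' @param n_herds,n_technicians numbers of herd and technician levels.
#' @param seed integer seed.
#' @return A `data.frame` of insemination records: `bull`, `month`, `parity`,
#'   `price`, `breed_comb`, `technician`, `herd`, `y`.
#' @export
simulate_inseminations <- function(bull_effects, n_per_bull,
                                   base_rate = 0.65,
                                   factor_sds = c(month = 0.05, parity = 0.05,
                                                  price = 0.03, breed = 0.03,
                                                  technician = 0.05,
                                                  herd = 0.1),
                                   n_herds = 100, n_technicians = 20,
                                   seed = 1) {
  if (length(bull_effects) == 0) stop("bull_effects must not be empty")
  if (is.null(names(bull_effects)))
    names(bull_effects) <- sprintf("bull%03d", seq_along(bull_effects))
  if (base_rate <= 0 || base_rate >= 1) stop("base_rate must lie in (0, 1)")
  fs <- as.list(factor_sds)
  needed <- c("month", "parity", "price", "breed", "technician", "herd")
  if (!all(needed %in% names(fs)))
    stop("factor_sds must name: ", paste(needed, collapse = ", "))
  set.seed(seed)
  n_per_bull <- rep_len(n_per_bull, length(bull_effects))
  eff <- list(month = stats::rnorm(12, sd = fs$month),
              parity = stats::rnorm(2, sd = fs$parity),
              price = stats::rnorm(3, sd = fs$price),
              breed = stats::rnorm(4, sd = fs$breed),
              technician = stats::rnorm(n_technicians, sd = fs$technician),
              herd = stats::rnorm(n_herds, sd = fs$herd))
  nrec <- sum(n_per_bull)
  bull <- rep(names(bull_effects), n_per_bull)
  mo <- sample.int(12, nrec, replace = TRUE)
  pa <- sample.int(2, nrec, replace = TRUE)
  pr <- sample.int(3, nrec, replace = TRUE)
  br <- sample.int(4, nrec, replace = TRUE)
  te <- sample.int(n_technicians, nrec, replace = TRUE)
  he <- sample.int(n_herds, nrec, replace = TRUE)
  eta <- stats::qlogis(base_rate) + rep(bull_effects, n_per_bull) +
    eff$month[mo] + eff$parity[pa] + eff$price[pr] + eff$breed[br] +
    eff$technician[te] + eff$herd[he]
  data.frame(bull = bull,
             month = sprintf("M%02d", mo),
             parity = c("heifer", "cow")[pa],
             price = paste0("P", pr),
             breed_comb = paste0("B", br),
             technician = paste0("T", te),
             herd = paste0("H", he),
             y = stats::rbinom(nrec, 1L, stats::plogis(eta)),
             stringsAsFactors = FALSE)
}

#' Simulate ejaculate records with quality-filter fields
#'
#' Populates every field the ejaculate filter cascade inspects: age at
#' collection, interval to the preceding ejaculate (absent for a bull's first
#' collection), volume, mixed/processed flags, within-day collection order,
#' motility, head/tail anomaly scores, sperm per straw, sex-sorting,
#' collector/handler, genotype availability and concentration. Default rates
#' leave a realistic share of records failing each filter.
#'
#' @param bulls character vector of bull ids.
#' @param params named list overriding defaults (see function body).
#' @param seed integer seed.
#' @return A `data.frame`, one row per ejaculate.
#' @export
simulate_ejaculates <- function(bulls, params = list(), seed = 1) {
  p <- utils::modifyList(list(
    n_mean = 30, volume_mean = 4.5, volume_sd = 1.5,
    conc_mean = 1200, conc_sd = 300, motility_mean = 82, motility_sd = 8,
    straw_mean = 21, straw_sd = 3,
    p_volume_missing = 0.02, p_mixed = 0.05, p_unprocessed = 0.10,
    p_same_day = 0.05, p_bad_score = 0.01, p_sorted = 0.02,
    p_collector_missing = 0.03, p_genotyped = 0.9,
    birth_age_min = 330, birth_age_max = 500, interval_mean = 5
  ), params)
  bad <- vapply(p[grep("_sd$", names(p))], function(v) v < 0, logical(1))
  if (any(bad)) stop("negative dispersion parameter")
  set.seed(seed)
  rows <- lapply(bulls, function(b) {
    k <- max(1L, stats::rpois(1, p$n_mean))
    gaps <- 1L + stats::rpois(k, p$interval_mean - 1)
    same <- stats::runif(k) < p$p_same_day
    gaps[same] <- 0L
    gaps[1] <- 0L
    day <- cumsum(gaps)
    age0 <- sample(p$birth_age_min:p$birth_age_max, 1L)
    data.frame(
      bull = b,
      day = day,
      time_s = sample.int(86400L, k, replace = TRUE),
      age_days = age0 + day,
      volume_ml = ifelse(stats::runif(k) < p$p_volume_missing, NA_real_,
                         pmax(0.5, stats::rnorm(k, p$volume_mean, p$volume_sd))),
      mixed = stats::runif(k) < p$p_mixed,
      processed = stats::runif(k) >= p$p_unprocessed,
      motility_pct = pmin(100, pmax(0, stats::rnorm(k, p$motility_mean,
                                                    p$motility_sd))),
      head_score = ifelse(stats::runif(k) < p$p_bad_score, 9L,
                          sample(0:3, k, replace = TRUE, prob = c(.7, .2, .07, .03))),
      tail_score = sample(0:3, k, replace = TRUE, prob = c(.7, .2, .07, .03)),
      sperm_per_straw = pmax(5, stats::rnorm(k, p$straw_mean, p$straw_sd)),
      sex_sorted = stats::runif(k) < p$p_sorted,
      collector = ifelse(stats::runif(k) < p$p_collector_missing,
                         NA_character_, paste0("C", sample.int(8, k, TRUE))),
      handler = paste0("H", sample.int(8, k, replace = TRUE)),
      genotyped = stats::runif(1) < p$p_genotyped,
      concentration = pmax(100, stats::rnorm(k, p$conc_mean, p$conc_sd)),
      stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  # interval to preceding ejaculate per bull (days); NA for the first
  rec <- rec[order(rec$bull, rec$day, rec$time_s), ]
  rec$interval_days <- ave(rec$day, rec$bull,
                           FUN = function(d) c(NA, diff(d)))
  rownames(rec) <- NULL
  rec
}

#' Simulate sperm-morphology examinations
#'
#' Each examination classifies `assessed` spermatozoa into a normal class and
#' the 16 defect categories used in the breeding soundness examination via a
#' multinomial draw (only the most severe defect per sperm is recorded, hence
#' the categories are exclusive). Homozygous carriers of the causal haplotype
#' draw the head-shape defect (category 0) with `hom_head_multiplier` times
#' the base probability, emulating a recessive head-shape anomaly.
#'
#' @param bulls character vector of bull ids.
#' @param carrier_status data.frame with columns `id`, `copies` (0/1/2).
#' @param params named list overriding defaults: `defect_probs` (length-16
#'   base category probabilities), `hom_head_multiplier`,
#'   `assessed_range`, `p_fail_exam` (probability of a 50-sperm exam),
#'   `exams_mean`.
#' @param seed integer seed.
#' @return A `data.frame`: `bull`, `exam`, `assessed`, `defect_0` ...
#'   `defect_15`.
#' @export
simulate_morphology <- function(bulls, carrier_status, params = list(),
                                seed = 1) {
  p <- utils::modifyList(list(
    defect_probs = c(0.054, 0.010, 0.005, 0.010, 0.020, 0.020, 0.020, 0.010,
                     0.020, 0.010, 0.010, 0.010, 0.030, 0.030, 0.010, 0.005),
    hom_head_multiplier = 2,
    assessed_range = c(150L, 200L),
    p_fail_exam = 0.03,
    exams_mean = 2.5
  ), params)
  if (length(p$defect_probs) != 16 || any(p$defect_probs < 0))
    stop("defect_probs must be 16 non-negative probabilities")
  set.seed(seed)
  copies <- stats::setNames(carrier_status$copies, carrier_status$id)
  rows <- lapply(bulls, function(b) {
    k <- max(1L, stats::rpois(1, p$exams_mean))
    pr <- p$defect_probs
    if (!is.na(copies[b]) && copies[b] == 2L)
      pr[1] <- min(1, pr[1] * p$hom_head_multiplier)
    probs <- c(max(0, 1 - sum(pr)), pr)
    out <- lapply(seq_len(k), function(e) {
      tot <- if (stats::runif(1) < p$p_fail_exam) 50L
             else sample(p$assessed_range[1]:p$assessed_range[2], 1L)
      cnt <- as.vector(stats::rmultinom(1, tot, probs))
      d <- as.list(cnt[-1])
      names(d) <- paste0("defect_", 0:15)
      cbind(data.frame(bull = b, exam = paste0(b, "_e", e), assessed = tot,
                       stringsAsFactors = FALSE),
            as.data.frame(d))
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
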