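---
title: "Mapping recessive fertility loci from phased haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive fertility loci from phased haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Male fertility in dairy cattle is measured exceptionally well: each
artificial-insemination bull sires hundreds to thousands of first
inseminations whose 56-day non-return outcome (NRR56, whether the cow was
re-inseminated within 56 days) is recorded, and every ejaculate entering a
semen collection centre is scored for volume, concentration, motility and
sperm morphology. Loci acting *recessively* on fertility are easy to miss
with the standard additive association test, because heterozygous carriers
are unaffected and homozygotes are rare (at haplotype frequency $q = 0.18$,
only $q^2 \approx 3\%$ of bulls are affected). `haplorec` implements the
complete mapping workflow for this setting: a sliding-window haplotype scan
under additive and recessive inheritance, conditional dissection of known
loci, carrier-compatibility fine-mapping of sequence variants, the
mixed-model derivation of the fertility phenotype, and the semen-quality
trait construction — together with a synthetic breeding-population
generator that lets the whole pipeline be exercised and power-checked
without access to (restricted) production data.

## The association model

Phased genotypes are cut into windows of 50 contiguous SNPs advanced in
steps of 15 SNPs along each chromosome; trailing partial windows are
dropped so that haplotype complexity is comparable across windows. Within a
window, every allele string with frequency strictly above 1% among the $2N$
phased haplotypes is tested one-vs-rest with the linear model

$$ y = \mu + \sum_{j=1}^{10} a_j \mathrm{PC}_j + b\,\mathrm{HT} + c\,k + e, $$

where $y$ is the fertility phenotype in phenotypic-SD units,
$\mathrm{PC}_j$ are the top principal components of the genomic
relationship matrix (population-structure correction with fixed covariates,
not a mixed model), $\mathrm{HT}$ is the haplotype dosage and $k$ an
optional conditional covariate such as the recessively coded status at an
already-known QTL. Under the additive coding $\mathrm{HT} \in \{0,1,2\}$
counts haplotype copies; under the recessive coding it is the indicator of
homozygosity, and the test is only performed when the haplotype is observed
in the homozygous state in at least 0.5% of individuals (rarer homozygote
classes cannot support the contrast). Inference is ordinary least squares
with a two-sided $t$ test on $b$ at $n - p$ residual degrees of freedom;
internally the scan residualises $y$ and all window dosages on the
covariates once per scan (Frisch–Waugh–Lovell), which is algebraically
identical to the full regression and is what makes genome-wide scans cheap.
Significance uses Bonferroni correction at the *realised* test count of the
scan — each eligible haplotype contributes one test — and calibration is
summarised by the genomic inflation factor
$\lambda = \mathrm{median}\{\chi^2_1(1-p)\} / \mathrm{qchisq}(0.5, 1)$.

Choices worth making explicit:

* **Frequency is haplotype (allele) frequency** over $2N$ phased
  haplotypes, not diplotype frequency.
* **The 1% frequency filter and the 0.5% homozygote rule are strict
  (`>`)**, read literally from "above"/"at least" conventions; the MAF
  retention rule for the GRM ("greater than 0.5%") is likewise strict.
* **Top-hit tie-breaking**: smallest $p$, then highest frequency, then
  lexicographic allele string.
* **Degenerate tests** (monomorphic windows, constant dosage after
  projection, perfect fits) are marked and skipped rather than reported
  with meaningless $p$ values.

## Relatedness and heritability checking

The genomic relationship matrix is VanRaden method 1,
$G = ZZ^\top / \sum_j 2 p_j (1 - p_j)$, computed from allele-frequency
centred dosages after excluding SNPs with MAF $\le$ 0.005 — the same
construction the standard tooling (plink) uses, so principal components of
$G$ play the role they do in practice. `top_pcs()` offers an exact
symmetric eigen-decomposition and a randomized (Halko-style) subspace
iteration; the randomized method is the default for the large simulated
cohorts, matching the randomized PCA used by large-scale tools, and is
tested against the exact decomposition on matrices with well-separated
spectra.

Variance-component estimation by REML is deliberately out of scope (it
belongs to external tooling); instead `he_regression()` provides a
Haseman–Elston check used to validate the generator: regressing phenotype
cross-products $y_i y_j$ on $G_{ij}$ estimates the SNP heritability.
Because pairs sharing an individual are correlated, the naive OLS standard
error is anti-conservative; the reported standard error is a
leave-one-individual-out jackknife computed in closed form, which restores
near-nominal coverage of the generating $h^2$ in the calibration tests.

## Fine-mapping by carrier compatibility

Given the top haplotype, carrier status (0/1/2 copies, exact string match)
splits the cohort into three classes. A sequence variant within $\pm$3 Mb
of the haplotype is *compatible* with recessive inheritance of the
haplotype when, for at least one allele orientation, its allele frequency
is above 0.8 in homozygous carriers, within [0.4, 0.6] in heterozygous
carriers, and below 0.05 in non-carriers. Both orientations are tested
because the haplotype-linked allele may be reference or alternate; boundary
semantics are strict for the outer thresholds and inclusive for the
heterozygote band, read literally from "greater than / between / less
than". Classes that are empty give undefined frequencies and mark the
variant *indeterminate*, never compatible. An optional `slack` parameter
relaxes all thresholds symmetrically for genotyping error; the default is 0
because no error allowance is published, which is also why published
compatible-variant counts are not reproducible targets. Variant association
testing mirrors the haplotype machinery with recessive coding keyed to the
minor allele, after excluding variants with MAF $\le$ 0.05 or imputation
quality $\le$ 0.4.

## The fertility phenotype

The 56-day non-return outcome of each first insemination (1 = no
re-insemination recorded, the fertility-positive reading of an ambiguous
convention) is modelled linearly, in the tradition of Schaeffer-style sire
evaluations, with fixed insemination month, parity, semen price class,
breed combination and technician, and random herd and bull effects. The
mixed-model equations are assembled sparsely and solved directly; bull
solutions are deviations from the average non-return rate. Variance ratios
$\sigma^2_e/\sigma^2_u$ are user configuration (none are published); the
defaults, 9 for herd and 19 for bull, encode small random-effect variances
and are deliberately arbitrary. The synthetic generator produces outcomes
from a *logistic* latent model while the evaluation model is linear — the
recovery tests tolerate this intentional mismatch, as the linear evaluation
does in practice. Bull solutions are standardized to $100 \pm 12$;
phenotypic outliers more than 5 SD *below* the mean (strictly) are removed;
cohorts measured on different scales are z-standardized within cohort
before being merged into one mapping phenotype. The homozygous-load
analysis counts, per bull, the top haplotypes carried homozygously, and the
load contrast uses Welch's unequal-variance two-tailed $t$ test (the
published analysis says only "two-tailed t-test"; Welch is the safer
default). The heterozygote-vs-non-carrier contrast excludes homozygotes and
tests the heterozygote indicator with the same covariates as the scan —
under true recessivity it must be null, and the tests check exactly that.

## Semen quality and sperm morphology

Ejaculate records pass a fixed filter cascade (collection age strictly
between 400 and 1000 days; interval to the preceding ejaculate known, which
drops each bull's first ejaculate; volume recorded; unmixed; processed;
inter-ejaculate interval at most 8 days; first ejaculate per day, earliest
collection time with ties by record order; motility at least 70%; integer
0–3 anomaly scores — the reading of "score plausible"; at least 15 million
sperm per straw and not sex-sorted; collector and handler known; genotype
available; finally at least 8 surviving ejaculates per bull), with bull and
ejaculate counts reported after every step. Morphology examinations
classify 150–200 spermatozoa (evident failures: 50) into a normal class and
16 exclusive defect categories — three non-compensatory (abnormal head
shape, vacuoles, condensed DNA) and thirteen compensatory, cross-classified
as major or minor; only the most severe defect per sperm is recorded, so
percentages add to 100 exactly. Exams with fewer than 150 assessed sperm
are excluded from the proportion traits but still counted in the
examination-number trait. Breeding suitability: at least 75% normal sperm
with at most 20% non-compensatory defects is suitable; 65 to just under 75%
normal (implemented as $[65, 75)$ on the continuous percentage) with at
most 20% non-compensatory is processed with compensation (more sperm per
dose); the examination is "passed" at 65%/20%.

## What the generator emulates — and what it does not

The synthetic-data module creates the statistical structure the analysis
assumes, with founder-mosaic copying instead of coalescent simulation:
every haplotype copies one of `n_founders` templates and switches templates
with probability `switch_rate` per SNP, producing block LD whose scale is
`1/switch_rate` SNPs. Defaults — 10 founders, switch rate 0.01, founder
allele frequencies uniform on [0.05, 0.95] — give windows a realistic
handful of common haplotypes, so that common haplotypes reach the 0.5%
homozygote eligibility rule as they do on real cattle arrays with strong
LD. The causal recessive haplotype is embedded by drawing carrier
haplotypes independently with probability `target_freq` (redrawn until the
realised frequency is within tolerance; exact Hardy–Weinberg is *not*
forced) and rewriting the window; the embedded segment spans more SNPs than
one scan window (80 by default in the study driver) so at least one window
lies fully inside it regardless of the window grid — mimicking the long
shared segment that LD creates around a real causal allele. Fertility is
simulated at unit variance ("phenotypic SD" scale): homozygote effect
$\beta_{hom}$ (default $-0.8$ SD), a polygenic term from a 10% causal SNP
fraction scaled to variance $h^2$ (default 0.10 — the published variance
fraction is stated once as "0.10 ± 0.02%" and once as 10%; the proportion
reading 0.10 is adopted), Gaussian residual of variance $1 - h^2$. The
$100 \pm 12$ scale exists only in `standardize_fertility()`.

Sequence variants place one designated variant in perfect concordance with
the carrier haplotypes ($r^2 = 1$), linked variants whose per-haplotype
copying error grows with distance (LD decay scale 1 Mb), and unlinked
background variants; imputation quality is uniform on [0.2, 1] with the
designated variant at 0.99. Insemination outcomes are Bernoulli around a
65% base non-return rate with Gaussian logit-scale factor effects;
ejaculate and morphology records populate every field the filter cascade
and trait derivation inspect, with homozygous carriers drawing the
head-shape defect at twice the base probability.

The generator does **not** emulate cattle demography or pedigree structure,
sex chromosomes, genotyping error, phasing/imputation error, selection, or
the spatial herd structure of real insemination data. Consequently, passing
power and calibration tests here demonstrates that the *methods* behave as
intended under their own assumptions — not that real data meet those
assumptions.

## Problem sizes, numerical choices, defaults

* The power study (`simulate_mapping_study()`) uses the mapping-cohort
  size $N = 3736$, causal frequency 0.18, homozygote effect $-0.8$ SD and
  $h^2 = 0.10$, on a 10,000-SNP panel over five chromosomes — about 660
  windows and a few thousand eligible recessive tests per scan, which a
  20-replicate study completes in minutes on one CPU while leaving the
  per-window haplotype structure (the thing being tested) at full scale.
* Null calibration runs at $N = 1000$, $M = 5000$; Haseman–Elston
  calibration at $N = 2000$, $M = 2500$, twenty replicate cohorts each.
* Window haplotypes are keyed by exact 50-bit dyadic codes (windows of at
  most 50 SNPs fit the double mantissa; wider windows fall back to chunked
  string keys), so tallying is a matrix product plus `match()`.
* The scan's batched OLS residualises once per scan; degenerate columns
  are detected by a scaled sum-of-squares threshold ($n \times 10^{-12}$).
* Randomized PCA uses an oversampled sketch (10 extra vectors) and 4 power
  iterations with a deterministic seed derived from the GRM dimensions, so
  identical inputs give identical components.
* The published genomic-inflation formula is typographically garbled in
  its source; the standard median-$\chi^2_1$ definition is used.
* Published Bonferroni thresholds reproduce as $0.05/186{,}278 =
  2.68\times10^{-7}$ and $0.05/12{,}861{,}528 = 3.89\times10^{-9}$ (the
  source prints $3.88\times10^{-9}$, a truncation of the same quotient).

## Known limitations

* The scan corrects structure with fixed principal components only; a
  mixed-model scan is out of scope, so strong cryptic relatedness beyond
  what PCs capture would inflate the tests.
* Polygenic background is *true* signal: scans on phenotypes with
  $h^2 > 0$ legitimately show $\lambda > 1$; calibration claims are made
  under the null generator ($\beta_{hom} = 0$, $h^2 = 0$).
* The linear model on 0/1 outcomes is the field's convention for
  non-return evaluation, not an efficient binary-data model; variance
  ratios are configuration, not estimates.
* Compatible-variant *counts* depend on an unpublished genotyping-error
  allowance and are not reproducible; only the behaviour of the filter is.
* Biallelic SNPs only; no BGEN/PLINK-bed input; no strand flipping
  (single-panel imputed data are assumed consistent).
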