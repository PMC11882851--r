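---
title: "Maternal polygenic risk scores from low-coverage prenatal cfDNA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maternal polygenic risk scores from low-coverage prenatal cfDNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Non-invasive prenatal testing (NIPT) sequences cell-free DNA (cfDNA) from
the plasma of pregnant women at very shallow depth (around 0.25x genome-wide)
to screen for fetal aneuploidy. The same reads carry the mother's genotype —
diluted two ways: the coverage is far too low to call genotypes directly, and
a fraction of the fragments (the fetal fraction, typically 3–20%) come from
the placenta and carry fetal, not maternal, alleles. `niptprs` implements and
stress-tests the pipeline that nevertheless recovers maternal polygenic risk
scores (PRS) from such data: forced genotype likelihoods at a panel of known
sites, haplotype-copying imputation of maternal dosages, and weighted-sum
scoring — plus the simulation machinery needed to quantify how coverage and
fetal fraction degrade the scores.

Everything runs on synthetic data generated by the package itself; no
external files are required. The simulators are first-class, tested code, and
every experiment is reproducible from a single master seed.

## The simulation model

### Reference panel

Phased reference haplotypes are generated by a *copying-mosaic* process on a
single pseudo-chromosome: after `n_founders` independent founder haplotypes
(allele drawn per site around a uniform base frequency), each new haplotype
copies segments from the previously generated ones, switching template at
`mosaic_switch_rate` per centimorgan (default 1/cM) and miscopying alleles at
`mutation_rate` (default 0.002). Sites below the minor-allele-frequency floor
(default 1%) are dropped. This produces linkage disequilibrium that decays
with genetic distance — the only feature haplotype-copying imputation needs —
without the machinery of a coalescent simulator. A VCF import/export path
(`write_panel_vcf()` / `read_panel_vcf()`) allows substituting externally
simulated or real phased haplotypes.

Default scale: 200 haplotypes over 5,000 candidate sites on 20 Mb with a
uniform 1 cM/Mb map. At these sizes every experiment below runs in minutes on
one core; the diploid HMM cost grows as (copying-set size)² × sites.

### Study subjects

A mother is drawn as a *low-switch* mosaic of the panel (0.5 switches/cM,
miscopy 1e-4), so she is related to, but not present in, the panel. This
mirrors a clinical population drawn from the same ancestry groups as the
imputation reference, and it is what makes the high-coverage arm of the
coverage study nearly perfect — the information is in the panel; only the
data to find it varies. The fetus inherits one recombinant maternal haplotype
(crossovers Poisson in the genetic map length) plus an independent
panel-mosaic paternal haplotype, so every pair is Mendelian-consistent by
construction.

### cfDNA pileups

Per-site read counts are Poisson(coverage); each read is fetal with
probability equal to the fetal fraction; its allele comes from a uniformly
chosen haplotype of its origin individual and flips with the error rate
(default 0.005); its fragment length is a truncated normal — mean 166 bp for
maternal reads, 143 bp for fetal reads, sd 15 bp, bounds 50–400 bp. The two
length means are the well-established cfDNA size peaks; the sd and bounds are
free parameters. Reads are independent across sites: at 0.25x with panel
sites kilobases apart, one fragment essentially never covers two sites, and
all inference consumes per-site pileups only. The origin tag is simulation
truth and is never visible to inference (the TSV writer excludes it by
default).

`filter_by_length()` implements the in-silico removal of short fragments
(intended to deplete fetal reads), and `downsample_pileups()` the binomial
thinning used to emulate FASTQ down-sampling.

## Inference

### Forced genotype likelihoods

At every panel site — including zero-depth sites — the genotype likelihood
for g ∈ {0, 1, 2} is the product over reads of
P(read = alt | g) = (g/2)(1−ε) + (1−g/2)ε, a symmetric single-parameter
binomial model (the pileup abstraction carries no base qualities).
Likelihoods are stored normalized per site; the HMM is invariant to per-site
scaling. Zero-depth sites get (1/3, 1/3, 1/3).

### Diploid Li–Stephens imputation

The maternal genotype is imputed with a haplotype-copying hidden Markov
model: the hidden state at each site is an ordered pair of reference
haplotypes, each of which switches template between adjacent sites with
probability `1 − exp(−n_eff·Δcm/K)`, landing uniformly on any of the K
haplotypes in the copying set. Emissions integrate the genotype likelihood
against the copied alleles with a per-allele miscopy probability μ (default
1e-3). A single exact forward–backward pass (no pre-phasing, no EM) yields
per-site posterior genotype distributions; the dosage is the posterior mean
allele count. The forward–backward is verified in the test suite against
exhaustive path enumeration on small instances (K ≤ 3, L ≤ 5, tolerance
1e-10).

Fetal reads are deliberately *not* modelled: they are the confounder whose
effect the experiments measure.

Two implementation choices matter for accuracy and runtime:

* **Copying-set collapse.** The K²-state pass over the full 200-haplotype
  panel costs 40,000 states × 5,000 sites; the default collapses the panel
  to 60 haplotypes chosen by an allele-sharing score against the observed
  genotype evidence. Because a target switches templates along the
  chromosome, the score is computed within 2-cM windows and each window
  keeps its best candidates (remaining slots filled by the genome-wide
  ranking); a purely global ranking loses locally relevant templates and
  costs noticeably in dosage accuracy. Full-panel mode is available via
  `subset_size = Inf`.
* **`n_eff` calibration.** `n_eff/K` is the expected number of template
  switches per centimorgan. The default `n_eff = 30` with K = 60 equals the
  0.5 switches/cM at which simulated subjects copy from the panel, and was
  calibrated so that imputation from 1.0x pure-maternal coverage reaches
  dosage r² above 0.99 on the default simulations (a statement about this
  simulator, not about real data). Accuracy is insensitive to `n_eff` over
  an order of magnitude.

At the defaults, the remaining dosage error is data-limited, not
model-limited: it concentrates at template-switch boundaries that fall
between informative reads, and at sites where a single sequencing error
read flips a locally under-determined template choice. Both are visible in
the posterior (reduced per-site confidence), and both shrink with coverage.

### PRS

A score is the weighted sum of orientation-corrected dosages over the
markers of a scoring panel, divided by a scalar M:
PRS = Σᵢ βᵢ·gᵢ / M. Markers are matched to sites by position plus unordered
allele pair; when the effect allele is the site's reference allele the
dosage enters as 2 − d. M defaults to the matched non-missing marker count
(per-marker averaging, PLINK's average mode). The choice of M cannot affect
any correlation reported here — correlations are invariant under common
affine rescaling of scores, an invariance asserted in the test suite — but
it is fixed for reproducibility. Markers with missing dosage (possible only
in hard-called arms) are dropped from both the sum and M by default; a
mean-imputation policy (2 × allele frequency) is available.

PGS Catalog harmonized scoring files are read and written
(`load_scoring_file()` / `write_scoring_file()`); synthetic panels draw
markers uniformly from the simulated sites with weights ~ Normal(0, 0.1²)
and a random effect-allele orientation. Strand-flip resolution is out of
scope: synthetic data has no strand ambiguity, and real-data use would need
it added.

## The three experiments

* **Coverage** (`run_coverage_experiment()`): 10 pure-maternal subjects per
  cohort, pileups at 0.2x and 1.0x (imputed) and 30x (hard-called,
  non-imputed, missing below depth 4); PRS per arm; the three pairwise
  Pearson correlations pooled over 20 replicate cohorts (200 paired scores).
* **Mixture** (`run_mixture_experiment()`): 40 mother–fetus pairs, 0.25x
  pileups at fetal fractions 0, 5, 10 and 15% with 7 independent replicates
  per condition; per-sample mean PRS per arm; Pearson (and Spearman)
  correlation of each arm against the 0% arm, plus bias and spread of the
  per-sample deviations. The 0% arm is the baseline because the mixture
  study asks what the fetus adds, holding coverage fixed.
* **Cohort** (`run_cohort_experiment()`): 450 samples with per-sample fetal
  fraction uniform on 3–20% (the clinically typical range; the source study
  reports fetal fraction only as a stratifying variable). cfDNA arm = 0.25x
  mixture, imputed; gDNA arm = 15x pure maternal, hard-called (at 15x hard
  calls are essentially exact, and this mirrors the non-imputed
  high-coverage arm of the coverage study). Reported: per-panel correlations
  for scoring panels of 50/500/2,000/5,000 markers, correlations within
  low/high fetal-fraction strata split at the cohort median, and the
  high-risk misclassification rate at the top-5% cutoff — each vector flags
  its top ceiling(0.05·n) samples (stable ties), and the rate is the
  fraction of samples whose label differs between arms. The gDNA arm is the
  baseline here, as in the clinical comparison.

The panel-size axis (50–5,000 markers) is a desk-scale stand-in for the
"<50 to >1M" range of real catalog panels; trends across it, not absolute
sizes, are the meaningful output.

Every experiment derives all stage seeds from one master seed
(`derive_seed()`), embeds its configuration in the returned report, and is
bit-reproducible from (config, seed). `write_report()` emits TSV tables and
a JSON summary; a thin command-line front end (`inst/cli/niptprs`) exposes
the simulators and experiments as subcommands.

## What the synthetic study does and does not show

The generator reproduces the *mechanisms* that matter for this pipeline —
LD-driven imputability, Poisson coverage, maternal/fetal mixture at a known
fraction, origin-specific fragment lengths, panel-relatedness of subjects —
on one 20 cM pseudo-chromosome. It does not emulate GC or mappability bias,
duplicate reads, multi-chromosome genomes, population structure, or real
catalog weight distributions. Two consequences deserve emphasis:

* Because all markers sit on one short chromosome, imputation errors are
  block-correlated across markers within a subject. PRS errors therefore
  average out over independent genomic blocks (of which there are ~10 here),
  not over the full marker count, and simulated PRS correlations at a given
  dosage accuracy run *lower* than genome-wide analyses at the same
  accuracy. The fetal-fraction and coverage *trends* transfer; absolute
  correlation levels are conservative at this scale.
* The fragment-length filter behaves as its geometry dictates: with the
  realistic overlapping length distributions (sd 15 bp) it removes too few
  fetal reads per maternal read lost to help, while with artificially
  disjoint distributions (sd 0) it removes exactly the fetal reads and
  rescues the high-fetal-fraction arm. Both regimes are exercised in the
  tests; which one a given real dataset resembles depends on its actual
  length-distribution overlap.

## Numerical and degenerate-input choices

* Per-site rescaling keeps the forward and backward passes in range; an
  emission floor (`min_posterior_floor`, default 1e-12) guards underflow,
  and posteriors are renormalized per site (asserted to 1e-9).
* Zero-depth sites are legal everywhere; with no data at all the dosage
  reverts to twice the panel allele frequency (the copying-model prior
  mean), which the tests check against the full-panel computation.
* Ties in hard calls and in high-risk flagging break deterministically
  (first maximum; stable sample order), so repeated runs agree exactly.
* Haplotype-label and copying-set-permutation symmetries of the HMM are
  asserted; selection ties break by panel order.
* `error_rate = 0` is supported (0·log 0 handled explicitly) for
  noise-free limits.

## Problem sizes used by the shipped checks

The acceptance-style checks run the three experiments at 40 pairs × 7
replicates (mixture), 10 subjects × 20 cohorts (coverage), and 450 samples
(cohort) on the default 200 × ~4,500 panel — a few minutes each on one core.
Unit and property tests use an 80-haplotype, ~550-site panel, where a full
imputation takes milliseconds.

## Known limitations

* Single pseudo-chromosome, biallelic SNVs only; no chunking/ligation for
  long chromosomes.
* The fetal haplotype is never modelled jointly with the mother's; doing so
  is the natural next step for reducing the fetal-fraction bias but is
  beyond this package's scope.
* No phasing output; the HMM emits genotype posteriors only.
* Allele matching ignores strand flips (safe on synthetic data; unsafe on
  real array-derived scoring files).
* Fetal fraction is a simulation input, never estimated from data.
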