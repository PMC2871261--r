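---
title: "Methods: detecting allele-specific expression and imprinting in family trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting allele-specific expression and imprinting in family trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioase)
library(dplyr)
```

## The problem

Diploid genomes carry two copies of most genes, but the two alleles are not
always expressed equally. The extreme case is genomic imprinting, where one
parental allele is (almost) silenced; milder, non-parent-of-origin
imbalances are collectively called allele-specific expression (ASE). Both
can be read out at transcribed SNPs: in a heterozygous individual, the two
alleles of a transcript can be distinguished and quantified separately.

`trioase` analyses two-channel allelic intensity data (one fluorescence
channel per allele, many beads per SNP per array) collected on **family
trios**: placental genomic DNA (gDNA), placental cDNA, and both parental
gDNAs. The trio design is what turns an allelic imbalance into a
parent-of-origin statement: when at least one parent is homozygous, the
parental origin of the over-expressed allele in the child can be deduced.

## Preprocessing

Each array (one hybridisation of one sample) is processed independently:

1. **Between-channel quantile normalisation** across all beads of the
   array: both channels are mapped onto the mean of the two sorted
   intensity vectors, removing global dye differences. The premise is that
   the two channel distributions are exchangeable, which holds when allele
   labels are unrelated to channel assignment across a large SNP panel.
2. **Per-bead log-ratio and intensity**: `M = log2(A-channel / B-channel)`
   and `A = 0.5 * log2(A-channel * B-channel)`.
3. **Bead-type summarisation**: within each SNP, values further than
   `mad_k = 3` median-absolute-deviations (unscaled MAD, i.e. no 1.4826
   consistency factor — matching the plain meaning of "MAD") from the
   bead-type median are removed and the rest averaged. M and A are
   filtered independently. A zero MAD (constant beads) removes nothing, so
   a bead set is never deleted wholesale. With ~30 beads this yields one
   `(M, A)` pair per SNP per array.
4. **Median centring** of the summarised M values of the array, removing
   any residual global log-ratio offset (dye bias).

Non-positive raw intensities are floor-clipped to 1.0 before logs so that
log-ratios stay finite; the reader reports how many values were clipped.

## Genotype calling and Mendelian checks

Genomic DNA separates cleanly into three clusters on the M axis, so
genotypes are called with a fixed symmetric margin (default 1.5 log2
units): `M >= +1.5` is AA, `M <= -1.5` is BB, in between is AB, non-finite
is NN (missing). Boundary values go to the homozygote side. This
deterministic rule is deliberately simple — no clustering, no per-call
quality score — and is adequate for well-separated gDNA clusters.
Replicate arrays of a sample are averaged before calling.

Trio calls are screened with a Mendelian consistency check (a child call
must be formable from one allele of each parent; NN anywhere makes the
trio indeterminate, never inconsistent).

## The ASE test

For each SNP in each placental cDNA sample, the replicate centred
log-ratios are summarised by an intercept-only linear model: coefficient =
mean M (the log fold change between alleles), residual variance on
`n - 1` degrees of freedom, standard-error multiplier `1/sqrt(n)`.

With thousands of such fits and very few replicates each, per-fit
variances are noisy. The test therefore uses **empirical-Bayes variance
moderation**: sample variances are modelled as `s0^2 * F(d_g, d0)` draws
around an unknown prior variance `s0^2` with prior degrees of freedom
`d0`. Matching the mean and variance of `log(s_g^2)` to the theoretical
log-chi-square moments gives closed-form estimates of `(d0, s0^2)` (the
trigamma function is inverted by Newton iteration to relative tolerance
1e-8). Each variance is squeezed to the posterior
`(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and the moderated t-statistic uses
`d0 + d_g` degrees of freedom (capped at the total pooled residual df).
Fits with a single replicate (0 df) shrink fully to the prior. An infinite
`d0` (all variances equal up to sampling noise) is a valid outcome and
reduces to a common pooled variance. If fewer than 10 fits carry positive
df the prior is not estimable and the code falls back to ordinary
t-statistics with a warning.

Raw two-sided p-values are adjusted **globally** across all SNP-by-sample
tests of a run with the Benjamini-Hochberg step-up procedure. A posterior
log-odds of differential allelic expression (B-statistic, prior proportion
0.01) is also computed; it is used **only for ranking** (the mixture ROC),
never for calling.

### The three-criterion call rule

A SNP is called ASE when:

1. average cDNA intensity across all placentas exceeds **11.25** log2
   fluorescence units — below this the allelic quantification is not
   reliable (cross-platform concordance drops);
2. at least **2 heterozygous** placentas are individually significant:
   adjusted p < **0.01** and |log fold change| > **0.585**. The 0.585
   threshold is `log2(60/40)`: titration experiments show imbalances at or
   below a 60:40 allelic ratio are hard to detect on this platform;
3. at least **80% of homozygous** placentas pass the same significance
   rule. A homozygote carries only one allele, so a functioning probe
   *must* report strong imbalance there; failing homozygotes indicate the
   probe cannot distinguish the alleles in cDNA. The same |lfc| cutoff is
   applied to heterozygotes and homozygotes.

SNPs with zero informative homozygotes cannot be quality-controlled;
criterion 3 is indeterminate and the SNP is excluded from calls
(conservative). NN-genotype samples count in neither group.

## Parent-of-origin and pattern classification

For every significant heterozygous placenta, the sign of the cDNA M gives
the over-expressed allele, and homozygous parents give its origin: a
mother homozygous for an allele must have transmitted it; a homozygous
father fixes the transmitted paternal allele so the maternal one is the
child's other allele. An absent father still permits inference when the
mother is homozygous. Both parents heterozygous leaves the trio
origin-uninformative.

ASE-positive SNPs are then classified by a decision ladder (first match
wins) over their significant heterozygotes:

1. **imprinting** — at least 80% of origin-informative hets share one
   parental origin, and at least 80% of significant hets show *complete*
   silencing;
2. **partial imprinting** — origin-consistent but silencing incomplete;
3. **preferential** — the same allele *identity* over-expressed in at
   least 90% of significant hets, origins mixed;
4. **random monoallelic** — mostly complete silencing, alleles and origins
   inconsistent;
5. **random ASE** — the remaining significant SNPs;
6. **unclassified** — fewer than 2 origin-informative hets and no allele
   consistency.

SNPs whose `ase_flag` is not true are reported `biallelic`. These
percentage thresholds codify what is otherwise a visual categorisation of
trio bar plots; all are configurable in `ase_config()`.

**Completeness** compares the het cDNA log-ratio to the *homozygous gDNA
reference* of the same SNP (median |M| over homozygous gDNA samples), the
probe's effective dynamic range. We call silencing complete when
`|cDNA M| >= 0.6 * reference`. The factor is deliberately below a naive
0.8: the gDNA reference is saturated (one channel is essentially at the
background floor, e.g. `log2(2.01/0.01) ≈ 7.65` under the intensity model
below), while even canonically "complete" silencing leaves a few percent
of residual expression (expressed-allele fraction ~0.97, i.e.
`|M| ≈ 5.0`). At 0.6 the canonical complete case clears the bar
(`5.0 > 0.6 × 7.65 = 4.6`) while a partial bias at ~40% of the reference
stays partial. The 0.8 parent/completeness consistency and 0.9 allele
consistency levels were chosen once, before any benchmarking, as the
loosest values that still read as "consistent across individuals" with
~10 informative hets; they are package conventions, not measured
quantities.

The **fold difference** between expressed and silenced allele is computed
from reconstructed raw allele intensities `2^(A + M/2)` and `2^(A - M/2)`,
averaged over the significant hets — the per-gene quantity that shows
silencing is a continuum rather than all-or-none.

## The paired allelic-ratio arm (mass-spectrometry allelotyping)

The medium-throughput arm starts from per-sample allele quantifications
(fraction of allele-A signal) with a per-call confidence rating. Per SNP:

- the **success rate** (SR) is the fraction of attempts rated
  "conservative"; the cDNA/gDNA SR ratio proxies expression, and SNPs with
  ratio < 0.75 (inclusive boundary passes) are dropped;
- over trios with heterozygous placental gDNA, a **one-tailed paired
  t-test** compares allelic skew in cDNA vs gDNA on
  `d_i = |frac_cdna,i - 0.5| - |frac_gdna,i - 0.5|`. The absolute-skew
  formulation matters: under imprinting the over-expressed allele differs
  between trios, so raw fractions would cancel; absolute skew makes the
  one-tailed direction (cDNA more skewed) well defined. A consequence is
  that the gDNA reference must carry comparable measurement noise — a
  noiseless 0.5 reference would make any cDNA noise register as skew;
- p-values are BH-adjusted across SNPs, and the mean cDNA skew
  `mean(|2 frac - 1|) * 100` is reported in percentage points (the
  "difference" column; this formula is a reconstruction of that summary,
  not a quantity with an external definition).

## Mixture calibration

Sensitivity and specificity of the array test are calibrated with gDNA
titrations of two individuals in 17 proportions (0:100 … 50:50 … 100:0,
including a duplicated 5:95 entry, kept as given), each in duplicate.
Where the two individuals' genotypes differ, mixing changes the allelic
ratio (true positives); identical genotypes cannot change (true
negatives); NN calls are excluded. Per SNP, a mixture-indexed linear model
(cell means, pooled residual variance) yields contrasts of every mixture
against the 50:50 anchor — differencing against the anchor cancels dye
bias and other systematic shifts. Contrast variances are moderated with
the same empirical-Bayes machinery (prior fitted on one pooled variance
per SNP), SNPs are ranked by posterior log-odds, and a tie-corrected
Mann-Whitney AUC with full sensitivity/specificity curves is reported per
mixture. For equal-df designs the log-odds ranking coincides with ranking
by |moderated t|.

The simulated allele fraction of a mixture is the dosage blend
`(p1 d1 + p2 d2) / (2 (p1 + p2))` with `d` the per-individual allele-A
dosage, which makes every true-positive contrast analytic.

## The synthetic-data generator

The generator emulates the study design end to end: 23 trios, Mendelian
transmission from Hardy-Weinberg parents (minor allele frequency 0.3 by
default, minor allele assigned to either channel with equal probability),
~30 beads per SNP, duplicate placental hybridisations (parents once), and
a 17-point duplicate mixture series. Expression modes per SNP: biallelic
(0.5), maternal/paternal imprinting (expressed-allele fraction 0.97 —
complete silencing is deliberately not total, matching the observation
that repression of the silenced allele is rarely absolute), partial
imprinting (0.72 toward the maternal allele), preferential (0.8 toward a
fixed allele), random monoallelic (0.97 toward a fair-coin allele), and
random ASE (0.72 toward a fair-coin allele). The biased-mode fractions
0.72/0.8 were chosen once as mid-range biases: clearly inside the
detectable region (|M| of 1.35 and 2.0 vs the 0.585 cutoff) yet far from
complete silencing.

Bead intensities follow
`2^(base + log2(2 f + 0.01) + N(0, 0.3) + dye/2)` per channel (complement
fraction and `-dye/2` for channel B): lognormal per-channel noise (so the
per-bead log-ratio has SD `sqrt(2) * 0.3`), a constant additive dye bias
of 0.1 on M that median centring must remove, and an allelic-fraction
floor of 0.01 that keeps the silenced channel above zero. Baseline
intensities are uniform on 9-15 log2 units unless fixed.

`simulate_summaries()` generates data one level up — analytic M/A values
plus replicate noise of SD `sqrt(2) * 0.3 / sqrt(30)`, the sampling error
of a bead-type mean — for experiments that should isolate the test or the
classifier from preprocessing. `simulate_null_study()` builds an
all-heterozygous biallelic design in which the true M of *every* test is
zero. `simulate_benchmark_snp()` embeds one SNP with a fixed heterozygote
count and mode in a biallelic background panel.

### What the generator does not emulate

- **Dense panels.** Real arrays interrogate ~1500 SNPs; synthetic panels
  are 40-1400. Between-channel quantile normalisation reacts to the
  *composition* of an array: with few SNPs, the imbalance between
  A-bright and B-bright homozygous SNPs (binomial, relative magnitude
  `~1/sqrt(panel size)`) shifts the two channel CDFs against each other,
  and because a sample's composition is identical on its replicate
  arrays, the resulting log-ratio bias is shared across replicates — it
  inflates the apparent effect without inflating the replicate variance.
  At 100-SNP panels this bias is ~0.3 log2 units per het sample. The SNP
  call rule (|lfc| > 0.585 in >= 2 hets plus global BH) absorbs it — the
  measured SNP-level false-positive rate stays at 0 — but *per-test*
  type-I error under a mixed-genotype biallelic simulation does not reach
  the nominal level for this preprocessing-related reason. The type-I
  property is therefore measured on the all-heterozygous null design,
  where channels are exchangeable bead-by-bead and the premise of
  quantile normalisation holds exactly. Benchmark studies use 100-SNP
  background panels, the size at which per-het specificity was exact.
- **Extreme-tail fidelity.** Saturated beads (homozygote/gDNA silenced
  channel at the 0.01 floor) populate sparse distribution tails whose
  order statistics quantile normalisation averages; on small panels this
  compresses the largest |M| values. Hence classifier accuracy
  experiments run at summary level, and bead-level completeness
  judgements on small synthetic panels are conservative.
- No spatial artifacts, no background/cross-hybridisation signal, no
  array failures, no genotype-calling uncertainty beyond the threshold
  rule.

Passing tests on synthetic data therefore demonstrate the correctness of
the statistical machinery and the recoverability of the simulated effect
structure; they do not certify performance on real arrays, where probe
chemistry and background correction add variation the generator does not
model.

## Numerical and design choices

- Intensity floor-clip at 1.0 (raw scale) before logs; allelic-fraction
  floor 0.01 inside the generator.
- Genotype margin 1.5 log2 units, boundaries inclusive toward
  homozygotes.
- MAD unscaled, `k = 3`, no removal at MAD 0; M and A filtered
  independently (whether the original procedure filtered A at all is not
  documented; filtering both is symmetric and changes A only when a bead
  is a brightness outlier).
- `unscaled_sd = 1/sqrt(n)` for an intercept-only fit with n replicates.
- Two-sided raw p-values (the null of no allelic imbalance is symmetric
  on log-ratios); the allelotyping arm is the only one-tailed test.
- B-statistic prior proportion 0.01, coefficient prior variance estimated
  from the top `proportion/2` quantile of |moderated t| (limited to
  squared coefficient SDs in [0.1, 4] relative to the residual scale).
- Arrays with low dynamic range: no automatic discard rule is defined
  (the quantitative criterion used historically is unstated); the
  per-array summaries expose the M range for diagnostic inspection.
- Problem sizes in the test-suite and acceptance runs: 20 seeds for the
  power/specificity benchmarks (100-SNP panels), 20 seeds x 200 SNPs for
  end-to-end recovery, 1400 SNPs for the mixture series (>= 500 true
  positives and negatives), 2000 variances x 20 seeds for prior recovery,
  1000 random instances per brute-force oracle, 10 seeds x 100 SNPs for
  the type-I null. These sizes give stable estimates of each operating
  characteristic at desk scale.

## Known limitations

- The threshold genotype caller has no confidence score; borderline gDNA
  log-ratios near ±1.5 can flip calls and occasionally register as
  Mendelian inconsistencies in noisy data.
- The pattern thresholds (80%/90%, completeness 0.6) are conventions; on
  real data the boundary between preferential and random ASE is genuinely
  fuzzy (expect residual confusion between those two classes — in
  synthetic runs, preferential SNPs misclassify mostly into
  partial-imprinting/random-ASE and vice versa).
- Fold differences inherit the intensity model's saturation: when one
  channel sits at the background floor the ratio understates true
  repression.
- Global BH across SNP-by-sample tests treats tests within a SNP as
  exchangeable with tests across SNPs; no hierarchical (per-SNP) error
  control is attempted.
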