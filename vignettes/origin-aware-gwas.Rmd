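---
title: "Subspecies-origin-aware GWAS: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subspecies-origin-aware GWAS: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(origwas)
```

## The problem

Composite cattle populations mix genomes from two subspecies — *Bos taurus*
and *Bos indicus* — that diverged on the order of $10^5$ generations ago. At
that depth, linkage disequilibrium (LD) between a chip SNP and a nearby
causal variant is not expected to be conserved across subspecies: under a
uniform map (1 Morgan per $10^8$ bp here), segments surviving $10^5$
generations of recombination average $10^{-5}$ Morgan, about 1 kb
(`ibd_segment_length_bp(1e5)`), far shorter than typical inter-SNP
distances. A SNP allele may therefore tag a QTL allele on a taurine
background and tag nothing — or the opposite QTL allele — on an indicine
background. Pooling the two backgrounds in a conventional GWAS then cancels
or dilutes the signal.

`origwas` implements the remedy: classify each phased chromosome segment of
each animal by subspecies origin, recode every SNP allele into one of four
origin-by-allele classes, and fit association models that let the allele
effect depend on origin.

## Local ancestry from segment haplotype frequencies

Chromosomes are cut into consecutive segments of 30–31 SNPs
(`define_segments()`; chromosomes that do not divide evenly put the
remainder into the final segments, and a chromosome shorter than the target
becomes a single undersized segment with a warning). For a segment haplotype
$i$ with frequencies $p_{Bt,i}$ and $p_{Bi,i}$ in the taurine and indicine
reference panels, the probability of indicine origin is

$$ b = \frac{p_{Bi,i}}{p_{Bi,i} + p_{Bt,i}} , $$

i.e. the indicine share of the haplotype's reference occurrences. Haplotype
matching is exact string match — that is what frequency tabulation means —
and a string absent from both panels leaves $b$ undefined for that segment.

Because admixture is recent, true ancestry tracts span many segments, so a
centred rolling mean of $b$ over seven segments (truncated at chromosome
ends, skipping undefined values; an entirely undefined window falls back to
the uninformative 0.5) sharpens calls near the extremes. A segment is called
indicine iff smoothed $b > 0.6$; the boundary value itself is taurine,
reading the rule as a strict inequality. Reference panels are the pure-breed
animals themselves; composites never contribute to the frequency tables. We
smooth per haplotype (not per animal): the two haplotypes of an admixed
animal can legitimately have different origins at the same position.

## The contrast coding and the three scans

Each allele is one of taurine A, taurine B, indicine A, indicine B, coded by
seven 0/1 variables: x1 (B allele), x2 (indicine origin), x3 (their
product), and the one-hot x4–x7 over the four classes. The identities
x1 = x6 + x7, x2 = x5 + x7, x3 = x7 hold by construction, and paternal and
maternal codes are summed, so per-animal variables count 0/1/2 alleles.
Three scans share one polygenic mixed model:

* **conventional** — x1 alone: the standard allele-dosage GWAS, run on all
  animals or within a breed group;
* **interaction** — x1 + x2 + x3 jointly (3 df), equivalently
  re-parameterised as x2 + x6 + x7 (allele within taurine, allele within
  indicine). The two parameterisations span the same column space, so the
  joint statistic is identical (`model_equivalence_experiment()` checks this
  to numerical precision); marginal tests are Wald tests conditional on the
  other fitted terms;
* **best variable** — each of x1, x2, x4, x5, x6, x7 fitted one at a time
  (x3 equals x7), reporting the minimum-p variable. We fit each variable
  alone with the covariates rather than alongside the other contrasts: the
  interpretation grid (x4 best ⇒ QTL segregates in taurine, mutant linked to
  A, and so on) presumes the single-variable reading, and exact p ties break
  by the fixed order x1 < x2 < x4 < x5 < x6 < x7.

The interpretation of best-variable winners: x4/x6 point to a QTL
segregating only within taurine (linked to A or B respectively), x5/x7 the
indicine mirror, x2 to a fixed difference between subspecies, x1 to a shared
QTL with conserved phase. `infer_mutant_allele()` turns the winner into a
(subspecies, allele, within-subspecies frequency, signed effect) descriptor;
x1/x2 winners are reported as shared/indeterminate.

## The mixed model

The null model per trait is $y = X\beta + u + e$ with
$u \sim N(0, \sigma_g^2 G)$, $e \sim N(0, \sigma_e^2 I)$, where $G$ is a
VanRaden genomic relationship matrix scaled to mean diagonal 1 (a pedigree
is deliberately not used; the GRM is the modern equivalent and the simulator
has no pedigree). Variance components are estimated once by REML: after one
eigendecomposition of $G$ the criterion is a 1-d profile over
$\delta = \sigma_e^2/\sigma_g^2$, optimised numerically. Every SNP test is
then generalized least squares with that covariance held fixed — the
standard two-stage approximation for large scans. Tests are large-sample
Wald chi-squares (the exact denominator df of an F under a pedigree model is
not reproducible and irrelevant at the sample sizes simulated; with
$\sigma_g^2 = 0$ the machinery reduces exactly to OLS, which the tests
verify against a closed-form oracle). Constant or collinear SNP columns are
dropped with the joint df reduced; a SNP with nothing left is flagged
untestable rather than erroring. P-values are floored at 1e-300 to stay in
(0, 1].

No leave-one-chromosome-out GRM is used: the simulation controls confounding
by construction, and the small upward bias from proximal contamination is
irrelevant to the properties tested.

## Reporting

`estimate_fdr()` uses the expected-false-positives estimator: at threshold
$P$ over $T$ testable SNPs with $A$ declared significant,
$\mathrm{FDR} = \lfloor 100 \cdot P\,T / A \rfloor$ percent, capped at 100
and undefined (NA) at $A = 0$. $T$ is the number of *testable* SNPs in the
subset analysed, not the nominal map size. A refined variant
$P(1-A/T) / ((A/T)(1-P))$ sits behind a flag; the two differ negligibly at
GWAS-scale thresholds. At very small expected counts ($P\,T < 1$) the point
estimate is noisy: a single chance hit yields
$\lfloor 100\,P\,T \rfloor$ < 100 even though every discovery is false —
an inherent property of this estimator, worth remembering when reading
per-chromosome or small-panel summaries.

`classify_patterns()` labels each SNP significant for at least one of the
origin (O = x2), within-taurine (T = x6) and within-indicine (I = x7)
contrasts with the corresponding three-letter pattern; a QTL private to one
subspecies typically shows "OT-"/"-T-" or "O-I"/"--I", a fixed difference
"O--". `select_top_snps()` keeps the most significant SNP per trait ×
chromosome (ties to the smaller position) to avoid counting one QTL many
times, and `effect_frequency_plot_table()` / `plot_effect_frequency()`
produce the signed-standardized-effect versus within-subspecies allele
frequency view used to ask whether selection has pushed trait-increasing
alleles to high frequency.

## What the simulator emulates — and what it does not

The generator (`simulate_population()`) produces the statistical structure
the analysis assumes, with known truth:

* **Founder divergence.** Per-SNP Balding–Nichols draws: ancestral frequency
  uniform on (0.05, 0.95), each pool Beta-distributed around it with
  differentiation parameter `divergence_fst`; a configurable fraction of
  sites is forced to fixed alternate alleles. QTL sites override the drawn
  frequencies according to their mode.
* **Local LD.** Each pool's haplotypes are mosaics of a small template set
  (default 20 per pool) with exponential template-switch tracts (default
  mean 0.005 Morgan), so 30-SNP segment haplotypes recur and their panel
  frequencies are estimable — the property the b statistic needs. Real
  within-breed LD comes from pedigree structure; the template count and
  tract length are the knobs that stand in for it. A template slot is
  identical by descent in both pools with probability
  $(1-F_{ST})^{30}$ — the chance a segment-length haplotype survives the
  divergence intact — so weakly diverged pools share most haplotypes (and
  classification is legitimately hard) while subspecies-level divergence
  shares essentially none.
* **Map scale.** The default chromosome is a 0.05-Morgan piece carrying 600
  uniformly spaced SNPs (12,000 SNPs/Morgan), matching high-density-chip
  scale where a 30-SNP segment spans ~0.0025 Morgan. This matters: at
  sparse map density, ancestry-tract boundaries would chew through whole
  segments and put a hard ceiling on classification accuracy that the real
  data do not have.
* **Admixture.** Composite haplotypes are built from exponential ancestry
  tracts (mean 1/`admix_generations` Morgan) whose source pool is indicine
  with probability `admix_proportion`; tract alleles are fresh template
  mosaics from the source pool, so composites are relatives of the
  reference animals rather than copies, and small reference panels genuinely
  miss rare recombinant strings.
* **Phenotypes.** y = group offset + QTL dosages × effects + polygenic +
  residual on a unit-variance scale. The causal dosage of each QTL uses the
  *true* ancestry: e.g. a `shared_reversed_phase` QTL attaches its effect to
  the mutant-linked allele on taurine haplotypes and to the opposite allele
  on indicine ones, which is exactly reversed LD phase. One-subspecies QTL
  pin the marker frequency only in the pool where the causal class
  segregates; the marker itself segregates freely in the other pool, as a
  chip SNP tagging a subspecies-private QTL would. The polygenic term is
  multivariate normal with covariance $h^2 G$; the residual variance fills
  to 1, and a configuration whose QTL + polygenic variance reaches 1 is
  rejected.

Not emulated: mutation/selection dynamics, pedigree structure, imputation
error, genotyping error beyond injected missingness, more than two source
populations, and multi-allelic sites. Passing tests therefore demonstrate
the *method's* behaviour under its own assumptions — informative priors on
real-data behaviour, not guarantees.

## Numerical and design choices

* Smoothing window 7, centred, truncated at ends; all-missing window → 0.5.
  Centring minimises phase lag; the alternative trailing alignment would
  bias calls toward the chromosome start.
* b = 0.6 exactly → taurine (strict inequality for indicine).
* Leave-one-out re-estimation of haplotype frequencies (excluding the focal
  animal) is not done; with panels of hundreds of haplotypes the own-count
  contribution is negligible.
* REML profile bounded on $\log\delta \in [-12, 12]$; GRM eigenvalues
  clipped at 0; GRM must be symmetric PSD or the fit errors.
* Determinism: `sim_config()` seeds the whole generator; identical configs
  give identical panels, truth, phenotypes, and byte-identical pipeline
  output tables.
* Coordinates: VCF is 1-based, internal indices 1-based columns, tract
  output 0-based half-open.
* QC implements exactly the stated rules: SNP call rate < 90%, the
  degenerate no-heterozygote pattern (both homozygotes present, zero hets),
  duplicated positions dropped at read time, then animal call rate < 90%.
  No chi-square HWE test is applied — only the degenerate pattern is a
  specified exclusion.

## Problem sizes used in the shipped validation

The packaged simulation studies (also run by `scripts/acceptance.R`) use:
ancestry validation at $F_{ST}$ 0.3 with 250 reference animals per pool and
200 composites; power comparison with 10 replicates of 10 phase-reversed
QTL (effect 0.3 SD, n = 3000, $h^2 = 0.3$); best-variable recovery with
replicates of one subspecies-private QTL (effect 0.5 SD, n = 3000) run
without a polygenic term — the property under test concerns the fixed-effect
coding, and OLS is the $\sigma_g^2 = 0$ special case of the same engine;
and null calibration over 5000 SNPs at n = 2000 with $h^2 = 0.3$. These
sizes give stable Monte-Carlo behaviour while keeping a full run in minutes
on one core.

## Known limitations

* Accuracy of ancestry classification degrades near tract boundaries by
  construction (segment granularity) and for haplotypes absent from both
  panels; both effects shrink with map density and panel size.
* The expected-false-positives FDR estimator is a point estimate; at small
  expected counts it is noisy and can understate the FDR of a lucky null
  scan (see above).
* The two-stage mixed model holds variance components fixed across SNPs;
  for very large single-SNP effects the per-SNP REML fit would differ
  slightly.
* The best-variable scan's interpretation grid assumes a biallelic QTL in
  LD with exactly one coded class; echoes of a QTL across several tag SNPs
  are handled only by top-SNP-per-chromosome selection, not LD clumping.

```{r example, eval = FALSE}
# a small end-to-end run
cfg <- run_config(
  sim = sim_config(
    qtl_specs = qtl_spec(1, 300, "taurus_only", effect = 0.5,
                         mutant_freq = 0.5, mutant_allele = "A"),
    seed = 1),
  out_dir = "origwas_demo")
res <- run_pipeline(cfg)
res$top_snps
```
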