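---
title: "Methods: two-stage multi-trait QTL mapping for aluminum tolerance trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage multi-trait QTL mapping for aluminum tolerance trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

altqtl analyses biparental recombinant inbred line (RIL) trials in which
aluminum (Al) tolerance is measured twice: as relative net root growth
(RNRG) in hydroponics and as grain yield on a high-Al-saturation field site
paired with a limed control site. The package implements the full path from
plot- and plant-level records to a multi-trait QTL model, plus the
split-plot analysis of isogenic hybrids segregating for a single tolerance
locus. This vignette documents the models, every tunable parameter, the
synthetic-data generator, and the numerical and design choices — including
the places where the implementation had genuinely open options.

## Stage 1: from raw records to genotype means

**Hydroponics.** For each plant, net root growth is measured in control
solution, `crgr5d = fl_c - il_c`, and under Al stress,
`Alrgr5d = fl_Al - il_Al`; the tolerance index is
`RNRG = 100 * Alrgr5d / crgr5d` (percent). Plants whose control root did
not grow carry no usable signal and are excluded with a logged count.
Plants are averaged within (line, block) and the block mean is
log10-transformed. Two decisions here were open:

* *Transform order.* We average on the percent scale and then take
  logarithms, because the randomized-complete-block model operates on the
  block-level response. The alternative (log per plant, then average) moves
  block means by a Jensen-gap constant and differs materially only when
  plant-level noise is large; the chosen order is the package default and
  the other is obtainable by transforming upstream.
* *Non-positive block means.* `log10` is undefined at RNRG <= 0 (a root
  that shrank under Al). Block means at or below a floor of 1 percent are
  clamped to the floor before transforming (`floor` argument of
  `compute_rnrg()`); clamps are counted and logged. One percent is far
  below any biologically distinguishable growth signal, so the clamp
  orders "no growth" lines correctly without letting a single negative
  plant dominate the scale.

The RCBD mixed model `value ~ block + genotype + error` is fitted by REML
(`fit_rcbd()`), with block fixed. With genotype random it returns the
variance components and line-mean heritability `h2 = s2g / (s2g + s2e / r)`
with `r` the number of blocks (2 in the emulated design); with genotype
fixed it returns BLUEs, which on balanced data equal raw genotype means.

**Field trials.** Each environment (control, Al) is a resolvable
incomplete-block design: 3 replicates of 10 incomplete blocks holding 100
entries (90 RILs, the sensitive parent once, and the tolerant parent nine
times as a check — the duplicated check simply contributes all its plots to
one genotype level). `fit_incomplete_block()` fits
`yield ~ replicate + block(replicate) + genotype + error` by REML with
replicate fixed and incomplete block random. Environment-specific variances
are honoured by fitting each environment separately; the cross-environment
genotypic covariance is reported descriptively as the correlation of the
two BLUE vectors (`env_genetic_correlation()`), with the caveat — logged at
run time — that stage-1 noise attenuates it toward
`rho * sqrt(h2_control * h2_Al)`. A joint bivariate REML fit was not
implemented because only the per-environment BLUEs feed stage 2. Variance
components estimated on the zero boundary are reported, not errors.

The three BLUE vectors are inner-joined into the trait table
(`assemble_trait_table()`), dropping parents and checks so the mapping
population stays clean.

## Stage 2: the multi-trait QTL engine

**Genotype coordinates.** Genotypes are coded 0 (A parent) / 1 (B parent),
so an estimated QTL effect is the full difference between homozygous
classes — the convention under which a yield effect reads as the gain from
substituting both copies of the allele. Map distances use the Haldane map
function with the Haldane–Waddington selfed-RIL expansion
`R = 2r / (1 + 2r)`; the map function is configurable in principle but
Haldane gives closed-form chain algebra and the data cannot distinguish
map functions at this density. Note `R < 1/2` always: two unlinked loci
recombine in half the lines.

**Conditional QTL probabilities.** At every grid position (markers plus
interpolated points at a 2 cM default step), `qtl_genotype_probs()`
computes `x = P(genotype B | nearest informative flanking markers)` from
the two-state Markov chain with transition probability `R(d)` between
loci. Missing flanks fall back to one-sided conditioning; a chromosome
with no informative marker for a line scores 1/2. A full hidden Markov
model over all markers was deliberately not used: F7:8 RILs are nearly
fully informative, residual heterozygous calls are treated as missing
(with a logged count), and flanking-marker conditioning is standard
interval-mapping practice at this scale.

**The scan.** For the three traits jointly, the model at a tested position
is `y_t = mu_t + sum_c gamma_ct x_c + alpha_t x + e_t`, with trait-specific
fixed QTL and cofactor effects and an unstructured covariance for the
residual vector across traits. With one observation per line and trait,
the polygenic background and the stage-1 error are jointly unidentifiable,
so they are pooled into that single unstructured covariance; optional
per-trait error floors (`s2e / r` from stage 1) separate the genetic part
again for percent-genetic-variance accounting. Because the regressor set
is identical across traits, generalized least squares reduces to per-trait
ordinary least squares with the residual covariance estimated from
residuals — no iterative multivariate REML is needed. The Wald statistic
is `alpha' V(alpha)^{-1} alpha` with `V(alpha) = Sigma_hat (X'X)^{-1}_xx`.

**P-values.** The large-sample reference for the Wald statistic is
chi-square with one degree of freedom per trait. At 90 lines with an
estimated 3x3 residual covariance, however, the exact null distribution is
Hotelling's T-squared, and the chi-square reference is anti-conservative
exactly where the genome-wide threshold operates (comparisonwise p around
1e-4). The package therefore defaults to the exact T-squared-to-F
calibration — for a single trait this *is* the regression t-test, so the
textbook identity "Wald equals the squared t" is preserved — and keeps
`pvalue = "chisq"` as an option for comparability with asymptotic
software.

**Threshold.** The genome-wide threshold uses the effective number of
tests: per chromosome, the eigenvalues of the marker-score correlation
matrix give `M_eff = sum_i [1(lambda_i >= 1) + (lambda_i - floor(lambda_i))]`,
chromosome contributions are summed, and the comparisonwise cutoff is the
Sidak-type `1 - (1 - alpha)^(1/M_eff)` at a genome-wide alpha of 0.05.
M_eff is computed on markers, not grid points, because interpolated
positions carry no additional tests. *Known limitation:* this eigenvalue
rule counts correlation in the genotypes, while exceedance events of the
multi-trait statistic decorrelate roughly like the squared correlation, so
on a dense RIL map the realized genome-wide type-I rate exceeds the
nominal level (in the package's own null simulations, roughly 0.09-0.12
at a nominal 0.05). Users who need strict family-wise control should
tighten `alpha`; the default follows the eigenvalue-correction protocol
because the reported scan profiles and thresholds are meant to be
comparable with that practice.

**Model search.** One simple-interval-mapping round scans all positions
without cofactors; candidates are local maxima of `-log10(p)` above the
threshold, accepted greedily in decreasing significance subject to a
minimum separation (default 30 cM; ties break toward the lower position,
deterministically). Composite-interval-mapping rounds rescan with the
candidate scores as cofactors, excluding any cofactor within a window
(default 30 cM) of the evaluated position on the same chromosome, and
iterate until the candidate set stabilizes (at most 5 rounds; an
oscillating set stops with a warning). Backward elimination then fits all
candidates jointly and repeatedly drops the worst candidate whose joint
multi-trait Wald p exceeds the comparisonwise cutoff. None of step,
separation, window or round count is dictated by the data; the defaults
follow common composite-interval-mapping practice and are all exposed in
`scan_qtl()`.

**Effects and %GV.** The final joint model reports per-trait
allele-substitution effects (B-class minus A-class), standard errors, and
the high-value parent from the effect sign. The percentage of genetic
variance explained by QTL `q` for trait `t` is the relative drop in
genetic (residual-minus-floor) variance when `q` is added to the
polygenic-only base model; the per-trait total adds all QTL jointly.
Negative drops are floored at zero and logged.

## The isogenic hybrid trial

Eight hybrids (2 female x 4 male parents differing in their alleles at the
chromosome-3 tolerance locus) are grown in a split-plot design: the Al
treatment on whole plots (completely randomized, 4 per treatment), hybrids
on sub plots. `split_plot_anova()` tests treatment against the whole-plot
error (df 6) and everything else — female (df 1), male (df 3), female x
male (df 3), treatment x hybrid (df 7) — against the sub-plot error
(df 42). The error strata are stated explicitly because split-plot
analyses are frequently mis-stratified. LSDs at alpha = 0.05 use the
stratum appropriate to each factor.

`dosage_covariate_test()` replaces the female and male factors by the
linear count of tolerance alleles (0/1/2 per hybrid, from the parents'
genotypes): within whole plots, yield is regressed on the dosage, and the
per-copy coefficient is compared with the factorial model's average
substitution effect (the female marginal difference — the two females
differ by exactly one allele copy against every male). Equality of the two
indicates additive gene action; under dominance they diverge and the
divergence is reported.

## The synthetic-data generator

`sim_config()` fixes the emulated study conditions; they are conditions,
not tuning knobs. Defaults and their derivations:

* **Population and map.** 90 RILs; 344 markers on 10 chromosomes with
  near-even spacing (~5-7 cM), chromosome lengths 110-225 cM; the marker
  nearest each causal position is snapped onto it (chromosome 3 at
  184.2 cM, chromosome 9 at 214.0 cM) so both loci are grid-reachable.
  Genotypes descend by the same two-state chain the analysis assumes
  (single seed descent; marginal allele frequency 1/2).
* **QTL effects** on the 0/1 (B = tolerant-parent) coding:
  (0.71, 0.19, 0.61) at the chromosome-3 locus and (0.34, -0.66, -0.36)
  at the chromosome-9 locus for (RNRG_log10, Gy_control, Gy_Al) — the
  tolerant parent donates the positive allele for root growth and for
  yield at the chromosome-3 locus; the sensitive, higher-yielding parent
  donates the positive yield allele at the chromosome-9 locus.
* **Polygenic covariance.** With allele frequency 1/2, a QTL of effect
  `b` contributes `b^2/4` to a trait's variance. Back-solving the target
  variance shares of the two QTL for each trait gives polygenic variances
  (0.097, 0.135, 0.115) — genetic variance larger in control than under
  Al stress, as expected when stress compresses the genetic range.
  Polygenic correlations (0.1, 0.4, 0.5) for (RNRG-control, RNRG-Al,
  control-Al) encode that tolerance correlates with yield mainly where Al
  is present.
* **Error variances.** Chosen so line-mean heritability lands in the
  0.7-0.9 range with hydroponics highest and the Al site slightly below
  control: plant-level log10 SD 0.65 with 7 plants x 2 blocks in
  hydroponics; plot error variances 0.185 (control) and 0.22 (Al) with 3
  replicates in the field, incomplete-block variance 0.05, replicate SD
  0.15.
* **Trait means.** On the A-class baseline, mu = (1.05, 3.587, 2.221).
  The RNRG intercept puts the parents near 11 and 126 percent (log10
  scale); the yield intercepts were derived once from two population-level
  statements — a ~30 percent RIL-mean yield reduction under Al and a
  chromosome-3 Al-site effect equal to ~26 percent of the Al-site mean —
  and fix the expected means at 3.35 and 2.35 t/ha.
* **Hybrid trial.** Base 3.085 t/ha, treatment effects +/-0.47, 0.5 t/ha
  per tolerance-allele copy (purely additive by default; a dominance
  deviation and an Al-specific per-copy effect are exposed as parameters),
  whole-plot SD 0.41 and sub-plot SD 0.89. These reproduce, in
  expectation, female marginals of 3.46/3.96 t/ha, environment marginals
  of 4.18/3.24 t/ha, and LSDs near 0.45 (female) and 0.9 (environment).

One global seed fans out to fixed per-component child seeds, so any stage
can be regenerated in isolation and equal seeds give byte-identical files.

**What the generator does not emulate** — and therefore what passing tests
cannot certify about real data: segregation distortion, genotyping error,
residual heterozygosity, spatial field trends and other non-exchangeable
plot effects, genotype-specific error variances, and non-normal trait
noise. The hydroponic plant noise is log10-normal and multiplicative; real
root-growth data can be more irregular at the sensitive extreme, where the
clamp floor engages.

## Numerical choices and degenerate inputs

* Positions with a constant QTL score, or a score correlated above 0.999
  with a cofactor, are skipped (`NA` in the profile) rather than tested.
* A singular trait covariance in the base model receives a logged ridge of
  `1e-8 x trace`.
* Co-located contradictory flanking markers (distance zero on both sides
  with opposite genotypes) give probability 1/2.
* Variance components are REML estimates; zero-boundary estimates are
  legal and logged. Heritability is reported as the plug-in ratio, which
  carries a small O(1/n) downward bias relative to the generating value.
* Unbalanced split-plot designs are rejected outright — the stratum
  arithmetic is only exact under balance — with the offending cell counts
  in the error.

## Problem sizes used in the shipped checks

The package's own verification uses the emulated design at full size (90
lines x 344 markers, 3 traits, 2 cM grid): 200 replicates for the null
(type-I) and recovery studies in the test suite, and 150 scan replicates,
100 hybrid-trial replicates and 5 full stage-1 pipeline replicates in the
reproduction script (`scripts/acceptance.R`). These sizes put Monte-Carlo
standard errors on mean effect estimates near 0.005 t/ha, an order of
magnitude below the effects under study.
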