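---
title: "Models and methods: chromatin-accessibility QTLs, colocalization, and mediated heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qtlmediate)
```

## The scientific question

Most disease-associated variants found by GWAS are noncoding, yet only a
minority of such loci can be linked to an expression QTL (eQTL) in any
assayed cell type. Chromatin accessibility QTLs (caQTLs) sit one step
closer to the causal variant: a variant that disrupts regulatory-element
activity changes local accessibility directly, while its effect on any
particular gene is filtered through enhancer-promoter wiring that is
weaker at a distance and often specific to a cellular context. This
package implements, end to end on synthetic data with known truth, the
analysis repertoire used to dissect that gap:

* cis-QTL mapping of accessibility and expression count phenotypes;
* Bayesian colocalization of QTL and disease association signals;
* inverse-variance-weighted (IVW) fixed-effects meta-analysis across
  eQTL studies;
* stratified and QTL-mediated heritability regression with a
  union/intersection decomposition;
* peak-to-TSS-distance analyses of cis-heritability.

Because every dataset is generated by the package's own simulator, every
estimate can be compared against stored ground truth, and the
qualitative claims (signal conversion with sample size and context,
distance attenuation of eQTLs but not caQTLs) become testable recovery
properties.

## The generative model

### Genotypes

`simulate_genotype_panel()` draws two haplotypes per individual as a
first-order binary Markov chain along the variant positions. The target
correlation between adjacent variants at distance $d$ is
$e^{-d/\lambda}$ with decay scale $\lambda$ (`ld_decay`, default 20 kb).
Because the conditional expectation of a binary variable is linear,
correlation multiplies along the chain, so LD decays approximately
exponentially in distance. Allele frequencies follow a bounded random
walk whose step shrinks as LD tightens — variants in strong LD carry
nearly identical frequencies, which both mirrors real panels and keeps
the requested correlation inside the Fréchet bounds of the binary pair.
Per-segment log-normal multipliers on $\lambda$ (`ld_decay_sd`, default
0.75) create recombination-hotspot-like heterogeneity. This is not
cosmetic: LD-score regression separates per-variant ("direct")
heritability from the intercept only if LD scores genuinely vary along
the genome, exactly as in real data.

Blocks of equal variant counts store empirical LD correlation matrices
`R`; all downstream "population" computations (GWAS sampling law, truth
quadratic forms, LD and mediation scores) use these matrices, so the
generator and the estimators share one definition of LD.

### Regulatory architecture

`simulate_regulatory_model()` gives each peak at most one causal variant
(uniform among the variants it contains, with probability
`p_causal_peak`) and an accessibility effect
$b \sim N(0, \sigma_{ca}^2)$ on the standardized-dosage scale. Peak-gene
wiring weights are $w \sim N(0, \sigma_w^2)\,e^{-d/\tau}$ with
`wiring_decay` $\tau$; each edge is active per context with probability
`prop_active_per_context`. Latent phenotypes are

$$a_p = b_p x_{k(p)} + \varepsilon_a,\qquad
  x_g = \sum_{p} w_{pg}\, a_p + \varepsilon_x,$$

with noise variances `peak_noise_var` (0.64) and `gene_noise_var`
(0.5). With $\sigma_{ca} = 0.6$ this yields typical peak
$h^2_{cis} \approx 0.3$–0.4, substantially above typical gene
$h^2_{cis}$ — the asymmetry the distance analyses probe.

Disease liability receives three effect layers: through expression
($\gamma_g$ on a subset of genes), through accessibility beyond
expression ($\delta_p$), and directly on variants (non-mediated). The
layers are orthogonalized sequentially in the LD metric
$\langle a,b\rangle = \sum_{\text{blocks}} a^\top R\, b$, so the stored
truths are exactly additive:
$h^2_{SNP} = h^2_{med,eQTL} + h^2_{acc\text{-}only} + h^2_{direct}$, and
the conservation invariant $h^2_{med} \le h^2_{SNP}$ holds by
construction. When `h2_snp_target` (and optionally
`prop_mediated_target`) is supplied, the layers are rescaled so the
truth hits the target exactly; the liability is then defined on the
variant scale with unit total variance. The recovery experiments rely on
this exact calibration.

### Counts and summary statistics

Counts are negative binomial with mean
$\ell_s\, c_f\, e^{\eta\, \text{latent}}$ (library factor, per-feature
baseline, exponential link; `dispersion` 0 gives Poisson), which
exercises the TMM/CPM filter path. The count layer roughly halves the
realized heritability of the normalized phenotype relative to the
latent; planted effect sizes in the experiments account for this.

Disease summary statistics come directly from the asymptotic law
$z \sim \text{MVN}(\sqrt{N} R\beta,\, R)$ per LD block — the standard
device for simulating GWAS at arbitrary $N$ without individual-level
data — while molecular QTL statistics are produced by actual regression
on simulated cohorts, so both code paths are exercised.

## The estimators

**cis mapping.** Phenotypes are TMM-normalized (via edgeR, the canonical
implementation), features with CPM < 0.8 or counts < 10 in more than 20%
of samples are dropped, values are inverse-normal transformed
($\Phi^{-1}((\text{rank}-0.5)/n)$, average ranks on ties), latent
covariates are chosen by Buja–Eyuboglu parallel analysis (retain the
leading PCs whose eigenvalues beat the 95th permutation percentile,
stopping at the first failure), and each variant within the cis window
(200 kb from the nearest peak edge; 1 Mb from a TSS; in-sample MAF ≥ 5%)
is tested by simple regression of covariate-residualized phenotype on
residualized dosage. By Frisch–Waugh–Lovell this equals the full
multiple regression; residual degrees of freedom are
$n - 1 - \text{ncol(design)}$. Lead ties break by smaller position, then
id.

**Candidate loci.** A disease window (lead ± 100 kb) with lead
$p < 10^{-6}$ qualifies for a QTL feature when the feature's lead
$p < 10^{-4}$ inside the window and at least one variant *other than the
disease lead itself* simultaneously reaches 0.8× the feature's lead
chi-square and 0.8× the disease lead's chi-square (≥ at exactly 0.8×).
The window's maximum-chi-square variant defines the disease reference;
excluding it makes the overlap condition non-trivial — it must be
corroborated elsewhere in the locus. Later disease leads inside an
already-emitted window are skipped.

**Colocalization.** Per variant, the Wakefield approximate Bayes factor
$\log BF = \tfrac12\log\frac{V}{V+W} + \tfrac{z^2}{2}\frac{W}{V+W}$ is
averaged over the prior-variance grid $W \in \{0.01, 0.1, 0.5\}$; the
five-configuration enumeration (none / trait 1 only / trait 2 only / two
distinct variants / one shared variant) with per-variant priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ is evaluated in log space
(log-sum-exp; the distinct term via a stable log-difference, clamped at
zero with a warning if it underflows). A locus is colocalized when the
shared-configuration posterior exceeds 0.98. Variants are intersected
across the two statistic sets; swapped ref/alt records flip the effect
sign and strand-ambiguous variants (A/T, C/G) with MAF > 0.4 are
dropped.

**Meta-analysis.** IVW fixed effects: weights $1/se^2$, combined
$se = (\sum w)^{-1/2}$, p recomputed from the combined z. A variant
missing from some studies is combined from the studies that carry it;
Cochran's Q is emitted as a diagnostic only. No random-effects option is
provided.

**Heritability.** LD scores use the unbiased adjustment
$\tilde r^2 = r^2 - (1-r^2)/(n-2)$ within block and window; mediation
("expression") scores are $E_j = \sum_k \tilde r^2_{jk} \sum_g
\alpha^2_{kg}$, and the regression
$E[\chi^2_j] = 1 + N\sum_c \tau_c \ell_{jc} + N\sum_d \omega_d E_{jd}$
(intercept estimated) is fit by two-pass weighted least squares: first
with $1/\ell$ LD-redundancy weights, then adding inverse-variance
weights $1/(2(2\hat\mu_j - 1))$ from the fitted noncentral-chi-square
means. Mediated heritability is $\hat h^2_{med,d} = \hat\omega_d \times
\sum_g h^2_{cis,g}$ (the set's summed cis-genetic variance in the no-LD
convention); the non-mediated side aggregates the $\tau$ terms; standard
errors come from a 20-block delete-one jackknife (the 200-block default
of genome-scale tools is too many for these region sizes). Negative
$\omega$ estimates are reported as-is. In the mediated fits only the
base (all-variants) LD score enters the $\tau$ side: a peak-region
annotation column is near-collinear with the caQTL mediation score and
destabilizes the joint fit — the same redundancy argument used when
selecting annotations in mediated-heritability analyses of real data.

The union/intersection decomposition takes the separate caQTL and eQTL
fits plus the joint (union) fit and reports
$h^2_{int} = h^2_{ca} + h^2_{e} - h^2_{\cup}$,
$h^2_{just\,ca} = h^2_{\cup} - h^2_{e}$,
$h^2_{just\,e} = h^2_{\cup} - h^2_{ca}$. (A published form of the
intersection algebra equates the "just caQTL" term to
$h^2_{\cup} - h^2_{ca}$, which is algebraically the just-eQTL quantity;
the set-consistent formulas above are used here.) The identities hold to
double-precision rounding for any inputs and are property-tested on
random triples.

**cis-heritability.** Haseman–Elston regression of phenotype products on
the cis-relatedness $A_{ij} = m^{-1}\sum_k x_{ik}x_{jk}$ over $i<j$
pairs, clipped to [0, 1] for reporting with the raw value retained. Its
independent cross-check, `estimate_cis_h2_reml()`, maximizes the profile
restricted likelihood of $y \sim N(\mu, \sigma^2(h^2 A + (1-h^2)I))$
after projecting out the mean; the two agree (r > 0.8) on small designs
where the truth varies across replicates.

**Mediation scores: true vs estimated.** Tests and recovery experiments
use the true cis effects (isolating the regression's own behavior); the
pipeline estimates them by ridge regression on the correlation scale,
$\hat\alpha = (R_{cis} + \lambda I)^{-1} \hat z/\sqrt n$ with
$\lambda = 0.1$ — a deliberately simple shrinkage stand-in for the
REML/LASSO expression-score machinery of genome-scale tools. Estimated
scores at desk scale are noisy; see Limitations.

## Study conditions and problem sizes

The pipeline defaults mirror the study conditions the package models: a
caQTL cohort of 100 individuals; a primary eQTL study of 373; three
further eQTL studies of 190, 147 and 418 individuals entering the
meta-analysis (total 1128); a second cellular context surveyed at n =
400; GWAS $N = 50\,000$ (a scaled-down device — per-locus chi-squares,
not N itself, carry the information); disease $h^2_{SNP} = 0.3$;
thresholds $p < 10^{-6}$ (disease), $p < 10^{-4}$ (QTL), 0.8× overlap,
posterior > 0.98, MAF ≥ 5%, CPM < 0.8 / counts < 10 / 20% filter, 200 kb
and 1 Mb windows. Simulated regions hold 1 200–2 000 variants over 3–6
Mb with 60–220 features — sizes chosen so each recovery study runs in
seconds to minutes while leaving enough variants per window for the
filters and regressions to behave as designed. The staged-conversion
study plants three kinds of disease loci (strong primary-context wiring;
weak wiring detectable only after meta-analysis; second-context-only
wiring) with latent gene $h^2_{cis}$ of 0.3 / 0.06 / 0.3 and dense LD
(decay 60 kb), so conversions occur at the stage they are designed for.

## What the simulator does and does not emulate

It emulates: distance-decaying LD with hotspot-like heterogeneity;
causal variants inside peaks; expression driven by peak activity with
distance-decaying, context-masked wiring; disease liability mediated
through accessibility and expression plus a direct component;
overdispersed counts with library-size variation; multiple studies
sharing true effects.

It does not emulate: population structure or admixture; imputation
error; allele-frequency-dependent architectures (effects are drawn
independently of MAF); trans effects; read-level artifacts; sex
chromosomes; multiple causal variants per peak (one causal maximum,
matching the single-shared-variant colocalization model). Passing tests
therefore demonstrate internal consistency and statistical calibration
of the methods under these assumptions — not robustness to confounders
real data would add.

## Numerical choices and conventions

* Coordinates: peaks are BED-style 0-based half-open; TSSs 1-based.
  Peak-to-TSS distance is 0 when the TSS lies inside the peak, else the
  smaller distance to the flanking positions `start + 1` and `end - 1`.
* Distance quintiles assign ties to the lower quintile; lead-variant
  ties break by position then id.
* All log-scale posterior arithmetic uses log-sum-exp; the
  distinct-configuration score uses a guarded log-difference.
* Multiplicity for enrichment families uses Benjamini–Hochberg by
  default; a Storey-style option (`method = "storey"`, $\pi_0$ at
  $\lambda = 0.5$) is exposed. The two differ only by the $\pi_0$
  factor.
* Randomness flows from one integer master seed through
  `derive_seed(seed, label, index)` (a multiplicative string hash modulo
  $2^{31}-1$), so stages are independently reproducible.
* Degenerate inputs: constant features become zeros with a warning in
  the inverse-normal transform; zero-variance dosages are skipped;
  all-zero count columns are rejected with the sample id; non-PSD LD
  blocks are repaired by eigenvalue clipping with a warning.

## Known limitations

* Mediated-heritability ratios at desk scale are noisy: the denominator
  $\hat h^2_{SNP}$ can approach zero in single replicates, making
  individual ratio estimates unstable (recovery is assessed as a mean
  over 20 replicates). Genome-scale analyses average over orders of
  magnitude more variants and jackknife blocks.
* Ridge-estimated mediation scores are biased toward uniformity by
  estimation noise, attenuating and destabilizing single-run pipeline
  estimates relative to the true-score fits.
* The Haseman–Elston pair regression treats pairs as independent when
  computing its analytic SE; the likelihood-based estimator is the
  better-calibrated reference at small n.
* The greedy masking of overlapping disease windows and the satellite
  loci produced by long-range LD make locus counts (not locus sets)
  sensitive to LD density.
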