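---
title: "Methods: Bayesian colocalisation of lung-function and cardiovascular GWAS signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian colocalisation of lung-function and cardiovascular GWAS signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colocpipe)
```

## The scientific question

Lower adult lung function — particularly a restrictive pattern indicated
by low forced vital capacity (FVC) — is epidemiologically associated with
higher cardiovascular morbidity and mortality, and the association is not
explained by smoking or other adult risk factors. One candidate
explanation is shared developmental biology: signalling pathways critical
to lung development may also shape the cardiovascular system. A genetic
test of that idea asks whether, inside candidate lung-development genes,
the *same* variant drives both an adult lung-function association and a
cardiovascular one.

`colocpipe` implements that test as a reusable pipeline over GWAS summary
statistics: per-variant association (when individual-level data are
available), fixed-effect meta-analysis across cohorts, Bayesian
colocalisation of trait pairs within gene regions, single-causal-variant
fine mapping, LD-based promotion of near-shared signals, direction-of-
effect assessment in a harmonised allele frame, and one-sided
Bonferroni-corrected replication. Because the biobank datasets this kind
of analysis runs on are access-controlled, the package also ships a
synthetic-data module that generates LD-structured two-trait summary
statistics with known ground truth, so every stage is testable end to
end.

## The colocalisation model

For one gene region with $m$ variants and two traits, exactly one of
five hypotheses is assumed to hold:

* $H_0$ — no variant is associated with either trait;
* $H_1$ / $H_2$ — one causal variant for trait 1 only / trait 2 only;
* $H_3$ — both traits are associated, through *different* variants;
* $H_4$ — both traits are associated through the *same* variant.

Each variant contributes a Wakefield approximate Bayes factor per trait.
With estimate $\hat\beta$, standard error $V^{1/2}$, and a normal prior
$N(0, W)$ on the true effect,

$$\log \mathrm{ABF} = \tfrac12\left[\log(1 - r) + r z^2\right],
\qquad r = \frac{W}{V + W},\; z = \hat\beta / V^{1/2}.$$

Per-variant prior probabilities $p_1$, $p_2$ (association with one
trait) and $p_{12}$ (association with both) weight the single-causal
configurations. Writing $L_{ti}$ for variant $i$'s Bayes factor on trait
$t$, the unnormalised hypothesis masses are

$$S_0 = 1,\quad S_1 = p_1 \sum_i L_{1i},\quad S_2 = p_2 \sum_i L_{2i},$$
$$S_3 = p_1 p_2 \sum_{i \ne j} L_{1i} L_{2j},\quad
S_4 = p_{12} \sum_i L_{1i} L_{2i},$$

and $\mathrm{PP}_h = S_h / \sum_k S_k$. Conditional on $H_4$, variant
$i$'s posterior of being the shared causal variant is
$L_{1i}L_{2i} / \sum_j L_{1j}L_{2j}$.

Single-trait fine mapping (`finemap_abf`) uses the same Bayes factors
under the one-causal-variant assumption:
$\mathrm{snpPP}_i = L_i / \sum_j L_j$, with a null posterior that weighs
the configuration "no causal variant" at prior mass $1 - m p_1$ against
the $m$ single-causal configurations at $p_1$ each.

### Priors and tunable parameters

| parameter | default | units / scale | role |
|---|---|---|---|
| `p1`, `p2` | $10^{-4}$ | per variant | prior that a variant is associated with one trait |
| `p12` | $10^{-5}$ | per variant | prior of a shared association |
| `w_sd_quant` | 0.15 | trait SD units | prior effect SD, quantitative traits |
| `w_sd_cc` | 0.20 | log-odds | prior effect SD, case-control traits |
| `pp_threshold` | 0.70 | posterior probability | colocalisation call threshold |
| `r2_equivalence` | 0.8 | LD $r^2$ | floor for H4-equivalence (strictly greater) |
| `maf_min`, `info_min` | 0.01, 0.5 | — | QC floors (MAF $\ge$ 1%, imputation INFO $\ge$ 0.5) |
| replication `alpha`, `m_tests` | 0.05, explicit | — | family-wise level and test count per cohort |

The priors are the long-standing defaults of the approximate-Bayes-factor
colocalisation framework. They are configurable everywhere and echoed in
every result object, since conclusions about $H_3$ vs $H_4$ can be
prior-sensitive. No multiplicity correction is applied across
colocalisation pairs — the prior odds already penalise association — but
the replication stage corrects for its declared number of tests, which is
an explicit input (never inferred from the data) so report tables stay
auditable.

### Classification and H4-equivalence

`classify_coloc` labels a pair H4 if $\mathrm{PP}_4 \ge 0.70$, else H3 if
$\mathrm{PP}_3 \ge 0.70$, else the highest-posterior hypothesis if it
reaches the threshold, else "none". H4 is checked first deliberately:
when both shared and distinct configurations are probable, the shared
call is the biologically conservative summary at the gene level.

An H3 pair can still reflect one functional signal if each trait's
association peaks on a different but tightly linked variant. For every
pair the package fine-maps both traits, takes each trait's top variant
(ties broken by genomic position, then id — a deterministic, documented
rule), and promotes H3 to `H4_EQUIVALENT` when the two top variants'
squared allelic correlation exceeds 0.8 (strictly; the published
exemplar of this situation had $r^2 = 0.85$). Promotion is only applied
to H3 labels; an H4 label is never re-labelled.

### Direction of effect

Effects are re-expressed so the effect allele is the one detrimental to
lung function (oriented lung beta < 0). A cardiovascular effect is
*consistent* with the lower-lung-function/higher-risk hypothesis when the
oriented odds ratio exceeds 1 (binary traits: hypertension, coronary
heart disease) or the oriented beta is positive (continuous traits).
Odds ratios are carried internally as log-odds so allele flips are sign
changes; conversion to OR happens only at report time. For H4 pairs the
anchor variant is the shared top variant; for H4-equivalent pairs it is
the cardiovascular trait's top variant, matching how the one published
H4-equivalent signal was reported. A lung effect of exactly zero leaves
the detrimental-allele frame undefined and is an error rather than a
silent choice.

### Replication

Replication is defined as a same-direction effect, so the external
cohort's two-sided p-value converts to a one-sided p: $p/2$ when the
direction matches discovery, $1 - p/2$ otherwise. Signals beat either
the Bonferroni threshold $\alpha/m$ or the nominal $\alpha$, or they do
not replicate; a missing variant is looked up through the best LD proxy
with $r^2 \ge 0.8$ (the same floor as H4-equivalence), and a signal with
no usable proxy is `UNTESTABLE` rather than a failure. When a proxy is
used, the direction of its effect is carried through the sign of the
allelic correlation between proxy and target, since the proxy's alleles
are not the target's.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated.

**Genotypes.** A Gaussian-copula haplotype model: each haplotype is a
latent multivariate normal draw thresholded at the allele-frequency
quantile; genotype = sum of two haplotypes. Thresholding attenuates
correlation (the tetrachoric effect), so the latent correlations are
pre-inflated by numerically inverting the tetrachoric map (own bivariate
normal CDF via one-dimensional quadrature plus root finding, cached over
distinct entries); the realised allelic correlation then matches the
target LD matrix in expectation. LD itself defaults to an AR(1) decay
$r_{ij} = \rho^{|i-j|}$, a reasonable stand-in for distance-decaying LD
along a region.

**Phenotypes.** Additive: $y = \beta g_c + X\gamma + \varepsilon$ for
quantitative traits, logistic in the same linear predictor for binary
traits. Covariates are independent standard-normal columns emulating the
age/sex/array/centre/principal-component adjustments of a biobank
analysis; their effects default to zero. Derived cardiovascular traits
follow their clinical definitions: pulse pressure = SBP − DBP;
hypertension iff SBP $\ge$ 140 mm Hg or DBP $\ge$ 90 mm Hg or treatment.

**Direct summary statistics.** The fast path skips individuals entirely:
the z-score vector of a trait is drawn from
$N(R e_c \lambda,\; R)$ with $R$ the LD matrix, $e_c$ the causal
indicator and $\lambda$ the causal non-centrality,
$\lambda = \beta \sqrt{2 n f (1-f)} / \sigma$ for a quantitative trait
(the case-control version carries an extra
$\sqrt{\varphi(1-\varphi)}$ for case fraction $\varphi$). Betas and
standard errors follow from the Hardy–Weinberg dosage variance. A
dedicated test confirms that z-scores produced by regression on
simulated individuals agree in distribution with this direct route
(two-sample Kolmogorov–Smirnov statistic below 0.1 over 300 replicate
regions).

**Study conditions.** Validation regions use $m = 100$ variants,
$\rho = 0.5$, allele frequency 0.3, $n = 10{,}000$ per trait and causal
non-centrality $\lambda = 7$ — a clearly powered but not overwhelming
signal, with the H3 causal pair placed 40 AR(1) steps apart
($r^2 \approx 10^{-24}$, far below the 0.2 de-correlation requirement).
Under these conditions the modal classification recovers the generating
hypothesis in well over 85% of regions for H0/H1/H2/H4 and over 70% for
H3 (observed ~95–100%; see `scripts/acceptance.R`).

**What the generator does not emulate.** Real human LD panels (block
structure, long-range LD), imputation uncertainty (INFO is fixed at 1),
population structure and confounding, relatedness, multi-causal regions,
indels and multi-allelic sites. Passing the validation suite therefore
demonstrates correctness of the statistical machinery under the stated
model, not robustness to those real-data complications; in particular
the single-causal-variant assumption is shared by the model and the
generator, so the tests cannot detect its violation.

## Numerical choices

* All Bayes-factor arithmetic is in log space and hypothesis masses are
  accumulated with log-sum-exp: signals of $|z| \approx 20$
  (p $\sim 10^{-18}$, as in strong biobank hits) overflow linear space.
* The $H_3$ sum over distinct pairs is enumerated exactly over the
  off-diagonal of the $m \times m$ log-sum grid for $m \le 300$; the
  algebraically equivalent subtraction
  $\sum_i \sum_j - \sum_{ii}$ loses ~6 digits when one variant dominates
  both traits, which is precisely the interesting H4 regime. Beyond
  $m = 300$ the subtraction identity with a guarded `log1p` is used.
* An exhaustive-enumeration oracle (`brute_force_coloc`, deliberately
  naive, linear-space, $O(m^2)$, refuses $m > 12$) provides an
  independent recomputation; agreement is verified to relative error
  below $10^{-10}$ on random regions.
* Exact posterior ties in top-variant selection break by position then
  id; proxy ties likewise. Degenerate inputs error loudly: constant
  genotype columns, collinear covariates, perfectly separated logistic
  fits, zero residual variance, zero lung effect in direction
  assessment, empty variant intersections.
* The perfect-fit rule and the noise-free recovery guarantee meet in the
  middle: an exactly perfect fit (residual sum of squares at rounding
  level relative to the total) is an error rather than `se = 0`, while
  near-noiseless data recover the generating effect far beyond
  statistical precision.
* LD values are clipped to $[-1, 1]$ on read, warning past
  $1 + 10^{-6}$; the simulator repairs almost-PSD matrices by a small
  diagonal inflation, then an eigenvalue clip, and refuses matrices with
  eigenvalues below $-0.05$.
* Strand-ambiguous (A/T, C/G) variants are dropped during alignment when
  the minor allele frequency in either trait exceeds 0.4, where
  frequency cannot resolve strand; the scope is biallelic SNVs only.

## Design decisions that were genuinely open

* **Association stand-in.** The per-variant covariate-adjusted
  `lm`/`glm` regressions are statistically equivalent, at simulated
  scale without relatedness or polygenic background, to the whole-genome
  ridge/LOCO machinery a biobank GWAS would use; the latter is out of
  scope by design.
* **Coordinates** are 1-based inclusive (the common summary-statistic
  convention); region flank defaults to 0 ("within gene boundaries") and
  is configurable.
* **Replication test count** `m_tests` is explicit input. Published
  analyses counted 9 (FinnGen) and 18 (CKB) gene–trait tests; how such
  counts are constituted varies, so inferring them silently would hide
  an analysis choice.
* **Wald p-values** throughout (not likelihood-ratio), matching how
  summary statistics are published.
* **Fixture scale.** The packaged per-hypothesis fixture regions default
  to 50 variants with $\lambda = 8$, decisive enough that fixture-driven
  tests are not flaky, small enough to regenerate in milliseconds.

## Known limitations

Single causal variant per trait per region (no SuSiE-style multi-signal
decomposition, no conditional analysis, no credible sets); no GWAS-VCF
or binary genotype formats; no liftover or dbSNP integration; the prior
effect scales are global per trait type rather than per trait; the
direction assessment presumes the lung and cardiovascular records refer
to the same variant (guaranteed by the pipeline's anchoring, but a
caller using the function directly must ensure it).
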