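---
title: "Triage of plasma-protein drug targets by two-sample Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of plasma-protein drug targets by two-sample Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtriage)
```

## The problem

Circulating proteins are attractive drug targets: they are measurable,
druggable, and causally proximal to disease. Observational protein-disease
associations are confounded, so this package uses genetic variants that
regulate a protein's plasma level (cis-pQTLs) as instrumental variables:
if variants that raise the protein also raise disease risk, and the usual
instrumental-variable assumptions hold, the protein is causally upstream of
the disease. The package implements the full evidence chain a
proteome-wide target triage needs — not just a point estimate, but
replication, directionality, colocalization, external validation, and a
final four-tier grade per protein-outcome pair.

All computation runs on GWAS summary statistics; no individual-level data
are touched. The unit of data is one variant's association record
(`variant_id`, alleles, EAF, beta, SE, p, N) inside a `summary_dataset`.

## The causal model and the estimator suite

For instrument $j$, let $\hat\gamma_j$ (SE $\sigma_{xj}$) be its effect on
the protein (SD units per allele) and $\hat\Gamma_j$ (SE $\sigma_{yj}$) its
effect on the disease (log-odds per allele). Under a linear causal effect
$\theta$ and instrument validity, $\Gamma_j = \theta\,\gamma_j$. The suite
in `mr_fit()`:

* **Wald ratio** (1 SNP): $\hat\theta = \hat\Gamma/\hat\gamma$, first-order
  SE $\sigma_y/|\hat\gamma|$ (a second-order delta-method SE is available).
* **IVW** ($\ge 2$): weighted regression of $\hat\Gamma$ on $\hat\gamma$
  through the origin with weights $1/\sigma_{yj}^2$. By default the SE is
  inflated by $\max(1,\sqrt{Q/(J-1)})$, the multiplicative-overdispersion
  model with a fixed-effect floor. This default is deliberately
  conservative: under a pure null its 95% CI covers slightly more than 95%
  (about 96% in our calibration runs), which is why the calibration checks
  in the test suite exercise the exact fixed-effect variant
  (`scale_overdispersion = FALSE`).
* **MR-Egger** ($\ge 3$): WLS of $\hat\Gamma$ on $\hat\gamma$ with a free
  intercept after orienting every instrument to $\hat\gamma_j \ge 0$. The
  intercept estimates directional pleiotropy; the slope is the adjusted
  causal effect.
* **Weighted median** ($\ge 3$): the 0.5 quantile of the Wald-ratio
  distribution weighted by $\hat\gamma_j^2/\sigma_{yj}^2$, using
  midpoint-standardized cumulative weights $(S_j - w_j/2)/S_J$ with linear
  interpolation; consistent while instruments carrying $>50\%$ of the
  weight are valid. Its SE comes from a seeded parametric bootstrap.
* **MR-PRESSO** ($\ge 4$): the observed weighted residual sum of squares
  about leave-one-out IVW predictions is compared with a seeded parametric
  null; per-instrument empirical p-values are Bonferroni-corrected and
  flagged outliers are removed before an IVW re-fit.
* **Profile score (RAPS-style)** ($\ge 2$): solves
  $\sum_j (\hat\Gamma_j - \theta\hat\gamma_j)\hat\gamma_j /
  (\sigma_{yj}^2 + \theta^2\sigma_{xj}^2) = 0$ by root bracketing on
  $[-10, 10]$, accounting for exposure measurement error (weak
  instruments); the SE is the profile-score information, which reduces to
  the fixed-effect IVW SE when $\sigma_x = 0$.

The reporting policy (`choose_estimate()`) prefers IVW; it switches to the
MR-Egger slope when the Egger intercept is significant at $\alpha = 0.05$,
and to the MR-PRESSO-corrected estimate when the global test is significant
and outliers were identified. Discovery p-values are Benjamini-Hochberg
corrected across proteins within each outcome (q < 0.05).

```{r fit-example}
sim <- simulate_instruments(sim_config(theta = 0.3, seed = 7))
fit <- mr_fit(sim$exposure, sim$outcome, seed = 7)
summary(fit)
```

## Instrument selection and harmonization

`select_instruments()` applies, in order: the cis filter (position within
1 Mb of the gene body, closed interval — the convention adopted here since
"1 Mb up- or downstream of the gene" does not distinguish TSS from gene
body), genome-wide significance ($p < 5\times10^{-8}$), and exclusion of
the extended MHC region (chr6:26-34 Mb, closed, any overlap). LD pruning
(`ld_clump()`) is greedy by ascending p-value with lexicographic
variant-id tie-break (so results are order-invariant), accepting a variant
only if $r^2 < 0.001$ against everything already accepted.

`harmonize()` aligns outcome to exposure effect alleles, resolving swaps
and strand complements by sign/frequency flips. Palindromic variants (A/T,
C/G) carry no strand information in their allele codes; they are kept only
when the allele frequency is decisive — EAF outside $(0.42, 0.58)$, the
common two-sample-MR margin — and are then strand-aligned by frequency
concordance. Records with missing EAF fail the palindrome check and are
dropped only if palindromic.

## Directionality and exclusion

The Steiger test compares instrument variance explained on the two sides
using $r^2 = z^2/(z^2 + n - 2)$ per variant (no EAF needed, valid for
binary traits), summed over the clumped — hence approximately independent
— instruments, with a Fisher-z independent-samples comparison (exposure
and outcome cohorts do not overlap here). Reverse MR re-runs the full
suite with disease as exposure at a stringent corrected threshold
($p < 0.01$). A pair is excluded only when both alarms fire: Steiger fails
to support the forward direction *and* reverse MR is significant.

## Replication meta-analysis

Per-cohort estimates — reconstructed from printed OR (95% CI) cells via
$\mathrm{se} = (\ln U - \ln L)/(2z_{0.975})$ with $z_{0.975} = 1.959964$
when raw values are unavailable — are pooled by fixed-effect inverse
variance. Heterogeneity uses $I^2 = \max(0, (Q - \mathrm{df})/Q) \cdot
100$; strictly above 50% the DerSimonian-Laird random-effects model is
used instead (moment estimator of $\tau^2$; REML is not implemented).
Replication passes when the pooled p-value is below 0.05 with the same
sign as discovery — a criterion we fixed from the observed pass/fail
behaviour of the published replication table, since no explicit rule is
stated there.

```{r meta-example}
galk1 <- cohort_estimates(c("discovery", "replication"),
                          or = c(0.7228, 0.5958),
                          lower = c(0.6363, 0.4337),
                          upper = c(0.8211, 0.8184))
meta_analyze(galk1)
```

## Colocalization

`coloc_abf()` implements single-causal-variant Bayesian colocalization
from per-SNP Wakefield approximate Bayes factors,
$\log \mathrm{ABF} = \tfrac12\log\frac{V}{V+W} + \frac{z^2 W}{2(V+W)}$,
with priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ and prior effect SD
0.15 for quantitative and 0.2 for binary traits (the cited method's
conventional defaults; only the configuration priors are published). All
hypothesis sums are accumulated in log space with log-sum-exp — regional
z-scores of 40 would overflow linear space. A region "colocalizes" when
$PP_{H4} > 0.8$ strictly. The implementation is checked against an
exhaustive enumeration over all $(M+1)^2$ causal configurations on small
regions (agreement to $10^{-10}$).

## External validation, PPI and tiering

TWAS/PWAS-style external evidence uses the weighted-score statistic
$z = w^\top z_{\mathrm{gwas}} / \sqrt{w^\top \Sigma w}$ and passes at FDR
q < 0.05 on either the transcript or the protein branch; an absent panel
entry fails its branch. Direction concordance is a configurable
requirement defaulting off, because the published evidence table applies
it inconsistently. PPI drug-target linkage requires a *direct* edge with
interaction score $\ge 0.4$; path-based linkage deliberately does not
count.

`assign_tier()` evaluates, in order: Excluded (directionality);
Tier 1 = colocalization AND replication AND external; Tier 2 = PPI linkage
AND (replication OR external); Tier 3 = colocalization AND (replication OR
external OR PPI); Tier 4 otherwise. Tier 3 is read conjunctively
(colocalization is required); grading is total and monotone — upgrading
any single piece of evidence never demotes a protein.

## The synthetic-data generators

No real pQTL or biobank GWAS data ship with the package; seeded
generators (pure functions of their configuration, seed included)
emulate their statistical structure:

* `simulate_instruments()`: EAF uniform on (0.1, 0.9); true effects
  $\gamma_j$ with random sign and magnitude $\sim N(\mu_\gamma,
  \mathrm{gamma\_sd}^2)$, $\mu_\gamma$ set so the expected exposure
  z-statistic is about 8 at the least-informative frequency —
  pre-selected, genome-wide-significant instruments; per-allele SEs
  $1/\sqrt{2f(1-f)n}$ (quantitative) and $1/\sqrt{2f(1-f)n \cdot 0.25}$
  (binary, balanced-design variance factor). Defaults use an exposure
  panel of 7,213 and an outcome GWAS of 449,500 — the scale of the
  pQTL/biobank studies this pipeline targets. Pleiotropic shifts
  $\alpha_j$ act along the exposure-increasing allele, so a non-zero
  `alpha_mean` is directional in the oriented frame MR-Egger works in
  (applied to the raw allele coding it would cancel under orientation and
  no estimator could recover it).
* `simulate_cohorts()`: shared $\gamma_j$, cohort-specific
  $\theta_k \sim N(\theta, \tau^2)$, independent noise.
* `simulate_coloc_region()`: AR(1) LD $\Sigma_{ij} = \rho^{|i-j|}$,
  marginal z-vector $\sim \mathrm{MVN}(\Sigma\lambda, \Sigma)$ with the
  causal configuration of the requested hypothesis (H0-H4).
* `simulate_twas_weights()`: sparse weights over an AR(1) LD block; under
  `causal = TRUE` the weighted-score statistic is given noncentrality
  $6\sqrt{h^2/0.1}$ — a calibration choice (no published effect-size scale
  exists for this layer), set so that power at $h^2 = 0.1$ is essentially 1.
* `simulate_ppi_graph()`: Erdős–Rényi edges with uniform scores.

What the generators do **not** emulate: realistic MAF spectra, LD beyond
AR(1), sample overlap between exposure and outcome, winner's-curse
selection of instruments, and multi-causal-variant regions. Tests passing
on these generators therefore demonstrate correctness of the estimators
and decision logic under the stated models, not robustness to every
pathology of real GWAS data.

## Numerical choices and problem sizes

The 95% normal quantile is fixed at 1.959964 so CI reconstructions are
stable; p-values are floored at $10^{-300}$; the profile-score root is
bracketed on $[-10, 10]$ (log-OR per SD outside that range is not
biologically meaningful); MR-PRESSO and the median bootstrap default to
1,000 seeded draws. Degenerate inputs fail loudly: zero exposure effect in
a Wald ratio, an LD matrix missing a variant, weights with
$w^\top\Sigma w \le 0$, an MR-PRESSO run that flags essentially all
instruments.

The packaged calibration studies use 2,000 null replicates of 50
instruments (test size and coverage), 500 replicates for the
invalid-instrument and Egger-recovery studies, 200 for MR-PRESSO flagging
and coloc H4 power, and 500 for the false-exclusion rate — sizes chosen so
Monte-Carlo error is well inside each property's decision band while the
whole suite runs in well under a minute.

## Known limitations

Only univariable MR (no multivariable or contamination-mixture
estimators); single-causal-variant colocalization (no SuSiE-style
extension); DerSimonian-Laird only for random effects; no winner's-curse
correction; no proxy-SNP lookup or reference-panel LD estimation; the
published per-protein posterior probabilities are not reproducible without
the real regional data, so colocalization is validated against enumeration
and scenario power instead.
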