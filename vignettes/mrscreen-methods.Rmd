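---
title: "Methods: two-sample MR screening, colocalization and network discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening, colocalization and network discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

`mrscreen` screens many exposures (for example circulating proteins,
immune-cell features or metabolites) against a disease outcome with
two-sample Mendelian randomization, then follows up hits with Bayesian
colocalization and dense-subnetwork discovery. This vignette records the
statistical model behind each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the design decisions taken where more than one convention exists.

## The two-sample MR model

Each instrument is a genetic variant j with an estimated per-allele effect
$\hat\gamma_j$ (SE $s_{xj}$) on the exposure in one cohort and
$\hat\Gamma_j$ (SE $s_{yj}$) on the outcome in a second, non-overlapping
cohort. Under the instrumental-variable assumptions (relevance, no
confounding of the variant–outcome relation, and effect on the outcome
only through the exposure), each ratio
$\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$ estimates the causal effect
$\theta$, on the log-odds scale when the outcome is binary.

### Instrument selection

- **Association threshold**: variants with exposure p-value `< 5e-6`
  (strict inequality) are candidates.
- **LD clumping**: greedy thinning, best remaining p first (ties broken by
  variant id so runs are reproducible), removing candidates on the same
  chromosome within a 10,000-kb window (closed interval, centre to centre)
  whose squared correlation with the index variant is at least 0.001.
  Pairs missing from the supplied LD matrix count as independent and are
  tallied with a warning; `ld = NULL` declares all pairs unlinked.
- **Strength filter**: per-variant
  $R^2 = 2\beta^2p(1-p)\,/\,(2\beta^2p(1-p) + 2\,SE^2Np(1-p))$ and
  $F = R^2(N-2)/(1-R^2)$; instruments with $F \le 10$ are removed. The
  frequency factor cancels algebraically, so $R^2$ reduces to
  $\beta^2/(\beta^2 + SE^2 N)$; variants lacking a frequency are still
  excluded because their record is incomplete.

### Harmonisation

Outcome effects are re-expressed on the exposure's effect allele: direct
matches are kept, swapped alleles flip the outcome beta and frequency, and
strand differences in non-palindromic pairs are bridged by complementing
both outcome alleles. Palindromic pairs (A/T, C/G) carry no strand
information in their labels, so orientation is taken from allele
frequency: if both frequencies lie outside the ambiguity band
(default [0.42, 0.58]) the minor/major side decides the alignment;
otherwise — including when either frequency is missing — the variant is
removed. Every removal is tallied by reason, and the accounting identity
(input = usable + removed per category) is asserted in the tests. The band
is a configuration knob because toolchains differ; 0.42–0.58 is the common
default.

### Estimators

With first-order delta-method weights $w_j = (s_{yj}/|\hat\gamma_j|)^{-2}$
(a second-order option adds the exposure-noise term):

- **Wald ratio** (single instrument): $\hat\Gamma/\hat\gamma$, SE
  $s_y/|\hat\gamma|$, normal p.
- **IVW** (primary, 2+ instruments): precision-weighted mean of ratios.
  Cochran's Q (against the fixed-effects estimate, chi-square with n−1 df)
  decides the error model: p < 0.05 switches to a multiplicative
  random-effects SE, the fixed SE times $\sqrt{\max(1, Q/(n-1))}$; the
  floor at 1 guarantees the random-effects SE is never smaller than the
  fixed one.
- **MR-Egger** (3+ instruments): weighted least squares of outcome on
  exposure effects with a free intercept, weights $1/s_{yj}^2$, after
  orienting every pair so the exposure effect is non-negative (the
  intercept is only interpretable under a fixed orientation). The
  intercept estimates average directional pleiotropy. SEs are taken from
  the weighted regression as-is — the multiplicative error model, residual
  SD scaling included — with t tests on n−2 df. Some MR toolchains
  additionally floor the residual SD at 1; we do not, because the
  unfloored test is exactly calibrated when instruments are valid
  (measured type-I error 0.046 at 2000 null replicates, versus 0.035 with
  the floor), while overdispersion from pleiotropy still inflates the SE
  through the residual SD.
- **Weighted median** (3+ instruments): the ratio at cumulative normalized
  weight 1/2, interpolating linearly between order statistics (each order
  statistic carries its weight centred on its cumulative mass, so three
  equal weights return the middle ratio exactly). Consistent while valid
  instruments hold over half the weight. Its SE comes from a seeded
  parametric bootstrap (default 1000 draws of each ratio from
  $N(\hat\theta_j, \sigma_j^2)$); the common alternative of resampling
  both effect estimates separately changes little and the simpler form
  keeps the bootstrap exactly reproducible from one seed.

Estimates are reported as OR with 95% CI using the normal multiplier
`qnorm(0.975)` = 1.959964.

### MR-PRESSO

The global statistic is the weighted residual sum of squares
$\sum_j w_j(\hat\Gamma_j - \hat\beta_{(-j)}\hat\gamma_j)^2$ with
$w_j = 1/s_{yj}^2$ and leave-one-out IVW slopes $\hat\beta_{(-j)}$
(weighted regression through the origin). The null distribution comes from
re-drawing outcome effects around their leave-one-out predictions
(default 1000 simulations); p-values use the add-one rule, so the smallest
attainable p is $1/(n_{sim}+1)$. Per-variant residual contributions are
compared with their simulated counterparts the same way, and variants
passing Bonferroni (p < 0.05/n) are reported as outliers. The distortion
test of the original method is deliberately omitted: the screen never
reports outlier-corrected estimates, only exclusion decisions; outlier
removal plus re-estimation is available as an explicit manual step.

### The pleiotropy gate and two-tier calling

An exposure is excluded from causal calling when the Egger intercept test
is significant at 0.05, or the MR-PRESSO global test is significant with
at least one unresolved outlier. The two diagnostics are combined
disjunctively because they capture different failure modes (systematic
directional bias vs. individual outliers); exposures with too few
instruments for a diagnostic pass the gate flagged untested. The gate runs
before FDR, and excluded exposures take no part in the FDR family — the
correction is computed over the exposures actually eligible for calling.
Benjamini–Hochberg adjustment (via `stats::p.adjust`) is applied within
each exposure family (e.g. proteins, immune cells, metabolites screened as
separate panels); a single pooled family is obtained by leaving the
`family` argument at its default. Tiers: `significant` (raw and adjusted
p < 0.05), `potential` (raw only), `null`, `excluded_pleiotropy`, and
`not_analyzable` for exposures with no surviving instruments (these are
always reported, never silently dropped).

### Colocalization

Per-variant evidence uses Wakefield's approximate Bayes factor: with
$V = se^2$, $W$ the prior effect variance and $z = \beta/se$,
$\log ABF = \tfrac12[\log(V/(V+W)) + z^2 W/(V+W)]$. Under a single causal
variant per trait, the five regional hypotheses H0–H4 have unnormalized
weights $1$, $p_1S_1$, $p_2S_2$, $p_1p_2(S_1S_2-S_{12})$, $p_{12}S_{12}$,
where $S_1, S_2, S_{12}$ are sums over variants of the trait-1, trait-2
and joint Bayes factors. All sums run in log space with log-sum-exp, so
regions of thousands of variants cannot underflow, and the cross term is
evaluated as $S_1S_2 - S_{12}$ via `log1p`; with a single shared variant
it is an empty sum and PP3 is exactly zero. Priors default to the
conventional $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$, prior effect SD
0.15 for quantitative traits and 0.2 (log odds) for binary traits; all are
arguments. PP.H4 > 0.75 is labelled strong colocalization. No
multi-signal conditioning is attempted; regions with several causal
variants per trait are outside the model.

### MCODE

Vertices are weighted by `k * density` of the highest k-core of the
induced subgraph on their closed neighbourhood (degree < 2 scores zero).
Complexes grow from unassigned seeds in decreasing weight order, adding
neighbours whose weight is at least the seed's times (1 − 0.2), breadth
first to depth 100; each node joins at most one complex. Candidates
without a 2-core are discarded; haircut iteratively prunes
singly-connected members (on by default, as in the reference plugin);
fluff is off. The complex score is the density of the member-induced
subgraph times its size. Every ordering decision (seed order, output
order) breaks ties lexicographically, so results are reproducible and
invariant to node-label permutation up to relabelling. Edges are
unweighted: any confidence filtering of the interaction network is the
caller's responsibility when building the edge list.

## The synthetic-data generator

`simulate_mr_pair()` draws, per variant, a frequency from `maf_range`
(default 0.05–0.5), a true exposure effect $\gamma_j \sim N(0,
\gamma_{sd}^2)$ (default SD 0.1), and observed effects with the analytic
SE $1/\sqrt{2Np(1-p)}$ of a unit-variance trait — scaled by
$1/\sqrt{cf(1-cf)}$ for a binary outcome (default case fraction 0.2),
whose effects are read as log odds ratios. Default sample sizes are
100,000 per cohort, typical of the biobank-scale GWAS this design
emulates. Direct (pleiotropic) effects $\alpha_j$ are attached to a
`prop_invalid` subset: none, balanced ($N(0, \alpha_{sd}^2)$) or
directional ($N(\alpha_{mean}, \alpha_{sd}^2)$). Directional effects
enter the outcome as $\mathrm{sign}(\gamma_j)\,\alpha_j$, i.e. per
exposure-increasing allele: the sign of an allele coding is arbitrary, so
a "shared direction" of pleiotropy is only well defined relative to the
allele that raises the exposure, and this convention makes the Egger
intercept estimate $\alpha_{mean}$ rather than averaging to zero under
re-orientation. A `palindrome_prob` fraction of variants (default 0.1)
receives A/T or C/G allele pairs, with frequencies placed inside the
ambiguity band with probability `ambiguous_prob` (default 0.3) so both
harmonisation branches are exercised. All randomness flows from one
integer seed; identical calls are bit-identical, and the caller's RNG
state is left untouched.

`simulate_coloc_region()` places causal variants per scenario (shared,
distinct, trait1-only, null) on a chain of variants with AR(1) LD
(default autocorrelation 0.9 between neighbours, 200 variants, effect
0.15, n = 50,000 per trait). True marginal effects are the causal effect
propagated through LD, and the sampling noise carries the same AR(1)
correlation — marginal estimates from one cohort are correlated like the
genotypes themselves ($\mathrm{Cov}(\hat\beta) \propto R$). An early
version of the generator drew independent noise per variant; that
overstates disagreement between neighbouring variants and misdirects a
noticeable fraction of strong shared-causal regions toward H3, so the
correlated model, which is the statistically correct one, replaced it.

`simulate_ld_blocks()` and `simulate_ppi_graph()` build block-diagonal
correlation matrices and planted-clique interaction graphs with known
memberships.

What the generator does **not** emulate: realistic human LD maps and
block structure, allele-frequency spectra, variant–gene annotation,
sample overlap between cohorts, winner's-curse selection of instruments
from the same data, and multi-signal regions. Passing tests therefore
demonstrate correctness of the machinery under the stated model, not
robustness to every pathology of real GWAS data.

## Simulation sizes used by the checks

The test suite runs the calibration studies at 1000 replicates for IVW
recovery and coverage (true effect 0.3, 30 variants, n = 100,000 per
cohort), 2000 for type-I error of IVW and the Egger intercept, 500 for
weighted-median robustness (40% invalid instruments, directional direct
effects of mean 0.1) and Egger-intercept recovery (constant direct effect
0.05), 200 for MR-PRESSO (planted ten-sigma outlier, and null), 200 per
colocalization scenario, and 50 end-to-end screens of 20 exposures
(3 causal). `scripts/acceptance.R` recomputes the same quantities at
150–800 replicates per study, sizes chosen so a complete run finishes in
a couple of minutes on one CPU while keeping Monte-Carlo error well below
the margins of interest.

## Known limitations

- First-order ratio SEs ignore exposure-side noise; with weak instruments
  (F near the threshold) weights are optimistic. The second-order option
  exists but is not the default, matching common practice.
- The fixed/random IVW rule and the pleiotropy gate are hard 0.05
  switches; no smooth model averaging.
- Colocalization assumes one causal variant per trait and takes the
  variant intersection of the two traits as the region.
- The reverse screen reuses the forward machinery per outcome; it does
  not model exposure–outcome sample overlap.
- Steiger directionality filtering, multivariable MR and mode-based
  estimators are out of scope.
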