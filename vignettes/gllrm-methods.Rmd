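---
title: "Graphical log-linear Rasch models for scale validation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graphical log-linear Rasch models for scale validation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

The package implements conditional inference for polytomous Rasch
measurement. A person $v$ with latent trait $\theta_v$ answers items
$i = 1,\dots,k$ in ordered categories $y_i \in \{0,\dots,m_i\}$. The base
model is the Partial Credit Model (PCM): the log-probability of a response
vector is, up to normalization,

$$\log P(Y = y \mid \theta) \;\propto\; \sum_i \big(\alpha^i_{y_i} + y_i\,\theta\big),$$

with item-category parameters $\alpha^i_y$ ($\alpha^i_0 = 0$). Its defining
property is that the total score $R = \sum_i y_i$ is sufficient for
$\theta$: conditional on $R$, the response distribution is free of the
person parameter, which is what makes conditional maximum likelihood (CML)
estimation and all the conditional diagnostics below possible.

Real health-science scales routinely violate two PCM assumptions: responses
to some item pairs remain associated after conditioning on the trait
(*local dependence*, LD), and some items work differently across exogenous
groups at equal trait level (*differential item functioning*, DIF). The
Graphical Log-linear Rasch Model (GLLRM) keeps the Rasch skeleton and adds
log-linear interaction terms for exactly these two departures:

$$\log P(Y = y \mid \theta, C = c) \;\propto\;
  \sum_i \big(\alpha^i_{y_i} + y_i\theta\big)
  + \sum_{\{i,j\}\in \mathrm{LD}} \lambda^{ij}_{y_i y_j}
  + \sum_{(i,g)\in \mathrm{DIF}} \delta^{ig}_{y_i c_g}.$$

Both interaction types are *uniform*: $\lambda$ and $\delta$ do not depend
on $\theta$. Under uniform LD the total score stays sufficient; under
uniform DIF it stays sufficient within the subgroups defined by the DIF
covariates — which is why DIF-affected total scores can be equated across
subgroups through a conversion table instead of discarding the items.

## Conditional estimation

All estimation conditions on the total score. The normalizing constants are
elementary symmetric functions (ESF)
$\gamma_r = \sum_{y:\,\Sigma y_i = r}\exp\big(\textstyle\sum_i \alpha^i_{y_i} + \dots\big)$,
computed by the standard recursion over items, strictly in log space with
log-sum-exp updates (compiled code; stability is exact by construction, no
scaling heuristics). An LD pair is treated as one composite "super-item"
block whose cells are the $(m_i+1)(m_j+1)$ category combinations; DIF
enters through covariate-profile-specific block weights. Because the
dependence graph consists of disjoint pairwise cliques, the ESF recursion
over blocks is an *exact* evaluation of the conditional likelihood at any
scale — the same quantities one would get by enumerating all response
patterns, which the test suite verifies against brute-force enumeration on
small instances. (A dual enumeration engine was considered and rejected:
the two paths are mathematically identical, and a second production path
adds risk without adding capability.)

The conditional log-likelihood is concave in the log-linear parameters. The
block log-weights are affine in the free parameters, so each evaluation
reduces to two small matrix products plus one compiled ESF pass per
covariate profile; BFGS with analytic gradients is followed by Newton
polishing. Convergence is declared when the gradient max-norm falls below
`1e-6` *per used observation* (floored at the objective's machine-precision
limit): an absolute `1e-6` is below the numerical noise floor of a
log-likelihood of magnitude $10^4$, where no optimizer step can move the
objective.

Identification: $\alpha^i_0 = 0$ per item; one global sum-zero constraint
on the item locations (the gauge direction $\alpha^i_y \to \alpha^i_y + d\,y$
leaves every conditional probability unchanged); interaction grids are
corner-constrained at category 0 and at the reference covariate level.
Never-observed categories are collapsed with the adjacent lower category
(recorded and reported). Free-parameter counts are then
$\sum_i m_i - 1$ for the PCM — 55 for fourteen five-category items, 27 for
seven — plus $m_i m_j$ per LD pair and $m_i(G-1)$ per DIF term.

### Sparse-cell stabilization

Interaction cells (and, in subgroup refits, any parameter) supported by
fewer than `min_count = 5` observations are not estimated: they are fixed
at zero (flagged) or, in subgroup refits, pinned at the pooled estimates.
This departs from a fix-only-empty-cells rule deliberately. Null
simulations (800–1000 replicates, $n = 1000$, five 5-category items)
showed that estimating log-linear parameters from a handful of
observations makes the likelihood-ratio statistics heavy-tailed: the
homogeneity CLR test rejected at 0.061–0.10 instead of 0.05 (subgroup
refits that hit never-observed categories rejected at 0.26, a boundary
artifact), and the LD Kelderman test at 0.09–0.10. With the min-count rule
the measured sizes are 0.042–0.056 across all five test families, with
power at the study's effect sizes unchanged (1.00 at a calibrated partial
gamma of 0.2, $n = 3000$). The threshold follows the usual
expected-count-of-five rule of thumb for sparse categorical tables.

## The diagnostic battery

**Overall fit and global DIF (CLR).** The conditional likelihood-ratio
test compares the pooled fit against group-wise fits:
$\mathrm{CLR} = 2(\sum_g \hat\ell_g - \hat\ell)$, $\chi^2$ with
$\sum_g \mathrm{df}_g - \mathrm{df}$ degrees of freedom. Groups are the
lower/higher halves of the score distribution (split at the median, ties to
the low group — a balanced split maximizes power; the rule is configurable)
or covariate levels. Group refits retain the pooled LD/DIF structure; DIF
terms on the splitting covariate are dropped inside its groups since the
covariate is constant there. The df is reported from this arithmetic;
no attempt is made to mimic any particular software's df conventions.

**Conditional item fit.** Residuals are standardized against the exact
conditional moments given $(R, C)$: outfit is the mean squared standardized
residual, infit the information-weighted version; both have expectation 1
under the model. Their reference distribution is a parametric bootstrap
that redraws patterns conditional on each person's observed score *and
re-solves the CML equations on every replicate* (chord–Newton steps reusing
the observed information). The refit matters: without it the observed
statistic is adaptively closer to its expectation than the replicates are,
and the measured test size drops to 0.01–0.03; with it, 0.041–0.042.
P-values are two-sided bootstrap percentiles (the null distribution is
right-skewed).

**LD/DIF screening (Kelderman LR).** Each candidate uniform term is tested
by the likelihood ratio between the augmented and the current model, df =
number of added free interaction parameters ($m_i m_j$, or $m_i(G-1)$,
minus pinned sparse cells). Screening families are BH-adjusted per
iteration; item-fit p-values are BH-adjusted over the item family the same
way.

**Effect sizes (partial gamma).** LD magnitude is the Goodman–Kruskal
gamma between the pair within strata of each restscore, pooling concordant
and discordant pair counts across strata (Davis-type aggregation), reported
in both stratification directions and as their mean. The pooled-count
aggregation replaces inverse-variance weighting of per-stratum gammas,
which is ill-posed whenever a stratum is degenerate (gamma $\pm 1$ has zero
asymptotic variance). DIF magnitude is the analogous total-score-stratified
gamma between item and covariate. SEs use the Goodman–Kruskal asymptotic
formula accumulated across strata.

**Dimensionality.** Two fitted subscale models are compared through the
gamma correlation of their total scores: the observed gamma against the
gamma expected if one common trait drove both subscales. The expected value
is Monte Carlo (200,000 simulated persons by default): one standard normal
draw per person is mapped into each subscale's latent metric through its
estimated person distribution — operationalizing "same trait up to the
subscales' different metrics" — and responses are simulated from the
fitted models, covariate profiles drawn with their observed joint
frequencies. The test is one-sided: a weaker observed than expected
correlation rejects unidimensionality.

## Person-side quantities

Warm's weighted maximum likelihood (WML) estimator maximizes
$r\theta - \log D(\theta) + \tfrac12 \log I(\theta)$ and is finite at the
extreme scores; $I(\theta) = \mathrm{Var}(R \mid \theta)$ is the test
information, with LD pairs contributing through their joint block
distribution. The targeting index is
$E_{\theta\sim \hat F}[I(\theta)] / \max_\theta I(\theta)$, and the target
score is the expected total score at the information maximum (the
alternative reading — the score whose WML estimate sits at the maximum —
is nearly identical here; the label in all outputs states which is
computed).

The person distribution $\hat F$ (normal per DIF subgroup) is estimated by
matching the observed total-score mean and variance to the model-implied
mixture moments. Fitting a normal to WML point estimates was tried first
and rejected: WML estimates shrink toward the center at extreme scores and
carry measurement noise, and their SD misestimates the latent SD (measured
1.33 against a generating 1.4), which propagates into the expected-gamma
of the dimensionality test and into reliability.

Reliability is Cronbach's alpha when items are locally independent, and
otherwise a Monte Carlo estimate $\mathrm{Var}(E[R\mid\theta]) /
\mathrm{Var}(R)$ that simulates from the fitted model *including its LD
terms* — so it is not inflated by local dependence the way alpha is; with
DIF it is computed per subgroup. A quadrature study of the population
quantities showed that alpha's LD inflation interacts with its ordinary
lower-bound slack: for items with spread locations the two nearly cancel
(gap $\approx 0.002$), for parallel items the inflation is clean
($\approx 0.009$ at a rank-one LD scalar of 0.35–0.5), and at extreme LD
(scalar 0.8) the tau-inequivalence induced by the pair flips the sign. The
reliability-ordering checks therefore use parallel items at scalar 0.5. Person separation is the probability that
two random persons' total scores rank them like their true traits (ties in
scores count half; trait ties have probability zero under a normal
distribution — the half-credit convention is a documented choice). Both
are bit-reproducible under a fixed seed.

**DIF score adjustment.** For each subgroup and observed score, the trait
is WML-estimated under the subgroup's item parameters and converted to the
expected total score under the reference subgroup's parameters (LD terms
included). The reference group maps to itself; adjusted scores are reported
unrounded with a rounded companion column, because rounding before
aggregation destroys the observed/adjusted/bias decomposition. When DIF is
present, subgroup comparisons of unadjusted total scores are invalid; the
conversion table is the supported route.

**Criterion validity.** Kendall's tau-b (tie-corrected — Likert scores are
heavily tied; the untied variants differ materially here).

## The stepwise pipeline

Per subscale the loop is: fit → item fit → screen all candidates →
(a) if an item misfits (BH-adjusted infit p below $\alpha$), try the
strongest surviving candidate terms — those involving the item first, then
the strongest overall (up to 5) — and keep the first whose addition renders
the item's fit acceptable; trying non-involving terms matters because fit
statistics are relative to the whole item set, so unmodelled LD/DIF
elsewhere surfaces as spillover misfit of clean items; (b) if none does,
an item is excluded and the term set reset — the exclusion target is the
worst significantly *under*-discriminating item when one exists (the
poor-measure signature; over-discrimination usually reflects LD that later
terms absorb), otherwise the focal item; terms are always tried before
exclusions; (c) with no misfit, add the single most
significant surviving term (ties by larger absolute partial gamma);
(d) stop when nothing survives screening, no item misfits, and the
homogeneity and global-DIF CLR tests — BH-adjusted as one family, like
every other test family in the procedure — are all non-significant (an
unadjusted triple gate wrongly rejects a correct model in ~14% of
replicates). Exclusion
and term budgets are enforced; exhausting them yields an explicit
"no admissible model" verdict, never a silent pass. One item is removed
per iteration (batched removals are ambiguous to attribute). With a fixed
configuration seed the whole decision path is a pure function of the data.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
every other module is validated against. The default scenario emulates a
national-survey administration of the 14-item instrument: $n = 3857$;
female prevalence 0.619 and technical/university education 0.675; two
latent traits (stress, control) with correlation $-0.794$, calibrated so
the reverse-scored stress subscale and the control subscale correlate at
gamma $\approx 0.527$; uniform LD (items 1–2; items 7–10) and uniform DIF
(items 1 and 3 by sex, item 1 by education on the stress side; items 10
and 6 by sex and item 10 by education on the control side) injected as
rank-one interactions ($\lambda_{ab} = \lambda_0 ab$) whose scalars were
bisected against large-sample realized partial gammas (tolerance 0.005,
150,000 persons per evaluation, two sweeps because terms sharing an item
interact) to the targets +0.18, +0.24, +0.33, −0.14, +0.22, −0.23, −0.15,
−0.17, stratified over the post-exclusion item sets. Rank-one interactions
make the gamma-calibration monotone and well-posed; the *fitting* side
always estimates the full unconstrained grids.

Items 12 and 8 (stress) and 9, 13, 4 and 5 (control) under-discriminate:
they are generated from a two-parameter flavored model with discrimination
multipliers 0.33–0.7 (generation only — fitting never uses a
discrimination parameter). This reproduces the flat observed item
characteristic curve of a poorly measuring item and gives the exclusion
loop realistic work. Thresholds use a wide-bottom/compressed-top spacing
with positive locations and trait SD 1.4, chosen once so the
post-exclusion subscales land near the reported score pattern (stress
means ≈ 7.5–9.6 of 0–20 with SD ≈ 3.9–4.3 and an information maximum near
score 13.5; control means ≈ 3.7–4.5 of 0–12) — a qualitative anchor, not a
numeric target. Latent mean shifts (women +0.267 SD units on stress;
tertiary-educated +0.34 on control) reproduce the direction and rough size
of the reported adjusted subgroup differences. Criterion-validity
correlates are continuous monotone transforms of the stress trait with
Kendall's tau set through the Greiner relation.

What the generator does *not* emulate: the survey's three-stage sampling
design and weights, non-normal trait distributions, missing data (the
emulated study had 0.0–1.3% item missingness and needed no imputation; the
loader and complete-case machinery handle missingness, but the default
scenario generates complete data), and any non-uniform (trait-dependent)
LD or DIF. Passing tests on these data therefore demonstrate correctness
of the machinery under the stated generating structure, not robustness to
survey-design artifacts or non-uniform departures.

## Problem sizes and reproducibility

The acceptance checks run at the study-scale conditions: exact-oracle
agreement on 3-item enumerable instances (tolerance $10^{-10}$); PCM
recovery over 20 seeds and GLLRM recovery over 5 seeds at $n = 3000$; test
calibration over 500 null replicates at $n = 1000$ against the exact
binomial band around $\alpha = 0.05$; detection power over 100 replicates
per effect at $n = 3000$; calibration round trips at 150,000 persons per
simulation with three-replicate-averaged evaluations and four-replicate
verification (partial-gamma estimates for the education-DIF terms carry a
sampling SE near 0.013 at 120,000 persons, so single-draw verification
would be dominated by Monte Carlo noise);
dimensionality and DIF-adjustment scenarios at $n = 3000$; and 25 stepwise
replicates of the decoy-recovery scenario at $n = 3857$.
`scripts/acceptance.R` recomputes the same quantities from scratch (400
null replicates, 60 power replicates per effect, 15 pipeline replicates,
the same calibration sizes) under a user-supplied seed. Measured
test sizes of 0.04–0.06 mean an honest calibration check against the
exact binomial band fails occasionally by design; the sizes themselves
are reported, not only the verdicts.

## Known limitations

- LD pairs must be disjoint (an item may belong to at most one pair);
  chained or higher-order dependence would require composite blocks beyond
  pairs, which uniform pairwise GLLRMs do not use.
- Non-uniform (trait-dependent) DIF and three-way interactions are out of
  scope.
- The LD Kelderman LR retains a mildly heavy tail at $n = 1000$ (measured
  size ≈ 0.056 at $\alpha = 0.05$); at $n = 3000$ it is nominal.
- In the decoy-recovery scenario, full term-set recovery is limited by the
  weakest generating term (DIF of item 1 by education at partial gamma
  −0.14): its Kelderman LR runs at roughly 16–25 on 4 df at $n = 3857$,
  which sits at the BH boundary of a ~20-candidate screening family, so the
  stepwise procedure misses it in roughly a fifth of replicates; measured
  full-recovery rates are ~70–85% across seed batches.
- The homogeneity CLR df arithmetic is the package's own
  ($\sum_g \mathrm{df}_g - \mathrm{df}$); reported dfs need not match
  other software whose grouping or df conventions differ.
- Pointwise information functions are not comparable across an LD-aware and
  an independence fit of the same data (different latent metrics); the
  supported comparison is scale-free (reliability, person separation).
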