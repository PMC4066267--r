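---
title: "Models and methods behind vagilong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vagilong}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vagilong analyses longitudinal 16S rRNA gene surveys of the vaginal
microbiota in pregnancy cohorts: repeated vaginal-fluid samples per
subject, a taxon-by-sample read-count table, and a two-group design
(term versus spontaneous preterm delivery). This vignette explains the
models the package fits, the choices behind their implementation, and
what the synthetic-cohort generator does and does not emulate.

## Community states and their dissimilarity

A *community state* is the vector of relative abundances of all
phylotypes in one sample. Dissimilarity between two states $p$ and $q$
is measured by the Jensen-Shannon divergence,

$$D_{JS}(p, q) = \tfrac12\left[D_{KL}(p, a) + D_{KL}(q, a)\right],
\qquad a = \tfrac{p + q}{2},$$

with $D_{KL}(p,q) = \sum_{i\,:\,p_i>0} p_i \log_2 (p_i/q_i)$. Base-2
logarithms are used throughout so that $D_{JS}$ lies exactly in
$[0, 1]$: 0 for identical states, 1 for states with disjoint support
(natural logs would bound it by $\ln 2 \approx 0.693$ instead). Terms
with $p_i = 0$ contribute zero, the limit of $x \log x$. Where $q$
lacks support, $D_{KL}$ is reported as `Inf` explicitly — never a
capped large number — while $D_{JS}$ is always finite because the
midpoint $a$ has support wherever $p$ or $q$ does. The square root of
$D_{JS}$ (the Jensen-Shannon *distance*) is a metric; the package
property-tests the triangle inequality rather than assuming it.

**Community state types (CSTs).** Samples are clustered on the pairwise
$D_{JS}$ matrix with the classical Ward criterion
(`stats::hclust(method = "ward.D")`), which treats the supplied
dissimilarities as squared-Euclidean surrogates, and the tree is cut at
`k = 3` by default. Both the divergence and its square root are exposed
as clustering metrics (`jsd` is the default) because either is a
defensible reading of the CST literature; `k` is a parameter because a
three-type structure is an empirical finding, not a law. Clusters are
labelled from their mean composition: a cluster whose total
*Lactobacillus* abundance falls below 0.5 is `IV-B` (diverse,
anaerobe-rich); otherwise the dominant indicator taxon decides
(*L. crispatus* → I, *L. iners* → III), and anything else is `other`.
The 6-type CST nomenclature is supported in the labels, but only I,
III and IV-B are expected in data of this design.

## The count-model ladder

Differential abundance is assessed one phylotype at a time by modelling
its read counts $y_{sj}$ (subject $s$, visit $j$) with a ladder of three
mixed-effects families sharing the linear predictor

$$\log \mu_{sj} = x_{sj}^\top \beta + \log N_{sj} + b_s,
\qquad b_s \sim \mathcal N(0, \sigma_b^2),$$

where $N_{sj}$ is the sample's total read count. The natural-log offset
makes the coefficients describe *relative*, not absolute, abundance; the
package verifies the contract that multiplying all totals by $c$ shifts
the intercept by $-\log c$ and leaves the group coefficient unchanged.

* **PLME** — Poisson observations; parameters $(\beta, \sigma_b)$.
* **NBLME** — negative binomial with size $k$ (variance
  $\mu + \mu^2/k$); parameters $(\beta, \sigma_b, k)$.
* **ZINBLME** — a point mass at zero with probability $\pi$ mixed with
  the NB component; parameters $(\beta, \sigma_b, k, \pi)$. The random
  intercept enters only the NB mean, never the zero-inflation logit,
  and $\pi$ is intercept-only: excess zeros are treated as a
  taxon-level detection property, not a covariate effect.

Only phylotypes present (at least one read) in 25% or more of the
samples are modelled; the boundary is inclusive. For each taxon all
three families are fitted and the smallest-AIC *converged* fit is
retained, with AIC $= 2\,\text{(parameters)} - 2\,\text{(log-likelihood)}$
and ties broken toward the family with fewer parameters. Taxa where no
family converges are reported unfit and excluded from the multiple-testing
family. The group coefficient of the retained fit (preterm minus term,
natural-log scale) is summarised by a normal-theory Wald interval and
converted to a signed fold change: $\exp(\hat\beta)$ for
$\hat\beta \ge 0$ and $-\exp(-\hat\beta)$ otherwise, so a decrease is
the fold-decrease magnitude with a minus sign (an estimate of $-0.864$
is a $-2.4$-fold change). p-values are Benjamini-Hochberg adjusted
across the modelled taxa (Benjamini-Yekutieli available), and a taxon is
called significant when $q < 0.1$ and $|\text{fold change}| > 1.5$.

### Likelihood evaluation and optimization

The marginal likelihood integrates the random intercept out of each
subject's contribution. The integral is evaluated by *adaptive*
Gauss-Hermite quadrature: a damped Newton search finds the per-subject
posterior mode of $b$, the local curvature rescales the node grid, and
25 nodes (configurable) are combined through log-sum-exp. Adaptive
centring matters because subjects with many observations concentrate
the integrand far from zero on the $b$ scale. Against dense-grid
trapezoid integration the kernel agrees to well below $10^{-6}$; the
test suite asserts that tolerance across all three families.

Maximization is quasi-Newton (`nlminb`) on an unconstrained scale
($\log \sigma_b$, $\log k$, $\operatorname{logit} \pi$) with analytic
gradients obtained from the Fisher identity (the posterior expectation
of the complete-data score, evaluated on the same quadrature grid).
Because the adaptive grid itself moves with the parameters, this
gradient is very slightly approximate; the optimizer's internal
false-convergence heuristic can therefore fire *at* the optimum.
Convergence is consequently judged by a direct optimality check — the
Newton decrement $\tfrac12 g^\top H^{-1} g < 10^{-2}$ with a
positive-definite observed information — rather than by the return code
alone. Starting values are moment-based (Poisson GLM coefficients,
method-of-moments $k$, half the observed zero fraction for $\pi$) plus
3 randomly jittered restarts by default. Standard errors come from the
inverse observed information (finite differences of the gradient), with
the delta method for the transformed parameters. Boundary solutions
($\sigma_b$ or $\pi$ at the edge) are flagged and their standard errors
computed from the reduced information with the boundary parameter
fixed. Wald intervals are normal-based; a $t$ reference with
subject-level degrees of freedom would widen them slightly at this
design size but the normal form matches the reporting convention the
fold-change arithmetic implies.

## Gestational-age trends

Trends are analysed in the term-delivery group only. Two complementary
analyses are run:

1. **Three windows.** The 5th and 95th percentiles of the sampled
   gestational ages are computed and the interval between them is
   trisected into equal-width windows; the outer windows extend to the
   observed minimum and maximum so every sample is covered. (This
   percentile-trisection-with-extension is the only construction
   consistent with describing the same interior cutpoints both from the
   full data range and from the percentile range.) Windows are closed
   on the left, open on the right, the last closed on both ends;
   cutpoints are rounded to 0.1 week for display only. The model ladder
   is fitted with the window as a three-level fixed factor, and the
   three pairwise contrasts (2v1, 3v2, 3v1) are extracted with their
   covariance-aware Wald tests, each contrast BH-adjusted across
   phylotypes at a 10% FDR.
2. **Continuous.** An NBLME (only) with orthonormal polynomial terms of
   gestational age (`stats::poly`, degrees 1-7), the degree chosen by
   AIC, and each polynomial term's p-value BH-adjusted across
   phylotypes *within* that term (term-1 p-values together, and so on);
   the wording of per-term adjustment is ambiguous between within-term
   and pooled, and within-term was chosen as the stricter reading.

A taxon's direction is `up`/`down` from the sign of its significant
contrasts (the 1v3 contrast takes precedence), `flat` otherwise. For
the polynomial analysis a monotone direction claim requires the
*linear* term itself to be significant, in which case its sign decides;
a significant quadratic or higher term alone is evidence that the taxon
is not constant, not that it moves in a direction, and such taxa are
classified `flat` for the up/down/flat summary. On
synthetic cohorts with planted monotone trends the two analyses agree
in sign, mirroring the confirmation role the continuous analysis plays.

## Shannon diversity

The Shannon Diversity Index, $-\sum_{p_i > 0} p_i \ln p_i$ (natural
log, the ecology convention), is computed per sample and compared
between groups with a Gaussian linear mixed model on $\log$ SDI with a
subject random intercept (`nlme::lme`). Monodominant samples are
common in CST I/III data and give SDI near zero, so values are floored
at $10^{-6}$ (configurable) before the log transform. Gestational age
can optionally be added as a fixed covariate; the default is
group-only. Raw-scale medians and IQRs accompany the model estimate.

## The synthetic cohort generator

`simulate_cohort()` provides ground truth for every stage. Its defaults
encode the study design: 72 term and 18 preterm subjects (delivery
around 39.6 and 30.5 weeks respectively), entry between 7 and 16 weeks,
protocol visits every 4 weeks until 24 weeks and every 2 weeks after,
and 99 taxa of which the 21 analysis phylotypes carry the named
profiles. Attendance is partial (each protocol visit kept with
probability 0.35, at least two per subject), reproducing the observed
median of ~4 visits per term subject and a cohort of roughly 250-450
samples. Depths are log-normal with median 7,548 reads and log-SD 0.42,
matching the reported depth quartiles.

Each subject draws one CST from the mixture (18.6% I, 58.5% III, 22.9%
IV-B) and keeps it for all visits — transitions are not modelled, by
design. A sample's composition is a Dirichlet draw (concentration 60)
around its CST profile, tilted by $\exp(\text{group effect} +
\text{GA slope} \times (\text{GA} - 26))$ and renormalized. Counts are
then drawn multinomially at the sampled depth from weights combining
the composition, a subject-by-taxon log-normal random intercept
($\sigma_b = 0.5$), per-taxon gamma multipliers (NB size $k = 2$) and a
structural-zero mask ($\pi = 0.05$ for *Lactobacillus*, 0.2 for named
anaerobes, 0.7 for rare fillers). Conditioning on the depth keeps the
library-size model exact while each taxon's marginal counts remain
approximately zero-inflated negative binomial with a log-total offset —
the structure the model ladder assumes.

Default effects are the null for the group comparison (all group
effects zero) and, for gestational age, +0.15/week for *L. crispatus*,
*L. jensenii*, *L. gasseri* and *L. vaginalis*, −0.15/week for the
eleven anaerobes reported to decline, and zero elsewhere. The slope
magnitude deserves a note: because compositions are renormalized, a
common tilt applied to taxa that jointly dominate a sample (the CST
IV-B anaerobes) largely cancels, so the realized relative-abundance
trend is substantially weaker than the planted coefficient.
±0.15/week was chosen so that the *realized* trends are of the clearly
detectable magnitude the study reports for these taxa at this sample
size; the planted direction labels remain the ground truth against
which recovery is scored.

One consequence of the design is worth spelling out: preterm subjects
stop contributing samples at delivery (before 34 weeks), so the two
groups have different gestational-age distributions. When
gestational-age trends are planted, this induces *marginal*
relative-abundance differences between the groups even with every group
effect set to zero — taxa that rise late in pregnancy are
under-represented in the preterm samples. The group comparison, which
(by design, matching its reporting convention) does not adjust for
gestational age, will correctly detect those marginal differences.
A cohort that is null *for the group test* therefore requires both the
group effects and the gestational-age slopes to be zero, and that is
the configuration the false-discovery-rate validation uses.

What the generator does **not** emulate: real attendance patterns
(thinning is independent per visit), CST transitions over pregnancy,
taxonomic misassignment or chimeric reads, batch effects, and any
dependence of sequencing depth on community composition. Passing
recovery tests on this generator therefore demonstrates that the
pipeline's inferential machinery is correct under its own assumptions,
not that those assumptions hold in any particular real cohort. Rare
taxa also acquire most of their zeros from the Dirichlet composition
step rather than the structural mask, so the configured $\pi$ is a
lower bound on a taxon's observed zero fraction.

## Problem sizes used in validation

The test suite validates the pipeline at the cohort scale of the
design: quadrature-versus-trapezoid likelihood checks on 21 small
instances across the three families; 100 NBLME parameter-recovery
simulations at 90 subjects with 2-6 visits (bias and coverage of the
group coefficient); 200 fully null cohort replicates through the
complete ladder-plus-BH procedure (empirical FDR); and one full
trend-recovery cohort scored against the planted 4-up/11-down/6-flat
pattern. The Monte-Carlo runs use 7-9 quadrature nodes and no extra
restarts — at these data sizes the adaptive rule is already accurate to
far better than the Monte-Carlo noise, and the moment-based start is
reliable — while single-fit examples use the 25-node default.

## Known limitations

* Wald inference is normal-based; with 18 subjects in the smaller group
  the intervals are mildly anticonservative.
* More consequentially, the subject random intercept is assumed
  Gaussian, while CST structure makes the true between-subject
  distribution of an anaerobe's abundance effectively two-point
  (present-high in IV-B subjects, near-floor otherwise). When the
  binomial draw of CST memberships happens to be imbalanced between
  groups — with 18 subjects in one group this is not rare — the
  parametric p-values substantially understate the permutation-level
  evidence, and the ladder-plus-BH procedure rejects more often than
  its nominal FDR under a group-exchangeable null. The package's own
  null-replicate validation measures this anticonservativeness rather
  than hiding it (an independent Laplace-approximate fit of the same
  models reproduces the same small p-values on such cohorts, so this
  is a property of the model class, not of this implementation).
  Practitioners worried about it should verify group findings with a
  subject-level permutation test.
* The AIC comparison assumes the candidate likelihoods are evaluated on
  the same data; unfit families simply drop out, which can bias family
  selection for taxa where the richer family fails numerically.
* The compositional nature of relative-abundance data means per-taxon
  offset models cannot distinguish a taxon's change from a compensating
  change in the rest of the community; the generator's renormalization
  dilution is the same phenomenon seen from the other side.
* CST labelling keys on *Lactobacillus* indicator taxa and will return
  `other` for clusters outside the I/III/IV-B repertoire.
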