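---
title: "Estimating migratory movement probabilities from band recoveries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating migratory movement probabilities from band recoveries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandmove)
```

## The problem

Band-recovery (ring-recovery) data are the longest-running source of
information on waterfowl movement: a bird is captured and marked with a
uniquely numbered leg band, and if it is later shot by a hunter the band
may be reported to the banding laboratory. For American black ducks
(*Anas rubripes*), six decades of such records exist across a range
partitioned by the Black Duck Joint Venture into seven management
regions — four breeding regions (NW Canada, SW Canada, NE Canada,
SE Canada) and three wintering regions (N Atlantic, S Atlantic,
Interior). `bandmove` estimates the probability that a bird banded in
region $i$ is in region $j$ during the migration/wintering period — the
region-to-region movement matrix $\Psi$ — from these data, together
with the uncertainty that the patchy, unevenly reported recovery
process implies.

The difficulty is that a recovery confounds three events: the bird
moved to $j$, it was shot there, and the band was reported. Reporting
probability depends strongly on the band type (old mail-in bands,
modern web-address bands, and reward bands are reported at very
different rates), so long time series cannot be analysed as if
reporting were constant.

## The model

For one band type, the probability that a bird banded in region $i$ is
recovered and reported in region $j$ is

$$\pi_{ij} = \Psi_{ij}\,\lambda\,h$$

where $\Psi_{ij}$ is the movement probability (each row of $\Psi$ lies
on the 7-simplex), $\lambda$ is the band type's reporting probability,
and $h$ is the harvest rate, held constant across regions. The observed
counts $D_{ij}$ (birds banded in $i$, recovered in $j$) are modelled as
independent binomials

$$D_{ij} \sim \mathrm{Bin}(N_i,\; \pi_{ij})$$

with $N_i$ the number banded in region $i$. Priors: each row of $\Psi$
is symmetric Dirichlet (flat, $\alpha = 1$, by default); $\lambda$ is
Beta with parameters moment-matched so the prior mean equals the band
type's known reporting probability; and $h$ is Beta(2, 19).

Only the product $\lambda h$ enters the likelihood, so $\lambda$ and
$h$ are confounded; informative priors on both are what make $\Psi$
identifiable, and the package makes no attempt to separate them from
data. Two structural consequences are worth knowing. First, because
each row of $\Psi$ sums to one, the row totals $\sum_j D_{ij}/N_i$ do
inform the product $\lambda h$, so a mis-centred harvest prior mostly
shifts $\lambda h$, not $\Psi$. Second, rescaling the two prior means
by reciprocal factors leaves the $\Psi$ posterior essentially
unchanged — a property the test suite checks explicitly.

The analysis is run separately per band type (each with its own
$\lambda$ prior) and the per-type posteriors are combined with weights
equal to each type's share of the recovery data.

### Choices the model text leaves open

* **$N$ in the binomial.** We use per-region banded totals $N_i$
  (row $i$'s binomials share $N_i$): it is the only reading under which
  $D_{ij} \le N_i$ is guaranteed and regional banding effort is
  respected. A `n_mode = "global"` option (all cells share $\sum_i
  N_i$) is available for sensitivity analysis.
* **Beta(2, 19) versus a mean of 0.055.** Beta(2, 19) has mean
  $2/21 \approx 0.095$, while continental harvest-rate syntheses give a
  mean near 0.055 (which Beta(2, 19) approximates by its *mode*,
  $1/19 \approx 0.053$). The default keeps Beta(2, 19) as printed;
  `priorConfig(..., h_prior_mode = "mean_matched")` instead
  moment-matches a Beta to mean 0.055 at the same strength
  ($\alpha \approx 1.155$, $\beta \approx 19.845$). Because of the
  confounding geometry above, the choice has little effect on $\Psi$.
* **Independent binomials versus a multinomial.** The cells are
  modelled as independent binomials given $(\Psi, \lambda, h)$, exactly
  as the likelihood above is written. With $\pi_{ij}$ small (a few
  percent at most) the difference from a multinomial with a
  "never-recovered" cell is negligible in practice.
* **Combination rule.** "Weighting the results" is implemented as the
  full-posterior mixture: the combined mean is $\sum_k w_k
  \bar\Psi_k$, and SDs and credible intervals are computed from the
  pooled draws in which each draw of type $k$ carries weight
  $w_k / n_k$ ($n_k$ = retained draws of type $k$). This is the exact
  mixture distribution — equivalent in expectation to resampling draws
  with probability $w_k$, but deterministic and free of added
  Monte-Carlo noise — and it is insensitive to unequal chain lengths
  across band types.

## Record selection

Three design filters restrict the records before any modelling, in a
fixed order so audit counts are reproducible:

1. **Preseason banding** (default window 1 July–30 September): birds
   must be banded before the hunting season, so the banding region is a
   breeding/staging location.
2. **Hunting-season recovery** (default months October–February, when
   migration occurs): the recovery region is a migration/wintering
   location.
3. **No direct same-region recoveries**: a bird shot in the hunting
   season *immediately after* banding, in its banding region, had no
   opportunity to move and would bias $\Psi_{ii}$ upward. Seasons are
   labelled by their starting year, so a January recovery is correctly
   attributed to the season that began the previous calendar year.
   Same-region recoveries in *later* seasons are genuine site fidelity
   and are kept.

Banded totals $N_i$ cannot be recovered from recoveries alone; they are
tallied from the banding-only rows of the record table
(`tallyBandedTotals()`) or supplied as a separate table.

## The sampler

The posterior is explored by Metropolis-within-Gibbs with three block
types per sweep:

* each row of $\Psi$, proposed from a Dirichlet centred at the current
  row (concentration $s_i \cdot \Psi_{i\cdot} + 0.05$; the small offset
  keeps proposals near simplex faces proper and reversible);
* $\lambda$ and $h$, by Gaussian random walks on the logit scale;
* a product-preserving exchange $(\lambda, h) \to (\lambda e^u, h
  e^{-u})$ that moves along the confounding ridge, where single-site
  updates mix slowly.

Proposal scales are adapted during burn-in only (windowed
multiplicative updates toward 30% acceptance for the row blocks and
44% for the scalar walks — the standard targets for multivariate and
one-dimensional random-walk Metropolis) and frozen before the first
retained draw, so the retained chain has a fixed, valid kernel.
Adaptation is what lets one sampler serve both the prior-only model
(cell SD $\approx 0.12$) and a 700,000-band dataset (cell SD
$\approx 10^{-3}$) without per-problem tuning.

Chains start from overdispersed draws of the priors. One master seed
drives everything: chain $c$ takes a sub-seed drawn deterministically
from the master seed, so runs are bit-reproducible while chains remain
independent. Convergence is summarised by the Gelman–Rubin potential
scale reduction factor computed for every scalar (49 movement cells,
$\lambda$, $h$); the estimate is clamped below at 1, and any fit with
$\hat R$ above the threshold (default 1.1) is flagged and warned
about, never silently accepted. Proposals that would leave the open
simplex evaluate to log-posterior $-\infty$ and are rejected rather
than raising errors.

Defaults: 3 chains, 4000 iterations with the first half as burn-in, no
thinning. The data-free posterior and small problems are cheap enough
that running several times longer costs seconds.

### Correctness anchors

The sampler is validated against independent oracles rather than
against any reference MCMC implementation:

* on a 2-region, single-row problem with $\lambda$ and $h$ held fixed,
  the posterior of the single free movement probability is
  one-dimensional and is integrated exactly by grid quadrature; the
  MCMC mean and SD must agree within 0.005;
* with all $N_i = 0$ the posterior equals the prior, so every movement
  cell must recover $1/7$ and $h$ its Beta(2, 19) mean $2/21$, within
  Monte-Carlo error (data-free runs require the explicit
  `allow_empty = TRUE`, since an all-zero $N$ in a real analysis is
  almost certainly an input error);
* on synthetic data at 10,000 banded per region, nominal-95% credible
  intervals must cover the generating $\Psi$ in at least 93% of cells
  across 20 replicates.

## The synthetic-data generator

`simulateDataset()` inverts the model: each bird of a cohort gets a
uniform preseason banding date, a destination drawn from its region's
row of the true $\Psi$, and an independent Bernoulli($\lambda_k h$)
recovery; recovered birds get a recovery date in a hunting season one
to three years after banding (never the direct season, so clean
records cannot trip the direct-recovery filter). The simulator keeps a
ledger of exact per-cell recovery counts, so the preprocessing chain
can be tested for *exact* reconstruction, and it can plant records
that violate each filter rule in known numbers so filter audits can be
verified against truth.

`blackDuckScenario()` is the built-in continental-scale scenario:
three band types (`mail_in` $\lambda = 0.32$, `web` $\lambda = 0.70$,
`reward` $\lambda = 0.98$ — reporting probabilities in the range used
for those band classes; real per-type values are management data and
must be user-supplied for a real analysis), harvest rate 0.055,
cohorts over banding years 1951–2008 totalling about 764,000 banded
birds, allocated more heavily to the eastern breeding regions. The
expected number of reported recoveries, computable from the scenario's
own parameters as $h \sum_k \lambda_k N_k$, is about 15,000. Its true
$\Psi$ encodes the qualitative continental pattern: tiny stay
probabilities in the northern breeding regions, strong movement of
NE Canada birds into SE Canada, flyway fidelity, coastal wintering
mass, and 15–45% northward movement out of the wintering regions.

What the generator deliberately does **not** emulate: survival and
age structure (one Bernoulli collapses harvest, death and reporting),
year-to-year variation in $\Psi$ or $h$, geographic coordinates within
regions, and reporting-rate drift within a band type. Passing
recovery tests on these simulations therefore demonstrates that the
estimator is correct *under the model's own assumptions*, not that
the model captures every feature of real banding data.

## Problem sizes and numerical choices

The validation suite uses problem sizes chosen to keep Monte-Carlo
error well inside each check's tolerance: 20,000-iteration chains for
the quadrature comparison, 30,000 for prior recovery, and twenty
replicates of 70,000-bird simulations (6,000 iterations, 2 chains
each) for interval coverage. Weighted quantiles use left-continuous
interpolation of the weighted empirical CDF at cumulative-weight
midpoints; degenerate (zero-variance) draw sets return the common
value. Movement proposals containing entries below $10^{-12}$ are
rejected outright.

## Limitations

* $\Psi$ is a single time-averaged matrix over 1951–2011; trends in
  movement are out of scope (though the per-band-type machinery is the
  natural starting point for a time-stratified extension).
* Absolute movement rates depend on the supplied reporting
  probabilities; only their ratios across destinations are robust to a
  mis-scaled $\lambda h$.
* Regions are categorical labels; no within-region geography, distance
  moved, or boundary effects are represented.
* The independent-binomial likelihood ignores the weak negative
  correlation among cells of a row that a multinomial would impose;
  at black-duck recovery rates the effect is far below posterior
  uncertainty.
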