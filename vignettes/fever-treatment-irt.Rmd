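---
title: "Modelling fever treatment-seeking with a Bayesian 3PL item response model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fever treatment-seeking with a Bayesian 3PL item response model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Household surveys in low- and middle-income countries record, for each
child with recent fever, whether care was sought in the formal health
sector. Raw proportions are hard to compare across communities with very
different access; this package instead treats the survey question as a
single test *item* and each caregiver's propensity to seek care as a
latent trait, following the item-response-theory tradition.

The response model is the three-parameter logistic (3PL):

$$P(Y_j = 1 \mid \theta_j, a, b, c) \;=\; c + (1 - c)\,
  \frac{e^{a\theta_j - b}}{1 + e^{a\theta_j - b}},$$

where $a > 0$ is the item discrimination, $b$ the difficulty and
$c \in (0,1)$ the **threshold probability**: the floor the curve never
drops below. Epidemiologically, $c$ is the probability that a febrile
child is treated formally *no matter how far* the household is from care
— the "roughly 30% at any distance" phenomenon seen in national data.
The latent trait is regressed on standardised travel time to the nearest
formal facility,

$$\theta_j = \alpha + \beta x_j,$$

so distance decay appears as $\beta < 0$. Four variants differ only in
prior/hierarchical structure:

| variant | trait structure | difficulty prior |
|---|---|---|
| M1 | fixed $\alpha, \beta$ | $b \sim N(0, 10)$ |
| M2 | fixed $\alpha, \beta$ | $b \sim N(0, 10)\,I(b>0)$ |
| M3 | random intercepts $\alpha_j \sim N(\alpha, \sigma^2_{re})$ | as M1 |
| M4 | $(\alpha_j, \beta_j) \sim MVN((\alpha,\beta), \Sigma)$, $\Sigma^{-1} \sim \text{Wishart}(\Omega, p)$ | as M1 |

Random effects sit at the *individual* level (an option the model
comparison is designed to stress: each child contributes one binary
observation, so individual effects are identified almost entirely by
their prior and inflate the effective parameter count dramatically).

## Priors and their defaults

Several hyperparameters are not pinned down by the originating analysis;
the package's defaults are weakly informative choices, all configurable
through `prior_spec()`:

* $a \sim N(0, 10)\,I(a>0)$ — "N(0, 10)" is read as mean 0, **variance**
  10 (SD $\approx 3.16$). The truncated-normal density is renormalised
  over $a > 0$.
* $b \sim N(0, 10)$, truncated at 0 under M2.
* $c \sim \text{Beta}(\kappa, \tau)$ with $\kappa = \tau = 2$: prior mean
  $\kappa/(\kappa+\tau) = 0.5$, unimodal, weakly informative.
* $\alpha, \beta \sim N(0, 1)$.
* M3 random-intercept SD: half-normal$(0, 1)$.
* M4 precision: Wishart with identity scale and $p = 2$ degrees of
  freedom (the number of random components; the minimum proper choice).

Whether the original "N(0, 10)" denoted a variance or a JAGS-style
precision is unknowable from the text; the variance reading is the
package default and the precision reading can be reproduced by passing
`b_var = 1/10`.

With a single item, $(a, \theta)$ carry an exact scale non-identifiability
— only $a\theta_j - b$ enters the likelihood — so identification comes
entirely from the priors and from fixing the covariate scale *before*
fitting. The covariate is the z-score of travel time in minutes over the
modelling sample (mean 0, SD 1), frozen at generation time so truth and
fit share a scale. The originating analysis never states its
standardisation, which is the main reason its posterior tables are not
exactly reproducible from outside.

## The synthetic survey generator

Because the real microdata are restricted-access, `generate_survey()`
produces DHS-like tables with known ground truth: a two-stage cluster
design (clusters sampled within regions, households within clusters,
defaults 13 regions × 20 clusters × 15–30 households, 0.82 enumerated
under-fives per household, giving ≈ 4,800 children), fever status
Bernoulli(0.236), and treatment outcomes drawn **from the 3PL model
itself** at each febrile child's standardised travel time. Travel-time
distributions are log-normal with a longer rural than urban tail (rural
median 45 min, urban 15 min, $\sigma_{\log} = 0.8$) — unstated in the
source, chosen to reproduce the wide range of regional mean travel times
(roughly 18–146 min) national tables show. Three facility-type columns
(dispensary/clinic, health centre, hospital) are generated as correlated
draws sharing a log-normal base, ordered clinic ≤ health centre ≤
hospital on average; only the minimum (nearest formal facility) feeds
the model.

The default generating truth is the national-fit posterior means
($a = 0.704$, $b = 0.807$, $c = 0.340$, $\alpha = -0.084$,
$\beta = -0.098$). Note these imply a marginal formal-treatment fraction
of ≈ 53%, not the ≈ 64% raw tally the real survey reports — the
published fitted curve does not reproduce its own raw proportion
(plausibly an artefact of the unstated covariate transformation), and the
generator follows the fitted curve, which is the quantity under test.

What the generator does **not** emulate: probability-proportional-to-size
cluster selection weights, household socio-economic covariates,
facility bypassing, missing data, and spatial autocorrelation of access
beyond the urban/rural split. Passing tests therefore demonstrate that
the estimation machinery recovers a known 3PL truth under a realistic
survey geometry — not that the model is correctly specified for any real
country's data.

## The sampler

`run_mcmc()` is an adaptive random-walk Metropolis-within-Gibbs sampler
(compiled core), one block per parameter group:

* $a$ and $b$: Gaussian random walks; proposals outside the support
  (truncated priors) are rejected outright.
* $c$: Gaussian random walk on $\mathrm{logit}(c)$ with the Jacobian
  correction.
* $\alpha$, $\beta$: Gaussian random walks; for hierarchical variants
  these are hyper-mean updates touching only the prior terms.
* person-level random effects: elementwise proposals with a shared
  adapted scale (each touches one record's likelihood, so a full sweep is
  $O(n)$).
* M3 $\sigma_{re}$: random walk on $\log\sigma$.
* M4 $\Sigma^{-1}$: conjugate Wishart Gibbs draw (Bartlett
  decomposition).
* M1/M2 additionally use a **rescaling move**
  $(a, \alpha, \beta) \to (a s, \alpha/s, \beta/s)$, $s = e^\varepsilon$,
  which leaves every linear predictor unchanged and is accepted on the
  prior ratio times the Jacobian $1/s$. The single-item posterior has an
  exact ridge along this direction; plain scalar blocks cross it slowly
  (PSRF ≈ 1.1–1.25 at desk scale), while with the move all fixed-effect
  PSRFs sit near 1.01.

Proposal scales adapt toward 0.44 acceptance per scalar block during
burn-in (Robbins–Monro drift in batches of 50) and are **frozen at the
end of burn-in**, so the retained chains are genuine Metropolis chains
with the correct stationary distribution. Chains start at $a = 1$,
$b = 0$, $c$ at its prior mean, $\alpha = \beta = 0$, random effects 0,
plus per-chain $N(0, 0.5^2)$ jitter so the between-chain variance in the
Gelman–Rubin statistic is meaningful. Each chain is seeded `seed + k`;
runs are bitwise reproducible.

Two scales are used throughout. The **full-scale** configuration of the
original analysis (5 chains × 100,000 iterations, 50,000 burn-in) is
available as `chain_config(paper_scale = TRUE)`. The package's working
default is a **desk scale** — 3 chains × 20,000 iterations, 10,000
burn-in — chosen so that a 20-replicate recovery experiment at
$n = 2000$ completes in minutes while leaving 30,000 retained draws per
fit; the test suite and the analysis scripts run at this scale, with some
unit tests smaller still (hundreds of records, a few thousand
iterations).

## Convergence diagnostics

`gelman_rubin()` implements the plain potential scale reduction factor
$\sqrt{\hat V^+/W}$ with $\hat V^+ = \frac{n-1}{n}W + B/n$ — no
degrees-of-freedom correction — because that is the closed form the
hand-checkable examples pin down; the upper bound inflates the
between-chain component by an F-quantile. Chains below 1.05 are treated
as converged, matching the criterion the original analysis used.

`raftery_lewis()` implements the standard two-state Markov-chain
run-length analysis of the binary quantile indicator (thinning chosen by
BIC against a second-order chain), with
$n_{min} = z^2_{(1+s)/2}\,q(1-q)/r^2$ and dependence factor
$n_{required}/n_{min}$. The published run-length numbers are internally
inconsistent (the Methods state accuracy 0.0005 at quantile 0.025 with
coverage 0.975; the Results quote a minimum of 55,318 iterations at
coverage 0.999 with quantile 0.05, which the closed form cannot
reproduce); the implementation takes no side and always echoes its
inputs alongside its outputs. A correlated-chain cross-check against an
independent reference implementation is part of the test suite.

## DIC

`dic()` reports $\overline{D}$, $\hat D$, $p_D = \overline{D} - \hat D$
and $DIC = \overline{D} + p_D$; the identities hold exactly by
construction. The plug-in $\hat D$ is evaluated at the **posterior mean
of each record's fitted probability** $\bar P_j$, tracked during
sampling. This focus matters: the record-level 3PL log-likelihood is
sigmoid (not concave) in the linear predictor because of the floor $c$,
so plugging in marginal means of $a$, $b$ and the trait parameters
separately can land off the scale ridge and fit *worse* than a typical
draw, yielding meaningless negative $p_D$ — which is exactly what
happens for the individual-level random-effect variants. With the
probability-scale plug-in, $p_D \ge 0$ record by record (Jensen), a
degenerate posterior gives $p_D = 0$, and the qualitative complexity
ordering $p_D(\text{M4}) \gg p_D(\text{M1})$ emerges as it should.

On synthetic data the random-effect variants can attain a lower DIC than
M1 (their record-level effects buy more deviance than $p_D$ charges);
the package reports the table as computed rather than forcing the
ordering the original data produced.

## Validation

`split_records()` partitions the modelling table either by fraction
(default 0.4) or by exact count — exposed separately because the
original analysis describes a 40% subset whose reported size (247 of
1138, i.e. 21.7%) does not match; the package resolves nothing and lets
the caller choose. Prediction is plug-in at posterior-mean parameters
(matching the DIC convention; a draw-averaged posterior-predictive
option would be a natural extension but is deliberately not the
default). Classification is positive when the predicted probability is
**greater than or equal to** the cut-off, default 0.65. The ROC uses the
sorted unique scores plus infinite sentinels and trapezoidal
integration, which makes the AUC equal the Mann–Whitney concordance with
ties counted one half; the printed sensitivity of 96.7% in the source is
inconsistent with its own confusion matrix (155/162 = 95.7%), and the
package reports matrix-derived values only.

## Numerical choices and degenerate inputs

* Equal-tailed 95% intervals use type-7 linear-interpolation quantiles
  throughout, so results are bit-reproducible across implementations of
  the same convention.
* The 3PL curve is evaluated through a numerically stable
  `log(1+e^x)` form; it saturates cleanly at $c$ and 1 for linear
  predictors beyond ±700.
* All-one (or all-zero) response vectors are sampled with a warning —
  the parameters are then identified only by their priors.
* Zero within-chain variance makes the PSRF undefined and is signalled
  as an error; a chain shorter than $n_{min}$ makes the Raftery–Lewis
  analysis return an explicit "insufficient" result rather than throw.
* Response-curve grids more than 4 SD beyond the covariate mean trigger
  an extrapolation warning (default grid 0–240 minutes in 2-minute
  steps).

## Known limitations

The single-item design leaves $(a, b, c)$ only prior-identified; desk-
scale posteriors for these parameters are wide and their PSRF converges
more slowly than the trait-regression parameters (full convergence under
the 1.05 criterion is a full-scale-run property). Regional summaries
evaluate one fitted curve at per-facility-type mean travel times; they do
not refit per facility type. No survey weights, no missing-data
handling, no spatial model — all outside the originating analysis's
scope as well.
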