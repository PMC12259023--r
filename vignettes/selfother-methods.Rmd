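---
title: "Self-other generalisation models for the Intentions Game: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-other generalisation models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(selfother)
```

## The task and the scientific question

`selfother` implements a computational pipeline for a three-phase social
value orientation paradigm (the "Intentions Game"). In phase 1 (36 trials) a
subject chooses between two splits of points between themselves and an
anonymous partner; in phase 2 (54 trials) they predict the choices of a new
partner and receive feedback; in phase 3 (36 trials) they choose for
themselves again. The scientific question is how representations of self and
other interact: whether people *insert* their own preferences into their
prior beliefs about others, and whether observing another person's
preferences *shifts* their own (social contagion).

Option pairs come in three contrasts, twelve of each per choice phase:
prosocial vs individualistic (e.g. 5/5 vs 10/5), prosocial vs competitive
(e.g. 10/10 vs 10/5), and individualistic vs competitive (e.g. 10/5 vs 8/1).

## Utility and the preference grid

Choices are modelled with a constricted Fehr-Schmidt utility. For an option
giving `r_ppt` to the subject and `r_par` to the partner,

$$U_{\alpha,\beta} = \alpha\, r_{ppt} + \beta \max(r_{ppt} - r_{par},\, 0),$$

where $\alpha \ge 0$ weights absolute reward and $\beta$ weights the
advantageous payoff gap ($\beta < 0$ prosocial, $\beta > 0$ competitive).
Preferences are represented as a probability mass over a discretised grid:
$\alpha \in [0, 30]$ in steps of 0.125 and $\beta \in [-30, 30]$ in steps of
0.25 (241 x 241 states). Choice stochasticity follows a random-preference
(random utility) construction: the probability of choosing option 1 is the
belief-weighted unit-slope logistic of the utility difference,

$$p(c = 1) = \sum_{(\alpha,\beta)} \sigma\!\big(\Delta U_{\alpha,\beta}\big)\,
\theta(\alpha, \beta),$$

with no separate choice-temperature parameter: all stochasticity enters
through the spread of the preference distribution. Beliefs are products of
independent per-dimension normals evaluated on the grid; a noise floor of
2.22e-16 is added before every normalisation.

## The model lattice

Four models cross two mechanisms (plus a reduced variant):

| model | self-insertion | contagion | free parameters |
|-------|----------------|-----------|-----------------|
| M1    | yes            | yes       | 6 |
| M2    | yes            | no        | 6 |
| M3    | no             | yes       | 8 |
| M4    | no             | no        | 8 |
| Beta  | yes            | yes       | 3 (relative dimension only, $\alpha$ = 1) |

Self-insertion sets the phase-2 prior over the partner at the subject's own
central tendencies with free reference spreads (`alpha_ref`, `beta_ref`);
without it, the prior central tendencies are free parameters. Beliefs about
the partner are updated trial-by-trial by Bayes rule on the partner's
observed decisions; the subject's predictions are probability-matched to the
current partner-choice probability, and the prediction likelihood on each
trial uses the belief *before* that trial's feedback.

Contagion produces the phase-3 preference distribution by per-dimension
precision weighting of the phase-1 self distribution and the final partner
posterior: with self spread $\sigma_{ppt}$, prior reference spread $ref$ and
posterior partner summary $(m_{par}, \sigma_{par})$,

$$\acute v = \Big(\sigma_{ppt}^{-2} + \big(2\,ref^2 +
\sigma_{par}^2\big)^{-1}\Big)^{-1},\qquad
\acute m = \acute v\Big[\sigma_{ppt}^{-2} m_{ppt} + \big(2\,ref^2 +
\sigma_{par}^2\big)^{-1} m_{par}\Big],$$

and the phase-3 spread is $\sqrt{\acute v}$. A certain self
($\sigma_{ppt} \to 0$) does not move; adding the partner's precision always
tightens the phase-3 distribution. We read the first quantity as a variance
(precisions add); the source formulation is ambiguous about whether the
combined quantity is a variance or a standard deviation, and the variance
reading is the one under which the midpoint and limit properties hold
exactly.

Two numerical conventions matter here. First, the reported central tendency
of a discrete marginal is its median (first grid value reaching cumulative
mass 0.5), but *inside the likelihood* the contagion combination uses the
marginal mean: the discrete median is a step function of the parameters, and
routing it into the phase-3 belief makes the log-likelihood discontinuous,
which breaks quasi-Newton optimisation and makes Laplace Hessians
step-size-dependent. Mean and median differ by at most about one grid step
for the near-symmetric posteriors involved. Second, the reduced Beta model
runs on a grid whose $\alpha$ axis holds only the value 1: simulating a
near-point mass on the full axis instead would let the noise floor re-seed
other $\alpha$ rows, which can compound over 54 updates.

## Fitting and model comparison

Per-subject fits are MAP estimates over unbounded latent parameters with
independent Gaussian priors (initially mean 0, variance 6.5) and a Laplace
approximation to the log marginal likelihood. Central tendencies map onto
the grid through scaled logistics ($\alpha$-type: $30\,\sigma(l)$;
$\beta$-type: $60\,\sigma(l) - 30$) and spreads through $\exp(l)$. This
parameterisation is a deliberate design choice: the choice likelihood is
almost invariant along joint rescalings of the four self parameters (the
decision boundaries are rays through the origin of the $(\alpha, \beta)$
plane), so a zero-centred prior on *raw* magnitudes would systematically
collapse every subject to the smallest scale that saturates the logistic,
regardless of the data. Under the logistic maps the same broad latent prior
spreads roughly uniformly over the grid and leaves the weakly identified
scale direction to the hierarchical prior.

The hierarchical random-effects comparison iterates: (1) per subject x model
MAP fits and Laplace evidences under the current group priors; (2)
responsibilities proportional to exponentiated evidence plus the expected
log model frequency; (3) a Dirichlet update of frequencies; (4)
responsibility-weighted updates of each model's group prior mean and
variance. The group variance adds the mean within-subject posterior variance
to the dispersion of the modes — using mode dispersion alone demonstrably
collapses the hierarchy for weakly identified parameters — and is floored at
0.01. Exceedance probabilities are Monte-Carlo estimates from the final
Dirichlet counts, protected by the Bayes omnibus risk computed from the
variational free energy of the random-effects model against the
equal-frequency null: $pxp = xp\,(1 - BOR) + BOR/M$.

Numerically: the optimiser is BFGS with numerical gradients and two starts
(a heuristic start from flat-prior grid point estimates of the phase-1 and,
where needed, partner medians; and the prior mean), warm-started between
hierarchical iterations; Hessians are central-difference `optimHess` at the
mode, with diagonal jitter and a flag when not positive definite; all
per-trial probabilities are clipped away from 0 and 1 by the noise floor;
ties in discrete argmax operations resolve to the first (lowest-index) grid
point, and utility ties in deterministic choices resolve to option 1.

## Partner matching

The matching algorithm reproduces the study server's objective: a phase-2
partner whose choices differ from the participant's on at least half the
trials. The participant's phase-1 choices are reduced to a grid point
estimate (flat-prior Bayesian update, maximum-mass point); candidate
partners on a coarse sub-grid (every 8th node per dimension) are scanned in
seeded random order; each candidate's deterministic utility-maximising
choices over the 54 phase-2 trials are compared with the participant's, and
among candidates at or above the target dissimilarity the one closest to the
target is selected. The partner's deterministic choices are then fed to the
subject in phase 2. Because selection is always from *above* the target,
achieved similarity sits just below 0.5 on average.

## The synthetic cohort generator

The generator replaces the clinical dataset: it emulates two groups of ~50
subjects whose phase-1 preferences, partner priors and learning follow the
group-dominant models, seeded by the study-scale group central tendencies —
control-like: M1 with mean $\alpha_m$ = 18.41, $\beta_m$ = -7.50; bpd-like:
M4 with mean $\alpha_m$ = 10.57, $\beta_m$ = -6.59 and a near-neutral
partner prior over relative reward (mean -0.47, its own $\alpha$ prior
centred on the group's $\alpha$ mean, reflecting that self-other
disintegration in the study was specific to relative reward).

Quantities the study does not print are configuration, chosen once on
plausibility grounds and exposed in `default_group_spec()`:
between-subject dispersions of the central tendencies ($\alpha$: 6, $\beta$:
4 for control-like; 60% of those for the bpd-like group, which was more
certain about itself); within-subject spreads and reference spreads
(control-like medians 6/6 and 8/8; bpd-like 4.5/5 and 4/6.5, the last
reflecting the group's lower flexibility over a partner's absolute-reward
preferences); and log-normal between-subject variation of spread-type
parameters with log-sd 0.4. For mixed-model cohorts, subjects generated
from free-prior models inside a control-like cohort draw neutral partner
priors (mean 10 for $\alpha$, 0 for $\beta$) so that insertion and
non-insertion generators are actually distinguishable.

What the generator emulates: balanced pair types, matched partners at ~50%
choice dissimilarity, probability-matched predictions with veridical
feedback, model-consistent learning and contagion. What it does not emulate:
reaction times, questionnaire traits, attention lapses, sequential
dependencies beyond the model (e.g. perseveration), or the exact
(unpublished) trial tables — synthetic trials are drawn from a template
library built on the three printed exemplar pairs and integer-scaled
variants with values 1-15. A consequence worth stating plainly: within each
pair type the utility-difference coefficients of scaled variants are
proportional, so the effective decision boundaries span only three rays
through the preference plane, and several parameters (notably
$\sigma_\alpha$ and $ref_\alpha$) are only weakly constrained per subject.
Passing tests on this synthetic structure therefore demonstrate internal
consistency of the pipeline, not estimation performance on richer real trial
tables.

## Validation analyses

`run_parameter_recovery()` mirrors the study's generative-accuracy workflow:
fit the cohort, simulate fresh data from each subject's *fitted* parameters
(fresh environments, partners and seeds rather than the original trials — a
deliberately harsher variant), refit, and correlate (Spearman) generating
against re-estimated values per parameter. `run_model_recovery()` simulates
mixed-model cohorts and reruns the hierarchical comparison.
`belief_trajectories()` replays phase 2 and emits per-trial Kullback-Leibler
divergences (natural log; joint grid and per-dimension marginals — both
scopes are supported, marginals being the default reporting unit) together
with running prediction accuracy. `contagion_metrics()` reports the
phase-1-to-phase-3 shift implied by contagion-bearing fits.
Group contrasts on parameters are provided as percentile-bootstrap
mean-difference intervals (`bootstrap_group_diff()`), deliberately simpler
plumbing than the hierarchical Bayesian t-tests used on the clinical data.

## Problem sizes and resolution

Simulation uses the full 241 x 241 grid. Fitting in the packaged analyses
and tests uses a coarser grid (alpha step 0.5, beta step 1.0; 61 x 61
states) — the discretised normals involved have spreads of several grid
units, so the coarse likelihood differs negligibly while evaluation is ~16x
cheaper — with cohort sizes of 40-50 per group for recovery analyses and
hierarchical comparisons of all four models over 3-5 iterations. These
choices are stated here as the package's defaults for its own analyses;
all of them are arguments.

## Known limitations

- The $\alpha$ dimension of the self block and the partner-prior spread
  `alpha_ref` are weakly identified from the task's three pair-type
  boundaries; their recovery correlations are structurally lower than those
  of the $\beta$-dimension parameters, and spreads recover less well than
  central tendencies (126 binary trials carry limited shape information).
- M1 and M2 differ only through phase-3 contagion; when generated contagion
  shifts are small relative to choice noise, their evidences differ by
  fractions of a nat per subject and hierarchical comparison legitimately
  hesitates between them.
- The Laplace evidence is a local approximation; multimodality (e.g.
  insertion-like solutions inside free-prior models) is handled only through
  restarts.
- The Beta model's contagion is assumed to follow the same precision
  weighting as M1 restricted to the relative dimension.
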