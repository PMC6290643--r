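---
title: "A two-mode mixture learning model for responses and response times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-mode mixture learning model for responses and response times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixlearn)
```

## The model

`mixlearn` models long-format learner logs from computer-based learning
programs: `N` learners work through `T` testing/learning modules, each
module presenting a set of items that measure `K` binary skills through a
Q-matrix, and every (learner, item) cell records a binary response and a
latency in seconds. The model's central idea is that at any module a
learner occupies one of two latent engagement modes, and every part of the
data-generating process is conditioned on that mode.

**Engaged mode** (`D[i,t] = 0`). Responses follow the DINA measurement
model: the ideal response `eta[i,j,t] = prod_k alpha[i,k,t]^q[j,k]` is 1
exactly when all skills the item requires are mastered, and

$$P(X_{ijt} = 1) = (1 - s_j)^{\eta_{ijt}} g_j^{1 - \eta_{ijt}},$$

with slipping `s_j` and guessing `g_j` constrained to the order region
`0 <= g_j < 1 - s_j <= 1`. Latencies are log-normal with a person-item
structure,

$$\log L_{ijt} \sim N(\gamma_j - (\tau_i + \phi G_{ijt}),\; 1/a_j^2),$$

where `gamma_j` is the item's time intensity (log-seconds), `a_j` its time
discrimination (inverse log-latency spread), `tau_i` the learner's initial
latent speed, and `G` is the same dominance indicator as `eta`: once a
learner has mastered everything an item needs, their speed on it shifts by
`phi`. (A negative `phi`, as estimated for the spatial-rotation program,
means masters respond *more slowly* — deliberate solution behavior.)
Between modules, skills are acquired through a higher-order logistic
hidden-Markov transition,

$$\text{logit}\, P(\alpha_{i,k,t+1} = 1 \mid \alpha_{i,k,t} = 0)
  = \lambda_0 + \lambda_1 \theta_i + \lambda_2 \sum_{k' \neq k} \alpha_{i,k',t},$$

with a general learning ability `theta_i` and a boost from the number of
other skills already mastered; mastered skills are never forgotten.

**Disengaged mode** (`D[i,t] = 1`). The learner rapid-guesses: every item
is answered correctly with one flat probability `gstar`, latencies are
log-normal with one mode-specific law `log L ~ N(mu1, sigma1_sq)`
independent of the items and the profile, and the skill profile is frozen
(`alpha[i,t+1] = alpha[i,t]`). Modes are independent Bernoulli draws with
probability `omega` per (learner, module) cell.

The two modes are identified structurally, not by an ordering constraint:
the disengaged component is item-free (flat accuracy, item-independent
latency law), while the engaged component is item-structured. The initial
profile is multinomial over all `2^K` classes with simplex `pi`;
`theta ~ N(0,1)` and `tau ~ N(0, sigma_tau_sq)`.

## Estimation

All parameters and latent states are sampled by an
MH-within-Gibbs sampler (`fit_mlm()`). The update cycle is: discrete
latents, person parameters, item parameters, structural parameters. The
full conditionals are derived from the priors

- `omega, gstar ~ Beta(1,1)`; `pi ~ Dirichlet(1)`,
- `lambda0 ~ N(0,1)`, `lambda1 ~ LogNormal(0.5, 1)`,
  `lambda2 ~ LogNormal(-0.5, 0.6^2)`,
- `(s_j, g_j)`: Beta(1,1) x Beta(1,1) truncated to the order region,
- `gamma_j, phi, mu1 ~ N(0,1)`; `a_j^2 ~ Gamma(1,1)` (read as a prior on
  the log-latency precision, which gives conjugacy);
  `sigma1_sq ~ InvGamma(1,1)`; `sigma_tau_sq ~ InvGamma(2.5, 1)`,

times the complete-data likelihood. Every conjugate conditional
(`tau`, `gamma`, `a^2`, `phi`, `mu1`, `sigma1_sq`, `sigma_tau_sq`, `pi`,
`omega`, `gstar`, truncated `s`/`g`) is unit-tested against its closed
form on pinned micro-data; `theta` and the `lambda` block use random-walk
Metropolis (on `(lambda0, log lambda1, log lambda2)`), with proposal
scales 0.5 and 0.2 adapted during warm-up toward a 20-50% acceptance rate.

Four aspects of the latent-state sampler deserve comment.

1. **Frozen-segment blocks.** Because a disengaged link forces
   `alpha[t+1] = alpha[t]`, runs of modules tied together by disengaged
   links share one profile. These segments are resampled as blocks over
   all `2^K` classes, conditioning on the profiles before and after the
   segment and the data at the segment's engaged modules (disengaged
   measurement carries no profile information).
2. **Latent speed is collapsed out of the discrete updates.** The
   engaged latency terms of one learner share `tau_i`, which is
   conjugate-normal; all discrete latent updates integrate it out
   analytically and `tau_i` is redrawn from its full conditional in the
   person step (a partially collapsed Gibbs scheme, sampled in the valid
   order). Without this, a learner whose speed has adapted to a wrong
   profile can essentially never flip that profile: the flip and the
   compensating speed shift must happen together.
3. **Modes and profiles move jointly.** Flipping `D[i,t]` re-segments
   the trajectory: entering a frozen link demands that the profiles on
   both sides become equal in the same step. Separate `D | alpha` and
   `alpha | D` conditionals can never do this (the mode flip has zero
   probability until the profiles already agree), which deadlocks
   learners in wrong explanations — with enough such learners, whole
   chains can anchor a spurious mode in which mastery is over-attributed
   and `phi` absorbs the latency gap. Each sweep therefore draws
   `(D[i,t], the profiles of the segments its link touches)` jointly
   from their exact conditional: `2^K` merged-segment options for the
   disengaged branch plus `2^K x 2^K` split options for the engaged
   branch. This is the same block the model's frozen-link logic defines,
   sampled together with the mode.
4. **Whole-trajectory draws.** Under no-forgetting, a learner's whole
   profile path is described by one acquisition time per skill (from
   "mastered at the start" through "acquired across engaged link t" to
   "never"), at most `(T+1)^K` monotone paths — 625 for the default
   `K = 4, T = 4`. Every few sweeps the whole path is resampled exactly
   from this enumerated conditional (tau again collapsed), letting a
   learner jump between distant explanations such as
   mastered-from-the-start vs fast-acquirer in one step.

The latent sampler's exactness is verified against a brute-force path
enumeration with quadrature over `tau` on a `K = 1, T = 2` instance, and
the whole update cycle passes a simulate/update successive-conditional
(Geweke-style) prior-recovery check.

One weakly identified location ridge gets a dedicated level-shift
Metropolis move: shifting all `gamma_j` and all `tau_i` together leaves
every engaged cell mean unchanged, so only the priors resist; a small
symmetric proposal along this ridge keeps the item/person split of the
overall latency level anchored by its priors rather than by the chain's
starting point.

Point estimates are post-burn-in means (EAP); the discrete `alpha` and
`D` are dichotomized at posterior frequency 0.5, with exact ties resolved
to 0 (non-mastery / engaged) for determinism. The default production
recipe is 30,000 iterations with 5,000 burn-in; the package's own
experiments use 5,000 iterations with 1,000 burn-in, which the
convergence diagnostics below justify for these problem sizes.

## The simulator and what it does (not) emulate

`simulate_learning_data()` generates fully synthetic logs under the
design of the motivating spatial-rotation study: `K = 4` skills, `T = 4`
modules of 10 items each, `N = 585` learners by default, and true
parameters fixed at the published empirical estimates — the 40-item
slipping/guessing/intensity/discrimination table, transition coefficients
`(-2.214, 2.757, 0.286)`, `phi = -0.332`, `gstar = 0.503`,
`(mu1, sigma1_sq) = (2.528, 1.158)`, and `omega` 0.03 or 0.10. Three
quantities the study did not publish are completed by documented
defaults:

- the initial-class simplex: 0.527 on full mastery (the published
  figure), the remaining 0.473 uniform over the other 15 classes —
  a minimal-assumption completion;
- `sigma_tau_sq = 2/3`, the mean of its Inv-Gamma(2.5, 1) prior;
- the Q-matrix, generated per module by `generate_q_matrix()` under a
  fixed seed: each module contains every single-skill row once
  (completeness, so all skills are identified at every module) plus
  one- and two-skill rows in equal proportion, redrawn until every skill
  is measured at least twice.

The simulator emulates the statistical design only: it does not model
learning-intervention content, incentive conditions, item exposure order,
or item-level engagement switching (modes are per module by assumption).
Passing recovery tests on this synthetic design therefore shows the
estimator recovers the model's own data-generating process at the study's
scale — not that the model is correct for any particular real program.

Because the operational Q-matrix is unpublished, the synthetic one makes
the recovery experiment reproducible but not identical to the published
one; agreement-rate and detection results are therefore compared as
bounds rather than matched value-for-value. One visible consequence of
the unpublished `sigma_tau_sq`: with the prior-mean default 2/3, the
latent speeds are spread widely relative to their measurement error
(about 40 items per learner), and the truth-estimate correlation for
`tau` comes out near 0.99, somewhat above the published 0.968 — the
published figure is consistent with a smaller empirical speed variance.

## Diagnostics and evaluation

- `psrf()` implements the classic Gelman-Rubin statistic
  `sqrt(((n-1)/n W + B/n)/W)`; identical chains are defined as converged
  (PSRF 1). `psrf_summary()`/`max_psrf()` evaluate every stored
  parameter across chains run with `burnin = 0`, using the first half of
  each chain as burn-in; `psrf_trajectory()` traces the maximum against
  chain length. The finite-sample statistic can dip slightly below 1 on
  stationary chains; the tests treat that as expected behavior rather
  than an error.
- `joint_dic()` reports a DIC for the joint response + latency
  measurement model *conditional on the sampled latent states* (deviance
  of a draw = -2 x measurement log-likelihood given that draw's latents;
  plug-in at EAP parameters with dichotomized latents). "Joint DIC" has
  no unique definition for latent-variable mixtures; this
  conditional-on-latents convention is computable from stored draws and
  is labeled as such in reports. Stored deviances are cross-checked in
  the tests against an independent R implementation of the likelihood.
- `ppc_pvalues()` simulates replicate datasets from stored draws and
  reports upper-tail posterior predictive p-values
  (`P(T_rep >= T_obs)`) for the min/mean/max over learners of the
  change score and change time between the first and last modules,
  flagging both extremes. With discrete bounded score statistics the
  `>=` convention can tie at the ceiling, so a p-value of exactly 1 on a
  max-score quantity is not by itself evidence of misfit.
- `attribute_agreement()` (AAR/PAR per module, excluding learners
  estimated disengaged at every module), `mode_detection_metrics()`
  (sensitivity/specificity over cells), `structural_recovery()`
  (bias/RMSE across replicates) and `correlation_recovery()` implement
  the recovery criteria; the ability correlation excludes learners whose
  *estimated* initial profile is full mastery, since they contribute no
  acquisition transitions. Replicate-level metrics are computed per
  replicate and then averaged.

## Problem sizes and numerical choices

The package's experiment harness (`recovery_experiment()`,
`convergence_experiment()`, `misspecification_experiment()`) defaults to
3 replicates at `N = 585` with 5,000-iteration chains (1,000 burn-in) for
recovery, and 5 dispersed chains at `N = 200`, `omega = 0.10`, 5,000
iterations for convergence; a complete run stays within minutes on one
CPU thanks to the compiled sampler. The joint mode/profile draws of the
latent sampler are not optional polish: without them, dispersed starting
states at these sizes occasionally anchor a spurious, self-consistent
configuration (mastery over-attributed, the latency level absorbed into
`phi`) that single-site conditionals cannot leave, and the between-chain
diagnostic correctly flags the resulting disagreement. With the full
kernel set, the maximum PSRF at 5,000 iterations sits in the 1.05-1.20
range across seeds at both `N = 200` and `N = 585`. Degenerate inputs
are defined: `omega = 0` fits the
engaged-only joint model (`mixture = FALSE`), learners with no engaged
cells draw their person parameters from the prior, items with no engaged
observations draw truncated prior values, and a zero-learner dataset
reproduces every prior marginal (tested). Underflow in the discrete
conditionals is avoided by log-space weights with log-sum-exp sampling;
the truncated `s`/`g` draws use inverse-CDF sampling with a `1e-12`
clamp.

## Limitations

Two engagement modes only; module-level (not item-level) mode switching;
no missing-data support (complete logs are required and validated); no
covariates on the disengagement probability; correlations between ability
and speed are not modeled (independent priors). The transition
coefficients `lambda` and abilities `theta` are weakly informed at
`T = 4` — each learner contributes at most three transitions — so their
posteriors remain wide at realistic sample sizes, as the recovery
experiments show.
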