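# mixlearn

Learners working through a computer-based training program do not all
behave the same way: most engage with the material and acquire skills,
but some disengage — rapid-guessing their way through assessment items —
for a module or for the whole program. Ignoring this contaminates both
skill diagnosis and the measurement of learning itself. `mixlearn` fits a
**two-mode mixture learning model** to long-format logs of item responses
and response times, for psychometricians and learning-analytics
researchers who want per-learner, per-module estimates of (a) which
skills are mastered and (b) whether the learner was engaged at all.

## The model

At module *t*, learner *i* holds a binary skill profile
**α**<sub>it</sub> ∈ {0,1}<sup>K</sup> and an engagement mode
D<sub>it</sub> ∈ {0,1} with P(D<sub>it</sub> = 1) = ω.

**Engaged (D = 0):** responses follow the DINA model through the
Q-matrix, P(X<sub>ijt</sub> = 1) = (1 − s<sub>j</sub>)<sup>η</sup>
g<sub>j</sub><sup>1−η</sup> with ideal response
η = ∏<sub>k</sub> α<sub>ikt</sub><sup>q<sub>jk</sub></sup>; latencies are
log-normal, log L<sub>ijt</sub> ~ N(γ<sub>j</sub> − (τ<sub>i</sub> +
φG<sub>ijt</sub>), 1/a<sub>j</sub>²), where G = 1 once all required
skills are mastered; and skills are acquired between modules by a
higher-order hidden-Markov transition, logit P(α<sub>ik,t+1</sub> = 1 |
α<sub>ikt</sub> = 0) = λ₀ + λ₁θ<sub>i</sub> + λ₂·(# other mastered
skills), with no forgetting.

**Disengaged (D = 1):** flat rapid-guessing accuracy g\*, one
item-independent latency law log L ~ N(μ₁, σ₁²), and a frozen profile
(α<sub>i,t+1</sub> = α<sub>it</sub>).

Estimation is fully Bayesian via a Metropolis-Hastings-within-Gibbs
sampler (compiled core) with block updates of the attribute segments
frozen together by disengaged links, exact whole-trajectory draws, and
the learner's latent speed collapsed out of the discrete updates. See
`vignette("mixture-learning-model")` for priors, full conditionals,
and design decisions.

## A worked example

Simulate a program of 200 learners (4 skills, 4 modules of 10 items,
10% disengagement) under the package's reference truth — the published
empirical estimates of the spatial-rotation training study — then refit
and score recovery:

```r
library(mixlearn)

sim <- simulate_learning_data(n_learners = 200,
                              params = default_true_params(omega = 0.10),
                              seed = 7)
fit <- fit_mlm(sim$data, sim$q_matrix, n_iter = 5000, burnin = 1000,
               seed = 42)
fit
#> <mlm_fit> mixture model; 5000 iterations (1000 burn-in), 200 learners
#> # A tibble: 9 × 3
#>   term         estimate std.error
#>   <chr>           <dbl>     <dbl>
#> 1 lambda0       -1.05      0.842
#> 2 lambda1        7.08      3.81
#> 3 lambda2        0.445     0.247
#> 4 omega          0.0913    0.0105
#> 5 gstar          0.499     0.0187
#> 6 mu1            2.57      0.0411
#> 7 sigma1_sq      1.17      0.0631
#> 8 phi           -0.397     0.0355
#> 9 sigma_tau_sq   0.824     0.109
```

The estimated disengagement rate (ω̂ ≈ 0.091), rapid-guessing accuracy
(ĝ\* ≈ 0.50 — accuracy near a flat chance level), the disengaged
log-latency law (μ̂₁ ≈ 2.57, i.e. a typical disengaged latency of
e^2.57 ≈ 13 s) and the speed-change coefficient (φ̂ ≈ −0.40: learners
slow down slightly on items whose skills they have mastered — deliberate
solution behavior) all sit near their generating values (0.10, 0.503,
2.528, −0.332); the acquisition coefficients λ are the least determined,
as each learner contributes at most three transitions. Latent-state
recovery:

```r
lat <- latent_estimates(fit)   # alpha, D dichotomized at 0.5
attribute_agreement(sim$truth$alpha, lat$alpha, lat$D)
#> # A tibble: 4 × 4
#>    time   aar   par n_included
#>   <int> <dbl> <dbl>      <int>
#> 1     1 0.849 0.64         200
#> 2     2 0.912 0.765        200
#> 3     3 0.926 0.79         200
#> 4     4 0.928 0.8          200
mode_detection_metrics(sim$truth$D, lat$D)[, 1:2]
#> # A tibble: 1 × 2
#>   sensitivity specificity
#>         <dbl>       <dbl>
#> 1       0.972           1
```

85–93% of per-skill mastery calls agree with the simulated truth
(rising over modules as evidence accumulates), and disengaged cells are
detected with 97% sensitivity at 100% specificity. Model fit and
convergence tooling: `joint_dic()`, `ppc_pvalues()`, `psrf_summary()` /
`psrf_trajectory()`, and `autoplot()` methods for fits and PSRF
trajectories; `fit_mlm(..., mixture = FALSE)` fits the engaged-only
joint model nested at ω ≡ 0 for comparison.

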