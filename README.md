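# decoyrace

Modelling and analysis of **distractor (decoy) effects in two-attribute
risky choice**, for researchers in decision neuroscience and behavioural
economics who work with speeded choices between prospects defined by a
reward magnitude *X* and a reward probability *P*.

The scientific core: in ternary trials an *unavailable* distractor prospect
D is shown alongside the two available targets H and L (labelled so that
EV(H) ≥ EV(L), with EV = X·P). Apparent effects of D's value on the
relative accuracy *p*(H over L) can arise from covariations baked into
pseudo-random trial designs — visible as "notional distractor" effects in
matched binary trials where no distractor was ever shown — rather than from
D itself. The package implements the tools needed to make and test that
argument end to end:

* **Race likelihoods.** Analytic choice + RT likelihoods for the
  feedforward-inhibition (FFI) race — accumulators
  `dx_i = (kU_i − ck·mean(U_j≠i) + I0)dt + ξ√dt` with unit noise, absorbed
  at bound θ; first-passage times are inverse Gaussian, so the likelihood
  of choice *i* at decision time *T* is its first-passage density times
  every competitor's survival — and for the dual-route model (simultaneous
  mutual-inhibition races on raw and divisively normalised EVs).
  A seed-controlled Euler–Maruyama simulator serves as the stochastic
  oracle.
* **Utility models.** EV, additive utility `λX + (1−λ)P`, expected-utility
  and prospect-theory distortions, selective integration (rank-dependent
  within-attribute gating with weights w2 ≤ w3), adaptive gain
  (context-centred sigmoid), and divisive normalisation.
* **Fitting and comparison.** Multi-start bounded maximum likelihood,
  stratified k-fold cross-validation, BIC, and random-effects Bayesian
  model selection with protected exceedance probabilities
  (`pxp = xp·(1−BOR) + BOR/K`), plus parameter- and model-recovery
  harnesses.
* **Behavioural analyses.** Weighted logit GLMs of relative accuracy with
  z-scored regressors and product interactions, matched binary baselines
  with observation weights, permutation-based condition-unspecific bias
  correction, 71×71 sliding quantile-window accuracy maps, and the 2×2
  decoy table (proximity × AU-dominance) with a closed-form
  repeated-measures ANOVA.
* **Synthetic data.** A generator that emulates the published trial
  structure (150 ternary + 150 binary trials, many-to-one baseline
  matching, the `|cor(DV−HV, HV−LV)| ≤ 0.1` decorrelation constraint, and
  optional induced covariation between DV−HV and the targets' AU
  difference), plus static/dynamic simulated agents.

## Worked example

```r
library(decoyrace)

# the two worked prospect pairs: equal EV differences, unequal AU differences
fx <- make_fixture("intro_pairs")
fx$truth
#>   pair ev_diff au_diff_sum
#> 1    1     0.1         0.1
#> 2    2     0.1         0.2
```

Both pairs differ by 0.1 in expected value, yet the additive-utility
difference of the second pair is twice that of the first — so an agent
integrating attributes additively finds the second pair much easier, and
any design quantity that covaries with ΔAU will masquerade as a distractor
effect in an EV-based analysis.

```r
# simulate a selective-integration agent on a decoy-rich design and
# recover the classic attraction/repulsion signature
spec <- model_spec("si", "static", si_w = "ordered")
trials <- generate_choice_sets(generator_config(seed = 1))
sim <- simulate_agent(trials, agent_spec(spec,
        list(lambda = 0.5, w3 = 0.8, w2_ratio = 0.375, beta = 10)), seed = 2)

p <- choice_probability(c(0.65, 0.45),
                        ffi_params(k = 6, c = 0.5, theta = 1, i0 = 1))
round(p, 4)
#> [1] 0.7585 0.2415
```

The FFI race with these settings chooses the higher-utility option on
75.9% of trials; `mean_rt()` gives the matching conditional mean response
times, and `simulate_race()` reproduces both to within Monte-Carlo error.

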