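---
title: "Models and methods for distractor effects in two-attribute risky choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for distractor effects in two-attribute risky choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoyrace)
```

## The problem

In a speeded risky-choice task, two available prospects — each defined by a
reward magnitude $X$ and a reward probability $P$ on normalised $[0,1]$
scales — are shown either alone (*binary* trials) or together with a third,
*unavailable* distractor prospect $D$ (*ternary* trials). The available
targets are labelled by expected value ($EV = X \cdot P$): $H$ for the
higher-EV target, $L$ for the lower. The scientific questions this package
operationalises are (i) whether the distractor's value genuinely modulates
the relative choice accuracy $p(H\ \mathrm{over}\ L)$, or whether apparent
distractor effects ride on covariations built into pseudo-random trial
designs; and (ii) whether classic multiattribute decoy effects (attraction
and repulsion) account for what remains.

`decoyrace` implements the full pipeline: the data model and matched-baseline
machinery, static and dynamic (choice + RT) utility models with
context-dependent transforms, maximum-likelihood fitting and
cross-validation, random-effects Bayesian model selection, the behavioural
GLM/permutation/decoy analyses, and a design-faithful synthetic-data
generator so that every stage is testable without access to the original
datasets.

## Utility models

All utilities operate on the normalised attribute scales.

* **EV**: $U = XP$ (multiplicative, the normative baseline).
* **Additive utility (AU)**: $U = \lambda X + (1-\lambda) P$ with magnitude
  weight $\lambda \in [0,1]$. A plain attribute-sum convention ($X + P$) is
  also provided; it differs from the weighted mean by a factor of 2 at
  $\lambda = 0.5$ and is rank-equivalent, which matters only when quoting
  absolute utility differences.
* **Non-linear distortions**: magnitude may pass through a power law
  $X^\gamma$; probability through either a linear-in-log-odds transform with
  slope $\eta$ and fixed point $P_0$, or the one-parameter inverse-S
  curvature $P^\tau / (P^\tau + (1-P)^\tau)^{1/\tau}$. Expected utility
  (free $\gamma$, linear probability) and the prospect-theory form (free
  $\gamma$ and $\tau$) are the multiplicative special cases. Endpoint
  probabilities 0 and 1 are mapped to themselves under the log-odds
  transform (its limit behaviour) with a warning rather than an error.
* **Selective integration (SI)**: within each attribute, alternatives are
  ranked; the top value is untouched, the intermediate is multiplied by
  $1 - w_2$ and the lowest by $1 - w_3$, with $0 \le w_2 \le w_3 \le 1$
  ("suppressed by $w$" is implemented as multiplication by $1 - w$, forced
  by the percent-reduction reading and the $w = 1 \Rightarrow 0$ boundary).
  Ties for the top leave both values untouched; ties for the bottom gate
  both by $w_3$; a three-way tie leaves the attribute unchanged (no rank
  information to act on). With two alternatives only one losing rank
  exists, so the lower value is gated by a single weight. The gated
  attributes are recombined as an AU.
* **Adaptive gain**: each attribute value is centred on the mean across the
  alternatives in the choice set and passed through
  $1/(1 + e^{(b - x)/s})$; slopes and biases are per-attribute by default
  (the attribute-subscripted parameterisation), with an option to tie them.
* **Divisive normalisation (DN)**: each utility is divided by the sum of
  utilities across the alternatives present (including an unavailable $D$).

Context-sensitive transforms (SI, adaptive gain, DN) see the full choice
set — the distractor shapes the transform — but only $H$ and $L$ ever race
or enter the softmax: the unavailable option is never a response.

## Dynamic models: feedforward-inhibition race

Each alternative drives an independent accumulator
$dx_i = \mu_i\,dt + \xi\sqrt{dt}$ with unit noise and zero starting point,
absorbed at bound $\theta$; fixing $\sigma = 1$ and $x_0 = 0$ measures $k$
and $\theta$ in noise units and removes the usual scaling degeneracy. The
drift combines utility excitation and feedforward inhibition by the
competitors' mean utility,
$$\mu_i = k U_i - c\,k\, \overline{U}_{j \ne i} + I_0,$$
so $c = 0$ is a pure race and $c = 1$ a drift-diffusion model on the
utility difference. First-passage times are inverse Gaussian; the trialwise
likelihood of choice $i$ at decision time $T = RT - t_{nd}$ is the
first-passage density of accumulator $i$ times the survival of every
competitor. The survival term
$\Phi\!\big(\tfrac{\mu T - \theta}{\sqrt T}\big) +
e^{2\theta\mu}\,\Phi\!\big(\tfrac{-\mu T - \theta}{\sqrt T}\big)$
is evaluated with the exponential folded into the normal log-CDF so large
$\theta\mu$ cannot overflow.

Choice probabilities and conditional mean RTs are trapezoidal integrals of
the trialwise likelihood on a configurable grid (default $dt = 1$ ms,
horizon 100 s; a warning is raised if more than $10^{-4}$ probability mass
lies beyond the horizon). Trial likelihoods are floored at $10^{-10}$
before logging so optimisation stays finite; the floor — and with it the
treatment of RTs at or below $t_{nd}$, which contribute the floor value —
is this package's numerical choice.

**Dual-route model.** Two mutual-inhibition races run simultaneously on the
expected values: a vanilla route, $I_i = U_i - f_{MI}\,\overline{U}$, and a
route on divisively normalised EVs. All $2n$ accumulators race; the first
absorption determines the response, so the likelihood of choice $i$ sums,
over routes, that route's density for $i$ times the survival of every other
accumulator in both routes. On ternary trials the unavailable distractor
contributes to the inhibition means and the DN denominator but does not
accumulate.

**Simulation oracle.** `simulate_race()` integrates the same dynamics by
Euler–Maruyama. Discretely monitored paths systematically miss intra-step
bound excursions, inflating first-passage times by $O(\sqrt{dt})$; the
simulator therefore applies the standard continuity correction (bound
shifted inward by $0.5826\,\sigma\sqrt{dt}$), after which simulated choice
frequencies and RT distributions agree with the analytic formulas to within
Monte-Carlo error at $dt = 1$ ms (the tests check 3 Monte-Carlo standard
errors for choice frequencies and Kolmogorov–Smirnov distance below 0.02 at
$10^5$ paths). Paths not absorbed by the horizon (or the response deadline,
when simulating agents) are censored and recorded as non-responses, which
downstream analyses exclude — matching how non-responses are treated in the
data model.

## Static models and fitting

Static models apply a softmax with inverse temperature $\beta$ to the
options' utilities and are scored by the weighted binomial log-likelihood
of per-condition choice proportions (the observation model for static fits
is per-condition proportions with trial-count weights, not trial-level
Bernoulli). Dynamic models are scored by the joint choice/RT likelihood
summed over trials with an $H$ or $L$ response; D-choices and non-responses
are excluded everywhere.

Fitting uses bounded L-BFGS-B from a Latin-hypercube grid of starting
values (default 10 starts), with convergence tolerances at $10^{-10}$ or
stricter. The parameter boxes are a design choice ($k, \theta > 0$,
$c, \lambda, w, f_{MI} \in [0,1]$, $\beta \in [0,100]$,
$t_{nd} \in [0,\ 0.9\,\min RT]$, distortion parameters in $(0.05, 20)$):
wide enough to cover plausible behaviour, tight enough to keep the search
stable; point estimates near a bound should be interpreted with care. The SI ordering constraint is enforced by fitting $w_3$ and the ratio
$w_2 / w_3$, both box-bounded on $[0,1]$, which keeps the feasible set a
box. Cross-validation partitions trials into five random folds, stratified
by condition type when both are present so each fold mirrors the design
(stratification is this package's design choice).

## Random-effects model comparison

`rfx_bms()` implements the variational random-effects scheme over a
Dirichlet prior (one count per model): iterative updates of per-subject
model attributions and Dirichlet parameters until the parameters move by
less than $10^{-6}$, exceedance probabilities by sampling the posterior
Dirichlet ($10^5$ draws by default, seed-controlled), the Bayes omnibus
risk from the free energies of the random-effects model and the
equal-frequency null, and protected exceedance
$\tilde\varphi_k = \varphi_k (1 - BOR) + BOR/K$. Cross-validated
log-likelihoods are the default evidence, with $-BIC/2$ as an option.

Model recovery simulates each candidate model with supplied generating
parameters, refits all candidates to each simulated dataset, and summarises
each generating model's row with the random-effects comparison. Recovery
scoring defaults to $-BIC/2$: raw in-sample likelihood would mechanically
favour the more flexible models (the SI variant carries more free
parameters than the dual-route model), and penalised evidence is the
appropriate in-sample analogue of the cross-validated comparison used for
real data.

## Behavioural analyses

**Matched baselines.** Every unique ternary condition is matched to all
binary trials sharing its exact target quadruple $(H_X, H_P, L_X, L_P)$
(tolerance $10^{-9}$ for float round-trips); the match count becomes the
observation weight, and unmatched conditions are flagged, never silently
dropped.

**GLMs.** Relative accuracy is modelled with a weighted binomial logit.
Regressors (value difference, distractor variable — relative $DV - HV$ or
absolute $DV$, on an EV or AU basis — and optionally the value sum) are
z-scored *before* interaction terms are formed as products of the z-scored
components. Combined ternary/binary models include a condition dummy $C$
and every effect crossed with $C$. Binary observations inherit their
matched ternary condition's *notional* distractor values. Group-level
inference is by two-sided one-sample t-tests with Holm's step-down
correction, plus optional across-subject rank correlations.

**Condition-unspecific bias.** The generic accuracy change from binary to
ternary context is estimated by shuffling the mapping between ternary
conditions and matched baselines (5000 permutations by default) and
averaging the T − B contrast under the shuffle; the bias is removed as a
per-subject constant, so corrected contrasts preserve all
condition-specific structure. Shuffles are uniform within subject, without
re-weighting by match counts.

**Binned maps.** Outcomes are averaged in a square window sliding through
quantile space: 30% quantile edge, 1% step, giving
$\lfloor(100 - 30)/1\rfloor + 1 = 71$ positions per axis. Quantiles use R's
default linear interpolation; empty cells are `NA`.

**Decoy table.** Bias-corrected T − B contrasts are averaged into
per-subject 2×2 cells (decoy closer to H vs L × inferior vs superior in
AU), tested cellwise with Holm correction, and analysed with a 2×2
repeated-measures ANOVA computed in closed form from orthogonal
within-subject contrasts (for a 2×2 design this is exact; no iterative
mixed-model machinery is needed). Equidistant decoys are reported as ties
and excluded, as are decoys whose AU lies between the targets'.

## The synthetic-data generator

`generate_choice_sets()` emulates the deposited designs' structure: 150
ternary and 150 binary trials, targets labelled by EV, binary trials copied
from a subset of ternary conditions (default 95 unique, matching the
many-to-one pattern and producing observation weights above 1), and a
pseudo-random decorrelation constraint $|cor(DV - HV,\ HV - LV)| \le 0.1$
(the threshold is this package's default and configurable; the deposited
designs' exact value is not recorded anywhere accessible offline). Attributes are sampled uniformly on $X \in [0.1, 1]$,
$P \in [0.1, 0.9]$ — comfortably inside the normalised scales, avoiding
degenerate zero-EV prospects.

Two structural facts discovered by construction are worth recording. First,
a distractor sampled independently of the targets can *never* satisfy the
decorrelation constraint: $DV - HV$ shares $-HV$ with $HV - LV$, pinning
their correlation near $-0.46$ under independent sampling. The constraint
is met by greedily swapping or replacing distractors — which is exactly the
kind of pseudo-random selection that builds target-related covariations
into a fixed trial set. Second, the confound knobs act on the component of
the targets' AU difference orthogonal to $HV - LV$: `au_covariation` drives
$cor(DV - HV,\ \Delta AU_{\perp})$ up to a target (values around 0.3 are
realistic for fixed pseudo-random sets of this size), and
`au_decor_threshold` drives it to zero. The orthogonal component is the right handle because a
difficulty-controlled accuracy analysis conditions on $HV - LV$, so only
the orthogonal part of any covariation can masquerade as a distractor
effect. Even with the orthogonal correlation forced below 0.02, the
weighted logit retains a small positive notional slope (about 0.07 at
$\beta = 8$): the IRLS weights of a binomial fit depend on $p(1-p)$, so the
*weighted* covariation is not exactly zero. The diagnostic contrast is
therefore the collapse of the slope (below half its confounded value, with
a significant paired decrease), not exact nullity.

Simulated agents draw choices from softmax probabilities (static) or from
the Euler–Maruyama race (dynamic), with deadline censoring recorded as
non-responses. What the generator does *not* emulate: the original visual
stimuli and their perceptual mapping, sequential effects, attentional
capture by salient distractors, and subject-specific attribute scaling —
so passing tests demonstrate correctness of the pipeline on data whose
generative process is known, not fidelity of any particular parameter value
to human behaviour.

## Problem sizes used by the test suite

The tests exercise the pipeline at sizes chosen to give stable statistics:
worked-example checks are exact; the likelihood–oracle comparison uses 20
random parameter sets at $10^5$ simulated paths each; parameter recovery
uses 50 agents with 300 trials each; model recovery uses 4 agents per model
(SI, adaptive gain, dual-route) on 300-trial designs; the decoy-signature
analysis uses cohorts of 10 (decoy cells) and 100 (notional-slope GLM)
static agents. The 2×2 decoy geometry
fixture places three decoys in each proximity × dominance cell around a
fixed target pair, with margins large enough that the classification is
unambiguous.

## Worked example

```{r, eval = FALSE}
library(decoyrace)

# a design-faithful synthetic experiment
trials <- generate_choice_sets(generator_config(seed = 1))

# a selective-integration agent making speeded choices
spec <- model_spec("si", "ffi", fixed = list(c = 0.5, i0 = 1),
                   si_w = "ordered")
agent <- agent_spec(spec, list(lambda = 0.5, w3 = 0.8, w2_ratio = 0.375,
                               k = 8, theta = 1, tnd = 0.3))
data <- simulate_agent(trials, agent, seed = 2)

# refit and compare against a context-blind additive-utility model
fit_si <- fit_model(data, spec, nstarts = 10, seed = 3)
fit_au <- fit_model(data, model_spec("au", "ffi",
                                     fixed = list(c = 0.5, i0 = 1)),
                    nstarts = 10, seed = 3)
c(si = fit_si$bic, au = fit_au$bic)
```

## Known limitations

* The analytic likelihoods assume independent accumulators (no leak, no
  collapsing bounds, no trial-to-trial drift variability); these variants
  are out of scope.
* The generator reproduces the stated structural constraints of the
  deposited designs, not the exact stimulus lists, which are only available
  from the data repositories.
* Participant-level statistics of the original datasets (GLM t-values,
  published protected exceedance probabilities, mean $\lambda$) can be
  recomputed by running this pipeline on the deposited data exported to the
  documented CSV schema; they are not reproduced from synthetic data.
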