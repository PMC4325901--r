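# nfadapt

Simulation toolbox for studying **decision-threshold adaptation in
restorative brain-computer interfaces** (neurofeedback). Restorative BCIs
reward subjects for reaching specific brain states via a linear classifier
with a constrained feature space; the only tunable element is the decision
threshold θ. `nfadapt` models the training loop as a two-action
beta-Bernoulli reinforcement-learning problem and asks which thresholds —
fixed or adapted over the course of training — teach fastest, in
particular for near-chance feedback ("BCI illiteracy"). It is written for
computational neuroscientists and BCI methodologists who want to
prototype threshold-adaptation policies before touching a subject.

## Model

The subject sits at position σ on a one-dimensional state continuum and
chooses between the trained action `a_T` (step δ toward the trained state)
and the false action `a_F`. Reward probabilities are logistic in the
classifier threshold θ:

    P(r | a_T; θ, σ) = 1 / (1 + exp(D(θ − Δ + σ)))
    P(r | a_F; θ, σ) = 1 / (1 + exp(D(θ + Δ + σ)))

with discriminability `D` and curve offset `Δ`. The subject holds beta
beliefs `Beta(α_a, β_a)` about each action's reward rate and selects the
trained action with probability

    P(a_T) = F̄(r_F; α_T, β_T) / (F̄(r_F; α_T, β_T) + F̄(r_T; α_F, β_F)),

where `F̄ = 1 − F` is the upper-tail regularized incomplete beta function
and `r_a = α_a/(α_a+β_a)` the anticipated rewards (Thompson-style
confidence comparison). Training progress is measured by the binary action
entropy `H = −[p log₂ p + (1−p) log₂(1−p)]` of the selection probability
and by the instructional efficiency `IE_i = (p_{i+1} − p_i)/(1 − p_i)`,
the realized fraction of the maximum possible one-step gain. Both a
deterministic expectation recursion and a stochastic Monte-Carlo sampler
are provided, along with maximum-likelihood calibration of `(D, Δ, σ)`
from per-threshold binomial reward counts and a point-wise
Kullback-Leibler analysis of the reward-information asymmetry.

## Worked example

Train in the moderate environment (`D = 1.7`, peak balanced accuracy
0.846) at the maximum-accuracy threshold, then sweep all thresholds:

```r
library(nfadapt)

env <- standard_environment("moderate")
tr  <- run_fixed(env, theta = 0, n_iter = 10000)
tr
#> Training trace: fixed schedule, 10000 iterations (confidence/selection_weighted/toward_trained)
#>   p_T: 0.500 -> 1.000   entropy: 1.000 -> 1.4e-07 bits
```

The trained-action probability rises from indifference (0.5) to near
certainty; entropy — the subject's residual uncertainty about which action
pays — falls from 1 bit to ~1e-07 bits. Sweeping every threshold shows
*when* each threshold teaches:

```r
sw <- threshold_sweep(env)   # 201 thresholds x 10,000 iterations
sw
#> Threshold sweep: 201 thresholds in [-10, 10], 10000 iterations (confidence/selection_weighted/toward_trained)
#>   argmin-entropy trace: early peak -0.3 (iterations 9-12), late peak 3.7 (iterations 205-205)
```

The entropy-minimizing threshold starts at 0 (maximum accuracy), dips to
−0.3 around iteration 10 — early on, abundant-reward thresholds teach
faster — then climbs to 3.7 by iteration ~200: once beliefs separate,
scarce but informative rewards dominate. Replaying the per-iteration
efficiency-maximizing thresholds as an adaptive schedule and comparing
against the fixed-threshold run:

```r
cmp <- adaptation_crossover(sw, "efficiency")
cmp
#> Entropy-ratio comparison over 10000 iterations
#>   test exceeds reference in iteration windows: 14-10000
#>   final relative entropy: 2.117 (3.26 dB)
```

Here adaptation trades early performance for information and, in this
environment, does not recoup it; in the illiterate environment
(`D = 0.4`) the same comparison crosses below the fixed reference at
iteration 906 and ends 25 dB better — threshold adaptation helps most
exactly where feedback is worst. Calibrating an environment from a
synthetic recording session:

```r
tab <- simulate_reward_counts(env, grid = threshold_grid(-10, 10, 0.5),
                              trials_per_threshold = 1000, seed = 1)
fit_environment(tab)
#> Logistic reward-environment fit
#>   D = 1.6712, Delta = 1.0013, sigma = 0.0017
#>   deviance 27.70 on 79 df
```

A thin command-line front end over the same functions is installed at
`inst/cli/nfadapt.R` (subcommands `run-fixed`, `sweep`, `adapt`,
`compare`, `mc`, `fit`, `repro`).

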