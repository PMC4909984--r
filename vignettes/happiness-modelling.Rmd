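---
title: "Modelling momentary happiness under social inequality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling momentary happiness under social inequality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mswb)
```

# The scientific problem

Momentary subjective well-being — the answer to "How happy are you at this
moment?", sampled repeatedly during a task — tracks the recent history of
rewards and expectations rather than cumulative earnings. In a risky-choice
setting, three event types per trial carry that history: the certain reward
(CR) when the safe option is taken, the expected value (EV) of a chosen
gamble, and the reward prediction error (RPE, outcome minus expectation)
when the gamble resolves. When the task is played alongside a social
partner whose gamble resolves independently, a fourth force appears:
inequality between one's own reward R and the partner's reward O.
Advantageous inequality (R > O) and disadvantageous inequality (O > R) map
onto the social emotions of guilt and envy, and individual sensitivity to
them turns out to predict altruistic behaviour (dictator-game generosity)
measured in a separate task.

`mswb` implements this entire analysis as testable, reproducible code: task
and session construction, a prospect-theory partner agent, the happiness
models, per-subject fitting and Bayesian model comparison, the model-free
descriptive analyses, the generosity linkage, and a synthetic-cohort
generator that makes every stage exercisable end-to-end without any
human data.

# The happiness models

All models express the z-scored happiness rating after trial $t$ as a sum
of exponentially decayed event terms with forgetting factor
$\gamma \in [0,1]$:

$$
\mathrm{happiness}(t) =
w_1 \sum_{j\le t} \gamma^{t-j}\,\mathrm{CR}_j +
w_2 \sum_{j\le t} \gamma^{t-j}\,\mathrm{EV}_j +
w_3 \sum_{j\le t} \gamma^{t-j}\,\mathrm{RPE}_j + \dots
$$

Terms for unchosen options are zero: a safe choice contributes only
$\mathrm{CR}_j$; a chosen gamble contributes $\mathrm{EV}_j$ at choice and
$\mathrm{RPE}_j$ at outcome (both attached to trial $j$). Ratings are
z-scored per subject, so no constant term is fitted. Three nested variants
differ in their social terms, computed from $(R_j, O_j)$ on social trials:

* **non-social** (4 parameters): CR, EV, RPE weights plus $\gamma$;
* **simple-inequality** (5): adds one weight on $|R_j - O_j|$;
* **guilt–envy** (6): adds $w_4$ on $\max(R_j - O_j, 0)$ (advantageous
  inequality, guilt) and $w_5$ on $\max(O_j - R_j, 0)$ (disadvantageous
  inequality, envy).

The identities $\max(d,0)+\max(-d,0) = |d|$ and $\max(d,0)-\max(-d,0) = d$
make the three models nested, which the test suite exploits (fitted residual
sums of squares must be ordered).

# Task and session design

Sessions follow the printed design exactly. The non-social task has 140
trials with a rating at the start and after every tenth trial (15 ratings).
The social task interleaves non-social and social trials — never more than
two non-social or four social trials in a row — with a rating after every
2–3 trials: procedure P1 runs 210 trials (70 + 140) with 85 ratings,
procedure P2 runs two 150-trial sessions (50 + 100) with 61 ratings each.
Because $2a + 3b = \mathrm{trials}$ and $a + b = \mathrm{ratings}$ has an
exact integer solution for both procedures, the generator draws the gap
sequence as a shuffled multiset rather than repairing a random draw. The
interleaving itself is built greedily with a feasibility look-ahead, so no
rejection loop is needed and any seed yields a valid schedule.

Trial amounts are not printed in the source design beyond one example
(a £0.95 gamble), so the default battery is a package choice: Gain safe
amounts £0.30–0.60 with gamble highs 1.6–2.8 times the safe amount, Mixed
gambles gaining £0.40–1.50 against losing £0.30–1.00, Loss trials mirroring
Gain. These ranges were set so that the typical prospect-theory agent
(below) gambles on roughly 55% of trials, the observed gamble rate in this
task family; narrower published-style ranges put the agent nearer 40%,
which distorts how often inequality can arise. Amounts snap to 5p.

# The partner agent

Social-trial choices come from a deterministic prospect-theory agent with
power utility $u(x) = x^\rho$ for gains, $u(x) = -\lambda(-x)^\rho$ for
losses, loss aversion $\lambda = 1.35$ and curvature $\rho = 0.9$ (risk
averse in gains, risk seeking in losses). Probability weighting is omitted:
every gamble is 50/50, so any weighting constant is absorbed into the other
parameters. Ties break toward the safe option, keeping the agent fully
deterministic; a softmax mode (inverse temperature `mu`) exists for
heterogeneous synthetic subjects but is off by default, since no choice
temperature is documented for the original agent. When the partner takes
the safe option both players receive it; when the partner gambles, two
independent fair coins resolve the subject's and the partner's outcomes —
the design feature that generates all four equality/inequality contexts.

# Fitting and model comparison

Per-subject fitting minimises the sum of squared errors between z-scored
ratings and model predictions. For fixed $\gamma$ the model is linear in
the weights, so the optimiser profiles $\gamma$: an exact least-squares
solve at each point of a $\gamma$ grid (step 0.01), then local refinement
of the best grid point by golden-section search (`stats::optimize`,
tolerance $10^{-8}$). This is deterministic, cannot leave $[0,1]$, and
matches a dense grid and a multi-start joint optimiser on test instances.
Boundary estimates ($\hat\gamma$ at 0 or 1) are flagged. Subjects whose
non-social model explains under 10% of rating variance are flagged but not
excluded.

For procedure P2 the two sessions are fitted jointly with one parameter
set: decayed sums reset at the session boundary (a dictator game and a
partner change separate the sessions) and residuals concatenate.

Model comparison uses the Gaussian least-squares BIC,
$n\log(\mathrm{rss}/n) + k\log n$, with $k$ counting weights plus
$\gamma$ (4/5/6) and $n$ the subject's rating count; BIC is summed across
subjects and reported relative to the winning model. $r^2$ is
$1 - \mathrm{rss}/\mathrm{TSS}$ on the z-scored ratings.

# Descriptive analyses

The model-free analysis classifies every social trial on which the partner
gambled by whether each player received the better of the two equiprobable
outcomes: both win, both lose, subject wins / partner loses, subject
loses / partner wins. Each qualifying trial contributes the next rating's
z-value to its context; a rating serves every qualifying trial since the
previous rating, since ratings are sparser than trials. The guilt measure
is mean(subject wins, partner loses) − mean(both win); the envy measure is
mean(subject loses, partner wins) − mean(both lose); their difference
equals the happiness difference between partner-loses and partner-wins
contexts and is the individual-difference measure linked to generosity.
Group tests use per-subject means as the unit and standard nonparametric
routines (Wilcoxon signed-rank and rank-sum, Spearman correlations) via
`stats::wilcox.test` and `stats::cor.test`.

# The synthetic-cohort generator

`simulate_cohort()` emulates a full study: 47 subjects by default, 22 under
P1 (endowment £3) and 25 under P2 (endowment £2), each with the
140-trial non-social task, their social session(s), ratings generated from
the guilt–envy model with subject-specific parameters plus Gaussian noise,
and a dictator-game allocation statistically linked to the subject's
guilt−envy weight difference. Identical `(config, seed)` reproduce every
byte; ground truth is stored apart from the observed tables.

Population defaults, and why:

* CR/EV/RPE weight means 0.83, 0.62, 1.15 — the documented non-social
  fitted means; sds default to half the mean magnitude (no population
  spread is documented).
* $\gamma \sim N(0.67, 0.25)$ truncated to $[0,1]$, with the latent
  location shifted so the *truncated* mean equals 0.67 (naive truncation
  would deliver 0.63).
* Guilt and envy weights are drawn independently (their observed
  reactivities are uncorrelated), with means −1.1 and −0.35 and sds 0.35
  and 0.25. The asymmetry is deliberately large: the printed Bayesian model
  comparison prefers the guilt–envy model over the one-parameter
  inequality model by roughly two BIC units per subject, and that margin is
  only attainable when per-subject $|w_4 - w_5|$ is substantial — a
  near-symmetric population (e.g. −0.5 vs −0.35) makes the extra parameter
  lose to its own penalty. This mirrors the finding that guilt weights
  exceeded envy weights in magnitude for most subjects.
* Rating noise sd 1.0 z-units, set so that fitted guilt–envy $r^2$ on
  default cohorts averages ≈ 0.44, the documented fit quality.
* Generosity: latent allocation $= 20 - 21\,(w_4 - w_5 - \overline{d}) +
  N(0, 15)$ percent of endowment, censored to $[0, 50]$, snapped to 0
  below 10 and to 50 above 35 (dictator allocations cluster at "nothing"
  and "half"), and rounded to 5%. This delivers a ≈ 20% mean allocation,
  ≈ 29% giving nothing, ≈ 19% giving half, and a Spearman correlation
  near −0.48 between the weight difference and the allocation. Setting
  `slope = 0` disables the linkage for null experiments.

## Rating scales: model units versus the display scale

The generator's native observation is the model-scale series
$y = \mathrm{prediction} + \varepsilon$ (z-units). For realism it also
emits a display-scale rating, `raw` $= m_i + s_i\,y$ clipped to 0–100 with
per-subject $(m_i, s_i)$, and the observational pipeline z-scores those raw
ratings before fitting — exactly what one does with human data. The two
paths are not numerically identical: sample z-scoring subtracts the
*sample* mean and divides by the *sample* sd, so it recovers $y$ only up
to a subject-specific affine map, and a model with no constant term cannot
absorb the induced offset exactly. Parameter-recovery studies therefore
run on the model scale (`ratings_scale = "model"`), where the noiseless
round trip is exact to optimizer precision, while model comparison,
descriptives and calibration run through the realistic raw path. A
practical consequence worth knowing: weights fitted after z-scoring are in
per-subject standardised units, which attenuates cross-subject
correlations between fitted and generative weights — the parameter-based
generosity linkage is therefore noticeably noisier than the linkage
computed from ground-truth weights.

# What passing tests show — and what they do not

The synthetic cohorts reproduce the *structure* of the phenomenon: the
four-context inequality pattern, independent guilt/envy variation, the
generosity linkage, and the model-comparison verdict. They do not
reproduce human rating dynamics (drift, autocorrelated mood, scale-use
habits), response times, timeouts, or partner-specific effects in P2, and
the non-social model's $r^2$ on synthetic data (~0.31) sits below the
documented 0.39 because the synthetic social contribution to rating
variance is larger than in the human data. Passing tests therefore
validate the analysis machinery and its statistical power under stated
conditions, not the biology.

# Problem sizes and numerical choices

The test suite and acceptance script use cohorts of 20–47 subjects: 20
(P1, noiseless) for exact recovery, 30 (P1, noise 0.5) for noisy recovery,
and the full 47-subject default for model comparison and linkage — sizes
chosen to match the study design while keeping a complete run in well
under a minute per experiment. Oracle checks (naive $O(n^2)$ regressor
construction, dense $\gamma$ grids, joint optimisation, exhaustive
signed-rank enumeration) run on instances of 4–36 trials. Degenerate
inputs are first-class: constant ratings refuse to z-score, `rss = 0`
flags BIC as degenerate, empty contexts and zero-variance correlations are
flagged rather than silently dropped, and rank-deficient design columns
(e.g. social terms in a purely non-social session) fit as zero weights.
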