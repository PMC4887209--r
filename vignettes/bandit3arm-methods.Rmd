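---
title: "Models and methods behind bandit3arm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bandit3arm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandit3arm)
```

This vignette documents the scientific content of the package: the task it
models, the learning model and its fitting, the lagged credit-assignment
kernel, the behavioural metrics, the synthetic agents, and the numerical
and design choices made where the underlying procedures left the design
genuinely open.

## The task

A subject faces three novel stimuli per session and chooses one per trial;
reward is a Bernoulli draw from the chosen option's scheduled probability,
independent of the other options, with no carry-over of unclaimed rewards.
Two schedule families are modelled:

* **Varying** (`stable`, `variable`): 300 trials; per-option probabilities
  drift continuously; one option (V1) is clearly best during the first 150
  trials, after which the best-option identity swaps to another option.
  The two kinds generated from a common seed differ *only* in the
  pre-reversal trace of the best option — stable holds it in a narrow high
  band, variable lets it wander over a wide band — so that any behavioural
  difference between them is attributable to the volatility of the initial
  learning period.
* **Fixed** (`fixed1`–`fixed3`): 150 trials of constant probabilities.
  The three levels share one option ratio; levels 2 and 3 scale the yield
  by 0.75 and 0.5. The shipped base probabilities (0.8, 0.5, 0.2) are a
  configurable default chosen to satisfy the ratio and yield constraints,
  which are the testable content; any strictly decreasing base in (0, 1]
  may be supplied.

Exact published probability traces for the varying schedules are available
only graphically, so the generator produces a parametric family: per-option
bounded smoothed random walks (Gaussian increments, reflecting boundaries,
5-trial smoothing confined to each half of the session) within dominance
bands, with a forced identity swap at trial 150. Each option and session
half draws from an independent RNG substream, which is what makes the
"stable and variable differ only in the pre-reversal V1 trace" property
exact rather than approximate. Explicit schedules can instead be loaded
from TSV via `read_schedule()`.

The objectively best option per trial, **V1_sch**, is the argmax of the
moving-window-smoothed scheduled probabilities. The window is 20 trials,
centred (±10), truncated at session edges rather than padded — padding
would fabricate data outside the session. Whether the original analyses
used a centred or trailing window for every quantity is not fully
specified; both alignments are exposed (`align` argument), with centred the
default for value labels and trailing hard-wired into the learning
criterion, where "trials to reach criterion" semantically requires a
window ending at the reported trial. Argmax ties break to the lowest
option index, a documented deterministic rule.

## The learning model

Option values follow the Rescorla–Wagner delta rule, applied to the chosen
option only, with Boltzmann (softmax) choice:

$$V_{t+1}(c_t) = V_t(c_t) + \alpha\,(r_t - V_t(c_t)), \qquad
P(c) = \frac{e^{\beta V_t(c)}}{\sum_{c'} e^{\beta V_t(c')}}.$$

Tunable parameters: the learning rate $\alpha \in [0,1]$ (dimensionless;
default 0.3 for simulated agents), the inverse temperature $\beta \ge 0$
(in units of 1/value; default 5, a moderately exploitative setting that
yields ~60–80% best-option choice on the fixed schedules, in the range real
subjects show), and the initial value (default 1/3, the symmetric prior
over a 0/1 reward). Values reset at every session start because each
session uses novel stimuli.

`fit_learning_rate()` minimises the negative log-likelihood of the choices
under forward-simulated values, computed in compiled code since it is the
hot loop of the fit. Optimisation is L-BFGS-B over $\alpha \in
[10^{-4}, 1]$ and $\beta \in [10^{-3}, 50]$ from a 5×4 multi-start grid
($\alpha \in \{0.05, 0.2, 0.4, 0.6, 0.9\}$, $\beta \in \{1, 3, 8, 20\}$);
the best converged start is returned with per-start diagnostics, and
estimates at the $\alpha$ bounds are flagged (`at_boundary`), as happens
for degenerate inputs such as identically rewarded forced choices. The
original fitting procedure reports only "a learning rate"; how the
temperature was handled is unstated, so the package fits both jointly by
default (`fit_beta = TRUE`) and offers a fixed-$\beta$ mode. Likelihoods
are exact up to the softmax's max-subtraction stabilisation; a
zero-probability choice under degenerate parameters yields `+Inf`, never
an error.

**V1_RL**, the subjectively best option, is the per-trial argmax of values
forward-simulated from the subject's actual choices and rewards at the
fitted (pre-phase) learning rate, reused unchanged for post-phase data so
that pre/post comparisons are not confounded by refitting.

## The history kernel

The package's centrepiece is a lagged choice×outcome logistic regression
measuring how outcomes are credited to past choices. For each target
stimulus, the response is "chose the target at trial $n$" and there are 36
explanatory variables, one per (choice lag $i$, outcome lag $j$) pair with
$i, j \in 1..6$: 0 if the outcome at $n-j$ was no reward, +1 if it was a
reward and the choice at $n-i$ was the target, −1 if a reward and the
choice was another stimulus. The 25 pairs with $i, j \le 5$ are the
weights of interest; the 11 pairs with $i = 6$ or $j = 6$ are confounds
capturing longer-term choice/reward trends, fitted but excluded from the
grid — this 6×6-grid completion is the unique reading that reproduces the
counts 36 = 25 + 11. The first six trials of each session contribute no
rows and histories never span sessions (novel stimuli each session). An
intercept is fitted and reported but excluded from the grid.

The three per-stimulus estimates are combined by the
inverse-covariance-weighted mean
$\hat\beta = (\sum_s \hat C_s^{-1})^{-1} \sum_s \hat C_s^{-1}\hat\beta_s$,
which reduces to the arithmetic mean under equal covariances and
discounts noisily estimated stimuli. The covariance is the inverse
observed information by default; a robust (sandwich) option is provided
since the original choice is not recorded. Singular covariances fall back
to the Moore–Penrose pseudo-inverse with a flag.

Because the EVs are sparse ternary variables, short synthetic sessions can
separate the logistic fit. Separation (non-convergence, fitted
probabilities at 0/1, or divergent coefficients) triggers a refit with a
small ridge penalty on the slopes ($\lambda = 10^{-2}$, intercept
unpenalised), always flagged, never silent; aliased columns are reported
and zeroed. The fitting unit is one subject × phase, pooling sessions;
per-session fitting is available by passing single sessions.

The 5×5 interest grid partitions into **contingent** weights (diagonal,
$i = j$: each outcome with the choice that produced it), **choice spread**
($i < j$: a recent choice associated with an unrelated earlier outcome)
and **outcome spread** ($i > j$: a recent outcome spreading backward onto
earlier choices) — 5 + 10 + 10 cells. By-lag summaries average the
off-diagonal triangle cells of each row/column and are undefined (`NA`) at
lag 5, which has no unrelated partner lags. `recency_contrast()` compares
the last outcome's interaction with recent (lags 1–2, or 2–3 in the
non-contingent variant that avoids conflating the contingent lag-1 cell)
versus distant (lags 4–5) choices.

## Behavioural metrics

All tables are event counts over conditional probabilities, cross-checked
in the test suite against deliberately naive trial-by-trial scanners.

The **A_kB** analysis required one genuine design decision. An event at
trial $n$ is: stimulus B chosen at $n-1$, preceded by a homogeneous run of
$k$ choices of a different stimulus A over $n-2 \ldots n-(k+1)$, with
$k \ge 4$ pooled into a "4–7" bin. Runs are assessed within a 7-trial
lookback window ($n-2$ to $n-8$); the run must be maximal *and clean*: a
history whose run stimulus reappears earlier within the window (e.g.
C, A, C then B) mixes identities and is not an A_kB condition. The
cleanliness requirement is what makes histories like that one ineligible
while keeping ordinary runs preceded by other stimuli eligible; runs
longer than the window are capped into "4–7" by default
(`pool_long_runs = FALSE` discards them), and the weaker reading in which
A_1B does not constrain trial $n-3$ is available as `maximal = FALSE`.
Bins are disjoint for a given trial in the default mode.

The **choice-frequency** table conditions repetition of the $n-1$ choice
on how often it was chosen over trials $n-2 \ldots n-6$ (0–5) and on the
$n-1$ outcome. The **criterion** is the first trial whose trailing
20-trial window (inside the segment; post-reversal counts restart at the
reversal) reaches ≥ 65% best-option choices, threshold inclusive.
**Latencies** are natural-log transformed; stay/switch classification
matches the switch table; histograms use [0, 100), [100, 200), … ms bins.
**Fixed-schedule sessions** classify as EARLY LOW (first-20 proportion
≤ 0.25) or EARLY HIGH (≥ 0.75), endpoints are last-20 proportions, and
group endpoint distributions are compared per class with a two-sample
Kolmogorov–Smirnov test treating sessions as independent samples — a
standard test, deliberately not bespoke.

## Synthetic agents and what they do (not) show

The generator exists because the original behavioural data are not
deposited; simulated cohorts stand in for them. The control agent is the
Rescorla–Wagner/softmax learner above with a lognormal latency model:
$\log \text{latency} \sim \mathcal N(\log(b + a\,\mathbb 1[\text{switch}]),
\sigma)$ with base $b = 400$ ms, switch addition $a = 150$ ms and
$\sigma = 0.35$ — a minimal model producing the characteristic
switch-trial slowing as a constant log offset, $\log((b+a)/b) \approx
0.32$.

The **lesion agent** operationalises an eligibility-trace account of the
MDmc lesion: a temporary record of recent choices gates how strongly an
outcome updates the chosen option's value. Concretely, the update is
multiplied by `trace_atten` (default 0.2 for lesion cohorts) whenever the
chosen option was selected fewer than 3 times over the previous 5 trials;
options with a long recent history update at full strength, leaving
long-run choice trends intact. The lesion latency phenotype sets the
switch addition to 0 and lowers the base to 300 ms. These settings were
chosen once as the cohort defaults; they are one configurable hypothesis
about the mechanism, not a claim of uniqueness — alternative mechanisms
can be added behind the same policy interface. Whether the general
latency speeding and the loss of the switch cost interact is unknown; the
generator treats them as independent parameters. This mechanism
reproduces, in direction: increased post-reward switching after the
reversal, a collapsed reward-vs-no-reward repetition difference at low
recent choice frequency with preservation at high frequency, and an
abolished stay/switch latency gap.

What passing tests on these agents show is that the *analysis pipeline*
measures what it claims to measure on data with the assumed generative
structure, including planted-ground-truth recovery: a `kernel_agent`
choosing by a multinomial logistic rule over planted kernel scores is
recovered by the regression with elementwise correlation > 0.9 at ~30,000
trials, and the learning rate 0.3 is recovered within ±0.1 in ≥ 90% of
50 replicate five-session cohorts. They do **not** show that real monkeys
satisfy those generative assumptions: real data have slow drifts in
motivation, stimulus-specific biases, autocorrelated latencies and
model-misspecified learning that the generator deliberately omits, so
agreement with the published animal results beyond structural constants
and phenotype directions is out of scope.

## Numerical choices and problem sizes

Softmax probabilities use max-subtraction; distributions sum to 1 within
1e-12. Ties in any argmax resolve to the lowest option index. The
moving-window mean truncates at edges. Degenerate inputs: empty sessions
are errors; sessions shorter than 7 trials contribute no regression rows;
zero-probability choices give infinite NLL; separation gives a flagged
ridge refit. All randomness flows through named integer seeds — schedule
seeds are shared per (kind, phase, session) across subjects, as in the
task, while behaviour seeds are per subject — and 32-bit substream seeds
are derived by hashing, so every cohort, session and report is a pure
function of its seed or manifest.

The shipped verification runs use 29,400 regression rows per stimulus for
kernel recovery, 50 replicate cohorts of 5 × 300 trials for learning-rate
recovery, and six-subject cohorts per arm for the phenotype contrasts —
sizes at which the Monte-Carlo error of each check is comfortably below
its decision margin.

## Known limitations

* The lesion mechanism is one hypothesis consistent with the qualitative
  findings; the package does not fit it to (unavailable) animal data.
* Group-level inferential statistics (repeated-measures ANOVAs, post-hoc
  tests) on such data are out of scope; only the KS endpoint comparison is
  included because it operates on per-session values the package computes.
* Per-stimulus regressions are binary logistic fits, as in the original
  analysis; when data are generated by a multinomial rule the per-stimulus
  coefficients are attenuated relative to the generator's weights, which
  is why recovery is asserted as correlation rather than unbiasedness.
* The schedule generator reproduces the published schedules' structure,
  not their exact traces.
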