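---
title: "Modelling altruistic choice under time pressure with a gaze-informed ADDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling altruistic choice under time pressure with a gaze-informed ADDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaddm)
```

## The decision problem and the model

The package models a modified dictator game: on each trial a participant
sees a proposal of $Self for themselves and $Other for an anonymous partner
(both $0–$100) and accepts or rejects it against a fixed $50/$50 default,
under either a 1.5 s (high time pressure) or a 10 s (low pressure) response
deadline.  A *generous* response sacrifices own payoff to the partner's
benefit: accepting when $Self < 50 < $Other, or rejecting when
$Self > 50 > $Other.

Choices and response times are generated by a multi-attribute sequential
sampling process.  Evidence for accepting, $x(t)$, starts at
$z = \mathrm{stbias} \pm \mathrm{genbias}$ (the sign follows the party the
proposal favours; positive $z$ leans towards accepting) and accumulates as

$$dx = V(t)\,dt + \sigma\,dW,$$

between symmetric collapsing thresholds $\pm b\,e^{-d t}$.  The momentary
value signal is a gaze-modulated weighted sum of three attributes,

$$V(t) = A_\mathrm{self}(t)\, w_\mathrm{self}\, \$\mathrm{Self}
       + A_\mathrm{other}(t)\, w_\mathrm{other}\, \$\mathrm{Other}
       + w_\mathrm{fairness}\, |\$\mathrm{Self} - \$\mathrm{Other}|,$$

where the attention factor $A$ is 1 for the currently fixated payoff and
$1-\theta$ for the unattended one ($\theta \in [0,1]$ is the attentional
discount; the inequality term carries no attention factor).  An attribute
contributes nothing until its information has been acquired: each first
fixation of an AOI opens an 80 ms perceptual-intake window during which
only *previously* acquired information (discounted by $1-\theta$) drives
the accumulator, and the attribute counts as "seen" only once its window
has completed.  Each opened window adds one fixed 80 ms `percept` latency
to the response time, and a fixed 80 ms `motor` latency is added at
threshold crossing, so

$$\mathrm{RT} = t_\mathrm{decision} + \mathrm{motor}
              + n_\mathrm{unique\ AOIs}\times\mathrm{percept}.$$

A trial is *missed* when the assembled RT would exceed the condition's
deadline.  The attention-blind comparison model (`model = "static"`) drops
$\theta$ and the fixation gating — all attributes drive the accumulator
from stimulus onset — and replaces the two fixed latencies with a single
fitted non-decision time `ndt`.

### Parameters, ranges, and the prior construction

Each of the 8 per-condition parameters lives on a fixed range (weights on
$[-0.1, 0.1]$ per dollar, $b$ on $[0, 0.5]$, $d$ on $[0, 2.5]$ s$^{-1}$,
the start biases on $[-0.5, 0.5]$, $\theta$ and `ndt` on $[0, 1]$).  The
sampler works on unconstrained parameters: a predisposition $M_p$ and a
time-pressure effect $\delta_p$ per parameter, combined as
$\Phi(M_p + \delta_p c)$ with $c = +1$ (high pressure) or $-1$ (low) and
then scaled linearly onto the range.  With independent $N(0, 0.5)$ priors
on $M$ and $\delta$, the sum is standard normal in each condition, so the
implied prior on every model parameter is exactly uniform over its range —
`log_prior()` and `to_model_space()` implement this construction, and a
test checks the push-forward uniformity by Kolmogorov–Smirnov.

### The diffusion scale

The noise scale $\sigma$ is not identifiable jointly with the weights and
threshold, so it must be fixed by convention.  The package fixes
$\sigma = 0.2$ per $\sqrt{s}$ (equivalently $0.02$ per 10 ms step, the
scale in widespread use for attentional drift-diffusion implementations).
This choice matters more than it may appear: with $\sigma$ of order 1, a
threshold confined to $b \le 0.5$ is crossed by noise within tens of
milliseconds — before the first fixation completes — so simulated choices
would be driven by the start point and noise alone, and the attribute
weights would be unidentifiable.  At $\sigma = 0.2$ a generative sweep
shows mean high-pressure RTs around 0.6 s, essentially no decisions before
information acquisition, and accept rates that respond strongly to the
weights, matching the qualitative regime of the experimental data.  All
weights and thresholds reported by the package are identified relative to
this convention; magnitudes are therefore comparable across fits of this
package but not directly to estimates obtained under another scale.

### Numerical integration

Trials are simulated by Euler–Maruyama on a fixed grid (1 ms by default
for data generation; the fitting presets use 10 ms).  Discrete-time
boundary checking biases first-passage times long by an effective barrier
shift of about $0.58\,\sigma\sqrt{dt}$, which at $\sigma=0.2$, $dt=10$ ms
is $\sim$4% of a typical threshold — small relative to the posterior
spread at the preset simulation counts.  The simulator-oracle test runs at
$dt = 0.05$ ms, where the bias is negligible against its 0.02 KS
tolerance.  Beyond 1.6 s into a trial the grid coarsens by a factor of 8;
this affects only slow low-pressure tails, where the resulting 80 ms
crossing-time granularity is far below the KDE bandwidths involved.
Degenerate inputs terminate immediately: if $|z| \ge b$ the trial resolves
at $t = 0$ (by the sign of $z$, or a fair coin at exactly zero).

## The simulation-based likelihood

The likelihood of an observed trial under candidate parameters is
estimated from `n_sims` fresh simulations of that trial (10,000 under the
`paper` preset).  For a responded observation it is the simulated
frequency of the observed choice class times a Gaussian kernel density —
over that class's simulated RTs — evaluated at the observed RT; for a
missed observation it is the simulated missed frequency.  Bandwidths
follow Silverman's rule of thumb halved
($0.5 \times 0.9\,\min(\mathrm{sd}, \mathrm{IQR}/1.34)\, n^{-1/5}$): gaze
switches between AOIs change the sampled evidence abruptly, producing
multi-modal, disjointed RT densities that a full-width bandwidth would
oversmooth.  Two stabilising conventions (the data admit no obvious value,
so fixed constants are used): likelihoods are floored at $10^{-10}$ so the
log-likelihood is finite everywhere on the parameter box, and a class with
fewer than two distinct RTs falls back to a 10 ms bandwidth.  The KDE
support is not truncated at the deadline; deadline censoring is carried
entirely by the separate missed-frequency term, and a test verifies that
accept density, reject density and missed mass jointly integrate to 1
within 2%.

## Posterior sampling

`addm()` fits both conditions of one subject simultaneously by
differential-evolution MCMC on the 16 unconstrained parameters.  Each
chain's proposal is its position plus a scaled difference of two other
randomly chosen chains ($\gamma = 2.38/\sqrt{2k}$; with probability 0.1 a
mode-jumping scaling $\gamma = 0.98$ is used instead, which lets chains
hop between separated posterior modes along the ensemble's difference
vectors) plus a small uniform jitter ($10^{-3}$), accepted by
Metropolis–Hastings on prior plus simulated log-likelihood.  Because the likelihood is stochastic, three
stabilisers are used: with probability 0.1 an iteration is replaced by a
*migration* step that cyclically offers a random subset of chains their
neighbour's state; a chain rejected three times in a row has its stored
log-likelihood re-evaluated with fresh simulations (de-biasing chains
stuck on a lucky noise draw); and halfway through burn-in, chains whose
mean position falls outside mean $\pm 1.96$ SD of the per-chain means in
any dimension are moved to a randomly chosen non-outlier chain's position.
Chains are initialised from the prior.  Convergence is assessed by the
Gelman–Rubin statistic on every sampled parameter with the usual
$\hat R < 1.1$ criterion, and estimates are posterior means mapped to
model space.  Subjects giving the same response on more than 90% of
responded trials are flagged by `exclusion_screen()`; their weights are
essentially unidentified and `addm()` warns when fitting them anyway.

Four presets trade fidelity for runtime: `paper` ($3k = 48$ chains,
$500+500$ iterations, 10,000 simulations per trial, 1 ms step — the full
estimation settings), `scaled_down` (48 chains, $300+300$, 250
simulations, 10 ms — a single subject in a few minutes), `recovery` (24
chains, $300+300$, 128 simulations, 10 ms — the multi-subject
parameter-recovery experiment, where accurate posterior means matter),
and `mini` (24 chains, $150+150$, 96 simulations, 10 ms — the quickest,
for directional comparisons).  The problem sizes in the test suite (10
fitted subjects at 80 trials per condition for parameter recovery; 8
gaze-coupled subjects at 40 trials per condition for model recovery) were
chosen so the full validation battery runs on one CPU in tens of minutes;
larger settings tighten the posteriors but do not change the structure of
any check.

Parameter recovery has a structural caveat: with proposals always on
opposite sides of the default, `w_other`, `w_fairness` and `genbias` trade
off along a likelihood ridge (for other-favouring proposals the drift is
effectively $(w_\mathrm{self}-w_\mathrm{fairness})\$S +
(w_\mathrm{other}+w_\mathrm{fairness})\$O$, and symmetrically for
self-favouring ones), so individual posterior means for these parameters
are noticeably noisier than for `w_self`, `b` or the start biases, and
short chains can land anywhere on the ridge.  A second, harder degeneracy
affects a minority of subjects in the low-pressure condition: their data
admit a sign-mirrored account — a near-collapsed threshold with
start-bias-driven choices and $\theta \approx 0$ — whose likelihood equals
the data-generating parameters' even when evaluated with very large
simulation counts and a fine integration step.  For such subjects the
posterior genuinely supports both solutions, and no sampler preset can
separate them; only more trials or a richer stimulus design would.  As a
result, recovery correlations for `w_self` and `w_other` pooled over both
conditions fluctuate from run to run (the high-pressure condition alone
recovers them strongly, and `b` and the start biases recover well
throughout), while the attentional discount $\theta$ and the collapse
rate `d` remain only weakly recoverable at desk scale.

## Gaze time-series analysis

`occupancy()` computes, per subject and millisecond, the proportion of
trials with gaze in the Self AOI, the Other AOI, or neither, among trials
still unresolved at that moment (missed trials contribute throughout; the
horizon defaults to 837 ms).  The pointwise statistic is a one-sample $t$
across subjects of the Self-minus-Other bias (or a paired $t$ of its
high-minus-low difference).  This subject-aggregated statistic replaces a
per-timepoint mixed-effects model: cluster-mass permutation practice only
requires a pointwise statistic whose sign and magnitude order candidate
clusters, and a subject-level $t$ keeps the permutation scheme exact under
subject exchangeability.  Candidate clusters are maximal runs of at least
2 adjacent milliseconds with two-tailed $p < 0.01$ and a common sign;
family-wise correction compares each cluster's mass (summed $|t|$) against
the 95th percentile of the maximum-mass distribution over sign-flip
permutations of whole subject series (for the condition contrast,
within-subject label swaps reduce to the same sign flip after
differencing).  A calibration experiment in the test suite verifies the
family-wise error over 200 null data sets built from the unbiased gaze
generator, and power against an injected early bias.
`early_gaze_bias()` is the signed Self-minus-Other dwell proportion over
the first 286 ms (or up to the RT when shorter), and `brown_forsythe()`
compares its between-subject variances across conditions via the
median-centred Levene ANOVA.

## Evaluation and model comparison

`quantile_ppc()` bins trials into ten within-subject quantiles of the
model-predicted acceptance rate and mean log RT (per condition) and
correlates observed with predicted bin means.  `split_half_cv()` fits each
candidate model on a subject's odd-numbered trials, predicts the
even-numbered ones by simulation at the posterior means, and compares
models on the across-subject correlation between predicted and observed
generosity — per condition and for the high-minus-low change — using
Williams' $t$ for dependent correlations (the standard test for two
correlations sharing an outcome variable).  Model recovery on synthetic
data with a strong attentional discount reproduces the expected ranking:
the gaze-informed model predicts held-out change in generosity better than
the attention-blind one.

## The synthetic-data generator

`gen_study()` produces complete study-like data sets with stored ground
truth.  Proposals are drawn from a $10 grid with $Self and $Other on
opposite sides of $50 (boundary amounts optional, since real stimulus sets
may or may not include them).  Subject-level parameters are drawn on the
unconstrained scale; the hyperprior keeps the attribute weights and
$\theta$ spread over their full ranges but concentrates the start biases
near zero and the threshold away from zero — under a fully flat draw a
large fraction of subjects would start on or outside a boundary and
respond instantly, which resembles no participant.  The default
time-pressure effect raises the collapse rate $d$ under high pressure
(mean $\delta_d = 0.8$ on the probit scale), reproducing the study pattern
of faster high-pressure responses and a higher missed rate under the 1.5 s
deadline.

Gaze is a two-state alternating renewal process: an initial NEITHER
latency (log-normal, median 100 ms), then strictly alternating SELF/OTHER
fixations (log-normal durations, median 250 ms, $\sigma_{\log} = 0.4$),
continued past the deadline so simulated slow paths always have gaze
defined.  The first fixated AOI is drawn with probability
$\mathrm{logit}^{-1}(\beta_{0,c} + \beta_{1,c}\, w_\mathrm{other}/0.1)$,
with a higher intercept and steeper negative slope under high pressure —
so early gaze is selfish on average under time pressure, more variable
across subjects, and negatively coupled to other-regard, the qualitative
structure the gaze analyses target.  Choices and RTs are then simulated
from the gaze-informed model itself at a 1 ms step.

What passing tests on these data do and do not show: the generator matches
the study's design (proposal grid, deadlines, trial counts) and its broad
descriptive statistics, but real gaze has within-trial dynamics (refixations,
off-AOI excursions, RT-locked final fixations) and real populations have
parameter correlations that the generator does not emulate.  Recovery
results certify the estimation machinery, not the identifiability of the
model on any particular empirical data set.

## Known limitations

- The diffusion scale is a convention; fitted weight magnitudes are not
  comparable to fits made under other scale conventions.
- The simulation-based likelihood is noisy at the reduced preset
  simulation counts; the stuck-chain refresh keeps the sampler mobile but
  the stationary distribution is only approximately the ideal posterior
  (as in any pseudo-marginal scheme with refreshing).  The `paper` preset
  reduces this noise by two orders of magnitude.
- Odd/even cross-validation splits use the global trial index; a
  within-condition split is available by renumbering trials.
- No hierarchical pooling across subjects: each subject is fitted
  separately, as in the original estimation procedure.
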