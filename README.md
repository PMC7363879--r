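# gaddm

Gaze-informed attentional drift-diffusion modelling of altruistic choice
under time pressure.

## What this package is for

In a modified dictator game, a participant sees a proposal — $Self for
themselves, $Other for an anonymous partner, each $0–$100 — and accepts or
rejects it against a fixed $50/$50 default, under a 1.5 s (high time
pressure) or 10 s (low pressure) response deadline while their eye
movements are tracked.  A *generous* response sacrifices own payoff to the
partner's benefit.  `gaddm` is for researchers in decision neuroscience and
behavioural economics who want to model how moment-to-moment visual
attention shapes such choices: it simulates and fits a gaze-informed
multi-attribute attentional drift-diffusion model (ADDM), runs the
accompanying millisecond-resolution gaze analyses, and validates the whole
pipeline by parameter recovery on synthetic data.

## The model

Evidence for accepting, $x(t)$, starts at
$z = \mathrm{stbias} \pm \mathrm{genbias}$ (sign set by the party the
proposal favours) and evolves as

$$dx = V(t)\,dt + \sigma\,dW, \qquad
V(t) = A_{\mathrm{self}}(t)\,w_{\mathrm{self}}\,\$\mathrm{Self}
     + A_{\mathrm{other}}(t)\,w_{\mathrm{other}}\,\$\mathrm{Other}
     + w_{\mathrm{fairness}}\,\lvert\$\mathrm{Self}-\$\mathrm{Other}\rvert$$

between collapsing thresholds $\pm b\,e^{-dt}$.  The attention factor $A$
is 1 for the fixated payoff and $1-\theta$ for the unattended one; an
attribute contributes nothing before its information has been fixated, and
each first fixation of an AOI opens an 80 ms perceptual-intake window that
also adds a fixed 80 ms `percept` latency to the RT (plus one 80 ms
`motor` latency at threshold crossing).  Parameters are estimated per
subject, both deadline conditions jointly, by differential-evolution MCMC
(with migration, stuck-chain likelihood refreshing and a mid-burn-in
outlier reset) on probit-transformed parameters whose prior is uniform
over each parameter's admissible range, using a simulation-based
likelihood: each trial is simulated thousands of times and observed
(choice, RT) pairs are scored by class-weighted Gaussian KDE with halved
Silverman bandwidths; missed responses are scored by their simulated
frequency.  An attention-blind multi-attribute DDM (no $\theta$, no gaze,
fitted non-decision time) serves as the comparison model.

See the methods vignette (`vignettes/gaze-addm-methods.Rmd`) for the full
model description, the diffusion-scale convention, and every numerical
choice.

## A worked example

```r
library(gaddm)

## a synthetic study with known ground truth
study <- gen_study(generative_config(n_subjects = 2,
                                     trials_per_condition = 20), seed = 7)
head(study$trials, 3)
#>   subject trial self other condition choice    rt
#> 1     S01     1    0    60      HIGH ACCEPT 0.416
#> 2     S01     2   40    60      HIGH ACCEPT 0.634
#> 3     S01     3   40    80      HIGH ACCEPT 0.355

generosity_by_subject(study$trials)
#>   subject condition generosity
#> 1     S01      HIGH       0.60
#> 2     S02      HIGH       0.60
#> 3     S01       LOW       0.10
#> 4     S02       LOW       0.55
```

Each row of `trials` is one proposal with the simulated choice and RT;
`generosity` is the share of responded trade-off trials on which the
subject sacrificed own payoff.  Fitting one subject with the quick `mini`
preset (about half a minute; use `"scaled_down"` or `"paper"` for real
inferences):

```r
set.seed(99)
fit <- addm(study$trials[study$trials$subject == "S01", ],
            study$fixations[study$fixations$subject == "S01", ],
            model = "gaze", preset = "mini")
fit
#> Gaze-informed ADDM model fit, subject S01 (40 trials)
#>   chains 24, iterations 150 + 150, 96 sims/trial (preset mini)
#>   acceptance rate 0.234, max R-hat 1.171 (NOT converged)
#> Posterior-mean parameters:
#>               HIGH     LOW
#> w_self      0.0788  0.0567
#> w_other     0.0027 -0.0667
#> ...
```

The printed matrix holds posterior-mean parameters per deadline condition;
`max R-hat` reports the Gelman–Rubin convergence diagnostic over all 16
sampled parameters (the quick preset shown here stops just short of the
1.1 criterion — longer presets converge).  `coef(fit)`, `predict(fit)`,
`simulate(fit)`, `residuals(fit)` and `plot(fit)` give the estimates,
per-trial predicted acceptance/RT, posterior-predictive data sets,
choice residuals and trace/R-hat plots.  Gaze analyses and model
comparison:

```r
occ  <- occupancy(study$trials, study$fixations, "HIGH")
res  <- permutation_tmax(occ, contrast = "BIAS")   # cluster-mass test
cv   <- split_half_cv(study$trials, study$fixations)  # gaze vs static DDM
```

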