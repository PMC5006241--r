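# flickertime

Flickering stimuli are perceived to last longer than stable ones — and a
*task-irrelevant* flickering distractor can dilate the perceived duration of
a stable target several degrees away, more strongly when the distractor is
ipsilateral (cortically near) than contralateral. `flickertime` is an R
package for psychophysicists and computational modellers who want to analyse
— or stress-test the analysis of — duration-reproduction experiments of this
kind. Since no trial-level data from the original experiments are public,
the package pairs the analysis with a faithful synthetic-data generator and
validates the whole pipeline by parameter recovery.

## The model

Reproduced durations are modelled with a hierarchical Bayesian
location–scale model. For trial $i$ in condition $c$, target duration $d$,
by participant $s$:

$$
y_i \sim \mathcal{N}\!\left(
 \beta^{\mu}_{c}(\gamma^{\mu}_{d} + u^{\mu}_{s}),\;
 \left[\beta^{\sigma}_{c}(\gamma^{\sigma}_{d} + u^{\sigma}_{s})\right]^2
\right),
\qquad u^{\mu}_s \sim \mathcal{N}(0,\tau_\mu^2),\;
       u^{\sigma}_s \sim \mathcal{N}(0,\tau_\sigma^2),
$$

with the stable–stable baseline fixed at
$\beta^{\mu}_{SS} = \beta^{\sigma}_{SS} = 1$, so each free
$\beta^{\mu}_{c}$ is the **dilation ratio** of condition $c$ relative to
baseline. The model is fitted by block-wise adaptive random-walk Metropolis
(three runs of 2000 iterations, latter 1000 of each pooled to 3000 draws);
estimates are posterior medians with equal-tailed 95% credible intervals,
and the six directional condition comparisons are one-sided posterior
probabilities, Bonferroni-corrected over the family.

The four conditions are `SS` (stable target + stable distractor), `FS`
(flickering target), `SFi` (flickering ipsilateral distractor) and `SFc`
(flickering contralateral distractor); target durations are 450/650/850 ms.

## Worked example

Simulate the long-distractor experiment (11 participants, 4 sessions, 180
trials per session) at the default truth — dilation ratios 1.20 (FS), 1.10
(SFi), 1.05 (SFc) — then exclude fixation breaks, merge target sides, and
fit:

```r
library(flickertime)

cfg  <- design_config(experiment = 1, seed = 11)
sim  <- simulate_experiment(cfg)
kept <- merge_target_sides(apply_gaze_exclusion(sim)$trials)
fit  <- fit_flicker_model(kept, seed = 101)
fit
#> Hierarchical location-scale fit: 7530 trials, 3 chains x 2000 iterations (1000 warmup), 3000 pooled draws
#>
#> Dilation ratios vs SS (posterior median [95% CrI]):
#>   FS           1.196 [1.182, 1.210]
#>   SFi          1.094 [1.082, 1.107]
#>   SFc          1.040 [1.027, 1.052]
#>
#> One-sided comparisons (Bonferroni over 6):
#>       label raw_p corrected_p family_size
#>     FS_gt_1     0           0           6
#>    SFi_gt_1     0           0           6
#>    SFc_gt_1     0           0           6
#>   FS_gt_SFi     0           0           6
#>   FS_gt_SFc     0           0           6
#>  SFi_gt_SFc     0           0           6
```

All three ratios are credibly above 1 (time dilation in every flicker
condition), the flickering target dilates more than either distractor, and
the ipsilateral distractor more than the contralateral one — the qualitative
pattern of the long-distractor experiment. Recovery against the generating
truth:

```r
rec <- recovery_report(attr(sim, "truth"), fit$summary)
attr(rec, "mean_abs_bias_beta_mu")
#> [1] 0.006359549
```

`tidy(fit)`, `glance(fit)` and `autoplot(fit)` give broom-style summaries
and a ratio plot; `distractor_correlations()` computes the per-participant
distractor-duration diagnostic for the jittered experiment;
`run_pipeline(pipeline_config(...))` runs the whole
simulate → preprocess → fit → report → recover chain with seeded, file-based
artifacts (and `stage_*()` functions expose each step via CSV/JSON handoff).

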