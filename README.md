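# stereodots

Random-dot stereograms, interocular correlation, and the binocular energy
model — a toolkit for studying how stimulus construction shapes
stereoscopic performance.

## The problem

In noisy disparity-discrimination experiments, human observers do better
with *mixed-polarity* random-dot stereograms (equal numbers of black and
white dots on gray) than with *same-polarity* ones (all black or all
white). This has been read as evidence that ON and OFF channels contribute
independently to stereopsis. `stereodots` implements the competing,
purely stimulus-level account: when dots are placed with a **no-overlap
rule** (each new dot is abandoned and redrawn if it would overwrite an
existing dot), disparity noise lowers the interocular Pearson correlation
*more* for same-polarity patterns than for mixed-polarity patterns with
identical dot layouts. Because early disparity encoding behaves like a
correlation computation, standard energy-model neurons — with no
polarity-specific machinery at all — then reproduce the psychophysical
mixed-polarity advantage. When dots are scattered freely (overlapping and
occluding one another), the correlation difference and the behavioral
advantage both vanish.

The package provides, as separately usable pieces:

- **Stimulus synthesis** (`stim_params()`, `generate_pair()`,
  `to_same_polarity()`, `normalize_pair()`, `generate_uncorrelated_pair()`):
  square-dot stereograms with either overlap rule, four polarity modes,
  and disparity-noise models (none, per-dot Gaussian, two transparent
  planes, partial decorrelation), with per-pixel dot provenance maps.
- **Correlation statistics** (`pearson_r()`, `cross_correlation_profile()`,
  `monocular_autocorrelation()`, `classify_pixel_pairs()`).
- **Closed-form theory** (`expected_r()`, `du_overlap()`, `r_overlap()`,
  `r_limit_no_overlap()`): expected correlation in terms of
  matched/unmatched pixel-pair probabilities `d, m, u, d_m, d_u, x`.
- **Energy-model simulation** (`gabor_rf()`, `monocular_response()`,
  `neuron_response()`, `population_tuning()`): Gabor receptive fields and
  the classic V1 model cells — ODF TE/TI/ODD, the rectified RPC TE/ODD
  variants, and phase-invariant complex cells — with tuning curves
  normalized by the response to uncorrelated stereograms.
- **Neurometrics and experiments** (`run_task()`, `efficiency_ratio()`,
  `run_task_experiment()`, `run_correlation_sweep()`,
  `run_profile_experiment()`, `run_tuning_experiment()`).

## The model in brief

Monocular images are normalized to zero mean and unit variance, and the
interocular correlation is the sample Pearson coefficient

    r = (<LR> - <L><R>) / sqrt((<L^2> - <L>^2)(<R^2> - <R>^2))

over aligned pixels. Classifying aligned pixel pairs as *matched* (forced
equal by a shared zero-noise dot or shared background, probability `m`) or
*unmatched* (probability `u = 1 - m`), with conditional dot probabilities
`d_m` and `d_u`, gives

    r_mixed = m d_m / d
    r_same  = (m d_m + u(2 d_u - 1) - d^2) / (d (1 - d))

Free scatter fixes `d_u = 1/(2 - d)` (approximately — see the methods
vignette for the exact sequential-occlusion value) and collapses both onto
`1 - u / (d (2 - d))`: no polarity difference. Forbidding overlap forces
`d_u` toward its floor of 1/2, and then `r_same < r_mixed` strictly — the
construction artefact.

Model neurons use even/odd Gabor receptive fields
`f(x, y) = exp(-(x^2 + y^2)/2 sigma^2) {cos, sin}(2 pi x / lambda)`
(sigma = 32 px, lambda = 128 px), monocular inner products
`v_Le(x0) = sum f_e(x - x0/2, y) L(x, y)` (and counterparts), and output
nonlinearities such as the tuned-excitatory subunit
`R = (v_Le + v_Re)^2` or the complex cell
`R = (v_Le + v_Re)^2 + (v_Lo + v_Ro)^2`. A front/back trial is scored
correct when the neuron tuned to the stimulus disparity (+6 px) responds
more than its anti-neuron (-6 px).

## Worked example

```r
library(stereodots)

p <- stim_params(100, 100, 4, 0.4, overlap = "no_overlap",
                 noise = noise_gaussian(4), seed = 42)
pair <- generate_pair(p)
mixed <- normalize_pair(pair)
same  <- normalize_pair(to_same_polarity(pair, "white"))
pearson_r(mixed$left, mixed$right)  # 0.380
pearson_r(same$left,  same$right)   # 0.183

run_task_experiment(n_trials = 500, seed = 7)
```

```
Front/back task, 500 trials/condition, disparity noise SD 4 px
  odf_te          mixed 71.2%  same 64.8%  efficiency ratio 2.17 (95% CI 1.07-4.84)
  complex_odf_te  mixed 82.0%  same 67.4%  efficiency ratio 4.12 (95% CI 2.43-7.89)
```

The two correlations are computed on the *same* dot layout with the same
disparity noise; converting the pattern to one polarity halves the
correlation here (0.38 vs 0.18) purely because the no-overlap construction
makes the unmatched pixel pairs anticorrelate once all dots share a sign.
The task experiment then shows the downstream consequence: a single
energy-model subunit (and, more strongly, a quadrature complex pair)
discriminates front from back better for mixed-polarity stimuli, and the
probit-based efficiency ratio quantifies the advantage. At 10,000 trials
the simple cell reaches ~73%/63% correct (mixed/same) and the complex pair
~82%/70% (see below).

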