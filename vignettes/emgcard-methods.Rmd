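---
title: "Cardinality-based myoelectric pattern recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardinality-based myoelectric pattern recognition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgcard)
```

## The problem

Myoelectric pattern recognition (MPR) decodes intended movement from
surface electromyography (EMG): multichannel recordings are cut into
short sliding windows, each window is summarized by a handful of scalar
features per channel, and a classifier maps the feature vectors to
movement classes. The choice of features largely determines the
attainable accuracy, and `emgcard` exists to study one particular
feature — *cardinality* — against the established time-domain
repertoire, under controlled variations of the acquisition conditions.

Cardinality of a window is simply the number of distinct sample values
it contains:

$$\mathrm{card}(x) = \left|\{\,x_1, x_2, \dots, x_N\,\}\right|.$$

On quantized ADC counts this is a meaningful amplitude descriptor:
a stronger contraction spreads the samples over more quantization
levels, so the count of occupied levels grows with activation. Two
bounds follow immediately: `card` can never exceed the window length
\(N = f_s \cdot T\) (e.g. \(2000\,\mathrm{Hz} \times 0.2\,\mathrm{s} =
400\)) nor the number of representable levels \(2^B\) for a
\(B\)-bit converter (e.g. \(2^{10} = 1024\)). Because only *distinct
values* are counted, cardinality is invariant under any constant DC
offset (electrode-impedance mismatch) and under any permutation of the
samples.

The feature's essential caveat is **precision alienation**: if the raw
counts are rescaled to a continuous representation (volts, doubles),
every sample becomes almost surely unique, `card` saturates at \(N\)
for every window, and all discriminative power vanishes. The package
therefore computes all features on raw integer counts, and
`jitter_windows()` makes the degenerate scenario reproducible on
purpose.

## The evaluation pipeline

`emgcard` implements a complete offline evaluation protocol:

1. **Sessions** (`recording_session()`): raw integer counts plus the
   guided-recording schedule — each movement performed 3 times for 3 s
   with 3 s of relaxation, at 2000 Hz by default.
2. **Segmentation** (`segment_session()`): each contraction is trimmed
   to its central fraction (the *contraction time percentage*, cTp) and
   cut into 200 ms windows advancing by 50 ms. cTp = 0.7 retains part
   of the dynamic onset; cTp = 0.4 keeps only the static plateau.
   Windows never straddle repetition boundaries and relaxation periods
   are not windowed. Trimming is symmetric (equal cut at both ends) —
   the protocol prescribes discarding the beginning and end but not
   the proportions, and a symmetric cut removes both the
   request-to-movement delay and anticipatory relaxation; this is a
   package design choice, recorded here.
3. **Features** (`extract_features()`): per channel and window.
   Registered features: `card`, the Hudgins set (`mabs`, `wl`,
   `slpch`, `zc`), `rms`, `var`, `dam`, `mfl`, Higuchi fractal
   dimension `fd` and sample entropy `sampen`. Columns are ordered
   feature-major then channel.
4. **Classifiers**: linear discriminant analysis (`lda_train()`), and a
   one-hidden-layer perceptron (`mlp_train()`) capped at 400 training
   iterations. Feature columns are min–max normalized with parameters
   fitted on the training rows only.
5. **Evaluation** (`cross_validate()`): windows are randomly assigned
   to training (40%), validation (20%) and test (40%) sets, stratified
   by movement; accuracy is computed on the test set only, per
   movement, and the random split is repeated 10 times. The *macro*
   (per-movement mean) accuracy is the primary aggregate; the micro
   average is reported alongside.
6. **Comparison** (`wilcoxon_signed_rank()`): two feature sets are
   compared with a paired two-sided Wilcoxon signed-rank test, pairing
   per movement.
7. **Experiments** (`run_single_feature_comparison()`,
   `run_set_substitution()`, `run_sweep()`,
   `run_static_vs_dynamic()`): the standard designs over a list of
   sessions, sweeping sampling rate, window length, ADC depth,
   contraction dynamics, or the continuous-jitter condition.

## Feature definitions and numerical conventions

With \(d_i = x_{i+1} - x_i\):

| feature | definition | offset-invariant |
|---|---|---|
| `card`  | number of distinct values | yes |
| `mabs`  | \(\frac{1}{N}\sum |x_i|\) | no |
| `wl`    | \(\sum |d_i|\) | yes |
| `dam`   | \(\frac{1}{N-1}\sum |d_i|\) | yes |
| `rms`   | \(\sqrt{\frac{1}{N}\sum x_i^2}\) | no |
| `var`   | sample variance, denominator \(N-1\) | yes |
| `zc`    | sign changes of consecutive samples with step above a threshold | no |
| `slpch` | sign changes of consecutive differences, both above a threshold | yes |
| `mfl`   | \(\log_{10}\sqrt{\sum d_i^2}\) | yes |

Conventions worth stating explicitly:

* `wl = (N - 1) * dam` exactly; the identity is property-tested.
* `zc`/`slpch` thresholds default to 0; real front-ends may need a
  deadband, so the threshold is exposed. Zero samples inherit the
  previous nonzero sign, making the count deterministic.
* `var` uses the sample (\(N-1\)) denominator, the common platform
  default.
* `mfl` is defined as the log-scaled Euclidean length of the
  first-difference curve, following the fractal-feature literature; a
  constant window would give \(-\infty\), so it returns 0 (the
  integer-signal floor, \(\log_{10} 1\)) instead.
* `sampen` uses embedding dimension \(m = 2\) and Chebyshev tolerance
  \(r = 0.2\,\mathrm{sd}(x)\), self-matches excluded. A constant
  window returns 0 and `fd` returns 1 by convention. When no template
  pair matches at length \(m+1\), the infinite entropy is capped at
  \(\ln(\max(B,1)) + \ln N\) so classifiers never see non-finite
  inputs.
* Higuchi `fd` uses `kmax = 8`; the value is a recorded package
  default, not derived from a reference.
* Rough entropy (`ren`) is intentionally absent: its algorithm is only
  cited, not defined, in the literature this package follows, and a
  registry lookup fails with a clear message rather than silently
  substituting something else.
* Sample counts from durations use half-up rounding
  (`floor(x + 0.5)`), which is deterministic across platforms, unlike
  banker's rounding.

## Classifiers

**LDA.** Class means with a pooled within-class covariance
\(\Sigma_w\), regularized as \(\Sigma_w + \varepsilon I\) with the
scale-free default \(\varepsilon = 10^{-6}\,\mathrm{tr}(\Sigma_w)/d\),
uniform priors, and discriminant scores
\(x^{\top}\Sigma^{-1}\mu_k - \tfrac12 \mu_k^{\top}\Sigma^{-1}\mu_k +
\ln \pi_k\). Under identity covariance this reduces to
nearest-class-mean assignment, which the test suite exploits as an
independent oracle. Ties break toward the earlier class in sorted
label order.

**MLP.** One hidden layer of logistic sigmoids, per-class sigmoid
outputs trained against one-hot targets with the cross-entropy
gradient, full-batch gradient descent with learning rate 0.1 and
momentum 0.9, weights initialized from a seeded normal draw. After
every iteration the validation accuracy is measured; the best weights
seen are kept, and training stops at 400 iterations or after 20
iterations without validation improvement. The 400-iteration cap is
part of the protocol being emulated; the topology (hidden units =
half of inputs + classes, floor 8), learning rate, momentum and
patience are open choices recorded here and exposed as configuration.
With a fixed seed training is bit-reproducible.

## Statistical comparison

Per-movement mean accuracies (averaged over cross-validation
repetitions, then over subjects) form the paired samples. Zero
differences are discarded (classic signed-rank handling rather than
Pratt's; the count of discarded zeros is reported), midranks resolve
ties, and the statistic is \(W = \min(W^+, W^-)\). For \(n \le 25\)
retained pairs the two-sided p-value is exact — the probability over
all \(2^n\) equiprobable sign assignments of a statistic at most the
observed one, computed via the generating-function recursion, which the
tests verify against literal enumeration — and beyond that a normal
approximation with continuity correction and tie-corrected variance is
used. An all-zero difference vector is an error, not a silent
\(p = 1\). Whether pairs should pool movements across subjects or be
tested per subject is genuinely ambiguous in the protocol this package
follows; `aggregate_subjects()` implements movement-level means across
subjects, and the per-subject matrix is returned so users can pair
differently.

## The synthetic generator

`generate_session()` produces sessions with the statistical structure
the method assumes, so every module is testable without human
recordings:

$$s_c(t) = b_c(t) + e(t)\, G_{m,c}\, n_c(t) + \delta_c,$$

band-limited (20–500 Hz, 4th-order zero-phase Butterworth) unit-variance
Gaussian noise \(n_c\), amplitude-modulated by a trapezoidal envelope
\(e(t)\) and a movement-by-channel gain matrix \(G\) (volts), plus
baseline noise \(b_c\) (sd 0.01 V) and a per-channel DC offset
\(\delta_c\) (0.02 V × channel index, nonzero on purpose so
offset-sensitive and offset-invariant features genuinely differ). The
sum is quantized to the configured bit depth (default 14) over a ±5 V
range by rounding to the nearest LSB; a sample outside the range is a
generation error unless rail saturation is requested.

Design choices a reader should know:

* **Envelope timing.** The envelope is zero for the first 10% of the
  prompted contraction (reaction delay), ramps up over 15%, holds, and
  ramps down over the final 15%. Consequently the central 70% of the
  contraction contains ramp (dynamic) content while the central 40% is
  pure plateau — exactly the contrast cTp trimming is meant to probe.
* **Gain patterns.** Default gains are fractional parts of
  \(m\sqrt{p_c}\) (movement index × square root of a per-channel
  prime), scaled into [0.12, 0.95] V — a low-discrepancy rule chosen
  once to give well-separated amplitude signatures; "rest" has zero
  gain. Cohorts (`generate_cohort()`) perturb the gains per subject
  with a seeded log-normal factor (sd 0.1) as a clearly synthetic
  stand-in for inter-subject variability, whose real structure no
  single protocol pins down.
* **Simultaneous movements.** Combination classes sum their
  components' gain vectors (capped with five-sigma headroom inside the
  ADC range); `enumerate_combinations()` builds the 27-class setup
  from 3 antagonist degree-of-freedom pairs.

What the generator does **not** emulate: motor-unit action-potential
shapes and firing statistics, electrode crosstalk, fatigue and
electrode-shift nonstationarity, or movement-dependent spectral
changes — its noise is spectrally identical across classes and only the
amplitude structure carries class information. Passing pipeline tests
on this generator therefore demonstrates that the implementation
recovers amplitude-coded class structure under quantization, not that
any feature will rank the same way on human recordings.

## Evaluation caveats

Random assignment of windows to train/validation/test — the protocol
this package reproduces — places temporally adjacent, overlapping
windows from the same contraction on both sides of the divide, so
offline accuracies are optimistic relative to leakage-free designs.
`split_features(..., by_repetition = TRUE)` (or
`cross_validate(..., split_by_repetition = TRUE)`) is provided as an
extension that assigns whole repetitions instead; it is off by default
because the standard protocol is the object of study. Offline accuracy
in general does not predict real-time usability, which is out of scope
here.

## Problem sizes used by the test suite

The suite and the experiment checks run on deliberately compact
configurations chosen as the package's own desk-scale defaults: most
structural tests use 3–5 movement classes with 1 s contractions at
500 Hz; the pipeline acceptance checks use the full 11-class,
4-channel, 14-bit, 2000 Hz protocol session; and the cohort experiment
check uses 5 synthetic subjects with 7 classes, six feature sets and
both classifiers at 10 cross-validation repetitions. Determinism is
enforced throughout: every stochastic step (generation, splits, MLP
initialization) takes an explicit seed, and rerunning any experiment
with the same seeds reproduces its tables bit-for-bit.

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 42)          # 11 classes, 4 ch, 14 bits
session <- generate_session(cfg)
windows <- segment_session(session)          # 200 ms / 50 ms, cTp 0.7
fm <- extract_features(windows, "card")
cv <- cross_validate(fm, list(type = "lda"), n_reps = 10, base_seed = 1)
cv$global_accuracy
```

On this separable synthetic session, cardinality alone with LDA reaches
a macro accuracy above 0.95; the acceptance suite asserts the ≥ 0.9
bound, chance-level behaviour on gain-degenerate and continuous-jitter
variants, and stability of `mabs`/`wl` accuracy across the ADC-bit
sweep.
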