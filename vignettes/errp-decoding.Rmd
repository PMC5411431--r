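---
title: "Transferable single-trial ErrP decoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transferable single-trial ErrP decoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(errpdecode)
```

## The problem

In a P300 speller, the interface selects a letter and shows it to the
user during a short feedback period. When the selection is wrong, the
user's EEG carries an error-related potential (ErrP): a positive
deflection around 200 ms after feedback onset, a large fronto-central
negativity around 250 ms, and a second positivity around 320 ms.
Detecting this response on single trials turns the user's own brain into
an error detector for the interface, enabling automatic correction.

The decoder implemented here is *transferable*: it is trained on one
group of subjects and applied unchanged to new subjects, with no
per-subject calibration. That constraint drives most design choices --
simple, strongly regularised learners, heavy feature reduction, and an
ensemble that averages posteriors rather than trusting any single fit.

`errpdecode` implements the full pipeline -- synthetic data generation,
preprocessing, feature extraction, electrode selection, the ensemble
classifier, a pseudo-online streaming decoder, and evaluation -- as
plain R functions. Because the original competition recordings are not
redistributable, a synthetic generator reproduces the statistical
structure the decoder relies on; every stage is testable offline.

## The processing pipeline

1. **Band-pass filtering.** ErrP energy lives in 0.1--10 Hz. The filter
   is a recursive elliptic design of order 4 (low-pass prototype; the
   band transform yields 8 poles), 1 dB passband ripple, 50 dB stopband
   attenuation, at the 200 Hz sampling rate. Filtering is causal
   (forward-only, no zero-phase second pass) so the offline and
   streaming paths are the same code path; the group delay this incurs
   is constant across classes and therefore harmless to classification.
2. **Ocular artifact removal.** Independent component analysis on the
   band-passed scalp channels; any component whose absolute correlation
   with the recorded EOG lead exceeds 0.7 is zeroed before
   back-projection (`remove_eog()`).
3. **Savitzky--Golay smoothing.** A cubic least-squares smoother over a
   31-sample (155 ms) moving window cleans single-trial waveforms while
   preserving peak amplitude and latency far better than a moving
   average (`sg_kernel()`, `sg_smooth()`).
4. **Epoching.** Each feedback onset `t` yields the window `t - 200 ms`
   to `t + 1000 ms` (240 samples). The pre-onset mean is subtracted per
   channel (baseline correction), after which the 200 post-onset samples
   are reduced to 8 bin means of 25 samples each.
5. **Meta-features.** Nine scalars per trial: the grand mean and grand
   population variance of the baseline-corrected epoch, plus seven
   experiment counters (session, feedback number, alphabet position,
   word number, cumulative feedback and word counts, and the flashing
   condition). With all 56 electrodes the feature vector has
   `56 x 8 + 9 = 457` entries.
6. **Electrode selection.** Greedy backward elimination driven by the
   10-fold cross-validated AUC of the *full ensemble* (not a cheaper
   proxy): one pass over the electrodes in montage order; an electrode
   is dropped permanently if the subset without it scores at least the
   current reference AUC (`backward_eliminate()`).
7. **Ensemble classification.** Four learners -- LDA, QDA with
   covariance shrinkage, and logistic regression with an L1 and an L2
   penalty -- are each fitted on M = 10 resamples; the decoder's output
   is the arithmetic mean of all `4 x 10` posterior probabilities of the
   Error class, thresholded at 0.5 (boundary inclusive).

## The ensemble model

For a trial with feature vector $x \in \mathbb{R}^d$ and label
$y \in \{\text{NoError}, \text{Error}\}$, each estimator $(\ell, m)$
(learner $\ell$, resample $m$) produces a posterior
$\hat g^{\ell,m}(x) = \hat P(y = \text{Error} \mid x)$, and the ensemble
posterior is

$$
\hat g_{\mathrm{ens}}(x) \;=\; \frac{1}{LM} \sum_{\ell=1}^{L}
\sum_{m=1}^{M} \hat g^{\ell,m}(x),
\qquad L = 4,\; M = 10 .
$$

Averaging proper posteriors keeps the output a proper probability, so
$\hat P(\text{Error}) + \hat P(\text{NoError}) = 1$ holds by
construction. The resamples are generated with the k-fold mechanism:
resample $m$ is the training split of stratified fold $m$ (so $M = k$
and each resample holds $(k-1)/k$ of the data without replacement). A
bootstrap variant -- $m$ draws with replacement -- is available via
`build_resamples(replace = TRUE)` for users who prefer classic bagging;
the k-fold splits are the default because they guarantee both classes
in every resample and reuse the familiar CV machinery.

Learner-specific regularisation, with defaults and rationale:

* **LDA** -- pooled-covariance closed form with a relative ridge of
  `1e-6` on the diagonal, purely for numerical rank safety at
  `d = 457` features.
* **QDA** -- per-class covariance shrinkage
  $\Sigma_c \leftarrow (1-\gamma)\Sigma_c +
  \gamma\,\mathrm{tr}(\Sigma_c)/d \cdot I$ with $\gamma = 0.07$. The
  shrinkage target preserves total variance while guaranteeing positive
  definiteness even when a class has fewer trials than features.
* **Logistic (L1, L2)** -- penalty weight $\lambda = 0.15$ on the
  coefficient norm, intercept unpenalised, fitted with `glmnet` along a
  short decreasing path ending at the target $\lambda$ (warm starts keep
  coordinate descent stable). A penalty this strong shrinks most
  waveform coefficients; on near-Gaussian features the discriminant
  learners then dominate the ensemble ranking, which is intended -- the
  logistic members mainly stabilise the posterior scale.

All features are standardised (per-feature z-score) with statistics
computed on the full training set; the scaler is part of the stored
model. Regularised logistic learners need comparable feature scales, and
storing the scaler keeps the training-time and decode-time layouts
identical.

Class imbalance (roughly 30 % error trials) is left untouched: priors
are estimated from resample frequencies, and no reweighting is applied.

## The synthetic generator

`generate_corpus()` emulates the structure of a multi-subject speller
study: per subject, four sessions of 12 five-letter words plus a fifth
session of 20 words -- 60, 60, 60, 60 and 100 feedback periods, 340
trials per subject. Words are spelled under a fast, more error-prone
flashing condition or a slow, less error-prone one (assigned at random
per word, 50/50, since the original interleaving is not documented);
default error rates are 0.35 (fast) and 0.20 (slow), consistent with an
overall error fraction near 0.29.

Each session is rendered into a 200 Hz, 56-channel recording plus EOG:

* **Background**: 1/f (pink) noise per channel, half of the variance
  shared across channels to mimic spatially correlated background EEG,
  scaled to `noise_rms` microvolts RMS; a 10 Hz alpha rhythm grows
  toward occipital sites.
* **Blinks**: a 300 ms biphasic transient on the EOG lead (Poisson
  arrivals, 0.2/s), leaking with coefficient 0.3 into Fp1/Fp2 and 0.15
  into the AF row.
* **ErrP**: on error trials only, a template of three Gaussian-windowed
  lobes (+2, -5, +3 uV before gain; 25 ms width) centred at 200, 250 and
  320 ms after feedback onset, jittered per trial
  (`latency_jitter_sd`, default 10 ms), with a fronto-central spatial
  profile maximal at Cz/FCz and decaying as a Gaussian of the
  schematic-layout distance (`errp_topography()`). With these
  amplitudes the error negativity dominates the difference wave, as it
  does in real feedback tasks.

The default `noise_rms = 1` uV is deliberately optimistic -- a clean,
high-SNR regime chosen so that a desk-scale corpus (a handful of
subjects) is decodable well above chance and the pipeline's recovery
property can be verified quickly. Real 0.1--10 Hz background EEG is
several times larger, which is precisely why published single-trial
ErrP performance sits far below the near-perfect AUC seen on these
defaults. Passing tests on synthetic data therefore demonstrate
*pipeline correctness and transfer across simulated subjects*, not
real-data performance. Other realism gaps, stated plainly: no
volume-conduction head model (the topography is a schematic Gaussian),
no P300 stimulation sequence or visual evoked activity, no
non-stationarity within a session, no muscle or line-noise artifacts,
and label-independent background (real error trials can differ in more
than the ErrP).

## Numerical choices

* **Filter realisation.** The 0.1 Hz lower edge at 200 Hz puts poles
  within 4e-4 of the unit circle; expanding the design into a single
  transfer function destroys stability in double precision (one pole
  lands at modulus 1.0003). The filter is therefore kept in zero-pole
  form, grouped into second-order sections, and applied as a cascaded
  biquad with carried state (compiled code), which also gives the
  streaming path chunk-size-invariant results.
* **Savitzky--Golay edges.** Interior samples are exact local
  least-squares values; the 15 samples at each end use mirror padding.
  In the streaming path the left edge of each block is covered by 100 ms
  of carried-over history, so every epoch sample has its full smoothing
  window and streaming equals batch decoding bit for bit; a prediction
  is emitted once the epoch plus the 75 ms half-window beyond its end
  has arrived.
* **Downsampling operator.** Bin means (8 bins of 25 samples) rather
  than every-25th-sample decimation: the averaged bins are robust to
  sample-level noise, and the feature dimensions (8 per electrode, 448
  signal features, 457 total) are the fixed points of the design.
* **ICA convergence.** On a background that is largely Gaussian only
  the artifact components are identifiable, so the symmetric FastICA
  update cannot meet a tight convergence tolerance -- it keeps rotating
  within the Gaussian subspace. `remove_eog()` caps iterations (60 by
  default), reports `converged`/`iterations` as attributes of its
  report, and proceeds; the blink component is typically locked in
  within the first few iterations. The unmixing matrix is estimated on
  every 4th sample for speed; whitening and back-projection always use
  all samples.
* **Cold start.** A feedback onset within the first 200 ms of a stream
  has no full baseline; the missing history is mirror-padded and the
  prediction flagged `cold_start`.
* **Ties in ranking and selection.** Metric ranks use mid-ranks;
  electrode elimination treats an exactly equal AUC as removable
  (prefer the smaller model).
* **AUC.** Pairwise concordance with ties counted one half, computed by
  the rank formula -- identical to the trapezoidal ROC area and
  invariant under monotone transforms of the scores.

## Open design points, decided

* The elimination pass runs once, in montage order, with the reference
  AUC updated after each removal; running to convergence is possible
  but unbounded, while the single pass costs at most 57 CV evaluations.
* Meta-features participate in selection-time classification and are
  never candidates for removal.
* ICA is fitted per subject and session, after band-passing.
* The decision threshold is 0.5 with the boundary counted as Error.
* Held-out subjects in the transfer experiment are featurized through
  the same batch path as training (band-pass + ICA + smoothing);
  streaming equivalence is established separately, so replaying the
  test subjects through the streaming decoder would add runtime without
  adding information.

## Problem sizes used in the test-suite

The package's own checks run at desk scale: the transfer experiment
trains on 4 synthetic subjects (1,360 trials) and scores 2 held-out
subjects (680 trials); the chance-level control decodes 680 trials
generated with `errp_gain = 0` and a condition-independent error rate
(so labels are independent of everything the decoder sees); property
suites use short recordings of 10--60 trials. These sizes were chosen
so the full suite completes in a few minutes on a single CPU while the
statistical assertions (error-rate recovery within 3 standard errors,
chance AUC within [0.45, 0.55], held-out AUC at least 0.9) retain
power.

## Known limitations

* The generator's ErrP is time-locked and shape-stable up to gain and
  latency jitter; real ErrP morphology varies across subjects in ways
  that the transfer experiment does not probe.
* Electrode selection on 56 channels with the full ensemble inside
  10-fold CV is expensive (57 CV evaluations); at desk scale the tests
  exercise the algorithm on reduced channel sets.
* Computation-time measurements in `stream_decode()` are
  hardware-specific and are reported, never asserted.
* Only the 200 Hz, 56+1-channel montage is supported; no EDF/BDF/FIF
  readers, no re-referencing, no bad-channel interpolation.
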