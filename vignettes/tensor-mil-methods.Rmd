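---
title: "Tensor-factorized multiple-instance learning for speaker-level speech classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tensor-factorized MIL: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

A speaker contributes a variable-length collection of utterances; a single
binary label (e.g. depressed / not depressed from a binarized
questionnaire score) attaches to the speaker, never to an utterance. The
package treats this as multiple-instance learning: fixed-size *bags* of
`k` utterances are drawn from each speaker, every bag inherits the speaker
label, and a model maps one bag to one probability.

Each utterance is a log-mel spectrogram, a `128 x 219` matrix for a 7-s
clip. A bag is the order-3 tensor `U x 128 x 219` obtained by stacking
slices along the utterance mode. The core computational element is the
**tensor feed-forward layer**, the learnable form of a multilinear
projection: for factor matrices `U_f (I_f x P_f)` and `U_t (I_t x P_t)`
and bias core `B`,

$$ Y = \phi(U_f^\top X\, U_t + B), $$

the order-2 case of projecting a tensor onto mode-wise subspaces
(`Y = X ×₁ U⁽¹⁾ᵀ ×₂ U⁽²⁾ᵀ ×₃ U⁽³⁾ᵀ` in mode-product notation). The
parameter cost is `I_f P_f + I_t P_t + P_f P_t` instead of the
`I_f I_t P_f P_t` of a dense layer over the flattened input — for the
first 3D layer of the default configuration, 83,160 versus 672,768,000.
Unlike a Tucker *decomposition*, nothing is orthogonal or ordered here:
the factors are free parameters learned by gradient descent, and no
decomposition-fitting algorithm (HOSVD/HOOI) is involved.

Four architectures are provided.

* **`cnn_mil`** (baseline): three conv blocks (64 filters 3×3, 64 filters
  3×3, 128 filters 2×2; each conv → batch-norm → ELU → 2×2 max-pool)
  applied to every utterance with shared weights, a dense sigmoid head per
  utterance, and MAX aggregation of utterance probabilities.
* **`tfnn_mil`**: four shared 2D tensor FF layers
  (`128×219 → 120×210 → 110×200 → 100×180 → 80×160`), a tensor-sigmoid
  read-out per utterance (full inner product with an 80×160 weight matrix),
  MEAN aggregation.
* **`tfnn3d`**: two 3D tensor FF layers over the whole bag
  (`U×128×219 → U×120×200 → U×100×180`, RELU), then one tensor sigmoid
  against a bag-sized weight tensor — a single probability for the bag with
  no per-utterance scores at all.
* **`tfnn3d_att`**: the same two 3D layers; each `100×180` utterance slice
  is pooled over time by softmax attention (`α_t ∝ exp(w·h_t)`,
  `c = Σ α_t h_t`, one learnable vector `w` of length 100); the `U×100`
  attentive vectors are summarized by statistics pooling (per-coordinate
  mean and standard deviation, length 200); a 256/256 dense head and a
  sigmoid produce the bag probability.

The `tfnn_mil` first-layer output (120×210) intentionally differs from the
3D variants' (120×200): both configurations are kept exactly as specified
for each architecture rather than reconciled.

## Evaluation protocol

Training treats every bag as an independent labelled example. At
evaluation, a speaker's probability is the arithmetic mean of its bag
probabilities, and the decision threshold τ is chosen on the *validation*
speakers by maximizing Youden's J (TPR − FPR) over the ROC — the
appropriate choice under class imbalance, where 0.5 is rarely the right
operating point. Thresholding uses speaker-level validation scores
(bag-level would be the alternative; speaker level matches how test
performance is reported). Metrics are the weighted accuracy (overall
fraction correct), unweighted accuracy (mean of per-class recalls), and
per-class F1, at both bag and speaker level, from a confusion matrix with
rows = truth.

# Design choices

Several points were genuinely open; the package resolves them as follows.

* **Unfolding convention.** Mode-n matricization follows Kolda–Bader:
  mode-n fibers become columns ordered with lower-numbered remaining modes
  varying fastest. The Kronecker form of the matricized multilinear
  transform is then
  `Y(n) = U(n) · X(n) · (U(N) ⊗ … ⊗ U(n+1) ⊗ U(n-1) ⊗ … ⊗ U(1))ᵀ`; the
  ordering and the transpose are forced by the convention, and an
  exhaustive index-map test plus the three-way agreement of the
  sequential, Kronecker and rank-one-sum formulations (≤ 1e-8 relative on
  random instances) lock it in.
* **Spread statistic.** Statistics pooling uses the population *standard
  deviation* (with ε = 1e-9 under the square root for differentiability at
  zero variance), the convention of statistics-pooling speaker-embedding
  architectures; variance is available via `spread = "var"`.
* **Attention weight shape.** A single learnable vector `w` of length
  equal to the feature dimension, shared across all utterances. A
  matrix-plus-nonlinearity scorer is out of scope.
* **Biases.** Each tensor FF layer carries a `P_f × P_t` bias core
  (broadcast across utterances in 3D) and the tensor sigmoid a scalar bias
  — standard practice; both can be disabled (`use_bias = FALSE`).
* **CNN aggregation.** MAX is the default for `cnn_mil` and MEAN for
  `tfnn_mil`; both rules are exposed in `model_config`.
* **Bag-level weight tensor (`tfnn3d`).** Default is *slot-indexed*
  (`U × 100 × 180`, one weight slice per utterance slot), which fixes the
  bag size and is deliberately **not** permutation invariant — the test
  suite asserts that asymmetry. A `broadcast` mode shares one
  `100 × 180` slice across slots and restores invariance and
  variable-size bags.
* **Utterance mixing.** 3D layers default to an identity utterance factor
  (weight sharing; any bag size). A learnable square `U × U` mixing factor
  is available (`utter_mode = "learned"`), which fixes the bag size.
* **Leftover utterances.** With `n mod k ≠ 0` the remainder is dropped,
  keeping bags strictly repetition-free; a `fill` mode completes the last
  bag by sampling from the speaker's other utterances for small corpora.
  One seeded partition is drawn per epoch, acting as augmentation.
* **Decision boundary.** `p ≥ τ` maps to the positive class (inclusive),
  and threshold ties resolve toward the smaller τ.
* **F1 degenerate case.** A class never predicted gets F1 = 0 and raises
  a flag in the metrics object rather than NaN.

## Front-end choices

The spectrogram parameters are: Hamming window of 2048 samples, hop 512,
128 mel bands, 16 kHz input fixed to 7 s (112,000 samples; shorter
utterances are zero-padded at the end, longer ones truncated). Getting
219 frames from 7 s forces a *centered* STFT — `1 + floor(112000/512) =
219`, whereas an uncentered framing gives 215 — so reflection padding of
1024 samples per side is used. The mel filterbank input is the
*magnitude* (not power) spectrum; the filterbank is Slaney-style (linear
below 1 kHz, logarithmic above, area-normalized triangles) with fmin 0 and
fmax 8000 Hz; compression is the natural log with a 1e-10 floor. No
per-utterance normalization is applied by default (`normalize = TRUE`
z-scores if wanted). Non-16 kHz input is polyphase-resampled at load time.

Utterance segmentation is a deliberately simple energy detector: frames
(2048/512) whose energy exceeds both `median + energy_threshold_db`
(default −20 dB, i.e. anything within 20 dB of the utterance's median
frame energy) and an absolute −60 dBFS floor are active; active runs
merge across gaps shorter than 0.2 s and runs shorter than 0.3 s are
dropped. This stands in for the SVM-based silence removal used with real
interview corpora and is exact enough for the synthetic corpus, whose
true boundaries the generator also emits.

# Training

Bags are optimized with Adam (lr 1e-3, β = 0.9/0.999) on class-weighted
binary cross-entropy; weights default to inverse class frequency
normalized to mean 1, so a 146:43 imbalance yields a minority:majority
weight ratio of ≈ 3.40. Defaults: batches of 8 bags, at most 50 epochs,
early stopping with patience 10 on validation UA, and the checkpoint with
the best validation UA is returned. All gradients are analytic (verified
against central finite differences at step 1e-5 to 1e-4 relative error)
and every source of randomness — initialization (Glorot-uniform factors,
zero biases), bag partitions, batch order — derives from the single seed
in `train_config`, so runs are bit-reproducible.

Batch normalization in the CNN baseline uses per-forward batch statistics
in training and running statistics (momentum 0.1, ε = 1e-5) at inference;
convolutions are "same"-padded with stride 1.

# The synthetic corpus

Real clinical interview audio is access-restricted, so the package ships
a generator that reproduces the *structural* properties that matter for
the method: per-speaker variable-length utterance collections, a single
binary label, adjustable class balance via per-split speaker counts, and
— the MIL ingredient — a signature present in only a Bernoulli(ρ) subset
of a positive speaker's utterances. Negative speakers never carry it. The
generator records which utterances carry the signature, so MIL-specific
facts (e.g. that a bag of `k` utterances from a positive speaker contains
signal with probability `1 − (1−ρ)^k`) are directly testable.

The fast path draws smooth random log-mel-like fields (moving-average
smoothed Gaussian noise, unit variance) and adds the signature as a mean
shift over mel bands 40–60; the shift is `log(10)·6/20 ≈ 0.69` natural-log
units (+6 dB) by default, and the background noise scale is the shift
attenuated by the configured SNR. The waveform path synthesizes
amplitude-modulated harmonic complexes (random fundamental 85–255 Hz) in
pink noise, separated by 0.3–1.0 s silences, with utterance durations
drawn from 2–12 s so both the padding and truncation branches of the
7-s fix are exercised; the signature there is an added narrowband
2.2 kHz component plus a 1.5× slowdown of the temporal modulation.

What the generator does *not* emulate: prosody, phonetic content, speaker
timbre, interviewer speech, channel effects, or any acoustically
realistic rendering of depressed speech. Consequently, passing the
synthetic recovery test demonstrates that the architectures, gradients,
bagging, thresholding and metrics interlock correctly and that the models
can learn a planted MIL signal — it says nothing about clinical
performance on real interviews, which would require the restricted
corpora.

## Problem sizes

The synthetic end-to-end experiments use 20+20 training, 5+5 validation
and 5+5 test speakers with 10–16 utterances per speaker, ρ = 0.5, 20 dB
SNR and bag size 10, trained for at most 20 epochs with patience 5 —
sizes chosen as a desk-scale stand-in for a full corpus while leaving the
class-signal structure intact. Unit tests use further-miniaturized
configurations (16×20 spectrograms with proportionally scaled layer
dimensions) where only mechanism, not learning difficulty, is under test.

# Numerical notes

* Oracle equality between tensor formulations is asserted at 1e-8
  relative / 1e-10 absolute; gradient checks at 1e-4 relative against
  central differences with step 1e-5.
* Probabilities are clipped to `[1e-7, 1 − 1e-7]` inside the loss; the
  tensor sigmoid output is strictly inside (0,1) for finite inputs.
* Degenerate inputs are rejected with informative errors: empty bags,
  single-class label vectors (for weighting and thresholding), bag sizes
  exceeding every speaker's utterance count, mismatched tensor shapes.
* `select_threshold` candidates are the unique score values — exhaustive
  for the rule `p ≥ τ` — and match brute-force maximization by
  construction; the all-equal-scores degenerate case returns that score
  with J = 0.

# Limitations

Only order-3 tensors (order-2 as the degenerate case) are implemented —
all four architectures need nothing more. Training is single-threaded
base R; it is comfortable at the desk scale above but not intended for
full-corpus deep learning. The slot-indexed `tfnn3d` read-out ties a
trained model to its bag size; use `broadcast` mode when bags vary. The
energy-based segmenter assumes reasonably stationary background noise and
will over-segment speech with long intra-utterance pauses.
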