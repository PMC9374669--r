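---
title: "wcepolyp: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wcepolyp: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`wcepolyp` re-implements the onboard intelligence of an AI-empowered
colon-capsule endoscope as testable, desk-scale software: a ~3.2M-parameter
depthwise-separable grid detector for colorectal polyps, the dataset and
training protocol around it, average-precision evaluation, a synthetic
endoscopy frame generator, and a session simulator for the capsule's
adaptive frame-rate / selective-transmission / power-budget behavior. This
vignette records the model, its assumptions, and every design decision made
where the description of such systems leaves the design open.

## The detection network

The detector is a MobileNet-style stack: a standard 3×3 stride-2
convolution, thirteen depthwise-separable layers (a per-channel 3×3 spatial
filter followed by a 1×1 pointwise channel mix), and a final 1×1
convolution emitting a 4×4×15 grid. Every convolution step is followed by
batch normalization except the final one, which carries the network's only
bias. Input frames are 240×240×3 in [0, 1].

A depthwise-separable layer with kernel size $k$, $c$ input and $n$ output
channels costs $k^2 c + c n$ parameters against $k^2 c n$ for the standard
convolution it replaces — a reduction approaching $k^2$ when $n \gg k^2$.

Parameter accounting (`count_parameters`) gives 3,200,463 trainable conv
weights + final bias, and 3,222,351 including batch-norm scale/shift (2 per
normalized channel; running statistics are not trainable and are never
counted). Both figures round to 3.2M, so the quoted 3.2M total does not
disambiguate whether BN was counted; we count it by default and test both.
The INT8 deployment footprint is accounting only — one byte per parameter,
3.2 MB — no quantized arithmetic is simulated.

Three details of the reference design needed resolution:

* **Channel-chain conflict.** The architecture table's layer-4 pointwise
  filter is printed as 1×1×128×256 while its printed output size is
  60×60×128. Only the output-size column yields a consistent channel chain
  and a total rounding to 3.2M, so the output column is authoritative and
  layer 4 emits 128 channels.
* **Activation.** Unstated (the target ASIC supports arbitrary
  activations). We use ReLU6 everywhere except the (linear) final layer —
  the standard choice for INT8-deployable MobileNet-class networks.
  Configurable in `network_spec()`.
* **Padding.** Spatial sizes in the table follow SAME padding with ceiling
  division at stride 2 (15 → 8 → 4); `infer_shapes()` implements exactly
  that (`same_ceil`), with the smaller pad before and larger after,
  matching the TensorFlow convention.

Weights initialize from a truncated normal (sd 0.03, clipped at 2 sd),
seeded; BN starts at scale 1 / shift 0 with running mean 0 / variance 1
(momentum 0.1, epsilon 1e-5). `canonical_network_spec(input_size,
width_multiplier)` scales the same topology down for desk-scale training:
channels scale by the multiplier and trailing stride-2 layers are demoted
to stride 1 until the output grid is at least 4×4.

## The detection head

Each of the 16 cells holds 3 anchored proposals of 5 elements
$(S_p, x, y, w, h)$, hence 15 channels and 48 proposals per frame. The raw
coordinate encoding is not specified by the reference design; we adopt the fully invertible
YOLO-v2 convention and document it as such: score and center offsets pass
through a sigmoid (centers stay inside their 60-px cell), width/height
scale 3 anchor priors exponentially. Decoded boxes use the upper-left
(x, y, w, h) pixel convention repo-wide and are clipped to the frame.

* **S_t vs. NMS.** The deployed threshold $S_t = 0.65$ appears only in the
  condition $S_p \ge S_t$ (inclusive); we therefore read it as the
  confidence threshold and keep a separate overlap threshold
  `nms_iou = 0.5` for greedy suppression. NMS ties in $S_p$ break to the
  lower box index, so results are deterministic.
* **Anchors.** Priors are never given. Defaults are (24, 24), (60, 60),
  (120, 120) px — small/medium/large polyps at 240 px. For reduced-scale
  synthetic runs, `anchors_from_boxes()` fits 3 priors to the training
  boxes by k-means under the center-aligned IoU distance (the YOLO-v2
  recipe), deterministically initialized at size quantiles.

A frame is *significant* iff at least one box survives the confidence
filter; insignificant frames are deleted onboard.

## Training protocol

The dataset protocol mirrors the clinical pipeline at any frame size:
`balance_dataset()` pairs every polyp frame with a sampled normal frame
(764 + 764 = 1,528 at trial scale); `augment()` expands each frame into
`factor` variants (original + random rotation ±180°, scale 0.8–1.2,
translation ±10%, horizontal/vertical flips, crops keeping ≥ 80% area),
transforming ground-truth boxes with the pixels — 1,528 × 10 = 15,280. A
transform that would crop out every polyp is resampled (8 retries, then a
flip-only fallback), so augmentation never flips a frame's class.
`split_by_patient()` assigns patients, not frames, to 80/10/10 parts and
down-samples the majority class in validation/test. We split **before**
augmenting so no augmented variant of a training frame can leak into
evaluation; the protocol order is ambiguous and this is the conservative
reading.

The loss is a grid-detector composite (not specified for this system):
each ground-truth box is assigned to the cell containing its center and
the best-IoU anchor. Matched anchors get a localization term that is an
IoU loss on the decoded box (differentiated through the predicted center
and size, so small boxes are held to the absolute precision AP_50 demands)
plus a 0.25-weighted squared error in (sigmoid-offset, log-scale) space
that keeps gradients alive when boxes barely overlap; their
binary-cross-entropy objectness target is the IoU of the currently
predicted box with its ground truth (constant w.r.t. the gradient) — the
YOLO-v2 trick that makes the confidence rank well-localized boxes first.
Unmatched anchors get a down-weighted no-object term. Term weights
5 / 1 / 0.5. In development, pure squared-error localization plateaued
near test AP_50 ≈ 0.6–0.7 on the fixed synthetic world while the IoU form
reaches ≈ 0.82–0.90 — the difference is entirely in small-box precision,
which the tests compute, not assume. The optimizer is Adam
at the reference step size 1e-3 (batch 20), with random horizontal
mirroring at training time, per-epoch validation, early stopping
(patience 10 by default), and best-on-validation weights returned.
Training aborts with a diagnostic on a non-finite loss.

## Evaluation

`match_detections()` matches greedily in confidence order, one-to-one, TP
iff best-IoU unmatched ground truth meets the threshold.
`average_precision()` pools detections across images, ranks them globally
(micro-averaging), and integrates the precision envelope over all recall
points (COCO-style all-point interpolation) — documented so numbers are
bit-reproducible. $AP_{25} \ge AP_{50} \ge AP_{75}$ holds on any fixed
detection set. The clinical values $AP_{25} = 99.5\%$ / $AP_{50} = 95.8\%$
were measured on a private trial test set and are reference values only;
the package's substituted acceptance property trains on the synthetic
generator and requires $AP_{50} \ge 0.80$ on held-out synthetic patients.

## The synthetic generator

The generator emulates the *statistical structure* of the trial database,
not its appearance: per-patient mucosa hue, texture amplitude, vasculature
density and illumination center (so patient-wise splitting is meaningful
and leakage detectable); low-frequency texture with an illumination
falloff; curvilinear vessel strokes (Bezier, darker and blue-shifted);
polyps as shaded elliptical protrusions (eccentricity up to ~0.45 plus
rotation, log-uniform box side 24–96 px at 240-px scale, brightness
gradient, specular highlight) with tight-box annotations; cleanliness
grades 0–3 adding occluding debris blobs; WLI native rendering with a
deterministic NBI transform (red attenuated ×0.3, green/blue
contrast-stretched about fixed pivots) that measurably raises vessel
contrast. Every frame derives its own RNG substream from the master seed,
so datasets are byte-reproducible and order-independent.

What a green test does **not** establish: photorealism, realistic polyp
morphology spectra, motion blur, bubbles, fluid, or any claim about
clinical performance. The generator is a fixture standing in for private
trial data.

## The session simulator

Per frame: forward → decode → confidence filter → NMS → classify → policy.
Significant frames are always transmitted, raise the frame rate to 2 fps,
and schedule an NBI capture of the same scene (processed as the next
frame). Insignificant frames are deleted, except every 5th *consecutive*
insignificant frame, which is transmitted for localization — the counter
resets on a significant frame, since those are transmitted anyway. After
10 consecutive insignificant frames (configurable) the rate decays to
1 fps. "Every 5th" could also be read as every 5th frame overall; the
consecutive reading preserves the localization cadence and is the one
implemented.

The power model is the two-point static + dynamic split
$P(d) = s + p_{dyn}/d$ calibrated from 300 mW at full clock and 50 mW at
the tenfold-reduced clock, giving $s \approx 22.2$ mW. Operating time vs.
sparsity $\sigma$ (fraction of the session spent idle) is
$T(\sigma) = E/(\sigma p_{idle} + (1-\sigma) p_{active})$, with battery
energy $E$ defaulting to 180 J so that $T(0) = 1$ h at the reduced clock —
the depletion experiment's calibration point. $p_{idle}$ is a free
parameter (default 10 mW). Note the tension: with 10 mW idle the
idle-limited maximum is 5 h, so the advertised 8–10 h recording window
requires $p_{idle} \le p_{active}/8 = 6.25$ mW; `sparsity_for_hours()`
returns the closed-form sparsity when attainable and NA otherwise. Energy
is decremented per frame by active power × capture interval (plus an
optional per-transmission surcharge, default 0), and the session ends when
the battery empties; the ledger balances to 1e-9 relative.

Over-the-air reprogramming (`otap_update`) swaps the network mid-session
iff the replacement matches the deployed spec hash; a mismatch is rejected
and the old network retained. Counters and energy are untouched either
way, so a swap to a weight-identical network leaves the session log
bit-identical.

## Numerical choices, in one place

* SAME-ceiling padding, smaller pad first (TF convention).
* Truncated-normal init sd 0.03 (clip 2 sd), seeded; BN eps 1e-5,
  momentum 0.1; biased batch variance.
* Offsets clamped to [1e-4, 1 − 1e-4] before the logit when building
  targets; log-scale factors clamped to ±4 when computing IoU targets.
* NMS and matching ties break to the lower index; suppression is
  inclusive (IoU ≥ threshold); the confidence condition is inclusive
  (S_p ≥ S_t).
* Boxes are clipped to the frame after decoding; zero-area boxes dropped.
* All CLI/dataset artifacts are JSON/CSV/PNG/BMP with seeds and config
  hashes recorded in a manifest.

## Known limitations

* No quantized (INT8) inference simulation — footprint accounting only.
* The hibernation/landmark mechanism is modeled only as an external mode
  flag; no landmark classifier exists.
* Desk-scale training uses reduced resolution and width (64 px, ×0.25);
  the full 240-px network trains with the same code but not within test
  budgets.
* The synthetic world is deliberately simple; detector scores on it say
  nothing about clinical data.
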