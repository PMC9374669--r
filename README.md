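# wcepolyp

Onboard polyp detection and session simulation for AI-empowered
colon-capsule endoscopy, implemented as a desk-scale, fully testable R
package.

Ingestible camera capsules image the bowel for hours on a coin-cell energy
budget and a few MB of memory. Putting the detector *inside* the capsule
changes the engineering problem: the network must fit an 8 MB accelerator
in INT8, frames without findings must be deleted rather than transmitted,
the frame rate and illumination (white-light vs. narrow-band) must react to
findings, and the whole model must be replaceable over the air mid-session.
`wcepolyp` implements that stack for colorectal polyp detection:

* **net** — a 15-layer MobileNet-style detector: standard 3×3 stride-2
  conv, thirteen depthwise-separable layers, and a 1×1 conv emitting a
  4×4×15 grid (3 anchors × (S_p, x, y, w, h) per cell) from a 240×240×3
  frame. 3,222,351 trainable parameters (≈ 3.2M; 3.2 MB at one byte per
  parameter in INT8). Forward *and* backward passes are implemented in the
  package (Rcpp kernels + BLAS GEMMs) — no external deep-learning runtime.
* **head** — YOLO-style grid decoding (48 proposals/frame), confidence
  filtering at S_t (default 0.65, inclusive), greedy NMS at IoU 0.5, and
  frame classification (significant/insignificant).
* **train** — the dataset protocol (class balancing, tenfold
  box-preserving augmentation, patient-wise 80/10/10 split with balanced
  validation/test) and an Adam training loop (batch 20, step 1e-3) for the
  composite grid-detection loss.
* **eval** — precision–recall and AP_n at IoU n/100 (pooled ranking,
  all-point interpolation): AP_25, AP_50, …
* **synth** — a seeded generator of endoscopy-like frames with per-patient
  appearance, elliptical polyps with tight ground-truth boxes, cleanliness
  grades, and a WLI→NBI rendering. It emulates the *statistics* of a polyp
  database, not its appearance; the real trial data is private.
* **sim** — a capsule session simulator: delete-or-transmit policy (every
  5th consecutive insignificant frame transmitted for localization),
  adaptive 1→2 fps frame rate, NBI recapture of significant scenes,
  over-the-air network replacement, and a two-point power model
  (300 mW @ full clock, 50 mW @ clock/10) with operating time vs. sparsity
  calibrated to 1 h at 0 % sparsity.
* **cli** — `wcepolyp_cli()` / `inst/cli/wcepolyp` with subcommands
  `generate`, `train`, `eval`, `detect`, `simulate`; JSON configs and
  annotations, PNG or BMP frames, CSV session logs, seeds and config
  hashes in manifests.

See `vignettes/wcepolyp-methods.Rmd` for the model, every convention, and
the design decisions taken where the reference design is silent.

## Worked example

```r
library(wcepolyp)

# the canonical architecture, built and accounted
net <- build_network(canonical_network_spec(), rng_seed = 1)
net
#> <wce_network> 15 layers, 3,222,351 parameters (3.2M), INT8 3.2 MB, version initial

# a synthetic mini-trial: 6 patients x 20 frames
frames <- generate_dataset(synth_config(n_patients = 6,
                                        frames_per_patient = 20, seed = 7))
split <- split_by_patient(frames, seed = 7)

# detect on one frame with the untrained net (expect noise), then simulate
dets <- detect_polyps(net, frames[[1]]$pixels, head_config())
sess <- run_session(frames[1:20], net, head_config())
sess
#> <wce_session> 20 captures: 4 transmitted, 16 deleted; energy 179000 mJ remaining

# power budget: the two calibration points and the sparsity curve
pm <- power_model()
power_at_clock(pm, c(1, 2, 10))
#> [1] 300.0000 161.1111  50.0000
operating_time(pm, c(0, 0.5, 1))   # hours
#> [1] 1.000000 1.666667 5.000000
```

With an untrained network and the default threshold nothing is significant,
so the session transmits exactly every 5th frame (4 of 20) and deletes the
rest — the localization cadence of the transmission policy. `161.1` mW is
the two-point power model interpolated at clock divisor 2, and the
operating-time curve shows the battery calibration (1 h at sparsity 0,
idle-limited 5 h at sparsity 1 with the default 10 mW idle draw).

Training at trial scale is a supercomputer-free but lengthy exercise; the
acceptance suite trains a width-0.25 variant on 64-px synthetic frames
(2,500 frames, 25 patients) in ~10 min and requires AP_50 ≥ 0.80 on
held-out patients. The clinical reference values (AP_25 = 99.5 %,
AP_50 = 95.8 %) come from a private trial test set and are not
reproducible here.

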