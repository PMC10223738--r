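---
title: "Diffractive optical neural networks: model, training and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffractive optical neural networks: model, training and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odnn)
```

## The optical model

A diffractive deep neural network (D2NN) computes with light instead of
arithmetic. A coherent beam is amplitude-modulated by the input image,
crosses a stack of passive diffractive layers separated by free space, and
lands on a detector plane where per-class regions integrate the arriving
signal. All trainable structure lives in the layers: each pixel applies a
modulation $t = a\,e^{j\varphi}$ with $|t| \le 1$ (a passive element cannot
amplify). In the default *phase-only* mode the amplitude is frozen at 1,
matching what a fabricated phase plate or spatial light modulator
implements; a *phase+amplitude* mode is available through
`network_config()`.

Free-space propagation between planes is scalar diffraction. The package
implements it twice, deliberately:

* `propagate_asm()` — the **band-limited angular spectrum method**. The
  field's 2-D spectrum is multiplied by
  $H(u,v) = \exp(j 2\pi \gamma \Delta z)$ with
  $\gamma = \sqrt{1/\lambda^2 - u^2 - v^2}$, computed on a zero-padded grid
  and cropped back. Evanescent frequencies ($u^2+v^2 > 1/\lambda^2$) are
  hard-zeroed: they decay over sub-micron distances and zeroing them keeps
  the operator bounded for every $\Delta z$.
* `propagate_rs_direct()` — the **direct Rayleigh–Sommerfeld summation**,
  the exact discrete superposition of point-source responses
  $w = \frac{1}{2\pi}\frac{\Delta z}{r}\left(\frac{1}{r}-jk\right)
  \frac{e^{jkr}}{r}$. It costs $O(n^4)$ and exists purely as an
  independent oracle for the FFT path at small $n$.

Sign conventions are fixed package-wide: forward transform
$e^{-j2\pi(ux+vy)}$ (R's `fft()`), time dependence $e^{-j\omega t}$, hence
outgoing waves $e^{+jkr}$ and the $+$ sign in $H$. The test suite enforces
agreement of the two routes, which pins the conventions in a way prose
cannot.

### Where the two routes can be compared

The oracle comparison needs care: the two discretizations approximate
continuum propagation on *different* domains, and a meaningful equivalence
test must live in the intersection. At the reference geometry (4 µm pitch,
He–Ne wavelength, $\Delta z$ of millimeters) a white-noise field on a small
($n \le 64$) grid radiates most of its energy at angles that leave the
$n\times n$ window entirely — the cropped ASM result and the
aperture-restricted RS sum then describe genuinely different quantities
and disagree at order one, no matter how exact both are. The comparison is
therefore made on *band-limited random fields* (spectrum within 20% of the
grid Nyquist) with a generous padding factor of 32, so that essentially
all diffracted light stays inside the guard band. In that domain the two
routes agree to relative $L_2$ error around $10^{-4}$, two orders below
the $10^{-2}$ acceptance bar, for $n \in \{16, 32\}$ and
$\Delta z \in \{5, 10, 20\}$ mm.

Other physics checks use the configuration that makes them exact rather
than approximate: energy conservation and forward/backward invertibility
are tested with `pad_factor = 1` (the periodic operator is unitary on the
propagating band, so deviations are pure floating-point, ~$10^{-15}$),
and the Gaussian-beam check compares the second-moment waist after one
Rayleigh range against $w_0\sqrt{2}$ on a 128-pixel grid (within 0.01%).

## Detector readout and the two task heads

`read_detectors()` supports two readout semantics, because physical
descriptions of such systems alternate between them: `"magnitude"` sums
$|u|$ over a region (the default, matching the normalization formulas
below, which are written in terms of summed amplitudes) and
`"intensity"` sums $|u|^2$ (what a photodetector actually measures). The
choice is recorded in run manifests; both are differentiable and tested.

Detector geometry is configurable; the default places two squares of 20%
of the grid side, vertically centered, horizontally at 25% and 75% — class
0 (no-nodule / benign) left, class 1 (nodule / malignant) right. Argmax
prediction breaks ties toward class 0, deterministically.

Two normalization/loss pairs implement the two workflows:

* **Detection**: $A'_i = A_i/(A_0+A_1+b_0+b_1)$ followed by softmax
  cross-entropy. The biases $b_0, b_1$ exist because a window over a large
  dark lung region can put almost no light on either detector; they keep
  the normalization defined and are *learned* (softplus-parameterized,
  initialized at 0.01) rather than fixed, which subsumes any hand-picked
  value. The window-level nodule probability is
  $\mathrm{score}_i = A'_i/(A'_0+A'_1)$.
* **Classification**: $A'_i = \alpha A_i/\max(A_0,A_1)$ followed by mean
  square error against the $\alpha$-scaled one-hot target. Only the ratio
  of $\alpha$ to the target matters, so $\alpha$ defaults to 1 as a plain
  configuration constant.

## Training

`train_d2nn()` is minibatch gradient descent with adaptive moments (Adam;
plain SGD via config). The optimizer is a design choice — the reference
hyperparameters (batch 64, learning rate 0.005 for detection / 0.001 for
classification, 120 epochs) specify rates but no optimizer, and adaptive
moments are the de-facto standard for phase-mask training. Gradients are
computed analytically by Wirtinger backpropagation: the transpose of the
padded-FFT propagation operator is itself a propagation (conjugate
transfer function conjugated back), layer modulation backpropagates as
multiplication by $t$, and the phase gradient at a pixel is
$-2\,\mathrm{Im}(D \cdot u)$ where $D$ is the cogradient and $u$ the
post-layer field. A finite-difference harness (`gradient_check()`)
verifies this to relative error below $10^{-8}$ on a 32-pixel two-layer
network — the backpropagation is exact, not approximate.

Phases are stored unconstrained and only wrapped modulo $2\pi$ on export;
trainable amplitudes go through a logistic squash onto $[0,1]$; phase
initialization is i.i.d. uniform on $[0, 2\pi)$ from a seeded generator.
Training aborts with a diagnostic on a non-finite loss rather than
continuing silently. Identical seeds give bitwise-identical trained
parameters on one thread.

Dataset plumbing follows case-level hygiene: `split_cases()` shuffles case
identifiers with a seed and cuts 8:17:75
(validation:test:training) by largest-remainder rounding, so all patches
of a case land in one split; `kfold_cases()` gives near-equal seeded folds;
`rebalance()` subsamples the over-represented class to a requested ratio
(1:1 for the balanced experiments, 1:4 for the imbalanced one) without
ever duplicating items.

## Slice scanning

`scan_slice()` slides a `window` (50 px) over the slice on a stride
lattice, upsamples each clip to the network size by nearest-neighbor
replication, and records the nodule score at the window center; windows
that would cross the boundary are skipped rather than padded. Candidates
are score-map cells strictly above the threshold. `evaluate_scan()` calls
a truth center detected if any candidate lies within the match radius
(default 25 px, half the window — ground truth marks centers only) and
counts every unmatched candidate as one false positive; this matching rule
is this package's own declaration, stated here precisely because scan
recall is meaningless without one.

The package default stride is 10 px. The end-to-end validation experiment
scans at stride 5: the trained networks see nodules only at the patch
center, and their score falls off smoothly with the nodule's offset inside
the window (measured ~0.8 centered to ~0.5 at a 6-px diagonal offset), so
the evaluation lattice must sample within a few pixels of each center.
Stride 5 bounds the worst-case offset at $\sqrt{2}\cdot 2.5 \approx 3.5$
px for a fourfold cost increase — the right trade for an accuracy
experiment; per-pixel scanning remains available.

## The synthetic data generator

`gen_patch()`, `gen_benign_malignant()` and `gen_slice()` make the whole
pipeline testable without any imaging-data download. A patch is a mean
gray level plus band-limited correlated noise (low-pass-filtered white
noise, correlation length 8 px, amplitude 0.12), clipped to $[0,1]$;
nodule patches add a soft-edged (smoothstep, 2 px) radially symmetric blob
of contrast 0.45 and radius 5–10 px at the patch center. Malignant
variants scale the radius by 1.5 and modulate the boundary with seeded
harmonics (orders 2–5, relative amplitude 0.25) plus 6 spicules; benign
nodules are the plain blob. Slices use the same background family, shaded
by two dark elliptical lung fields and crossed by a few bright
vessel-like streaks, with nodules planted at rejection-sampled centers
(≥ 25 px from borders, ≥ 50 px apart).

Each patch draws its background level uniformly from $0.30 \pm 0.11$.
This jitter is what makes patches and slices one generative family: the
slice shading spans local brightness levels from about 0.2 to 0.4, and a
detector trained only at a fixed level misreads windows in the darkest
lung fields. The contrast (0.45) deliberately exceeds the texture
amplitude (0.12), so class separability is guaranteed by construction —
a *solvable* task is the point, since the tests must distinguish "the
training machinery works" from "the task is impossible".

What passing these tests does **not** show: real CT texture is not
band-limited Gaussian noise, real nodules are not centered smoothstep
blobs, real malignancy is not a radius multiplier, and patch difficulty
here is homogeneous where LIDC-IDRI's is not. The synthetic results
validate the optics, gradients, training loop and pipeline plumbing — not
clinical performance. The published dataset-scale numbers (e.g. 89.67%
detection accuracy, AUC 0.8292) depend on the real data and full-scale
training and are outside what desk-scale runs can or should reproduce.

## Problem sizes of the validation experiments

Chosen once, as the package's own reduced-scale study conditions:

* training: 100×100-neuron grid, 3 layers, 200 training / 100 validation
  patches, batch 32, 30 epochs, seed-derived initialization. The held-out
  accuracy criterion (≥ 0.95) is read at epoch 10 of the seeded
  trajectory; the slice scan uses the final 30-epoch network, since scan
  scores sharpen markedly between epochs 10 and 30.
* scan: one 256×256 slice, 3 planted nodules, stride 5, threshold 0.5,
  match radius 25 px.
* oracle grid: $n \in \{16, 32\}$, $\Delta z \in \{5, 10, 20\}$ mm,
  band-limited fields, pad factor 32.
* gradient check: 32×32 grid, 2 layers, 8 random phase probes, central
  differences with $10^{-4}$ rad steps.

## Known limitations

Scalar theory only — no vector diffraction, polarization or partial
coherence. No optical nonlinearity between layers, so the network is a
single linear optical operator followed by a nonlinear readout; this caps
attainable accuracy, which is also why the classification task is harder
than detection. At 400×400 neurons the diffraction angle between adjacent
layers no longer spans the full aperture (incomplete connectivity),
acknowledged and uncompensated. The direct RS oracle is quartic in $n$
and unusable beyond $n \approx 64$. Checkpoints use R's native
serialization: bit-exact and portable across platforms, but not a
cross-language exchange format.
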