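---
title: "Methods: contrast source inversion with convolutional enhancement"
author: "csinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrast source inversion with convolutional enhancement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`csinet` implements a dual-stage quantitative microwave breast-imaging
chain on fully synthetic data. Stage one reconstructs the complex relative
permittivity of a 2D breast cross-section from scattered microwave fields
by finite-element contrast source inversion (CSI), using a three-tissue
prior map as an inhomogeneous numerical background. Stage two trains a
convolutional encoder-decoder (U-Net) to map the rough, artifact-laden CSI
images to clean permittivity maps, and quantifies the gain with RMS
reconstruction error and pixel-wise tumor ROC-AUC. Everything — phantoms,
fields, priors, training data — is generated inside the package, so every
number in the evaluation is reproducible from one master seed.

# The physical model

A transverse-magnetic (TM) 2D setup reduces Maxwell's equations to the
scalar Helmholtz equation for the out-of-plane electric field. With an
imposed numerical background permittivity $\epsilon_n(\mathbf r)$ and its
wavenumber $k_n = \omega\sqrt{\mu_0\epsilon_0\epsilon_n}$, the scattered
field of transmitter $t$ satisfies

$$\nabla^2 E^{sct}_t + k_n^2\, E^{sct}_t = -k_n^2\, w_t, \qquad
  w_t \equiv \chi\, E_t, \qquad
  \chi \equiv \frac{\epsilon_r - \epsilon_n}{\epsilon_n},$$

where $E_t$ is the total field and $\chi$ the contrast, zero wherever the
prior already equals the truth. We use the $e^{+j\omega t}$ convention with
$\epsilon = \epsilon' - j\epsilon''$, so outgoing waves are Hankel
functions of the second kind and lossy media have $\mathrm{Im}(k) < 0$.

## Finite elements

The problem domain $\Omega$ is a disk, triangulated by mapping a structured
square grid so that concentric squares morph into circles; the map is the
identity inside half the rim radius (the imaging domain $D$ keeps an
undistorted grid) and reaches an exact circle at the rim, where the
curvature-corrected first-order absorbing condition
$\partial_n u + (jk_b + 1/2R)\,u = 0$ is applied. Linear (P1) basis
functions give the system $A = K - M_{k^2} + (jk_b + 1/2R)B$.

Two numerical choices matter:

* **Dispersion-minimising mass blending.** P1 elements at practical mesh
  densities carry a phase (dispersion) error that accumulates over the
  several-wavelength propagation paths of a tomographic setup. The
  consistent and row-lumped P1 mass matrices have leading dispersion errors
  of opposite sign on this mesh family; the package uses
  $M = \theta M_{cons} + (1-\theta) M_{lump}$ with $\theta = 0.3$,
  calibrated once against the analytic line-source-and-cylinder series,
  which cuts the receiver-field error roughly fourfold at fixed mesh size
  (e.g. 12.5% to 3.4% at a 0.4 cm grid step). The calibration is a property
  of the discretisation, fixed package-wide.
* **Complex solves by real block embedding.** The complex sparse system is
  solved through its real $2n \times 2n$ block form with a cached sparse LU
  factorisation, so one factorisation serves all transmitters and all
  condensation right-hand sides.

## Forward data and the analytic oracle

Synthetic receiver data come from the scattered-field formulation
$A\,u = (M_{k^2(\epsilon)} - M_{k^2(\epsilon_b)})\,e^{inc}$ with the
analytic line-source incident field in the right-hand side — algebraically
the total-field solve minus the incident field, but without a singular
point-source load. The forward mesh is finer than, and independent of, the
inversion mesh, and 5% complex Gaussian noise (calibrated so the expected
noise RMS is 5% of the data RMS over the full measurement set) is added
before inversion; together these avoid the inverse crime. The solver is
validated against the cylindrical-harmonic series for a homogeneous lossy
cylinder (implemented with the package's own complex-argument Bessel/Hankel
evaluations: Miller's backward recurrence for $J_n$, ascending series and
Hankel asymptotics for $Y_0, Y_1$, upward recurrence for $H^{(2)}_n$),
agreeing to within 2% relative RMS at the receivers.

# Contrast source inversion

CSI minimises the sum of a normalised data error and a normalised domain
error,

$$F_{CSI}(\chi, w_t) =
 \frac{\sum_t \lVert f_t - M_S L[w_t]\rVert^2_S}{\sum_t \lVert f_t\rVert^2_S}
 + \frac{\sum_t \lVert \chi\odot e^{inc}_t - w_t + \chi\odot M_D L[w_t]\rVert^2_D}
        {\sum_t \lVert \chi\odot e^{inc}_t\rVert^2_D},$$

alternating one Polak-Ribière conjugate-gradient step (with exact
quadratic line search, per transmitter) on the contrast sources $w_t$ with
the closed-form nodewise least-squares update
$\chi = \sum_t w_t \bar E_t / \sum_t |E_t|^2$ of the contrast. The domain
normaliser is recomputed once per outer iteration from the previous
contrast, which keeps the source subproblem quadratic; sources are
initialised by back-propagation with the optimal per-transmitter scalar,
and the contrast by its closed-form update. Complex inner products are
conjugate-linear in the first argument. No positivity bounds are imposed
during iteration.

Because the FEM system of the prior background is factorised once, the
operators $M_S L$ and $M_D L$ are condensed into dense Green matrices,
making every CSI iteration plain BLAS work and making operator adjoints
exact conjugate transposes (the adjoint test holds to $10^{-10}$ by
construction, which is the precondition for trustworthy gradients).

Two implementation details are worth recording:

* **Receiver calibration without singular incident fields.** With
  colocated transmitters and receivers, both the measured total field and
  the prior's incident field are singular at the transmitting antenna. The
  prior-referenced data are therefore formed as the homogeneous-referenced
  scattered field minus the *incident difference* field of the prior
  (solved with sources only inside the breast), which is smooth at every
  receiver. Skipping this step poisons a handful of self-receiver data and
  visibly stalls the inversion.
* **Fixed iteration count.** No stopping rule beyond the configured
  iteration budget is used (250 at full scale, 30 at desk scale), with
  contrast snapshots stored at requested iterations for the robustness
  protocol.

# Synthetic phantoms and the surrogate prior

Three procedural base geometries span the breast-density range: model I,
heterogeneously dense, 10 x 9.5 cm with a 40% fibroglandular area
fraction; model II, fatty, 11.2 x 9.6 cm, 15%; model III, very dense,
10 x 5 cm, 65%. Each is a randomly perturbed ellipse with a closed 1-3 px
skin ring, a fat interior and one contiguous star-shaped fibroglandular
blob. Tumors are grown pixel-by-pixel from a uniformly drawn
fibroglandular start pixel, 4-connected, until no pixel can be added
without the mask's maximum pairwise pixel-centre distance reaching the
drawn maximum diameter (1.1-1.5 cm); a second tumor, when present, is
regrown until it does not touch the first. Tissue dielectric values are
configurable mid-range literature values at 1 GHz — immersion medium
(23, 1), skin (36, 4), fat (5, 0.5), fibroglandular (35, 6), tumor
(50, 10) as ($\epsilon'$, $\epsilon''$) — chosen for the high
fibroglandular/fat contrast characteristic of this problem; they are
assumptions, not measured constants. A 5% multiplicative uniform texture
stands in for intra-tissue heterogeneity.

The tissue-region prior emulates what an ultrasound segmentation would
deliver without simulating ultrasound: the tumor class is removed, region
boundaries are displaced by a smooth random field bounded by 2 px, and
each region's permittivity is off by a random factor within 5%. These
degradation levels are fixed study conditions, not tuning knobs. What the
generator deliberately does *not* emulate: real MRI-derived tissue
texture, 3D anatomy and out-of-plane scattering, antenna models, and
genuine ultrasound segmentation failure modes (e.g. missed regions) — so
passing tests demonstrate the method's internal consistency and the
enhancement trend under these conditions, not clinical performance.

# The enhancement network

Both architectures consume the same 3-channel input: real part, imaginary
part and magnitude $\sqrt{\epsilon'^2+\epsilon''^2}$ of the CSI
permittivity image, rasterised from mesh nodes by the P1 basis.
Architecture 1 trains two independent single-output networks for the real
and imaginary parts (motivated by their very different scales);
architecture 2 trains one three-output network (magnitude, real,
imaginary) whose unweighted summed loss is naturally dominated by the
real part — the package reproduces this behaviour by default and exposes
per-channel weights as an option. The network is a classic U-Net: per
level two 3 x 3 convolutions + ReLU and a 2 x 2 max-pool, a two-convolution
bottleneck, then mirrored 2 x 2 transposed-convolution upsampling with skip
concatenations, and a linear 1 x 1 head. Weights are Gaussian with Xavier
scaling; training minimises the mean pixelwise squared error
(proportional to the summed pixelwise squared error) with Adam at learning
rate $10^{-3}$, batch size 10, 75 epochs at full scale. Inputs and targets
are min-max normalised per channel with constants fitted on the training
split only and stored with the model. Optimiser, learning rate, depth
(4 levels, 32 base filters at full scale) are package choices where the
method leaves them open; all are configurable. The layers are implemented
directly (im2col + GEMM through compiled code) because no deep-learning
framework is part of the package's dependency stack; analytic gradients
are verified against finite differences in the test suite.

# Evaluation protocol

RMS reconstruction error (real and imaginary parts separately) and
pixel-wise tumor ROC-AUC are computed over breast-interior pixels — the
exterior is trivially known from the prior; the mask is configurable.
Pixels are pooled across all phantoms of a test subset before the ROC is
swept (one AUC per subset); the AUC is the tie-corrected rank statistic
and is checked against an exhaustive pairwise-comparison oracle. The
real-part image feeds the real-half ROC, the imaginary-part image the
imaginary half, with higher values more tumor-like (tumor permittivity
exceeds all other tissues in the default table). Four-fold
cross-validation splits the dataset per model; training settings A-D
include all models or exclude model III, II or I respectively, while
testing covers every model-subset combination, with raw CSI as the
baseline on identical inputs. The robustness protocol re-evaluates a
trained model on CSI inputs stopped at off-training iteration counts and
on rotated/flipped inputs (truth transformed identically); training uses
no augmentation, so these are genuine extrapolations.

# Scale choices

The full-scale configuration (128 x 128 phantoms at 0.1 cm, 1200 phantoms,
24 antennas, 250 CSI iterations, 75 epochs, four folds) is the package
default. The bundled desk preset — 64 x 64 at 0.2 cm, 40 phantoms per
model, 16 antennas, forward/inversion mesh steps 0.32/0.5 cm, 30 CSI
iterations with snapshots at 10/20/30, a depth-3/8-filter network for 15
epochs, one hold-out fold — is the configuration under which the package's
own validation suite reproduces the headline *direction* (enhancement
lowers RMS for both parts and raises pooled AUC, and stays above the CSI
baseline on transformed and early-stopped inputs). Desk-scale margins are
smaller than full-scale ones and individual training runs are stochastic;
the validation therefore requires the trend in at least two of three
training seeds.

# Degenerate inputs and numerical edges

* A contrast that is identically zero makes the domain normaliser vanish;
  the cost evaluation signals this explicitly rather than returning NaN.
* Nodes where the total-field energy vanishes get $\chi = 0$ and are
  counted in a diagnostics field.
* Zero measured data back-propagates to zero initial sources; the optimal
  initial scaling guarantees the initial data error never exceeds 1.
* Max-pool gradient ties route to the first of the four pool inputs, in a
  fixed order, keeping training bit-reproducible.
* The per-transmitter line search is exact for the quadratic subproblem,
  so the recorded cost is non-increasing (tolerance $10^{-10}$ relative
  per accepted step); a violation aborts the run with the history
  attached.
* Tumor growth with a maximum diameter of one pixel halts at the seed
  pixel; growth is rejected outright when no fibroglandular pixel exists.

# Known limitations

2D TM physics only; no antenna or cable modelling; single frequency with
non-dispersive tissues; the prior surrogate cannot produce the structured
failure modes of a real ultrasound segmentation; ROC-AUC on pooled pixels
rewards contrast separation, not lesion-level detection; and the
desk-scale network is far smaller than the full-scale one, so desk-scale
RMS/AUC values are not comparable to full-scale magnitudes — only their
CSI-versus-enhanced ordering is.
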