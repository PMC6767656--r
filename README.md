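# csinet

Quantitative microwave breast imaging on synthetic data, in two stages:
**contrast source inversion** (CSI) with tissue-region priors reconstructs
the complex relative permittivity of a 2D breast cross-section from
scattered microwave fields, and a **convolutional encoder-decoder
(U-Net)** learns to map the rough, artifact-laden CSI images to clean
permittivity maps. The package is aimed at inverse-scattering and
learned-reconstruction researchers who want a fully self-contained,
reproducible testbed: phantoms, fields, priors, reconstructions, training
data and metrics are all generated in code from a single master seed.

## The method

A transverse-magnetic setup reduces Maxwell's equations to the scalar
Helmholtz equation. With a known (possibly inhomogeneous) numerical
background εₙ(r) and its wavenumber kₙ, the scattered field of
transmitter *t* obeys

    ∇²E_t^sct + kₙ² E_t^sct = −kₙ² w_t,   w_t = χ·E_t,   χ = (ε_r − εₙ)/εₙ.

CSI minimises the normalised data-plus-domain cost

    F(χ, w_t) = Σ_t‖f_t − M_S L[w_t]‖² / Σ_t‖f_t‖²
              + Σ_t‖χ∘e_t − w_t + χ∘M_D L[w_t]‖² / Σ_t‖χ∘e_t‖²

by alternating a Polak–Ribière conjugate-gradient step on the contrast
sources w_t (exact line search, per transmitter) with the closed-form
nodewise update χ = Σ_t w_t Ē_t / Σ_t |E_t|². The operator L is a
factorised finite-element solve on a triangulated disk with an absorbing
rim; a tumor-free three-tissue prior map enters as εₙ, so the contrast is
concentrated where the prior is wrong — primarily at tumors. The U-Net
consumes the real part, imaginary part and magnitude of the CSI image and
is trained (Adam, Xavier-initialised weights, pixelwise squared error)
against the true phantom; architecture 1 uses two single-output networks
(real / imaginary), architecture 2 one three-output network. Performance
is scored by RMS reconstruction error and pooled pixel-wise tumor ROC-AUC
under four-fold cross-validation, including training settings that exclude
whole breast-density classes and robustness checks on rotated/flipped and
early-stopped inputs.

The forward solver is validated against the analytic cylindrical-harmonic
series for a homogeneous lossy cylinder (2% relative RMS at the
receivers); the methods vignette (`vignettes/csinet-methods.Rmd`)
documents the model, the numerical choices and the limits of the
synthetic study.

## Worked example

```r
library(csinet)

# one synthetic heterogeneously dense breast with a single tumor
labels  <- make_base_model("I", grid_shape = c(64, 64), pixel_size = 0.2, seed = 11)
tumor   <- grow_tumor(labels, max_diameter_cm = 1.3, seed = 12)
labels[tumor] <- 4L
phantom <- assign_permittivity(labels, texture_level = 0.05, seed = 13)
prior   <- make_prior(phantom, boundary_jitter_px = 2, value_error_frac = 0.05, seed = 14)
phantom
#> <csinet_phantom> model I, 64 x 64 px (0.2 cm/px), 1 tumor(s)

# scattered-field data at 16 antennas, 5% measurement noise
geometry <- acquisition_geometry(n_antennas = 16)
data <- forward_scatter(phantom, geometry, disk_mesh(geometry$omega_radius, 0.32))
data <- add_noise(data, 0.05, seed = 15)
data
#> <scatter_dataset> 16 rx x 16 tx, noise 5.0%, |f|_rms = 0.014

# contrast source inversion with the tissue-region prior
mesh   <- disk_mesh(geometry$omega_radius, 0.5)
ops    <- build_operators(mesh, prior, geometry)
result <- run_csi(data, operators = ops, n_iters = 30)
result
#> <csi_result> 30 iterations, final F_CSI = 0.02215 (F_S = 0.005275, F_D = 0.01688)

# rasterise the reconstruction and score it
eps   <- total_permittivity(result$chi, ops)
img   <- rasterize(eps, mesh, c(64, 64), 0.2)
recon <- list(real = Re(img), imag = -Im(img))
interior <- phantom$labels > 0
rms_error(recon$real, phantom$eps_real, interior)
#> 8.64
pixel_roc_auc(recon$real[interior], phantom$tumor_mask[interior])$auc
#> 0.992
```

The cost history shows the normalised data error F_S settling near the 5%
noise floor; the RMS error of 8.64 reflects the blurred tumor and the
prior's displaced tissue boundaries (the artifacts the enhancement stage
removes), while the AUC of 0.992 says tumor pixels already outrank
non-tumor pixels in this reconstruction. `run_pipeline(desk_config(...))`
chains generation → forward → inversion → training → evaluation for a full
desk-scale study and writes per-setting RMS/AUC tables plus ROC curves;
`inst/cli/csinet.R` exposes the same stages on the command line.

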