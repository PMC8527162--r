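# dotprops

Estimation of the average optical properties of breast tissue **and** the
underlying chest wall from frequency-domain diffuse reflectance.

## The problem

US-guided diffuse optical tomography of the breast starts by estimating
the background absorption and reduced scattering coefficients
(μa, μs′, in cm⁻¹) of healthy tissue from reflectance measured with a
hand-held probe (9 sources, 14 detectors, separations 3–7.6 cm, 140 MHz
modulation). The standard slope-based fit assumes a homogeneous
semi-infinite medium. In supine patients the chest wall — a strongly
absorbing layer — often lies less than 2.5 cm below the skin, breaking
that assumption and biasing the fitted tissue μa badly high.

`dotprops` implements and compares three estimators of the quadruple
(μa, μs′, μa_chest, μs_chest′), given the chest-wall depth and tilt from a
co-registered ultrasound image:

* **slope-based fit** — closed-form inversion of the slopes of log(A·ρ²)
  and phase versus separation ρ:
  μa = (ω/2c_m)(k_r/k_i − k_i/k_r), μs′ = (k_r²+k_i²)/(3√(μa²+(ω/c_m)²)) − μa;
* **two-layer fit** — Nelder–Mead inversion of a layered diffusion
  Green's function (Hankel transform) for all four coefficients;
* **CNN** — a small convolutional network (two conv blocks, kernel (9,1),
  batch norm, leaky ReLU, max pooling; 256-element input = 126 log
  amplitudes + 126 phases + 4 chest-wall depths) trained on simulated
  two-layer data with 1% noise, optionally fine-tuned on calibrated
  phantom measurements.

The package also provides the forward models (semi-infinite closed form,
analytic two-layer, and a 3D finite-difference solver for heterogeneous
voxel phantoms), least-squares source/detector gain calibration, digital
breast phantom generators, and comparison reporting. Everything, including
the network's forward/backward passes, is base R + Matrix; no GPU or deep
learning framework is required.

## Worked example

```r
library(dotprops)

probe <- default_probe()
geom  <- chestwall_geometry(depth_center = 2, tilt_deg = 0)   # from US image

# ground truth: tissue (0.02, 7), chest wall (0.12, 7), interface at 2 cm
medium <- two_layer_medium(optical_props(0.02, 7), optical_props(0.12, 7), geom)
m <- fluence_two_layer(medium, probe)          # forward model
m <- add_noise(m, 0.01, seed = 1)              # 1% measurement noise
m <- preprocess_measurement(m)                 # 7 cm cutoff + outlier screen

fit_slope_props(m)
#> slope fit
#>        mua       musp  mua_chest musp_chest
#>     0.0420     5.9306     0.0420     5.9306

fit_two_layer(m, geom, probe)
#> twolayer fit
#>        mua       musp  mua_chest musp_chest
#>     0.0205     6.9712     0.1210     7.9298
#>   iterations: 723, objective: 0.000821
```

The homogeneous slope fit reports tissue μa = 0.042 — more than double
the truth of 0.02, the classic shallow-chest-wall bias — while the
two-layer fit recovers 0.0205. The CNN route trains on a simulated sweep
and predicts in milliseconds:

```r
ds  <- make_simulation_dataset(n = 6000, seed = 101)   # ~1 min
cnn <- cnn_train(ds, cnn_config(epochs = 80, lr_decay_every = 40, seed = 11))  # ~10 min, 1 CPU
round(evaluate_cnn(cnn, ds, "test"), 2)
#>        mua       musp  mua_chest musp_chest
#>       3.21       0.98       7.62      16.31     # held-out mean relative errors, %

fv <- build_feature_vector(m, chestwall_depth_features(geom))
cnn_fit(cnn, fv)
#> cnn fit
#>        mua       musp  mua_chest musp_chest
#>     0.0187     7.0299     0.1170     7.3225
```

Tissue-layer properties are recovered best (a few percent), chest-wall
reduced scattering worst — most photons never probe the chest wall deeply,
so the measurements carry the least information about it.

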