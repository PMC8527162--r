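---
title: "Estimating breast and chest-wall optical properties: models and methods"
author: "dotprops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating breast and chest-wall optical properties: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dotprops)
```

## The problem

Frequency-domain diffuse optical measurements of the breast are usually
inverted under a homogeneous semi-infinite assumption: light from each
source diffuses through a single tissue with absorption $\mu_a$ and reduced
scattering $\mu_s'$, and the decay of log amplitude and the growth of phase
with source-detector separation $\rho$ identify both coefficients.  In a
supine patient the chest wall - a strongly absorbing layer - often lies
only 1-3 cm below the skin.  When it is shallower than about 2.5 cm the
semi-infinite assumption fails badly and the classical slope-based estimate
of tissue $\mu_a$ is biased high, which in turn corrupts every downstream
image reconstruction that relies on the background optical properties.

`dotprops` implements three estimators of the quadruple
$(\mu_a, \mu_s', \mu_{a,\text{chest}}, \mu_{s,\text{chest}}')$ from a
hand-held probe with 9 sources and 14 detectors (126 pairs, separations
3-7.6 cm, 140 MHz modulation), given the chest-wall depth and tilt read
from a co-registered ultrasound image:

1. the slope-based homogeneous fit (fast, biased when the chest wall is
   shallow);
2. a two-layer Nelder-Mead inverse fit against a layered diffusion model
   (accurate but slow and initialization-sensitive);
3. a small convolutional network trained on simulated two-layer data
   (fast at prediction time and robust across chest-wall depths).

## Forward models

All solvers share one set of conventions: diffusion coefficient
$D = 1/[3(\mu_a + \mu_s')]$ (the $\mu_a$-inclusive convention, so fitted
values are self-consistent); time dependence $e^{-i\omega t}$ with
$k = \sqrt{(\mu_a + i\omega/c_m)/D}$, $\mathrm{Re}\,k > 0$; an isotropic
point source one transport mean free path $z_0 = 1/(\mu_a+\mu_s')$ below
the surface; and an extrapolated boundary at $z_b = 2D(1+R_\text{eff})/(1-R_\text{eff})$
above it, with $R_\text{eff}$ from the standard polynomial fit to the
Fresnel reflection integrals.  The refractive index is not a measured
quantity here; we default to $n = 1.4$ for tissue simulations and $n=1.33$
for intralipid fixtures.  The measurement model is the complex surface
fluence: stored as natural-log amplitude and unwrapped phase lag per pair.

**Semi-infinite closed form.** The image-source solution
$\Phi = [e^{-kr_1}/r_1 - e^{-kr_2}/r_2]/(4\pi D)$ with $r_2$ the distance
to the image across the extrapolated boundary.

**Two-layer analytic model.** For a breast layer of thickness $\ell$ over
a semi-infinite chest wall, the fluence is computed in Hankel space: the
1D two-point boundary problem per lateral frequency $s$ is solved by
matching at $z=\ell$, and the result is written as the semi-infinite
solution for the top-layer properties plus an interface correction whose
integrand decays like $e^{-\alpha_1(2\ell - z_0)}$ (all exponentials
arranged in decaying form, so the quadrature - 512-point Gauss-Legendre on
$s \in [0, 40]\,\mathrm{cm}^{-1}$, cached Bessel kernel - is overflow-free).
With identical layers the correction vanishes identically, which is why
the homogeneous-limit check passes at quadrature accuracy.

**Tilted interfaces.** The training sweep tilts the interface by up to
$\pm 15^\circ$.  A tilted plane breaks the Hankel symmetry, so the analytic
route evaluates the flat-interface solution at each pair's local interface
depth beneath the source-detector midpoint.  This first-order treatment
keeps a forward evaluation at ~2 ms, which is what makes simulating
thousands of training sets and running simplex fits tractable on one CPU.
The finite-difference solver (below) resolves the tilted plane exactly on
its grid; the two routes agree within a few percent in log amplitude over
the separations the pipeline uses, and the residual difference is part of
what the CNN must absorb, not hide.

**Finite-difference heterogeneous solver.** A 7-point second-order stencil
with harmonic-mean face diffusivities on a regular voxel grid (default
2.5 mm), Robin extrapolated-boundary closure on the top surface and
outgoing-wave (DC decay rate) closures on the far boundaries.  The complex
symmetric system $(A + i\,\mathrm{diag}\,\sigma)x=b$ is solved per source
by a conjugate-orthogonal CG iteration preconditioned with a sparse
Cholesky factorization of the real part; because the frequency shift
$\omega/c_m \approx 0.04\,\mathrm{cm}^{-1}$ is comparable to $\mu_a$, the
iteration converges in about ten steps.  Three numerical choices matter at
2.5 mm resolution and are worth recording:

* a local dispersion correction raises the complex absorption by
  $h^2 s_0 (\mu_a + i\omega/c_m)^2 / (12 D)$ with $s_0 = 3/4$, cancelling
  the leading grid-dispersion error for near-lateral propagation;
* sources and detectors are snapped to grid columns and the sub-voxel
  displacement corrected analytically by $e^{-k\Delta\rho}(\rho_s/\rho_t)^2$,
  which is far more accurate than interpolating an exponentially decaying
  field;
* the top-boundary ghost value and the detector's surface extrapolation
  both use the depth profile of the analytic image solution for the local
  surface properties, so the discrete boundary matches the extrapolated
  -boundary convention of the analytic solvers rather than a linearized
  $(z + z_b)$ profile.

With these, uniform-medium solves agree with the closed form to a median
of 1-2% (maximum below 5%) in amplitude over the separations the pipeline
retains; the residual is grid dispersion at the longest separations, which
the 7 cm cutoff removes anyway.  Halving the step from 2.5 mm changes log
amplitude by well under 1%.

## Classical estimators

**Slope-based fit.**  Least-squares lines of $\log(A\rho^2)$ and phase
versus $\rho$ give $k_r$ and $k_i$, and the dispersion relation
$k^2 = 3(\mu_a+\mu_s')(\mu_a + i\omega/c_m)$ inverts in closed form:
$$\mu_a = \frac{\omega}{2 c_m}\Big(\frac{k_r}{k_i}-\frac{k_i}{k_r}\Big),
\qquad
\mu_s' = \frac{k_r^2+k_i^2}{3\sqrt{\mu_a^2+(\omega/c_m)^2}} - \mu_a.$$
The first expression is the singularity-free algebraic form of
$(\omega/c_m)[\tan(2\tan^{-1} k_i/k_r)]^{-1}$; both forms are unit-tested
against each other.  Since $\mathrm{Re}(k^2) = 3\mu_t\mu_a > 0$, physical
data always has $k_r > k_i$; inputs violating this raise an error naming
the slopes.  The $-\mu_a$ term in $\mu_s'$ is the exact inversion; at
tissue contrast it is a sub-percent correction and is sometimes dropped in
the literature.

The inversion is an asymptote.  At this probe's separations the residual
curvature of the semi-infinite solution biases the raw regression slopes
by 1-7%, and the near-cancellation $k_r/k_i - k_i/k_r$ amplifies that to
5-40% in $\mu_a$ at the low-absorption end of the range.
`slope_to_props` therefore runs a short fixed-point loop: refit the
closed-form model for the current estimate over the same separations,
subtract the finite-window slope bias, invert again.  On noiseless
homogeneous data the loop converges to the exact properties; on layered
data the estimator keeps the homogeneous-model bias that defines it (the
loop assumes homogeneity), so the characteristic chest-wall
overestimation of $\mu_a$ and its decay with interface depth are
untouched.  The raw-formula route stays available via
`correct_finite_rho = FALSE`.

**Preprocessing.**  Separations above 7 cm are masked (signal-to-noise),
then a single pass masks pairs whose residual against either slope line
exceeds 2.5 robust standard deviations (MAD x 1.4826).  The threshold is a
package choice; the screening rule, like the cutoff, follows standard
practice for these instruments.  Exactly linear data is never masked and
the pass is idempotent on clean data.

**Two-layer Nelder-Mead fit.**  Minimizes the mean squared mismatch of the
two measurement channels - each scaled by the standard deviation of its
measured values, so amplitude and phase contribute comparably - over the
quadruple in log-parameter space (positivity without constraints).  The
default initialization takes the tissue layer from the slope fit and the
chest layer at $(0.17, 7)\,\mathrm{cm}^{-1}$, the middle of the training
range.  Each simplex run is capped at 500 forward evaluations; a fresh simplex
is restarted at the incumbent (up to 3 times) until a run terminates by
tolerance without improving, which guards against the premature stalls
Nelder-Mead is prone to.  Hitting the budget flags the result rather than
raising.  On noiseless synthetic data the default initialization recovers
all four parameters within 10%.  At the classical single-run budget the
estimate depends strongly on the initialization on noisy data - the known
failure mode that motivates the learned estimator - and even from a
truth initialization the fitted chest-wall $\mu_s'$ scatters by tens of
percent on noisy realizations: photons barely sample the chest wall, so
the likelihood is nearly flat in that direction.  That flatness, not any
particular estimator, is what caps chest-wall scattering accuracy; the
CNN's held-out chest $\mu_s'$ error (~16% at the 6,000-set desk scale)
sits at this floor and is its worst output, mirroring the full-scale
study's ranking of the four parameters.

## The CNN estimator

The input is a fixed 256-vector: 126 log amplitudes, 126 phases (canonical
source-major pair order), and the interface depth at four equally spaced
lateral positions $(-1.5, -0.5, +0.5, +1.5)$ cm, a fixed convention
standing in for the ~4 cm ultrasound field of view (the training and
prediction code share it, which is all that matters).  Masked pairs are
imputed with the slope-line values at their separation so the vector
length never changes.  The network is two convolution blocks (kernel 9,
zero padding, batch normalization, leaky ReLU with slope 0.01, max-pool 2)
with 16 and 32 filters, then a 128-unit hidden layer and a linear 4-output
layer; filter and width counts are package choices sized for CPU training.
Features *and labels* are z-scored with statistics from the training split
only; z-scoring the labels balances the 4-output MSE across parameters
whose scales differ by two orders of magnitude.  Training uses Adam
($\beta_1 = 0.9$), learning rate $10^{-3}$ decayed by 0.1 every 100
epochs, batch size 32, up to 200 epochs, with the validation loss checked
every 5 epochs on an internal 10% fold and training stopped after 3
checks without improvement (best weights kept).  Fine-tuning continues
from the trained weights at $10^{-4}$ for 100 epochs with frozen
normalization statistics.  Whether "10-fold validation during training"
means a rotating fold within one run or a reporting protocol is genuinely
ambiguous; the default is a single random validation split per run, and a
k-fold harness (`cnn_cross_validate`) trains one model per fold for
reporting or ensembling.  Batch-norm population statistics are
re-estimated over the training data at every validation checkpoint and
after training (running averages always lag, because weight norms grow
freely under batch norm's scale invariance).  Everything - forward pass, backpropagation,
Adam - is implemented in base R matrix algebra and verified against
finite-difference gradients in the test suite; training is deterministic
given the seed.

## Synthetic data

**Simulation sweep.**  Six parameters drawn independently and uniformly:
tissue $\mu_a \in [0.01, 0.1]$, tissue $\mu_s' \in [4, 10]$, chest
$\mu_a \in [0.1, 0.24]$, chest $\mu_s' \in [4, 10]$ (cm$^{-1}$), depth
$\in [1.5, 3]$ cm, tilt $\in [-15, 15]^\circ$.  Noise is 1%: amplitude
multiplied by $(1+\varepsilon)$, $\varepsilon \sim N(0, 0.01^2)$, and
$N(0, 0.01)$ radians added to phase, keeping the two channels comparably
perturbed.  The full study size is 15,744 sets split 90/10; the
acceptance-scale runs in this package use 6,000 sets through the identical
code path, a size chosen so that data generation plus training fits in
roughly ten minutes on one CPU.  At that scale the desk schedule caps
training at 80 epochs; early stopping typically ends it near 40-60, where
the validation loss has already turned.

**Digital breast phantoms.**  A 14x14x8 cm grid at 0.5 mm voxels;
fibroglandular tissue is carved from a smoothed Gaussian random field
(correlation length 1.5 cm) by a rank threshold, so the realized volume
fraction matches the target to within one voxel; fat fills the rest of the
breast; the chest wall fills everything below the interface.  Per-label
properties: fat $(0.02, 5)$, fibroglandular $(0.04, 8)$, chest wall
$(0.1, 7)$ cm$^{-1}$ by default.  The phantom is numerically compressed to
5 cm (nearest-neighbour in z) and downsampled to 2.5 mm for the solver.
The stated chest depth is the *measurement-time* (compressed) depth - the
quantity an ultrasound image would show and the estimators receive; the
uncompressed grid places the interface deeper by the compression factor so
that compression restores it.  Placing the interface at the printed depth
*before* compression would drop it below 1.6 cm in all cases, outside both
the training range and the lab-experiment depths, which is why we read the
recipe this way.  The breast-tissue ground truth for a heterogeneous
phantom is the volume-weighted mean over fat and fibroglandular voxels
only (lesion and chest excluded); a 40/60 fat/fibroglandular mix gives
exactly $(0.032, 6.8)$.

What the phantom generator does *not* emulate: real anthropomorphic
phantoms have vascular trees, skin, and anisotropic fibroglandular
texture.  Only the label fractions, geometry, compression and per-label
optical properties are matched, so phantom-study results here validate the
estimation pipeline, not anatomical realism.

**Lab fixture.**  A synthetic stand-in for the intralipid + solid-phantom
fine-tuning experiment: 196 liquid backgrounds ($\mu_a \in [0.02, 0.06]$,
$\mu_s' \in [5.8, 6.7]$) times 4 fixed solid chest phantoms spanning
$[0.095, 0.18] \times [5.6, 7.1]$, depths 1.5-2.5 cm, tilts within
$\pm15^\circ$ - 784 sets, split 70/30.  Raw data passes through seeded
per-source/per-detector gains (log-moduli uniform $\pm 0.5$, phases
uniform $\pm 0.3$ rad) and 1% noise; calibration is fitted on a separate
homogeneous reference run ($(0.04, 6.2)$ at $n=1.33$) by two linear least
squares problems (log amplitude and phase), gauge-fixed so the first
source gain is $1 + 0i$.  The residual miscalibration left by the noisy
reference run is exactly the kind of instrument signature fine-tuning is
meant to absorb.

## Evaluation

The score is the relative error $|{\rm prediction} - {\rm truth}|/{\rm truth}$,
reported as a per-parameter mean percentage; note it is not symmetric in
its arguments.  Comparison reports run all three estimators per example
(the slope method duplicates its homogeneous pair into the chest slot) and
record per-example failures without aborting.  Published comparisons of
the form "errors reduced by 61 points" are percentage-point differences of
such means, and `error_reduction_pp` reproduces that arithmetic (rounded
to whole points) rather than a relative reduction - the wording is
ambiguous in general, so the convention is pinned here.

Timing is logged but never asserted: on one CPU a slope fit is
milliseconds, a simplex fit seconds (it typically needs one to three
hundred forward evaluations), and a CNN prediction milliseconds after the
model is loaded.

At the 6,000-set desk scale the network's accuracy is not uniform over
the sweep: errors concentrate at the edges of the training support.  The
clearest case is the combination of the lowest tissue absorption
(0.02 cm$^{-1}$) with the shallowest interface (1.5 cm), where the
tissue-$\mu_a$ relative error reaches ~17% (0.003 cm$^{-1}$ absolute)
against 1-6% at deeper interfaces; the full-scale study size is what
flattens this profile.  On heterogeneous digital phantoms -- whose
weighted-average truths sit in that same low-absorption region and whose
features come from the finite-difference solver rather than the analytic
models the network was trained on -- the CNN's tissue-$\mu_a$ error is
roughly twice the full-scale published figure, while the method ordering
(CNN best, slope-based worst) is reproduced.  And with the restarted
simplex fitter and exactly known fixture geometry, the two-layer fit
becomes genuinely competitive with the CNN on synthetic lab-fixture data:
the published advantage of the learned estimator over two-layer fitting
rests in part on the single-run, initialization-sensitive protocol the
classical fit is operated at, which is how the packaged comparison runs
it.

## Known limitations

* The tilt treatment in the analytic forward model is first-order (local
  midpoint depth); strongly tilted, shallow interfaces are the worst case,
  bounded in the tests at ~0.07 in log amplitude against the grid solver.
* The finite-difference solver's accuracy budget is ~2-5% at 2.5 mm; its
  residual bias is visible to the CNN (trained on analytic forwards) and
  is part of the phantom-study error, mimicking the model mismatch a real
  instrument would add.
* All simulated noise is i.i.d. Gaussian; real instruments drift and have
  separation-dependent SNR, which only the gain-calibration fixture
  partially emulates.
* The chest-wall layer is homogeneous in every model here; ribs and
  muscle layering are out of scope.
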