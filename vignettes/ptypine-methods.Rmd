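---
title: "Phase retrieval with a denoising engine: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase retrieval with a denoising engine: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the measurement model, the reconstruction engines, the nonexpansive
denoiser and its synthetic training corpus, the evaluation pipeline, and
the numerical choices made where the design was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The measurement model

Ptychography scans a specimen with a localized coherent beam at
overlapping positions and records far-field diffraction intensities. The
package represents the specimen as a complex transmission `O` (N x N; its
modulus is absorption contrast, its argument refractive phase contrast)
and the illumination as a complex probe `P` (M x M, M < N). For scan
offset `r` the model is

    I_r = | F( S_r(O) * P ) |^2 ,

with `S_r` the patch-extraction operator, `*` element-wise multiplication
and `F` the *unitary* two-dimensional DFT. The unitary convention is a
deliberate numerical choice: Parseval holds exactly, forward and inverse
transforms are mutual adjoints, and the modulus-replacement step below is
then an orthogonal projection in both domains. Dose is calibrated so that
a vacuum exposure has exactly `I0` expected photons at its zero-frequency
pixel — anchoring `I0` to a vacuum reference rather than per pattern keeps
the dose definition independent of the specimen. Photon noise is Poisson
per pixel; means above 1e7 use the rounded normal approximation (relative
error below 3e-4 there), keeping counts integer-valued and seeded.

Coordinates are 0-based, row-major; offsets are top-left corners and
regions are half-open, so patch extraction and replacement round-trip
bit-exactly.

## Reconstruction engines

All engines sweep the R observations once per epoch in a seeded random
order (the order is derived from `shuffle_seed + epoch`, so different
algorithms can share identical visit sequences). For each observation the
exit wave `W = O_r * P` is projected onto the measured modulus,

    Psi = F^-1( sqrt(I_r) * Xi(F(W)) ),

where `Xi` is the element-wise modified sign, defined as `z/|z|` with
`Xi(0) = 1`. The zero convention makes the projection total and
idempotent and assigns zero phase to unobserved frequencies. Object and
probe then take gradient steps scaled by the Lipschitz constants of the
respective subproblems:

    O_r <- O_r - (alpha / max|P|^2)   * Conj(P)   * (O_r P - Psi)
    P   <- P   - (beta  / max|O_r|^2) * Conj(O_r) * (O_r P - Psi)

with `alpha, beta` in (0, 2). Both updates use the pre-update `O_r` and
`P` — a simultaneous-style update from the shared residual; sequential
variants exist, and the choice is documented here because it matters for
bit-level reproducibility. The rPIE baseline replaces the step
denominators by the relaxed forms `(1-alpha)|P|^2 + alpha max|P|^2` (and
analogously for the probe, with `alpha` in (0, 1] and `beta` in (0, 5]);
its update formulas follow the original regularized-engine formulation
since this package's own sources do not restate them.

PINE appends, once per epoch and to the object only, a hybrid-steepest-
descent relaxation toward the fixed points of a denoiser `D`:

    O <- O - rho * (O - D(O)),   rho in (0, 1/2), default 0.49.

The fixed-point set of a good denoiser is a learned proxy for the set of
noiseless images; the `rho` window is the convergence condition of the
hybrid steepest descent scheme (which assumes `D` nonexpansive; global
convergence for this nonconvex problem is not guaranteed and not
asserted — the package instead checks empirical per-epoch descent). With
an identity denoiser, or in the `rho -> 0` limit, PINE reduces to ePIE
exactly — bit for bit under shared seeds, which the test suite asserts.

Divergence policy: any non-finite value during a sweep aborts with the
epoch and observation index, rather than silently clipping. The stopping
rule is a fixed epoch budget; no auto-stopping heuristic is applied.
The probe is updated from the first epoch (`update_probe = TRUE` by
default); freezing the probe for initial epochs is common practice
elsewhere but is not done here, and the flag is exposed.

## The denoiser and its training corpus

The denoiser is a DnCNN-style residual network: `depth` zero-padded,
stride-1 convolutions (default depth 7, width 32, 3x3 kernels) with ReLU
between them; the network estimates the noise field and the denoiser map
is `D(X) = X - net(X)`. The final layer is zero-initialized so an
untrained denoiser is exactly the identity. Batch normalization is
omitted deliberately — it interacts poorly with strict spectral
normalization — and biases are allowed (they do not affect Lipschitz
constants). The default depth/width is reduced from the 17/64 commonly
used for this architecture so that training runs at desk scale on a CPU;
the structure is otherwise identical.

Training minimizes the mean squared error between `net(X)` and the noise
`X - Y` over noisy/clean pairs on `[0, 1]`, with Adam (learning rate
1e-3), a seeded 90/10 train/validation split, and — after every optimizer
step — per-layer spectral normalization: the operator norm of each
convolution (estimated by power iteration on the full zero-padded
convolution operator at training image size, warm-started across steps)
is forced to at most 1 by rescaling layers that exceed it. Layers already
inside the unit ball are left untouched. If the power iteration has not
settled within its budget a warning is raised and a conservative extra
division applied. A training batch size of 4 is used in the package's
reduced recipes: at epoch counts this small, more optimizer steps per
epoch matter more than smoother gradients.

Layerwise norms at most 1 make the *residual-estimating network*
nonexpansive. Whether the full map `X - net(X)` inherits a useful bound
is a separate question the package does not assume away: the end-to-end
Lipschitz constant is estimated empirically (`estimate_lipschitz`, random
pairs plus adversarially close pairs) and reported alongside the layer
norms, with a flag when the estimate exceeds `1 + 1e-3`.

Complex fields are denoised part-by-part (`D(Re O) + i D(Im O)`), never
on amplitude/phase, which would be exposed to phase wrapping. Each part
is affinely mapped from its own min/max onto `[0.1, 0.9]` — a margin
inside the training range that avoids boundary clipping — and inverse-
mapped afterwards; a part with degenerate range bypasses the network
unchanged. The mapping is a package design choice; its consequence is
that the complex wrapper is exactly deterministic but only affinely
compatible with the training-range statistics.

The corpus is formula-driven: dead-leaves images, in which random shapes
(circles, triangles, rectangles) are layered with occlusion until the
canvas is covered. Shape radii follow the classic scale-invariance choice
`p(r) ~ r^-3` on `[4, size/3]`; the "diverse" variant fills shapes with
uniform grays, the "textured" variant with oriented band-limited noise
through a random monotone tone curve. These parameter choices are
documented defaults for a generator whose original parameterization is
not restated in this package's sources. Canvases are 128 x 128 by
default, intensities conceptually 8-bit (`[0, 255]`) normalized to
`[0, 1]`, and noise is Gaussian with `sigma = 15` on the 0-255 scale.
The generator emulates the occlusion statistics of natural images; it
does not emulate specimen-specific structure, instrument transfer
functions, or correlated noise, so denoising gains measured on held-out
dead-leaves pairs demonstrate transfer only to data sharing those
generic statistics.

## Evaluation

Reconstructions are compared to truth only after removing the gauge
ambiguity `(O, P) -> (c O, P / c)` and any residual translation:

1. pixels whose accumulated illumination `sum_r |P|^2` falls below 1% of
   its maximum are set to vacuum in both fields;
2. the closed-form least-squares complex scalar
   `c = sum(truth * Conj(recon)) / sum(|recon|^2)` fixes amplitude scale
   and phase offset;
3. the shift is estimated by phase-only correlation — normalized
   cross-power spectrum, inverse transform, integer peak plus the
   one-sided sinc-ratio estimator `delta = r1/(r0 + r1)` per axis (exact
   for a sinc-shaped peak) — then polished by maximizing the correlation
   magnitude over fractional shifts directly in the Fourier domain, and
   applied by Fourier interpolation. The polish step exists because
   pure 3x3 peak-fitting estimators carry worst-case biases of order
   0.1 px on Dirichlet-shaped peaks, above the 0.05 px bar the package
   sets for itself on synthetic shifts.

One registration subtlety deserves emphasis: the gauge scalar is
estimated from the *kept* pixels only, before the masked periphery is
replaced by vacuum. Fitting the scalar after substituting vacuum into
both fields pins the global phase to the substituted values, leaves a
uniform residual of magnitude `|e^{i phi} - 1|` across the entire field
for a reconstruction with global phase `phi`, and depresses every FRC
ring — an error mode that is easy to mistake for poor reconstruction
quality.

Fourier ring correlation uses one ring per integer frequency radius up to
Nyquist (standard practice; it maximizes curve resolution at these field
sizes), reports the real part of the normalized cross-correlation, and
marks empty rings as missing rather than zero. Frequencies are addressed
as fractions of Nyquist, so the half- and three-quarter-Nyquist probe
points are geometry-independent. No edge apodization is applied by
default; the periphery handling above follows the 1%-illumination rule.

## Study conditions and problem sizes

The package's self-contained experiments use a synthetic stand-in for a
particle-filled polymer film: a 192 x 192 canvas with 100 disks of radius
3-10 px (spherical-cap thickness profiles; transmission drop 0.15 and
phase depth 0.6 rad at full thickness), a 64 x 64 bump probe of support
radius 24 px, and an 11 x 11 grid scan with 12 px steps — a 75% linear
overlap ratio with the convention `overlap = 1 - step / (2 * support
radius)`, which reproduces the 75/50/37.5% ladder under step decimation
by factors 1, 2 and 2.5. The disk density is chosen so that every scan
position sees specimen structure: a sparse phantom leaves the joint
object/probe problem weakly anchored over featureless regions, and the
emulated specimen is a *filled* film. Doses of `I0 = 1e10` (high) and
`1e8` (low) photons at the vacuum DC pixel define the noise conditions.
The reduced denoiser recipe used by the acceptance runs trains the
default 7/32 architecture on 200 dead-leaves images for 3 epochs at
batch size 4.

The *simulation* probe carries a quadratic phase of pi radians at its
support edge — the wavefront curvature of a slightly defocused focused
beam. This is not cosmetic: a purely real, centrosymmetric simulation
probe makes the conjugate-reflected object an exact second solution of
the measurement model (the twin image), and iterative engines started
from a symmetric state converge to blends of the two twins, saturating
percent-level errors that no amount of iteration removes. Real beamline
illuminations are never conjugate-symmetric, and neither is this
package's. The *initial* probe estimate handed to the engines remains
the flat real bump of matching support — the conventional
blind-but-right-sized starting guess.

Reconstruction step scales follow a small grid search at these
conditions (the same best-of-grid protocol these engines are normally
tuned with), selected on gauge-corrected FRC and fixed as
`tuned_hyperparams()`: ePIE (0.7, 0.7), rPIE (0.3, 2), PINE (0.8, 0.5)
at both doses, with rho = 0.49 throughout.

The parameter-recovery check uses a variant of the phantom whose
particles keep a 44 px vacuum margin from the canvas edge and a +-2 px
jittered scan grid: the weakly illuminated periphery converges slowest of
all object modes and a perfectly periodic lattice leaves a residual
artifact ring at the scan frequency, and neither effect is the question
that a noiseless recovery test asks.

These sizes are the package's desk-scale choices; they are deliberately
small compared to beamline practice, and the acceptance thresholds
associated with them are interpreted accordingly.

One consequence of the desk scale deserves honesty up front: with a
64 x 64 detector, 1e8 photons at the vacuum zero-frequency pixel leave
every diffraction pixel well populated, so the package's "low-dose"
condition is barely noise-limited — the classical engines converge
essentially as they do at high dose, and the regime in which a denoising
prior pays for its bias (severely photon-starved data) is not reached at
this geometry. The convergence-speed comparisons the package runs at low
dose show PINE overtaking ePIE well within half the epoch budget, but
not the (noise-unhindered) rPIE baseline, whose asymptote the weakly
trained reduced denoiser's smoothing bias sits just below. Scaling the
detector and canvas up — spreading the same dose over more pixels —
is the faithful way to re-enter the photon-starved regime, at a
correspondingly larger compute budget.

## Known limitations

* The forward model omits partial coherence, multi-mode probes, detector
  point spread, readout noise and parasitic scattering.
* Position refinement, multi-slice objects and difference-map/RAAR
  backends are out of scope.
* The phase-ramp gauge (`O -> O e^{i q x}`, probe counter-rotated) is not
  corrected by the registration; with the symmetric bump probe used in
  the simulations the reconstructions have not been observed to drift
  into it, but evaluation against truth fields with strong ramps would
  require extending the gauge model.
* The denoiser's nonexpansiveness is enforced layerwise and audited
  end-to-end; it is not a proof, and the hybrid-steepest-descent
  convergence conditions are sufficient conditions for a convex problem
  this problem does not satisfy.
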