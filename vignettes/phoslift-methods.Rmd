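---
title: "Models and numerical methods in phoslift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in phoslift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phoslift` analyzes dual-oxyphor phase-delayed optical-section
phosphorescence lifetime images of the retina: it turns stacks of
phase-stepped intensity images into per-pixel lifetimes, oxygen tension (PO2)
maps, vessel tensions, an inner retinal oxygen extraction fraction (OEF),
tissue-tension depth profiles, and an outer retinal oxygen consumption rate
(QO2). This vignette describes the models, the tunable parameters, the
numerical choices, and what the bundled simulator does and does not emulate.

## The homodyne lifetime model

Excitation and detector gain are modulated at the same frequency
$f$ (default 1.6 kHz) and the relative phase $\theta$ is stepped through $K$
values (default 10 equal 18° steps from 0°, spanning half a period). A pixel
whose phosphorescence decays mono-exponentially with lifetime $\tau$ responds,
at the fundamental harmonic, as

$$ I(\theta) = A\,[1 + m\,M(\tau)\cos(\theta - \varphi(\tau))], \qquad
   \varphi = \arctan(\omega\tau),\quad M = (1+(\omega\tau)^2)^{-1/2},\quad
   \omega = 2\pi f. $$

Assumptions worth stating:

* **First-harmonic model.** Physical systems chop the excitation with a
  square wave and gate an image intensifier; we model only the fundamental
  harmonic, the standard approximation in frequency-domain lifetime imaging.
  Since the simulator and the estimator share this model, simulation tests
  verify the estimator, not the harmonic approximation itself. Chopper duty
  cycle and gate width are deliberately not modeled.
* **Mono-exponential decay** per pixel (one oxyphor per channel).
* **Half-period phase coverage.** With $\theta \in [0°, 180°)$ the cosine and
  sine basis vectors are *not* orthogonal, so `fit_phase_pixel()` solves the
  normal equations of $I_k \approx a + b\cos\theta_k + c\sin\theta_k$ exactly
  rather than using Fourier quadrature, which would be biased here. The phase
  lifetime is $\tau = \tan(\mathrm{atan2}(c,b))/\omega$.

A fit is **valid** only if the phase lag lies strictly inside (0°, 90°) —
boundary values are flagged, never clamped — and the DC amplitude $a$ exceeds
`amplitude_threshold` (default 0.1) times the stack's 99th-percentile DC
amplitude. The percentile reference makes the threshold robust to isolated hot
pixels. A modulation-ratio lifetime ($\tau_M$ from $M = B/(Am)$) is exposed as
a diagnostic via `modulation_lifetime()`; it requires the true modulation
depth $m$, which is why the phase lifetime is the primary estimate.

## Oximetry

Stern-Volmer quenching, $1/\tau = 1/\tau_0 + k_q \cdot \mathrm{PO}_2$, is
inverted per pixel. Negative outputs within `epsilon` (default 1 mmHg) below
zero are attributed to estimation noise and clipped to 0; anything below
$-\epsilon$ indicates a calibration inconsistency and is invalidated. The
tissue map is averaged across the three replicate acquisitions *in the PO2
domain* (mask conjunction), mirroring the acquisition protocol's order of
operations; vessels are likewise averaged per replicate and then across
replicates. Averaging in the PO2 and lifetime domains differ wherever the
field is not constant — the test suite asserts the difference rather than
hiding it.

Calibration constants are **required configuration**. The shipped defaults
(R0: $\tau_0$ = 637 µs, $k_q$ = 381 mmHg⁻¹s⁻¹; G2: $\tau_0$ = 251 µs,
$k_q$ = 281 mmHg⁻¹s⁻¹) are literature placeholders and every constructor
warns when one is used.

## Curvature flattening and depth profiles

The retina is curved in the optical section; depth profiles require a
flattened image. The method was chosen to be the smallest assumption set that
achieves sub-pixel alignment:

1. Per row, the chorioretinal interface is localized at the maximum of the
   axially box-smoothed signal (width `presmooth_z` = 5 px; ties resolved
   toward the choroid, where tension physically peaks). The tension map is the
   default signal since its maximum sits at the interface.
2. The position is refined to sub-pixel precision by **coverage inversion** of
   the amplitude edge: a pixel straddling the dye boundary carries amplitude
   proportional to its covered fraction, so the boundary sits at the last
   fully covered pixel plus the summed fractional coverages beyond it. This is
   exact for a box-sampled step edge and is what makes the downstream retinal
   thickness estimate — and hence QO2, which scales with thickness squared
   through the profile curvature — accurate to well below a pixel. Integer
   argmax alone quantizes the boundary by ±0.5 px, a 2–4 % QO2 error at the
   default geometry.
3. A quadratic in row index is fit to the per-row positions; each row is
   shifted by linear interpolation so the fitted interface is a constant
   column. Rows with no detectable signal are excluded and flagged.
4. The inner retinal surface is detected per row as the first position whose
   amplitude exceeds `inner_threshold` (default 0.1) of the row maximum,
   refined the same way. Retinal depth is normalized per bin, not globally,
   because retinal thickness varies across the section.

The flattened tension image is smoothed with a mask-aware anisotropic box
filter of 6 px (vertical, 3 µm pitch) × 4 px (axial, 4.5 µm pitch) — 18 µm in
both axes. Windows are truncated at borders and invalid pixels and
renormalized by the number of valid pixels actually present; padding would
drag boundary-adjacent tensions toward zero. Even-sized windows anchor the
extra taps before the center (offsets −3…2 and −2…1).

Rows are then grouped into `bin_px` = 10 contiguous bins (30 µm, giving 35
profiles for the default 350-row scan), averaged vertically per axial pixel,
and rescaled to fractional depth 0 (inner surface) → 1 (chorioretinal
interface) using the bin-mean boundary traces. The 50 % sample belongs to the
outer retina. Bins with retina thinner than 4 px are flagged unusable.

## The three-layer diffusion model and QO2

At steady state, oxygen diffuses one-dimensionally from the choroid across
the outer retina: $Dk\,P'' = Q(x)$ on $x \in [0, L]$ with $x = 0$ at the
chorioretinal interface, $L$ the outer-retinal thickness (half the retinal
thickness; the fit never sees the inner half), $P(0) = p_c$, $P(L) = p_l$.
Consumption is zero in layers 1 (photoreceptor outer segments) and 3 (outer
nuclear layer) and constant $q_2$ in layer 2 (inner segments), yielding a
linear–quadratic–linear profile; `three_layer_po2()` evaluates the closed
form obtained from continuity of tension and flux at the two free boundaries
$x_1 < x_2$. Reported consumption is averaged over the whole outer slab,
$QO_2 = 100\,q_2\,(x_2 - x_1)$ mL O₂/100 g/min (tissue density 1 g/mL) — this
averaging convention is stated explicitly because alternatives (per-layer
rates) differ by the layer-width factor.

`fit_three_layer()` minimizes the residual sum of squares over
$(p_c, p_l, x_1, x_2, q_2)$ with Levenberg–Marquardt (`minpack.lm`),
500 iterations and a relative tolerance of $10^{-8}$ per start. Constraints
stay smooth through reparameterization: $x_1$ and the relative width
$(x_2-x_1)/(1-x_1)$ pass through logistic transforms and $q_2$ through a
square. Initialization: $p_c$ = profile maximum, $p_l$ = value at 50 % depth,
$x_1 = 0.2$, $x_2 = 0.4$, $q_2$ from the largest discrete curvature of the
profile; three seeded, jittered starts guard against local minima, and the
best-RSS start wins. Fits that fail to converge or end with a layer boundary
at its bound are excluded from the mean QO2 and counted.

**Modeling the smoothing operator.** The 18 µm axial box filter is comparable
in width to the consumption layer itself, so fitting the raw closed form to
smoothed data systematically underestimates the profile curvature (and QO2 by
roughly 5–7 % at the default geometry). Because the pipeline *knows* the
filter it applied, the fit's forward model averages the closed form over the
same kernel taps (`smooth_kernel_x`), and samples whose window overlaps the
retina boundaries — where the mask-aware data smoothing renormalizes over
partial windows that a plain average does not describe — are excluded. This
removes the operator bias without touching the data. The residual bias from
the sub-pixel interpolation used during flattening (an additional, row-varying
two-tap kernel) is below 0.5 % at the default geometry and is accepted.

$Dk$ (diffusivity × solubility) is required configuration; the placeholder
$1.97\times10^{-10}$ mL O₂ cm⁻¹ s⁻¹ mmHg⁻¹ is converted to per-minute units
internally. $QO_2 = 100\,q_2 (x_2-x_1)$ depends on $Dk$ only through the fit.

## OEF and cohort statistics

A Hill curve models the rat oxyhemoglobin dissociation:
$S = \mathrm{PO}_2^n/(\mathrm{PO}_2^n + P_{50}^n)$, content
$C = c_{Hb} S + \alpha \mathrm{PO}_2$ with defaults $P_{50}$ = 36 mmHg,
$n$ = 2.7, $c_{Hb}$ = 0.2 mL O₂/mL, $\alpha = 3\times10^{-5}$ mL O₂/mL/mmHg
(placeholders, warned). The dissolved-oxygen term is included by default and
can be set to 0. OEF $= (C_a - C_v)/C_a$ is computed per animal from that
animal's mean arterial and venous tensions and only then averaged across
animals — a cohort-mean OEF is a mean of ratios, not the ratio of means.
`cohort_stats()` provides mean ± SD per quantity, paired two-sided t tests
for (PO₂A, PO₂V) and (PO₂V, inner tPO₂), and OLS regressions of QO₂ on
maximum outer tPO₂ and OEF on inner tPO₂, flagging degenerate-variance cases
rather than erroring.

## What the simulator emulates — and what it does not

`build_scene()` + `render_phase_stacks()` produce the study conditions as
defaults: a 350 × 100 px scene at 3 × 4.5 µm pixel pitch (a ~1 mm vertical
scan line; the pitch is back-derived from the protocol's 10 px = 30 µm
vertical bins and 4 px = 18 µm axial filter), 230 µm retinal thickness, a
quadratic chorioretinal interface with 8 px sag, two arteries at 41 mmHg and
one vein at 25 mmHg (circular cross-sections at 25 % depth), inner tissue at
23 mmHg with a 4 mmHg Gaussian elevation (60 µm width) near arteries decaying
to zero at half depth, and an outer profile built from the three-layer model
with $p_c$ = 33 mmHg, $p_l$ = 23 mmHg, $x_1$ = 0.2, $x_2$ = 0.4 and
QO₂ = 0.57 mL O₂/100 g/min. The boundary tension default of 33 mmHg is the
measured cohort-mean maximum outer tension, which the profile maximum equals
by construction. Acquisition defaults: 10 phases, 1.6 kHz, modulation depth
0.8, amplitude 1000 counts, 3 replicates per channel, additive Gaussian noise
(default σ = 20 = 2 % of amplitude; replicates differ only in noise draws and
all randomness flows from one seed). Retina-edge pixels carry fractional
(partial-volume) amplitude, the physical basis of the sub-pixel boundary
detection above.

Not emulated, deliberately: optical scattering and the instrument PSF (real
intraretinal scattering lowers depth resolution and flattens profile
curvature, biasing QO2 downward — a passing simulation test does not certify
against that); photon (Poisson) noise — additive Gaussian read noise is
assumed instead, keeping the estimator oracles analytic; photobleaching and
phototoxicity; eye motion; blood-column depth structure inside vessels; and
registration between the two channels (they are assumed co-located). Fixture
TIFFs are digitized to 16 bits with an affine intensity offset/scale recorded
in the YAML sidecar, emulating the camera ADC; the quantization step (~1.5e-5
of full scale) is far below the acquisition noise.

## Numerical choices and degenerate inputs

* Lifetime fits require K ≥ 3 distinct phases; rank-deficient designs raise an
  error, while per-pixel failures (no modulation, out-of-range phase) are
  masked, not thrown.
* Interface detection ties resolve toward the choroid; rows without signal
  are excluded and flagged; maps with fewer than 3 usable rows refuse to
  flatten.
* `extract_profiles()` on a map shorter than one bin returns a well-formed
  empty table; too-thin bins are flagged unusable rather than dropped
  silently.
* The flatten target column is the rounded mean fitted interface, so a second
  flattening pass moves rows by less than half a pixel (idempotence is
  tested).
* All file outputs are deterministic functions of configuration + seed (no
  timestamps), so identical runs are bit-identical — tested via checksums.

Problem sizes in the test suite were chosen to keep the full suite under a
minute of compute while exercising every code path: most unit tests run on a
60 × 60 px scene (144 µm retina, 6 profiles), and the end-to-end checks run
the full 350 × 100 px default scene with all three replicates.

## Known limitations

* The phase estimator assumes the sinusoidal fundamental; systematic
  deviations of a real chopper/gate waveform would bias lifetimes in a way
  the simulator cannot reveal.
* QO2 accuracy depends on the configured $Dk$ and on boundary detection; in
  real images with scattering, the amplitude edge is blurred and the
  coverage-inversion refinement degrades gracefully toward integer precision.
* The three-layer fit is only weakly identified when consumption is near zero
  (any $x_1, x_2$ fit equally well); such fits report near-zero QO2 and may
  be excluded by the at-bound rule.
* Cohort statistics assume one row per animal and at least three animals;
  they do not model within-animal correlation beyond the paired tests.
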