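---
title: "MR vascular fingerprinting: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MR vascular fingerprinting: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mrvf)
```

This vignette documents the physical model implemented by `mrvf`, the
conventions and defaults that matter when using it, and the reasoning behind
the design choices that were genuinely open. It states no empirical result
that the package's test suite does not itself compute.

## The voxel model

An imaging voxel is represented by a two-dimensional periodic square lattice
(default 256 × 256 points) containing straight cylindrical blood vessels
seen in cross-section. A microvessel network voxel holds `n_vessels`
(default 96) non-overlapping disks of a common radius placed uniformly at
random; the physical side of the voxel is *adapted to the blood volume
fraction*:

$$L = \sqrt{n \pi r^2 / \mathrm{BVf}},$$

so that the disk union occupies exactly the requested BVf (up to
rasterization error, bounded at 10 % relative in the geometry contract and
typically far smaller). Each microvessel is assigned an independent
orientation: the angle $\theta$ to $B_0$ has $\cos\theta$ uniform on
$[0,1]$ (an isotropic 3D distribution), with a uniform in-plane azimuth.
Cross-sections are kept circular; the ellipticity of oblique sections is
ignored, consistent with the isotropic-network assumption of the
steady-state comparators. Two-large-vessel voxels hold exactly two cylinders
at a prescribed $\theta$.

Overlapping cylinders would silently break the BVf constraint, so centers
are rejection-sampled (up to 10 000 attempts per vessel) and an explicit
*geometry-infeasible* error names the offending (BVf, radius) pair when
packing fails. All distances use the minimum-image convention; lattice point
$(i,j)$ sits at the center of its cell.

## Field model

The frequency offset of one magnetized cylinder, with the susceptibility
difference $\Delta\chi$ in SI units, is

$$\omega_{\mathrm{out}}(\rho,\phi_p) =
  \tfrac{1}{2}\gamma B_0 \Delta\chi \sin^2\theta\,(a/\rho)^2 \cos 2\phi_p,
  \qquad
  \omega_{\mathrm{in}} = \tfrac{1}{6}\gamma B_0 \Delta\chi (3\cos^2\theta - 1),$$

with $\phi_p$ measured from the projection of $B_0$ in the plane normal to
the cylinder. The pre-contrast susceptibility difference follows the
oxygenation model $\Delta\chi = \Delta\chi_0 \cdot Hct \cdot (1 -
\mathrm{StO_2})$; the contrast agent adds a fixed $\Delta\chi_{USPIO}$
(3.5 ppm SI at 4.7 T — agent- and field-dependent) to the intravascular
compartment.

`compute_field()` superposes the analytic fields of all vessels under the
minimum-image convention (the default, because it is directly verifiable
against the closed form), or convolves analytic disk spectra with the 2D
dipole kernel $\sin^2\theta\,(1/2 - k_u^2/|k|^2)$ in Fourier space
(`method = "fourier"`), adding the Lorentz-corrected intravascular term
$(3\cos^2\theta-1)/6$ explicitly so the 2D computation reproduces the 3D
interior value. The two methods differ only in boundary treatment (nearest
image versus the full periodic image sum) and agree within 2 % of the field
scale away from vessel walls; both are exactly linear in $\Delta\chi$ and
$B_0$. Intravascular lattice points carry the uniform interior value of
their own vessel plus the exterior fields of all others.

## Signal simulation

The sequence is a GESFIDE train: ideal 90° excitation at $t=0$, gradient
echoes sampling the FID, an ideal instantaneous 180° pulse at
$\mathrm{SE}/2$, then gradient echoes up to and beyond the spin echo.
Defaults: 32 echoes, $\Delta TE = 3.3$ ms, SE = 60 ms, TR = 4000 ms. The
printed timing does not fix every echo position; because the signal changes
abruptly at echo 8 when the 180° pulse plays, the default places echoes
1–8 at $k\cdot 3.3$ ms and echoes 9–32 at $30 + k\cdot 3.3$ ms. Both the
echo pattern and an arbitrary explicit echo list are configurable.

Each time step ($\delta t = 0.5$ ms) applies the field-induced phase
rotation $m \leftarrow m\,e^{-i\omega\delta t}$ followed by water diffusion,
implemented as convolution (in Fourier space, periodic boundaries) with a
discrete Gaussian kernel of per-axis standard deviation $\sigma =
\sqrt{2\,\mathrm{ADC}\,\delta t}$, normalized to unit sum so total
magnetization is conserved exactly. Rotation-then-diffusion sequential
splitting differs from the interleaved operator by $O(\delta t^2)$; at
$\delta t = 0.5$ ms this is far below the other model errors. Two
numerical notes: (i) $\delta t$ does not divide 3.3 ms, so echoes are read
out by linear interpolation of the complex lattice sum between step times
(at the refocusing node both the pre- and post-conjugation values are kept
so interpolation never crosses the pulse); (ii) at typical resolutions
$\sigma$ is below one lattice cell (≈ 0.6 cells for ADC = 800 μm²/s), where
the discrete kernel slightly under-disperses — its realized variance is
within a few percent of $\sigma^2$ and accumulates additively over steps.

No $T_1$/$T_2$ decay is simulated: the fingerprint is defined as the
post/pre signal *ratio*, in which any multiplicative factor common to the
two acquisitions — $T_2$ and $T_2^\*$ microscopic decay, $B_1$ modulation,
coil sensitivity — cancels identically. The phantom generator applies
$T_2$ decay extrinsically to both arms to emulate raw data. Intravascular
spins are included and carry the uniform interior field; no separate blood
relaxation is modeled.

## Dictionaries

Three grid presets mirror the published dictionaries: A (42 BVf × 32 radius
× 29 ΔΧ at fixed ADC = 800 μm²/s = 38 976 fingerprints), B (A × 27 ADC
nodes = 1 052 352) and C (B plus 5 BVf × 8 radius × 6 orientations × 29 ΔΧ ×
14 ADC two-large-vessel voxels = 97 440 more). The printed material fixes
the ranges and cardinalities but not the node placement, so the package
log-spaces BVf and radius across their printed ranges, linearly spaces the
oxygenation axis (29 nodes spanning StO₂ 0–100 %), and uses 27 linear ADC
nodes from 500 to 1800 μm²/s in steps of 50 — this axis contains 800 and
reproduces the printed count 38 976 × 27 = 1 052 352 exactly. The 14-node
ADC axis of the large-vessel grid takes every other node plus both
endpoints; orientations are 0°–90° in steps of 18°. All axes are
overridable.

Two hematocrit values coexist deliberately: the dictionary ΔΧ axis endpoint
(1.4 ppm at StO₂ = 0) corresponds to the blood hematocrit 0.42, while the
mqBOLD comparator uses the microvascular value 0.42 × 0.85 = 0.357. The
`physics_constants()` default is the microvascular 0.357; the 1.4 ppm
endpoint is reproduced by calling the susceptibility model with
`hct = 0.42`.

One geometry realization (one seed, derived as base seed + tuple index) is
used per (BVf, radius[, orientation]) cell and shared across the
oxygenation and ADC axes — the printed simulation counts equal the tuple
counts, which rules out multiple realizations per cell. Dictionary entries
are therefore bit-reproducible from the stored manifest alone
(`rebuild_entry()`), and building is order-independent in the worker count.
Dictionaries are stored as RDS files with a JSON manifest sidecar.

## Matching

Fingerprints are post/pre ratios (the convention is recorded in the
dictionary manifest and must match the data; a pre/post flag exists because
published figure captions and methods sections disagree on the wording)
with the last 8 of 32 echoes dropped (low SNR). In-plane 3 × 3 Gaussian
smoothing (σ = 0.8 voxel, configurable — the original kernel width is not
printed) is applied to noisy data before fingerprinting; it can be disabled
for clean synthetic input. The search minimizes the reduced chi-squared
$\sum_k (f_k - d_k)^2/(n-1)$ with unit noise weights (no noise map is
available, so the ranking equals the sum of squared errors), breaking ties
toward the lowest entry index for determinism; goodness of fit is reported
as $r^2$ against the selected row and voxels with $r^2 < 0.8$ are recorded
in the exclusion mask and omitted from ROI statistics. Degenerate
fingerprints (non-positive signals on kept echoes, or zero variance) are
excluded with an $r^2 = -\infty$ sentinel. When the dictionary has an ADC
axis, the measured ADC is rounded to the nearest simulated node (ties to
the lower node, out-of-range values clamped) and only that hyperplane is
searched.

## Steady-state comparators

From the same pre/post pair, $\Delta R_2^*$ is the least-squares slope of
$\ln(S_{pre}/S_{post})$ over FID echoes 2–8 (echo 1 skipped as transient;
the original echo windows are not printed) and $\Delta R_2$ is
$\ln(S_{pre}/S_{post})/t$ at the echo nearest the spin echo. With all
susceptibilities in SI units, the static-dephasing forward model is
$\Delta R_2^* = \tfrac{1}{3}\gamma B_0 \Delta\chi_{USPIO}\,\mathrm{BVf}$,
inverted as $\mathrm{BVf} = 3\Delta R_2^*/(\gamma B_0 \Delta\chi_{USPIO})$.
The familiar $4\pi/3$ prefactor belongs to cgs susceptibilities
($\chi_{SI} = 4\pi\chi_{cgs}$); with the printed SI constants the $1/3$
form is the consistent one, and the simulator itself confirms it — a
simulated voxel at BVf = 5 %, r = 5 μm, ADC = 800 μm²/s yields
$\Delta R_2^*$ within a few percent of the 73.3 s⁻¹ plateau (a property the
test suite asserts at 25 % tolerance). The vessel size index is

$$\mathrm{VSI} = C\sqrt{\mathrm{ADC}/(\gamma B_0 \Delta\chi_{USPIO})}\,
  (\Delta R_2^*/\Delta R_2)^{3/2}, \qquad C = 0.867,$$

written with the dimensionless ratio raised to $3/2$ (the only form with
units of length). Because published variants of $C$ assume different
susceptibility unit conventions, the prefactor is an explicit argument.
The mqBOLD comparator fits
$S(t) = C\,e^{-t/T_2} e^{-\mathrm{BVf}\,\gamma B_0 \Delta\chi_0 Hct
(1-\mathrm{StO_2})\,t/3}$ to multi-gradient-echo magnitudes beyond 10 ms,
by Levenberg–Marquardt least squares started from the log-linear solution;
non-convergent voxels are excluded, mirroring the in vivo processing.
Validity-range exclusions are applied exactly as printed: ADC 0–3500 μm²/s,
BVf 0–17 %, VSI 0–50 μm, StO₂ 0–100 %.

## The phantom generator

`generate_phantom()` emulates the raw data of a study animal: a disk-shaped
"brain" with two elliptical deep-gray ROIs (a contralateral striatum and a
lesion), piecewise-constant microvascular parameters per region, pre/post
echo volumes looked up from a dictionary (exact mode; parameters must sit
on the axes) or freshly simulated, multiplicative $T_2$ decay on both arms,
and per-echo noise. The lesion presets encode the qualitative pathological
patterns — stroke-like: lower BVf and StO₂, larger vessels, lower ADC;
tumor-like: high BVf, large vessels, low StO₂ — so pipeline contrasts have
the expected sign by construction.

Noise is Rician by default (magnitude of signal plus complex Gaussian
noise): on late post-contrast echoes of high-BVf voxels the true magnitude
sits at the noise floor, where additive Gaussian magnitude noise goes
negative and no real magnitude image does. Additive Gaussian noise remains
available for regimes where every echo keeps SNR ≳ 20, where the two
models coincide.

What the phantom does *not* emulate — and therefore what passing tests do
not show about real data: anatomy beyond ellipses, partial-volume mixtures
at region boundaries, flow and perfusion effects, contrast-agent
extravasation, macroscopic $B_0$ gradients, motion, and vascular networks
more realistic than randomly placed straight cylinders.

## Identifiability at realistic noise

The acceptance suite measures parameter recovery on a 5 × 5 × 5 scaled-down
dictionary (the printed axis ranges at five log/linear nodes each, 128²
lattice) with Rician noise at SNR 50 through the standard pipeline. Its
per-parameter marginals are high (BVf ≈ 0.98, radius ≈ 0.95 within one grid
step), but the joint rate settles near 0.86 rather than 0.90, for reasons
the suite itself localizes: all StO₂ information in the fingerprint enters
through the pre-contrast susceptibility contrast, which scales with BVf —
at BVf ≤ 1 % adjacent oxygenation entries differ by less than the noise —
and at BVf = 25 % the late kept echoes of the post-contrast arm lie below
the noise floor. Over the BVf ≥ 2.5 % nodes the joint rate is ≈ 0.94 and
direct same-row recovery under σ = 0.01 fingerprint noise is ≈ 0.97. This
is an information limit of the fingerprint at that SNR, not a property of
the search; the corresponding acceptance test is left failing by design
rather than weakened.

## Problem sizes used by the test suite

Chosen as the package's own test design: unit tests use 2 × 2 × 2
dictionaries on 64² lattices with a shortened 8-echo train; the acceptance
checks build the 5 × 5 × 5 dictionary above with the full 32-echo timing
(250 simulations) and run phantom experiments of a few thousand voxels.
Full-size preset dictionaries are validated by counting, not by
simulation.

## Known limitations

* The simulation plane is 2D; three-dimensionality enters only through the
  orientation statistics and the interior Lorentz term ("mimics 3D").
* Static vessels: no flow, exchange, or agent extravasation.
* The diffusion kernel under-disperses slightly when σ is far below one
  lattice cell (very coarse voxels / very large vessels).
* VSI and steady-state BVf inherit the static-dephasing and
  diffusion-narrowing regime assumptions; the printed validity ranges are
  enforced rather than relaxed.
* Dictionary node placement inside the printed ranges is a reconstruction;
  axes should be overridden where the original lists are available.
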