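# mrvf — MR vascular fingerprinting

`mrvf` implements MR vascular fingerprinting (MRvF): mapping microvascular
architecture and function — blood volume fraction (BVf), mean vessel radius
and blood oxygen saturation (StO₂) — from pre/post-contrast multi-echo MR
acquisitions, by matching each voxel's signal against a dictionary of
simulated signals from virtual vascular networks. It is aimed at
quantitative-MRI researchers who want a self-contained, testable
implementation of the full chain: voxel-scale simulator, dictionary
generation, fingerprint matching, the classical analytic comparators, and a
digital phantom so every stage runs without scanner data.

## The method

A voxel is modeled as a 2D periodic lattice containing straight cylindrical
vessels occupying a blood volume fraction BVf; the voxel side is adapted as
L = √(nπr²/BVf). The vessel–tissue susceptibility difference follows the
oxygenation model

    Δχ = Δχ₀ · Hct · (1 − StO₂),

and injection of an iron-oxide contrast agent (USPIO) adds Δχ_USPIO =
3.5 ppm (SI) intravascularly. Magnetic field offsets are the superposition
of analytic cylinder fields (ω ∝ ½γB₀Δχ sin²θ (a/ρ)² cos2φ outside,
⅙γB₀Δχ(3cos²θ−1) inside); the magnetization lattice evolves in 0.5 ms steps
under phase rotation and water diffusion (Gaussian kernel with
σ = √(2·ADC·δt), convolved in Fourier space) through a GESFIDE sequence
(32 echoes, ΔTE = 3.3 ms, 180° pulse at 30 ms, spin echo at 60 ms).

The *fingerprint* of a voxel is the vector of post/pre signal ratios over
the first 24 echoes — a quantity insensitive to T₂, B₁ and macroscopic B₀,
but shaped by the susceptibility microstructure. Dictionaries of simulated
fingerprints are generated over grids of (BVf, radius, StO₂, ADC,
orientation); matching minimizes the reduced chi-squared and reports r²,
with voxels below r² = 0.8 excluded. Steady-state comparators from the same
raw signals are included: ΔR₂*/ΔR₂ extraction, BVf = 3ΔR₂*/(γB₀Δχ_USPIO),
VSI = 0.867·√(ADC/(γB₀Δχ_USPIO))·(ΔR₂*/ΔR₂)^{3/2}, and the mqBOLD StO₂
fit. See `vignette("mrvf-methods")` for models, conventions and design
notes.

## Worked example

Simulate one microvessel voxel, fingerprint it, and compare with the
steady-state estimates:

```r
library(mrvf)
phys <- physics_constants()
g <- build_microvessel_geometry(bvf = 0.05, radius = 5, n_vessels = 96,
                                lattice_n = 256, seed = 1)
g
#> Voxel geometry (microvessel): 96 vessels, lattice 256^2, side 388.3 um
#>   BVf target 0.0500, achieved 0.0499

pair <- simulate_pair(g, sto2 = 0.7, adc = 800, seq = sequence_params(),
                      physics = phys)
fp <- make_fingerprint(pair$pre, pair$post)
round(fp$ratio[1:6], 4)
#> [1] 0.7242 0.5340 0.4006 0.2990 0.2275 0.1725

dr2s <- delta_r2star(pair$pre, pair$post)
dr2  <- delta_r2(pair$pre, pair$post)
c(dr2star = dr2s, dr2 = dr2)
#>  dr2star      dr2
#> 81.9...   19.0...
bvf_steadystate(dr2s, phys)   # steady-state comparator: 0.056
vsi(dr2s, dr2, 800, phys)     # vessel size index: 3.30 um
```

The fingerprint decays over the FID (ratios 0.72 → 0.17 by echo 6) because
the agent accelerates dephasing, then partially rebounds toward the spin
echo (ratio 0.32 at 59.7 ms) — the spin-echo-shaped signature that the
dictionary search exploits. The steady-state BVf (0.056) sits close to the
ground-truth 0.05 of the simulated voxel; VSI underestimates the 5 μm true
radius, illustrating why the two vessel-size measures are compared rather
than interchanged.

A full pipeline run — build a toy dictionary, render a phantom, match it —
is exercised end-to-end in `tests/testthat/test-acceptance.R`, and the same
steps are scriptable from a shell via the thin CLI:

```sh
Rscript inst/cli/mrvf simulate-voxel --bvf 0.05 --radius 5 --sto2 0.7 --out fp.csv
Rscript inst/cli/mrvf build-dict --preset A --out dictA.rds --workers 4
Rscript inst/cli/mrvf match --pre pre.nii.gz --post post.nii.gz \
        --adc adc.nii.gz --dict dictA.rds --out maps/
```

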