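# helicalem

Desk-scale helical cryo-EM analysis for actomyosin in R: synthetic
filament specimens, iterative helical real-space reconstruction (IHRSR)
with gold-standard half-datasets and helical-parameter search, FSC
resolution estimation with B-factor sharpening, simplified
multi-resolution flexible fitting of atomic models into density maps, and
the structural analytics (RMSD, domain centroids, displacement fields,
conservation mapping) used to compare actomyosin conformational states.

## The problem

Myosin motor domains decorate actin filaments, and the complex's helical
symmetry lets every filament segment act as a particle: images windowed
along filaments are aligned against reference projections, reconstructed,
and the helical parameters — the axial **rise** Δz and azimuthal **twist**
Δφ per subunit, with the filament density satisfying

ρ(r, φ, z) = ρ(r, φ + Δφ, z + Δz)

— are re-estimated from each reconstruction by maximizing the map's
self-correlation under the screw operator. Two independent half-datasets
are refined against their own references so the Fourier shell correlation

FSC(s) = Re Σ F₁F₂\* / √(Σ|F₁|² Σ|F₂|²)

between half-maps gives an unbiased resolution at the 0.143 criterion.
Atomic models are then fitted flexibly into the maps with a density
energy −g·Σᵢ wᵢ·ρ(xᵢ) on top of restrained mechanics, and the fitted
states are compared by Kabsch superposition, Cα RMSD, and domain-centroid
displacement. `helicalem` implements this whole chain at sizes that run in
minutes on one core, with a synthetic-specimen generator providing ground
truth for every stage.

Who it is for: method developers and students who want an inspectable,
fully testable implementation of the helical reconstruction + flexible
fitting + state-comparison workflow, and anyone who needs its individual
pieces (MRC IO, FSC/sharpening, helical symmetrization, Kabsch/RMSD
analytics, conservation mapping) as plain R functions.

## Worked example

Simulate decorated filaments at the actin-like rigor-state symmetry,
reconstruct with gold-standard halves, and recover the helical parameters:

```r
library(helicalem)

sym <- helical_symmetry(28.06, -166.73)   # rise (A), twist (deg)
sub <- default_subunit(decorated = TRUE)

sim <- simulate_segments(sub, sym, ctf = ctf_params(pixel_size = 3.2),
                         box = 48, step = 81, n_filaments = 20, snr = 5,
                         seed = 11, n_subunits = 48, pixel_size = 3.2)
sim$stack
#> Segment stack: 300 segments, 48 px boxes at 3.20 A/px, step 81.0 A
#>   20 filament(s); 3 asymmetric units per segment

init <- rasterize(build_filament(sub, helical_symmetry(28.3, -166.2), 24),
                  48, 3.2, clip = TRUE)
fit <- ihrsr(sim$stack, init, helical_symmetry(28.3, -166.2),
             refinement_config(n_iterations = 3, phi_step = 6, psi_step = 8,
                               sym_bounds = c(0.8, 1.5), initial_lowpass = 18,
                               seed = 2))
fit
#> Helical reconstruction (IHRSR, gold-standard halves)
#>   segments: 300 (270 included), polished
#>   refined symmetry: rise 28.006 A, twist -166.209 deg
#>   half-map FSC 0.143 resolution: 9.36 A
coef(fit)
#>      rise     twist
#>  28.00574 -166.20928
```

The refined rise is within 0.06 A and the twist within 0.6° of the
generating values (28.06 A, −166.73°) — the desk-scale recovery envelope
at SNR 5 with 5.5-subunit boxes; `fit$log` holds the per-iteration
(rise, twist, resolution) trace, `fit$map` the polished symmetrized map,
and `plot(fit)` the refinement and FSC curves. Noise-free runs of the same
experiment recover the parameters to ±0.05 A / ±0.1°.

Post-processing and comparison work the same way from R or through the
config-driven pipeline stages (`pipeline_simulate()`,
`pipeline_reconstruct()`, `pipeline_postprocess()`, `pipeline_fit()`,
`pipeline_compare()`, `pipeline_conserve()`; a thin CLI dispatcher over
these lives in `inst/cli/helicalem.R`).

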