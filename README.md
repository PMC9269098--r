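# flipdmd

Dynamic mode decomposition of fluorescence-loss-in-photobleaching (FLIP)
image series.

## The problem

In a FLIP experiment a small region of a cell expressing a fluorescently
tagged protein is bleached repeatedly while the whole cell is imaged between
bleach pulses. Any protein pool that exchanges with the bleached region
loses fluorescence; pools that are kinetically isolated — nuclei behind a
transport barrier, phase-separated condensates, solid protein aggregates —
lose it more slowly or not at all. The loss kinetics therefore map barriers
to intracellular protein transport, which is of particular interest for
aggregation-prone proteins such as polyglutamine-expanded Huntingtin.
Extracting those kinetics normally requires fitting decay models pixel by
pixel or calibrating reaction–diffusion models, both slow and heavy with
assumptions.

`flipdmd` takes a model-free route: dynamic mode decomposition (DMD).
The image stack `I(x, y, t)` is reshaped into snapshot matrices
`X = [x_1 … x_{k-1}]` and `X' = [x_2 … x_k]` (one flattened frame per
column) and the best linear one-frame propagator `X' ≈ A X` is compressed
through a rank-`r` SVD truncation, `Ã = U_r* X' V_r Σ_r⁻¹`. Its
eigendecomposition yields spatial modes `φ_j`, discrete eigenvalues `λ_j`
and amplitudes `b_j` such that

```
x(t) ≈ Σ_j φ_j · exp(ω_j t) · b_j ,   ω_j = log(λ_j) / Δt .
```

Each mode is an image with a single complex exponential time dependence:
`Re ω_j` is a per-second loss rate that can be read off directly, and the
mode map shows *where* that kinetic component lives. The truncation rank is
chosen automatically by the Gavish–Donoho optimal hard threshold, which
also makes the rank-`r` reconstruction an effective denoiser, and the
fitted exponentials extrapolate to frames not yet acquired.

The package also contains the closed-form three-compartment FLIP kinetic
model (aggregates → cytoplasm ⇄ nucleus, with cytoplasmic bleaching) used
to validate the decomposition, and a seeded synthetic FLIP image simulator
(cell, nucleus, aggregates, bleach ROI, optional unbleached neighbor cell,
Brownian/flow aggregate motion, Gaussian/Poisson noise) that doubles as the
test-fixture generator.

## Worked example

```r
library(flipdmd)

rates <- rate_constants(k1 = 0.016194, k_m1 = 0.016194,
                        k2 = 0.005, k3 = 0.617582)
model_eigenvalues(rates)
#>          l1          l2          l3
#> -0.00500000 -0.63420034 -0.01576966

scene <- flip_scene("basic", seed = 7)   # 128x128 px, 300 frames, 2% noise
sim   <- render_stack(scene)
model <- dmd(sim$stack, rank = "optimal")
model
#> DMD model: rank 3 (exact modes), 128x128 px, 300 frames, dt = 1 s
#>   modes (slowest first):
#>     1: omega = -0.00509+0.00000i 1/s  |lambda| = 0.99492
#>     2: omega = -0.01589+0.00000i 1/s  |lambda| = 0.98424
#>     3: omega = -0.63521+0.00000i 1/s  |lambda| = 0.52982

assign_modes_to_regions(model, scene_region_masks(scene))[,
  c("mode_index", "re_omega", "label", "classification")]
#>   mode_index     re_omega      label classification
#> 1          1 -0.005094654 aggregates     exchanging
#> 2          2 -0.015890514    nucleus     exchanging
#> 3          3 -0.635210218  cytoplasm     exchanging

psnr(sim$clean, sim$stack)                  # 33.98 dB
psnr(sim$clean, dmd_reconstruct(model))     # 51.15 dB
```

The hard threshold recovers exactly the three kinetic components present in
the simulation. The slowest mode localizes to the aggregates and its rate
(−0.0051 s⁻¹) reproduces the aggregate release rate `k2 = 0.005 s⁻¹` used
to generate the data; the other two modes carry the coupled
nucleus/cytoplasm loss. The rank-3 reconstruction gains ~17 dB of PSNR over
the noisy input — the denoising side effect of the truncation.

Experimental stacks enter through `read_stack("stack.tif", dt = 3)` (the
bleach/acquire cycle time must be supplied; TIFF timing metadata is not
trusted) and leave through `write_stack()`, `write_dmd_model()`,
`export_modes_csv()`. A thin command-line wrapper over the same functions
ships in `inst/cli/flipdmd.R`:

```sh
Rscript inst/cli/flipdmd.R simulate --preset basic --seed 7 --out stack.tif
Rscript inst/cli/flipdmd.R fit stack.tif --rank optimal --out model/
Rscript inst/cli/flipdmd.R reconstruct model/ --out recon.tif
```

Every run writes its fully resolved configuration as a
`*.runconfig.json` sidecar, so each artifact is reproducible from its
sidecar alone.

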