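# holophase

Iterative phase retrieval for **single-shot in-line (Gabor) digital
holography** with **adaptive support constraints built by binary
mathematical morphology**, in R.

A lensless in-line hologram records only the intensity
`I = |P_z(u)|²` of the interference between the object-scattered wave and
the unscattered beam; the phase is lost, and plain back-propagation is
overlaid by the out-of-focus conjugate *twin image*. `holophase`
reconstructs the full complex transmission `u = A·exp(iψ)` (amplitude and
quantitative phase, e.g. of cells or etched targets) by
Gerchberg–Saxton-style iteration between the sensor and object planes,
where the object-plane support mask is **re-estimated every iteration**
from the current reconstruction:

1. binarize (amplitude, and median-centred phase deviation) with a
   parameter-free **Poisson-model minimum-error threshold**;
2. average the **open-closing and close-opening cascades**
   `(OC(B) + CO(B))/2` with a radius-1 disk and a 2×2 square structuring
   element, trading the contraction of one against the expansion of the
   other;
3. Gaussian-smooth and re-binarize at a **Sobel-edge-derived threshold**.

The mask shrinks to fit the object as iterations proceed, filtering
twin-image artifact and measurement noise that a fixed aperture cannot
touch. Two baselines are included: a **static support** (rectangular or
circular aperture) and **multi-distance phase retrieval** (MPR, three
holograms at 0.5 mm plane spacing as amplitude constraints), plus a
band-limited **angular-spectrum propagator**, **Tamura-coefficient
autofocus**, a synthetic hologram **simulator** with calibrated Gaussian
noise, and reference-normalized **MSE metrics**
(`E = Σ|ρ−ρ₀|² / Σ|ρ₀|²`).

## Worked example

Simulate the reference scene (wavelength 500 nm, pixel pitch 5.86 µm,
500×500 hologram padded to 1000×1000, z = 6 cm), reconstruct it with all
three methods and compare:

```r
library(holophase)

sc  <- sim_scene(object = "flat", seed = 3)     # complex letters object
cmp <- run_comparison(sc, iterations = 100)
cmp$summary
#>     method      mse_amp   mse_phase correlation_amp iterations
#> 1 adaptive 0.0005872105  0.07280433       0.9714071        100
#> 2  support 0.0051361494  9.68659208       0.7504916        100
#> 3      mpr 0.0039765662 11.47418107       0.7961421        100
```

`mse_amp` / `mse_phase` are the reference-normalized mean-square errors of
the reconstructed amplitude and (piston-corrected) phase against ground
truth: the adaptive-constraint run reaches an amplitude NMSE of
6×10⁻⁴ — an order of magnitude below both baselines — and is the only
method whose phase error falls below 0.1, i.e. the only one that actually
recovers the stepped phase letters instead of a twin-image-dominated
estimate. `plot(cmp)` draws the NMSE-vs-iteration curves;
`plot(attr(cmp, "results")$adaptive)` shows the reconstructed amplitude,
phase and convergence trace.

Single-hologram reconstruction and autofocus:

```r
h  <- forward_hologram(sc$field, z = 0.06)
r  <- retrieve(h, iterations = 100, constraint = "adaptive",
               pad_shape = c(1000, 1000), ground_truth = sc$field)
af <- autofocus(h, 0.05, 0.07, 5e-4, refine_step = 1e-4)
```

## Command line

A thin Rscript front end lives at `inst/cli/holophase`:

```sh
holophase simulate --shape 500 --seed 7 --snr-db 20 --out scene
holophase retrieve --input scene_hologram.tif --method adaptive \
          --iters 100 --z 0.06 --out recon
holophase autofocus --input scene_hologram.tif --zmin 0.05 --zmax 0.07 \
          --step 5e-4
holophase compare --object flat --iters 50 --out cmp
```

Every run is seeded, writes its resolved settings next to its outputs
(YAML sidecars), and emits per-iteration trace CSVs that are
byte-identical across repeated runs.

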