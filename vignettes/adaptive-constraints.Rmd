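---
title: "Adaptive morphological constraints for single-shot in-line holography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive morphological constraints for single-shot in-line holography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holophase)
```

## The problem

An in-line (Gabor) hologram is the intensity of the coherent superposition
of the wave scattered by a semi-transparent object and the unscattered
reference beam, recorded on a single sensor a distance $z$ behind the
object.  The recorded intensity $I = |P_z(u)|^2$ destroys the phase of the
propagated field, and a plain back-propagation $P_{-z}(\sqrt{I})$ is
contaminated by the out-of-focus conjugate ("twin") image that is inherent
to the on-axis geometry.  Iterative phase retrieval recovers the complex
transmission $u = A e^{i\psi}$ by alternating between the two planes:

1. **Initialize.** The hologram ($M_1 \times N_1$ pixels) is padded with a
   constant to the working grid ($M_2 \times N_2$) to suppress the
   wraparound of the circular-convolution propagation model; the sensor
   field starts as $U_s^0 = \sqrt{I_0}\, e^{i\varphi_0}$ with
   $\varphi_0$ zero (default) or seeded-random.
2. **Back-propagate** to the object plane with the angular-spectrum method,
   $P_z(u) = \mathcal{F}^{-1}\{\mathcal{F}\{u\} \cdot H(f_x, f_y, z)\}$,
   where $H = \exp(i 2\pi z \sqrt{1/\lambda^2 - f_x^2 - f_y^2})$ on the
   propagating band $f_x^2 + f_y^2 \le 1/\lambda^2$ and exactly zero on the
   evanescent remainder.
3. **Constrain** the object-plane field.
4. **Forward-propagate** and restore the measured amplitude
   $\sqrt{I_0}$ at the sensor, keeping the phase.

Everything rests on step 3.  A *static support* (a rectangular or circular
aperture where the object is presumed to lie, zero or background outside)
suppresses artifacts outside the aperture but cannot touch the twin-image
energy inside it.  The method implemented here instead re-estimates the
support **at every iteration** from the current reconstruction, using
binary mathematical morphology to keep object structure and discard
speckle-like artifact.

## The adaptive mask generator

Given a nonnegative image (the current amplitude $A_o$, or the phase
deviation $|\psi_o - \mathrm{median}(\psi_o)|$), `adaptive_mask()` runs:

1. **Poisson-model minimum-error threshold** (`poisson_threshold()`).
   Image values are binned; each candidate split induces two classes
   modelled as Poisson populations with histogram-fitted means, and the
   split minimizing the classified histogram's negative log-likelihood is
   chosen.  The method is parameter-free; log-factorial terms are
   class-independent and cancel.  Polarity (`auto`) takes the minority
   class as object, since objects are sparse in the field of view; it can
   be forced `bright`/`dark`.
2. **Morphological averaging.**  With erosion
   $F \ominus G = \{\varepsilon : (G)_\varepsilon \subseteq F\}$ and
   dilation $F \oplus G = \{\varepsilon : (\hat G)_\varepsilon \cap F \ne
   \emptyset\}$ (outside-image samples are background for both), opening
   $F \circ G = (F \ominus G) \oplus G$ removes speckle smaller than the
   structuring element and closing $F \bullet G = (F \oplus G) \ominus G$
   fills comparable holes.  The open-closing and close-opening cascades
   $OC(F) = (F \circ G_1) \bullet G_2$, $CO(F) = (F \bullet G_1) \circ
   G_2$ err in opposite directions (contraction vs expansion), so their
   average $\bar F = (OC + CO)/2 \in \{0, \tfrac12, 1\}$ is used.
   Defaults: $G_1$ = disk of radius 1 (the 5-cell plus), $G_2$ = the
   $2 \times 2$ square with top-left origin.
3. **Gaussian smoothing** of $\bar F$ with $\sigma = 1$ px (the same
   scale as the structuring elements; configurable).
4. **Edge-derived re-binarization.**  The Sobel gradient magnitude of the
   smoothed image marks edge pixels (above $4\times$ its mean); the
   binarization threshold is the mean smoothed value over those pixels —
   the half-height of the mask transition — falling back to 0.5 when no
   edges are found.

A degenerate input (constant image, or a threshold leaving no object
pixels) returns an all-false mask flagged `degenerate`; the iteration then
skips that constraint rather than zeroing the field, which would be
unrecoverable early on.

## Applying the constraint

How the mask acts on the field is deliberately configurable, because the
literal textbook support rule ($u_i = 0$ outside $S$) contradicts a
transmissive specimen whose background is the unscattered beam:

* `background_fill` (default): amplitude outside the amplitude mask is set
  to the background level (estimated as the median amplitude outside the
  mask), phase outside the phase mask is set to zero — the surround
  reverts to the unscattered plane wave.
* `hadamard`: the literal elementwise product, amplitude and phase both
  zero outside support.

On simulated transmissive scenes the `hadamard` rule destroys the bright
background and the reconstruction with it (amplitude NMSE worsens by three
orders of magnitude in our head-to-head runs), which is why
`background_fill` is the default for both the adaptive method and the
static-support baseline — the comparison then isolates the mask, not the
fill rule.  Amplitude and phase masks are kept separate by default
(`combine_mode = "separate"`), since complex-valued specimens generally
have distinct amplitude and phase structure.

## Baselines

* **Static support** (`constraint = "support"`): a fixed aperture, by
  default the ground-truth footprint's bounding box plus a 10 px margin
  (`footprint_bbox_mask()`) — a deliberately loose, honest stand-in for
  "prior knowledge of the object size".
* **Multi-distance phase retrieval** (`retrieve_mpr()`): three holograms
  at 0.5 mm plane intervals serve as amplitude constraints; each iteration
  cycles the planes nearest-to-farthest (the order is not specified in the
  source method; fixed for determinism) and no object-plane mask is used.

## Autofocus

`autofocus()` back-propagates the hologram amplitude over a distance scan
and evaluates the Tamura coefficient $TC = \sqrt{\sigma(I)/\mu(I)}$ of the
reconstructed amplitude, optionally refining around the coarse optimum.
$TC$ is scale-invariant and single-extremum over a focus range, but the
*polarity* of the extremum depends on the object: for absorbing objects we
observe a maximum at focus, while phase structure converts to amplitude
contrast under defocus and can flip or flatten the curve.  The
`polarity` flag therefore offers `min`, `max` and `auto` (the extremum
farthest from the median of the scan), and the autofocus validation scene
is an amplitude-only object.

## The simulator and what it does (not) emulate

`sim_scene()` reproduces the reference simulation conditions used
throughout validation: wavelength 500 nm, pixel pitch 5.86 µm, a
500×500 hologram padded to 1000×1000 for reconstruction, recording
distance 6 cm, and 0.5 mm MPR plane spacing.  Objects are complex
transmissions $A e^{i\psi}$ with $A \in [0,1]$:

* `"flat"` boundary: block-letter amplitude pattern (absorbing letters,
  transmission 0.4, on a clear background) and a *different* stepped
  phase-letter pattern (0 → 1 rad), on a uniform background.
* `"random"` boundary: the scene fills the whole frame — the amplitude is
  a smooth Gaussian-random texture spanning the amplitude range and the
  phase is a sharp-edged bar pattern.  No clean support region exists,
  which is exactly the regime where a fixed aperture fails (it can only
  exclude the padded margin) while the per-iteration masks still track
  the content.  An earlier blob-with-clear-surround design was tried and
  discarded: when interior texture meets the background level the support
  boundary is physically ambiguous, and the multi-hologram baseline wins
  on amplitude simply because no single-shot method can segment an
  invisible edge.

Forward holograms use the same band-limited angular-spectrum propagator as
reconstruction — an acknowledged inverse crime, which is why the
propagator is independently validated against a direct Rayleigh–Sommerfeld
point summation (opaque-disk axial intensity, the Poisson–Arago bright
spot) and a paraxial Gaussian-beam closed form.  Noise is additive white
Gaussian at a stated SNR with signal power defined as the mean squared
clean intensity (the source convention is unstated; this one is used
consistently, including by the empirical-SNR check), clipped at zero.
Partial coherence, sensor MTF, shot noise and quantization beyond optional
16-bit rounding are not modelled, so passing tests demonstrate algorithmic
correctness on the stated forward model, not camera-grade realism.

## Metrics

Reconstruction error is the reference-normalized MSE
$E = \sum |\rho - \rho_0|^2 / \sum |\rho_0|^2$, applied separately to
amplitude and phase images.  Phase is compared after removing the global
piston (mean phase difference over the reference support, modulo $2\pi$):
intensity-only retrieval is blind to a global phase offset, and penalizing
an unrecoverable degree of freedom would make the metric depend on an
arbitrary gauge.  Raw comparison is available with `piston = FALSE`.
Objects keep $|\psi| < \pi$ so unwrapping is out of scope.

## Numerical choices

* DFT convention: unnormalized forward, $1/N$-scaled inverse (`fft()`
  pair), frequency grids in unshifted DFT order; round trips are exact
  identities in-band.
* Evanescent components are hard-zeroed per the transfer-function
  definition; a warning (not an error) is raised if the sampled grid
  reaches the evanescent region.
* Padding fill: mean of the hologram's 5-pixel border ring, matching the
  unscattered-beam level; the padded margin of $\sqrt{I_0}$ is enforced
  like measured data in the sensor update.  Centred placement puts odd
  remainders bottom/right and is recorded for exact inversion.
* Even structuring elements anchor at the top-left cell (a 2×2 square has
  no centre); the reflection in dilation is taken about the origin cell.
* The readout is the back-propagation of the *final sensor field* (after
  the last amplitude update), cropped to the hologram extent.
* Per-iteration MSE traces are computed from the object-plane field of
  each iteration (no extra transforms); wall-clock stamps are kept in
  memory for MSE-vs-runtime curves but excluded from the CLI trace CSV so
  seeded runs are byte-identical.

## Problem sizes used in validation

The bundled checks run the full reference geometry (500×500 → 1000×1000)
at 100 iterations for the three-method comparisons and the noise studies —
enough for the adaptive run to reach its plateau (amplitude NMSE well
under 0.05 noise-free) while the baselines' behavior (twin-image residue,
noise accumulation inside a fixed support at 15 dB) is already clearly
expressed.  Mechanistic unit tests use 96–256 px grids, where all
operators behave identically but runs are fast.

## Known limitations

* Opening a rectilinear block with the radius-1 disk rounds its corners —
  inherent to morphological smoothing, visible as a slightly conservative
  mask at sharp corners.
* With the background-false border convention on both erosion and
  dilation, closing is not extensive at the image border and the
  erosion/dilation duality holds only away from the border.  Masks of
  interest sit well inside the padded working grid, where the classical
  identities hold exactly (and are tested).
* On random-boundary objects whose interior texture approaches the
  background level, the support boundary is genuinely ambiguous and the
  adaptive mask saturates at the achievable contrast.
* Low-frequency phase is weakly encoded in in-line intensity; phase NMSE
  converges much more slowly than amplitude NMSE and its plateau depends
  strongly on the object class.
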