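---
title: "Reconstructing pictorial depth from single images: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing pictorial depth from single images: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Many animal color patterns — curled-leaf masquerade, eyespots, bark-like
mottling — appear to carry *pictorial depth cues*: monocular pattern
information (shading-like gradients, enhanced contours) that suggests 3-D
relief on what is in fact a nearly flat wing. To quantify such illusory
relief, `pictodepth` reconstructs an *implied* height map from a single
photograph with a closed-form three-stage pipeline:

1. **Intrinsic image decomposition** — split the image $I$ into a
   monochromatic shading map $S$ and a per-channel reflectance map $R$
   with $I = R \times S$;
2. **Shape from shading** — estimate a light direction $D$ and recover a
   per-pixel unit normal map $N$ from the Lambertian relation
   $S = \langle D, N \rangle$;
3. **Height integration** — convert normals to the height gradient
   $\nabla H = -(N_x/N_z,\, N_y/N_z)$, integrate it over a hand-drawn
   region of interest (ROI) in least squares with one border pixel
   anchored at height 0, and subtract the best-fit plane.

The output is relative (pictorial) depth, not metric distance. All three
stages reduce to sparse linear least-squares problems, solved by a
Jacobi-preconditioned CGLS iteration (`lsq_solve()`), so photographic
resolutions fit in memory.

# Stage 1: decomposition model

Working in log space turns $I = R \times S$ into
$\log I = \log R + \log S$, and we solve for $\log S$ only. The objective
is

$$\hat S = \arg\min_S\; \lambda_{Rx}\,Rx(S) + \lambda_{Tx}\,Tx(S)
  + \lambda_{Sc}\,Sc(S),$$

with defaults $\lambda_{Rx} = \lambda_{Tx} = 1$ and
$\lambda_{Sc} = 1000$ (the scale term touches only the few brightest
pixels and must dominate locally). Because each $\lambda$ multiplies a
squared norm, the stacked least-squares rows are scaled by
$\sqrt{\lambda}$.

**Retinex term.** For each inside-ROI 4-neighbour pair and channel the
residual is $\omega\,\Delta \log I + (1 - \omega)\,\Delta \log S$, where
$\omega$ is 0 if the pooled (max-over-channel) gradient magnitude of
$\log I$ exceeds the threshold $t$ and 100 otherwise. Below threshold
this drives $\Delta \log S \approx \frac{100}{99}\Delta\log I$ — smooth
variation is attributed to shading; above threshold it drives
$\Delta \log S \to 0$ — sharp edges go to reflectance. The threshold $t$
defaults to 0.1 log units (≈ 10% intensity contrast), a standard
shading/albedo boundary for natural images; it is exposed in
`decomposition_config()`.

**Scale term.** $b(I)\,\log S = 0$ where $b(I)$ flags pixels at least as
bright as 95% of the brightest pixel (brightness = max over channels),
evaluated within the ROI so that background pixels cannot anchor the
scale. This pins shading near 1 at the brightest pixels and removes the
global multiplicative ambiguity. A consequence worth knowing: a *global*
intensity rescaling of the image leaves $S$ unchanged and is absorbed
entirely by $R$.

**Texture term.** Locations with correlated local texture are assumed to
share reflectance, adding rows $\log R_p = \log R_q$ (i.e.
$\Delta \log S = \Delta \log I$) across k-nearest-neighbour patch links.
The construction is deliberately conservative, because a wrong link
forces shading to absorb an albedo difference:

* candidates sit on a stride-2 grid with the whole (default 5×5) patch
  inside the ROI, subsampled to at most 1500 under `rng_seed`;
* a patch is *textured* only if ≥ 30% of its pixels carry log-gradients
  above $t$. This is the load-bearing gate: a smooth shading ramp has
  variance but no edges, and an isolated contour between two flat
  patches has edges only along a thin line; mean-subtracted, normalized
  correlation cannot distinguish either from true repeated structure,
  and both would otherwise create catastrophic links (we measured the
  recovered/true log-shading correlation on a Mondrian-times-smooth-
  shading scene collapse from 0.999 to −0.17 without the gate);
* linked patches must have similar contrast (sd ratio ≤ 1.25), since
  normalization also discards edge strength;
* links closer than one patch side are discarded (overlap correlates
  trivially), each candidate links to at most `texture_knn = 4` partners
  with correlation ≥ 0.9, and ties are broken by candidate order.

An empty pair set is legal and simply disables the term.

# Stage 2: light and normals

**Light direction.** The planar azimuth is the dominant orientation of
the shading gradient — the principal eigenvector of the structure tensor
$\sum \nabla S\, \nabla S^\top$ over the ROI. Orientation leaves a 180°
ambiguity that shading alone cannot resolve (the classic convex/concave
flip). The package's convention targets its subjects — predominantly
flat sheets (wings, leaves) whose localized relief slopes *away* from
the light, so the lit flat expanse is bright and the relief dark: the
light is placed *opposite* the mean shading gradient. For a fully convex
blob the opposite convention would be right; with it, a curled sheet
reconstructs inverted (we measured end-to-end height correlation −0.95
instead of +0.95). Light elevation is fixed at 45°, the compromise
between a vertical light (no directional information) and a grazing one
(many unlit pixels); the tilt this induces is removed by plane
detrending in stage 3.

**Normal estimation.** With $D$ known, the stacked system over the three
per-pixel normal components is:

* data rows $\langle D, N\rangle = S$ (with $S$ pre-divided by its
  inside-ROI maximum when that exceeds 1 — values brighter than any
  Lambertian surface then simply carry residual);
* smoothness rows $\nabla N = 0$ between inside-ROI 4-neighbours;
* edge rows $\Theta(\lVert\nabla R\rVert - c)\,\langle \mathrm{Rot}_{90}
  \nabla R,\, N_{xy}\rangle = 0$: where the log-reflectance gradient
  magnitude exceeds $c$, the planar normal component is forced
  perpendicular to the contour. $c$ defaults to the 90th percentile of
  the *nonzero* gradient magnitudes — on piecewise-constant reflectance
  most gradients are exactly zero and a plain percentile would collapse
  to 0, which under a naive fallback disables the constraint exactly
  where strong edges exist;
* a weak fronto-parallel prior $\varepsilon\, N_{xy} = 0$ with
  $\varepsilon^2 = 0.01$.

The prior deserves its own paragraph. Without it the system is rank
deficient wherever shading is constant: any constant vector on the cone
$\{N : \langle D, N\rangle = S\}$ has identical residual, and a Krylov
solver would return the minimum-norm member $N \propto D$ — every flat
region would tilt toward the light. The prior selects the z-maximal cone
member instead, so a uniformly lit flat sheet recovers exactly
$(0, 0, 1)$, and it makes the sparse solution agree with a dense
reference solve on any instance. Solved vectors are renormalized to unit
length with $N_z$ clamped to $10^{-3}$ first, guaranteeing front-facing
normals and finite height gradients.

## What this linear system can and cannot recover

The quadratic energy has an instructive exact structure. Writing
$N = S\,D + T$ with $\langle D, T\rangle \approx 0$, the data rows fix
the $D$-component, smoothness penalizes $\nabla T$, and the prior pulls
the planar part of $T$ to a constant. The minimizer is therefore
approximately $N \approx S\,D + \text{const}$: *tilt varies only along
the light azimuth, modulated by shading*. Relief whose gradient is
aligned with the light (a curling sheet lit across the curl) is
recovered well; tilt *across* the light direction is simply not present
in the constraint set.

Two consequences are verified by the test suite rather than hidden:

* A hemisphere has radially varying tilt, so the median angular error of
  recovered normals plateaus around 33° on a 64×64 cap (small near the
  apex, large at the rim) no matter how the weights are tuned — the
  corresponding acceptance test expects < 15° and is deliberately left
  failing, because the limitation is structural, identical for the
  iterative and the exact direct solver, and not fixable within the
  stated constraint set.
* A tilted plane under uniform reflectance yields *constant* shading,
  which constrains the normal only to a cone; the recovered field is the
  prior-selected $(0,0,1)$. The tilt is unidentifiable in principle —
  which is harmless downstream, because plane detrending removes any
  constant tilt anyway.

# Stage 3: height integration and detrending

Forward-difference equations $H(x{+}1,y) - H(x,y) = g_x$ and
$H(x,y{+}1) - H(x,y) = g_y$ over inside-ROI neighbour pairs are solved
in least squares (Poisson-style) with one row pinning the anchor — the
first ROI-border pixel in row-major scan order — to 0. Least squares is
chosen over single-path integration deliberately: gradient fields from
illusory patterns are *inconsistent* (nonzero discrete curl), and the
least-squares solution is the smoothest compromise surface, with the
residual norm reported as a diagnostic. On a curl-free field over a
simply connected ROI the solution is exact (verified against a
breadth-first path-integration oracle to 10⁻⁶). Finally the OLS plane
over inside-ROI pixels is subtracted (idempotent), compensating the
arbitrary 45° elevation; display encoding min-max normalizes to 0–255,
with a constant field mapping to mid-gray 128 by convention.

# The synthetic world, and what a green test establishes

The generator (`make_height_field()`, `make_reflectance()`,
`render_scene()`) emulates directionally lit Lambertian surfaces:
height fields (flat; tilted plane; hemisphere; `curled_sheet`, a smooth
leaf-curl along one edge; `gabor_bumps`, bark-like seeded bumps) crossed
with reflectance patterns (uniform; Mondrian patches on a Voronoi
tessellation with geometric albedo levels in [0.1, 0.9], giving every
patch pair log-contrast ≥ log(9)/5 ≈ 0.44 > t; spots; stripes; a
concentric eyespot), values confined to [0.05, 1] for log-space safety.
Rendering inverts the pipeline's model exactly:
$N$ from forward differences of $H$, $S = \max(0, \langle D, N\rangle) +
\text{ambient}$, $I = \mathrm{clip}(R \times S)$. The ambient term
(default 0.1) keeps attached shadows off the log floor; the pure model
has none, so it can be set to 0. Optional i.i.d. Gaussian pixel noise is
seeded and off by default so stage tolerances stay tight. Every scene
asserts at construction that its normals round-trip to its height
gradient (≤ 10⁻¹⁰) and that the rendering equation holds exactly.

What the synthetics do *not* emulate: soft (anti-aliased) pattern edges,
interreflections, cast shadows, specularity, sensor noise and optics,
and multi-source illumination. Two honesty notes follow. First, a green
decomposition test on hard-edged Mondrians shows the Retinex machinery
separates *clean* edges; real wing patterns have gradient-magnitude
distributions that straddle $t$. Second, on these same clean synthetics
the decomposition is nearly perfect, so the false-depth artifact the
pipeline is designed to reveal (a flat high-contrast pattern
reconstructed with relief) is orders of magnitude weaker than on
photographs, where decomposition leakage at soft edges drives it; the
corresponding acceptance test therefore asserts a strict variance
ordering between the flat-Mondrian and flat-uniform reconstructions,
not an effect size.

# Numerical choices

* **Solver**: CGLS on the normal equations with Jacobi column scaling;
  relative tolerance 10⁻⁸ (10⁻¹⁰ for height integration), cap 10,000
  iterations; non-convergence raises a typed condition carrying the
  residual. The 128×128 acceptance scenes converge in ≈ 300–1300
  iterations, a few seconds each on one CPU. A sparse-Cholesky
  `"direct"` mode exists for cross-checks.
* **Gradients**: forward differences with replicate boundaries; pairs
  straddling the ROI boundary contribute no rows.
* **Ties and degeneracies**: structure-tensor sign broken as described
  (exactly zero mean projection selects azimuth in $[0, \pi)$); constant
  shading yields a degenerate-light warning and azimuth 0; masks with
  several 4-connected components keep the largest with a warning;
  min = max height displays as uniform 128.
* **Config files**: JSON via `jsonlite` (round-trip tested) rather than
  TOML — no TOML parser is available in the supported dependency set.
* **I/O**: PNG (8/16-bit) and baseline uncompressed TIFF (8/16-bit
  integer, 32-bit float) are implemented in pure R; PNG's DEFLATE is
  delegated to base R's zlib bindings, CRC32 and scanline filters are
  implemented directly, and both codecs are validated round-trip and, at
  development time, against an independent reader. JPEG is refused with
  a clear message. Inputs are assumed sRGB-encoded and linearized by
  default (`linearize_srgb = FALSE` for data already in linear units,
  e.g. the generator's renders, whose scene metadata records this).

# Known limitations

* Tilt across the light azimuth is unrecoverable (see above); recovered
  relief on isotropic shapes is bas-relief-like along the light.
* The azimuth sign convention assumes flat-sheet scenes; fully convex
  objects may reconstruct inverted. The convention is a config-free
  deterministic rule, so either sign is consistent across a study.
* The texture term is a k-NN patch-correlation surrogate for non-local
  reflectance constraints; it is conservative by design and contributes
  nothing on texture-free images.
* Single distant light, no shadows or interreflections, quasi-Lambertian
  surfaces; output is relative depth only.
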