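---
title: "Model, inversion and phantom design in mwii"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, inversion and phantom design in mwii}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the physical model behind `mwii`, the numerical
choices made in its implementation, and the deliberate limits of the
phantom generators used to validate it.

## 1. Forward model

The instrument modelled here illuminates a weakly scattering sample on a
reflective substrate with four narrow-band channels (447, 525, 593 and
692 nm) and records the interference between the field reflected by the
substrate (reference beam) and the field scattered by the sample. Under
the first-order (single-scattering) Born approximation, the camera
intensity at wavelength $\lambda$ is

$$ I = |U_1 + U_2|^2 - |U_2|^2, \qquad
   U_1 = T\,U, \qquad
   U_2 = T\,U \cdot \frac{2\pi n_1}{\lambda}\,S, $$

where $U$ is the illumination amplitude, $T = 4 n_0 n_1 /
\big((n_0+n_1)(n_1+n_2)\big)$ collects the Fresnel transmissions through
the medium/sample and sample/substrate interfaces, and $S$ is the
scattering integral of the axial contrast profile $\delta n(z)$,

$$ S = \int \delta n(z)\, \sin\!\big(k\,(z + \Delta z)\big)\, dz, \qquad
   k = \frac{4\pi n_1}{\lambda}. $$

Normalizing by the background intensity $|U_1|^2$ cancels both $T$ and
$U$; for a uniform slab $\delta n(z) = \Delta n$ on $[a, b]$ the integral
is elementary and the normalized intensity reduces to the closed form
used throughout the package:

$$ \hat I(\lambda) = 1 + \Delta n\,\big[\cos(k\,(a + \Delta z)) -
   \cos(k\,(b + \Delta z))\big]. $$

Three consequences drive the design:

* $\hat I$ is **linear in the contrast** $\Delta n$ (tested explicitly),
  so the model is only valid while $|\Delta n \cdot (\ldots)| \ll 1$;
  `coherent_intensity()` warns when the interference term leaves
  $[-0.5, 0.5]$.
* $\hat I$ is **periodic in $\Delta z$** with period $\lambda/(2 n_1)$
  (about 164 nm at 447 nm in water). A single wavelength therefore cannot
  determine the axial offset; the four channels have incommensurate
  periods and make the joint fit unique over the search window. The test
  suite demonstrates both halves of this statement directly.
* The normalization makes the measurement **independent of illumination
  and Fresnel factors**, which is why phantoms only need to store the
  background level per channel.

General profiles are evaluated by trapezoidal quadrature. The axial grid
must resolve the fastest oscillation: `scattering_integral()` refuses
spacings above one twentieth of the shortest period rather than silently
aliasing. Against the closed slab form the quadrature agrees to better
than $10^{-6}$ relative, which bounds the tolerances used in tests that
mix the two routes.

## 2. Ergodic inversion

Per pixel, the inverse problem is two-dimensional: find $(\Delta n,
\Delta z)$ minimizing the summed squared misfit over the four channels.
The package solves it by exhaustive search over a regular grid — the
default is $\Delta n \in [-0.3, 0.3]$ in steps of $10^{-4}$ and $\Delta z
\in [-300, 300]$ nm in steps of $0.1$ nm, i.e. $6001 \times 6001 \approx
3.6\times10^7$ candidates per pixel. These problem sizes are this
package's own defaults, chosen so a full-grid pixel inversion runs in
well under a second of compiled code while the contrast step ($10^{-4}$,
about $1.4\times10^{-4}$ RI units) sits below the RI jitter of realistic
bead standards.

Numerical conventions that the tests rely on:

* **Exact grid values.** When a grid origin is an integer multiple of the
  step, axis values are computed as `(i0 + i) * step`, so a grid that
  should contain $0$ contains it exactly and a pure-background pixel
  returns $\Delta n = 0$ bit-exactly, not $10^{-17}$.
* **Deterministic tie-breaks.** Ties in the misfit resolve by smaller
  $|\Delta z|$, then smaller $|\Delta n|$, then lexicographically. A
  pixel whose best contrast is $0$ (every $\Delta z$ fits equally) is
  flagged `degenerate` and reports $\Delta z = 0$.
* **Compiled = literal.** The Rcpp scan reduces the inner $\Delta n$ loop
  to a quadratic minimization per $\Delta z$, but accumulates in an order
  chosen to be *bit-identical* to a literal double loop in R; the test
  suite asserts `expect_identical` against such an oracle, including on
  noisy and degenerate inputs.
* **Quantization couples the axes.** For off-grid truths, rounding
  $\Delta z$ shifts the best-fitting contrast by a few contrast steps, and
  at very low contrast the $\Delta z$ axis is poorly conditioned. The
  guaranteed property is therefore "within a few steps at workable
  contrast", with a representative well-conditioned case recovered within
  one step per axis; what is always true is that the returned residual
  cannot exceed the misfit of the rounded truth.

### Wafer mode

For uniform layers the search runs over (thickness $t$, $\Delta z$) with
$a = \Delta z$, $b = t + \Delta z$ and the layer contrast fixed by the
oxide/substrate stack ($n_0 = 1$, $n_1 = 1.45$, $n_2 = 3.88$ by default).
The model obeys an exact symmetry $C(t, \Delta z) = C(t + 2\Delta z,
-\Delta z)$, so two distinct parameter pairs can tie to full precision;
the tie-break prefers smaller $|\Delta z|$, then smaller $t$. In floating
point the two evaluations agree bitwise only when the arguments are
exact; otherwise they differ at the $10^{-15}$ level, which is why the
compiled scan and its R oracle must use the *same* cosine-addition
arithmetic — a different association order flips exact ties.

On the full default grid, noise-free wafers at 285 and 500 nm are
recovered exactly (the residual is $\sim 10^{-32}$, not $0$, because
`fl(1 + x) - 1` re-rounds the interference term).

## 3. Dry mass

Recovered RI converts to dry-mass density by the Gladstone–Dale relation
$\rho = (n - n_w)/\alpha$ with water $n_w = 1.333$ and a specific
refractive increment $\alpha = 0.18$ mL/g, the standard value for
cellular protein. With pixel pitch in µm and an effective column height
in µm, one µm³ at 1 g/mL is exactly 1 pg, so mass integrals are plain
sums — additive over disjoint regions by construction, which the
nucleus/cytoplasm partition tests exploit (`nuclear + cytoplasmic =
total` holds exactly, not approximately).

The N/C ratio follows the *cytoplasmic* convention, nuclear mass over
cytoplasmic (non-nuclear) mass; `nc_ratio()` also implements the
total-mass convention for comparison. Nuclear density heterogeneity is
the population (divide-by-$n$) standard deviation of the density within
the nucleus mask.

## 4. Segmentation

Cell support comes from the contrast magnitude exceeding the per-field
noise floor, with small components removed and interior holes filled —
deliberately *without* erosion, which would shave boundary pixels and
bias total mass low. The nucleus starts from a strict RI $> 1.42$
threshold, is cleaned by disk erosion plus minimum-size filtering, and is
then refined against the Canny edges of the RI map: the detected contour
is closed by dilate–fill–erode with a small bridge radius (tolerant of
short gaps in the ring), and whole interior components touching the
dilated mask are kept. The component-wise rescue matters because
chromatin is textured: sub-threshold interior dropouts can sit farther
from the cleaned mask than any sensible dilation radius, yet they are
unambiguously nuclear once the boundary contour is closed.

## 5. Phantoms and their fidelity limits

All validation runs on synthetic phantoms with exact ground truth. Their
deliberate simplifications are worth stating:

* **Columnar geometry.** Cell and sphere phantoms render each pixel as an
  independent vertical slab of uniform contrast — there is no lateral
  diffraction, no point-spread function, and no partial-volume mixing at
  boundaries. This matches the per-pixel forward model exactly, which is
  the point: phantom error isolates the inversion and mass arithmetic
  from optical effects the model does not claim to capture.
* **No defocus envelope.** Axial scans shift $\Delta z$ only; real
  systems also lose interference contrast away from focus. Focus
  selection therefore keys on the residual map rather than contrast
  amplitude.
* **Dual-route mass.** Cell phantoms compute truth masses both from the
  continuous geometry and from the voxelized RI map; the two agree within
  a few percent at the default 64×64 sampling and converge as the grid is
  refined, which calibrates the tolerances used on recovered masses.
* **Scripted series.** The osmotic-shock series rescales the cell
  footprint while renormalizing density so total mass is conserved *by
  construction* (to $\sim 10^{-16}$), giving a true null against which
  pipeline-induced mass drift is measured. Growth series are piecewise
  linear with known breakpoint and per-phase rates.
* **Noise.** Additive Gaussian noise on the raw intensities is available
  for robustness checks; default phantoms are noise-free so that failures
  indicate logic errors, not statistics.

## 6. Reproducing the validation measurements

```{r}
# from the package source directory, against the installed package:
#   Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The script measures wafer thickness round trips at 285 and 500 nm,
the worst-case recovered-RI spread across three microsphere materials,
and the worst-case total-mass drift over the osmotic series, and writes
the values with their sample sizes as JSON. Every random quantity is
derived from `--seed`.
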