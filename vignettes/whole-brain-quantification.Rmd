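---
title: "Whole-brain cell quantification: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain cell quantification: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`clearcount` quantifies fluorescent cells in cleared whole-brain light-sheet
volumes. This vignette explains the statistical and geometric models behind
each stage, why the defaults are what they are, what the synthetic-data
generator does and does not emulate, and the numerical choices that a
maintainer or careful user should know about.

## 1. Image restoration

### Background model

Autofluorescence in cleared tissue varies smoothly on a length scale much
larger than a cell. Under that premise the background is estimated by
convolving the raw volume $I$ with a discrete Gaussian,

$$ I_\sigma(x,y,z) \;=\; \frac{1}{B}\sum_{i,j,k=-w}^{w}
   I(x{+}i, y{+}j, z{+}k)\, e^{-(i^2+j^2+k^2)/2\sigma^2}, $$

where $B$ normalizes the weights to sum to 1 over the cubic support of side
$2w+1$, and the image is flattened by division, $I_n = I / I_\sigma$.
Background voxels land near 1, structures land well above 1, and any global
gain (bit depth, exposure) cancels — which is why integer camera counts are
used as-is, with no rescaling on input.

Assumptions that matter:

* **Scale separation.** $\sigma$ must exceed the typical structure radius
  (otherwise structures are absorbed into their own background estimate)
  and stay below the scale of genuine background variation. The default
  $\sigma = 10$ voxels sits between cell radii of 2–5 voxels and background
  undulations of several tens of voxels.
* **Multiplicative foreground.** Division normalization treats foreground
  as a relative elevation over local background; the synthetic generator
  renders scenes the same way, so "amplitude 5" means 5× the local
  background regardless of where the cell sits.

### Parameters

| parameter | default | units | rationale |
| --- | --- | --- | --- |
| `sigma_bg` | 10 | voxels | between cell radius and background scale |
| `w` | `ceiling(3*sigma_bg)` = 30 | voxels | > 99.7% of Gaussian mass per axis; the kernel is renormalized over the cube so the truncation never biases a flat region |
| `sigma_denoise` | 1 | voxels | suppresses single-voxel digitization noise while blurring 4–8-voxel cells only mildly |
| `padding` | `"reflect"` | — | preserves local intensity statistics at volume faces so $I_n \approx 1$ at borders; `"periodic"` and `"replicate"` available |

The exponent scale of the kernel and the σ quoted with it are one and the
same parameter here; no second scale is ever introduced. The convolution is
computed separably (the cube-normalized kernel factorizes exactly, since
$B = (\sum_i g_i)^3$), and the test suite holds the separable path to the
brute-force cubic sum within $10^{-10}$.

### Numerical choices

* **Precision.** All computation is double precision; files are float32.
  Division amplifies quantization error, so quantizing before the division
  is avoided.
* **Division floor.** Where $I_\sigma \le 10^{-12}\,\overline{I}$ the output
  is set to 1 (pure background) instead of forming 0/0.
* **Boundary bias.** Any padding rule biases $I_\sigma$ where the true
  background has a steep gradient *into a face*; with reflect padding the
  error is proportional to the normal derivative at the face. In real
  acquisitions the volume faces are outside the tissue and dark, so this
  mostly doesn't matter; on synthetic data the generator's background field
  is built from a cosine basis (see §5) whose natural continuation is its
  mirror image, which makes the reflect assumption exact rather than
  approximate.

## 2. Detection

The negative Laplacian $I_{\mathrm{LoG}} = -\nabla^2 I_d$, by central
finite differences, is positive inside compact bright structures, negative
in the surrounding moat, and zero on the separating edge; for a Gaussian
blob of scale $s$ the zero crossing is the sphere $r = s\sqrt{3}$ (the test
suite checks the shell mean and the interior/exterior signs on a rendered
blob). Candidates are connected components of $I_{\mathrm{LoG}} > \alpha$.

Choices a user may want to revisit:

* **α = 10⁻³.** The threshold is dimensionless on the normalized intensity
  scale. For a unit-contrast blob of scale 2 the LoG peak is ≈ 0.75, so
  10⁻³ is far below any real cell's response, yet above the float-level
  response of genuinely flat fields. Background *noise* still crosses α
  liberally — by design; those components are cheap to carry and are
  removed by the intensity filter, because their maximum denoised intensity
  stays near 1 while true cells exceed the floor `i_d_min = 1.1`
  comfortably (a contrast-4 cell retains $I_d \gtrsim 3$ after denoising).
* **Connectivity 26, `min_voxels` 2.** 26-connectivity is the least
  fragmenting rule for convex blob interiors. Single-voxel components are
  dropped: their gyration tensor is identically zero, so they carry no
  shape information.
* **Finite differences in voxel units** (`h = 1`), matching a
  single-resolution pipeline; a physical-spacing mode divides each axis
  term by its spacing squared for anisotropic work.
* **Boundary handling.** $I_{\mathrm{LoG}}$ on a face replicates the
  nearest interior value (faces are overwritten axis by axis — z, then y,
  then x — so corners inherit deterministic values), which cannot create a
  spurious threshold crossing at the volume boundary.
* **Touching cells** are reported as single objects (cell conglomerates are
  legitimate members of the "cell" class); no watershed splitting is
  attempted.

Object ids are assigned in lexicographic order of each component's smallest
$(z, y, x)$ voxel, so outputs are stable across runs and platforms.

## 3. Morphology and classification

Shape descriptors use the standard polymer-physics definitions on the
gyration tensor $S = \frac{1}{N}\sum_p (r_p-\bar r)(r_p-\bar r)^{\top}$ of
the object's voxel centers (unweighted; intensity enters the feature vector
separately): sorted eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$,
$R_g^2 = \sum\lambda_i$, asphericity $b$, acylindricity $c$, and
$\kappa^2 = (b^2 + \tfrac34 c^2)/R_g^4 \in [0,1]$ — 0 for a sphere, 1 for
an ideal rod. The volume-to-$R_g$-sphere ratio is taken literally as
$N_{\mathrm{vox}} / (\tfrac{4\pi}{3} R_g^3)$; note a continuum solid ball
has $R_g^2 = \tfrac35 R^2$, so this ratio is $(5/3)^{3/2} \approx 2.15$ for
a perfect ball, not 1 — a constant offset the classifier absorbs.

The cell/non-cell discriminator is a random forest (100 trees, unlimited
depth, $\lfloor\sqrt{p}\rfloor$ features per split, fixed seed,
single-threaded so results are deterministic). Evaluation follows a
stratified 80%:20% split; because a single split is a noisy estimate, the
protocol repeats over $k$ derived seeds (default 10) and reports each
split's accuracy plus mean ± SD. Stratification is a deliberate deviation
from a plain random split: it protects small labeled sets from losing a
class entirely, and a `stratify = FALSE` flag restores the plain behavior.

## 4. Regional quantification

Classified cell voxels deposit their physical volume
($\prod$ spacing, e.g. $3.26 \times 3.26 \times 3\ \mu m^3$) into the
coarse voxel containing their center — 25 µm cubes by default, the Allen
Brain Atlas resolution. Whole-voxel assignment keeps conservation *exact*:
internally the map is an integer count grid scaled once, so
$\sum \text{cell volumes} = \sum \text{density map} = \sum \text{region
totals (incl. unassigned)}$ holds to the last bit of the shared factor.
Atlas registration is consumed, not computed: the label grid must be
congruent with the density grid (an external registration tool produces
it). Assignment is per-voxel by default — conserving volume when an object
straddles a region boundary — with a per-centroid mode for comparison.

Group summaries use the sample SD ($N-1$): group sizes in this kind of
study are small (2–8 brains), and a population SD would understate spread.
Single-sample groups are flagged and get `NA`, never a fabricated 0.
Region exclusion (e.g. a cerebellum dominated by Purkinje-cell
autofluorescence) is explicit, logged in the report's `excluded_regions`
attribute, and idempotent.

## 5. The synthetic-scene generator

`synthetic_scene()` + `render_scene()` produce volumes with exact ground
truth:

* **Cells** are isotropic Gaussian blobs, amplitude × $e^{-r^2/2s^2}$ with
  $s$ = radius/2 — matching the detector's model of closed surfaces of
  local maxima, and giving an analytic LoG zero crossing to test against.
* **Vessels** are Gaussian-profile tubes along random gently-curved
  polylines (per-vessel fields take the max over segments so joints don't
  double-count).
* **Background** is `level × (1 + amplitude × u)` where `u` is a zero-mean,
  unit-variance smooth Gaussian random field synthesized from a random
  cosine series with spectral weights $e^{-L^2|k|^2/2}$ (length scale `L`,
  default 40 voxels ≫ cell radius). The cosine (Neumann) basis means the
  field approaches every face with zero systematic gradient, so background
  variation is a property of the scene interior rather than an edge
  artifact — the regime the restoration stage's premise describes.
* **Noise** is additive Gaussian, sd = 2% of base level by default.
  Camera digitization noise is modeled generically; Poisson shot noise is
  deliberately out of scope (at the intensities involved its effect on the
  chain is equivalent to a slightly inhomogeneous Gaussian sd).
* **Truth masks** use the half-peak isosurface of each structure's
  noiseless contribution — well defined and resolution independent; the
  truth table records per-structure class, center and volume.

Default conditions (a 128³ grid at 3 × 3.26 × 3.26 µm, 20 cells of radius
3–5 voxels at 4–8× contrast, 5 vessels at 3–6× contrast, 20% background
field, 2% noise) are what the package's end-to-end properties run under.
Rendering is bit-reproducible from the scene seed, and one global pipeline
seed fans out to every stochastic stage by a fixed derivation.

What passing on synthetic scenes does **not** show: robustness to optical
point-spread anisotropy, light-sheet striping, tile seams, depth-dependent
attenuation, or densely packed/touching cells — none of which the
generator emulates. Results on real acquisitions depend on those factors.

## 6. Validation semantics

Manual annotations have uncertain boundaries, so the metrics are
boundary-tolerant. For each connected truth component, the *core* is the
erosion by a ball of `core_radius` voxels (if erosion empties the
component, its deepest voxel — the one surviving the most erosion passes —
stands in). If the prediction intersects the core, the component's whole
volume is credited as true positive; otherwise none of it. True negatives
are counted over background excluding the dilation-by-`band_radius` band
around truth cells; `band_radius = 0` restores strict per-voxel TN.

A note on monotonicity, since the direction can surprise: under this
intersects-the-core rule, increasing `core_radius` *shrinks* the required
target and therefore can only lower the TP fraction (the test suite pins
this down as non-increasing). The tolerance knob that loosens the metric is
`band_radius`, which widens the ignored boundary band and raises the TN
fraction. A coverage-style rule ("the prediction must contain the core")
would invert the first direction; the intersection rule is the weakest
reading of "the core was correctly detected" and is what is implemented,
fully parameterized for sensitivity analysis. The z-convergence series
recomputes both metrics on the first $k$ slices for $k = 1..Z$; its last
entry equals the whole-volume metrics by construction.

## 7. Problem sizes and determinism

The shipped tests run the full chain on twelve 128³ scenes (two for
training the discriminator, ten held out), twenty 48³ background-only
scenes for the flatness property, and brute-force oracle comparisons on
≤ 9³ fixtures — sizes chosen so the whole suite exercises every stage in a
few minutes on one core while keeping every numeric claim at its stated
tolerance. All stochastic stages are seeded; rerunning any pipeline with
the same config and seed reproduces every output table bit-identically
(the tests compare file checksums).

## 8. Known limitations

* Registration to a reference atlas is out of scope; the atlas grid must
  already be congruent with the density grid.
* Touching cells are counted as one object; volumes are conserved but
  object counts undercount in dense regions.
* The TIFF dialect is plain multi-page grayscale (8/16-bit integer or
  float32); tiled/BigTIFF pyramids and OME-XML metadata beyond voxel
  spacing are not handled.
* The boundary-tolerant TP/TN numbers depend on `core_radius` /
  `band_radius`; report them alongside the radii used.
* Classifier quality is bounded by the labeled objects supplied; the
  synthetic truth-labeling shortcut in the demo stands in for manual
  labels and inherits none of their ambiguity.
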