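---
title: "Methods: mesh-based dental topographic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mesh-based dental topographic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentaltopo)
```

Dental topographic analysis characterizes a surface — classically a molar
crown cropped above the cervical margin and oriented with its occlusal
plane parallel to XY — with whole-surface, landmark-free descriptors.
This vignette is the package's methods account: the discrete models behind
each metric, the parameters that matter and their defaults, the numerical
choices, what the synthetic fixtures establish, and the known limits.

All three metrics operate on a `tri_mesh`: an `n x 3` vertex matrix (any
length unit; areas come out in that unit squared) and an `m x 3` face
matrix. Indices are 1-based in R and translated to the 0-based PLY/OFF
convention at file boundaries. Non-triangular faces are rejected at parse
time rather than fan-triangulated, because re-triangulation would silently
change every metric below.

## Dirichlet normal energy

DNE treats the surface's unit normal map as a function and measures its
Dirichlet energy — the aggregate "spreading" of normals relative to the
spreading of the surface itself. Per-face unit normals (normalized cross
products, orientation following winding) are averaged, unweighted, into
vertex normals. For a triangle with edge vectors $u = p_1 - p_0$,
$v = p_2 - p_0$ and normal-map differences $n_u = n_1 - n_0$,
$n_v = n_2 - n_0$,

$$e(p) = \operatorname{tr}(G^{-1}H), \qquad
G = \begin{pmatrix}\langle u,u\rangle & \langle u,v\rangle\\
\langle u,v\rangle & \langle v,v\rangle\end{pmatrix}, \quad
H = \begin{pmatrix}\langle n_u,n_u\rangle & \langle n_u,n_v\rangle\\
\langle n_u,n_v\rangle & \langle n_v,n_v\rangle\end{pmatrix},$$

and total DNE is $\sum_p e(p)\,\mathrm{area}(p)$ over included faces. $G$
is the symmetric Gram matrix of the edge basis; because $e(p)$ is a trace
of a basis-change-invariant product, it does not depend on which two edges
are chosen, which the suite verifies under cyclic vertex reordering. In
the continuum limit DNE equals $\int (k_1^2 + k_2^2)\,dA$, giving the
$8\pi$ sphere benchmark the tests and acceptance script use. The measure
is dimensionless and exactly invariant to rigid motion and uniform scale
(density scales as $s^{-2}$, area as $s^2$).

Vertex-normal averaging is unweighted because the discrete construction
averages directions, not fluxes; an area-weighted option exists for
compatibility with older implementations but is off by default.

**Exclusion rules.** Faces are dropped in a fixed order, each face keeping
the first reason that applied:

1. *degenerate* — area below $10^{-12}$ (squared units), or a vertex whose
   incident normals cancel to zero, or singular $G$;
2. *boundary* — faces owning an edge shared by no other face (the rim of
   the inferior hole left by crown cropping); their vertices lack a full
   normal stencil, so their energies are biased;
3. *condition* — $\mathrm{cond}(G) = \sigma_{\max}/\sigma_{\min}$ above a
   threshold (default $10^5$: slivers whose energy responds unstably to
   vertex perturbations; no canonical published value exists, and $10^5$
   keeps well-shaped faces while catching near-singular ones);
4. *outlier* — energy (or energy density, selectable) above the 99.9th
   percentile of the distribution over faces surviving rules 1–3.
   Computing the percentile after the earlier filters stops boundary
   spikes from distorting it. The quantile uses the linear-interpolation
   definition (R type 7), stated here because quantile conventions differ.

An optional implicit-fairing pre-smooth (below) is off by default — a
smooth should be a deliberate preprocessing decision, not something a
metric forces — but is available for comparability with pipelines that
always smooth.

DNE on noisy scanned surfaces grows with mesh resolution (more faces
sample more noise bending), so comparative samples should be simplified
to a common face count; on noiseless analytic surfaces DNE instead
converges with refinement, and the suite checks both behaviors.

## Implicit fairing

`implicit_fair_smooth()` integrates Laplacian diffusion implicitly: each
iteration solves $(I - \lambda L)X' = X$ with $L$ the uniform "umbrella"
Laplacian $(LX)_i = \operatorname{mean}_{j \sim i} x_j - x_i$. Implicit
integration is unconditionally stable, so $\lambda$ is not step-limited;
the default $\lambda = 0.6$ matches the setting conventionally used when
preparing molar meshes, and the default of 10 iterations is a light
compatibility smooth (heavy preprocessing pipelines use on the order of
100). Uniform weights were chosen over cotangent weights for robustness
on irregular scan meshes, where obtuse triangles make cotangent weights
negative. A flat plane is a fixed point of the z-component; a noisy
sphere strictly loses DNE under smoothing (both tested).

## Relief index

RFI is `3da / 2da`: summed triangle area over the area of the XY-plane
silhouette. `2da` is measured by rasterization — the automated equivalent
of exporting an occlusal-view bitmap and counting pixels against a scale
bar: a grid with `resolution` pixels along the longest XY extent (default
1000), a pixel filled when its center lies inside any face's projection.
Stacked regions (undercuts, sheer walls) therefore count once toward
`2da` while contributing fully to `3da`. Pixel centers exactly on a
projected edge are counted inside via a sign-normalized inclusive test —
a deterministic tie rule. Discretization error is of order silhouette
perimeter × pixel size; on a convex silhouette the error shrinks with
resolution (verified at 250/500/1000), and at the default resolution is
well under the ~1–2% level that matters for comparative work. No fixed
published pixel resolution exists for this measurement, so resolution is
an explicit parameter with a convergence guarantee instead of a constant.

Orientation is the caller's responsibility: relief is meaningful relative
to the occlusal plane, and automatic re-orientation is known to interact
with high-crowned surfaces, so the package ships an explicit rotation
utility rather than guessing. All three published RFI forms (ratio, ×100,
ln) are always returned.

## Orientation patch count rotated

Complexity counts the surface's distinct "facets": faces are binned by
aspect — `atan2(n_y, n_x)` of the face normal, i.e. the compass direction
of its XY projection — into eight half-open 45° arcs with boundaries at
0°, 45°, …, 315° from +X. The arc width is canonical; the phase is not,
and is immaterial to the rotation-averaged result. Normals within
$10^{-8}$ of vertical in XY norm have no aspect and stay unbinned.
Downward-pointing normals are binned like any other face — handling
overhangs is precisely the advantage of computing OPCR on meshes rather
than on raster elevation models, which can store only one elevation per
XY cell. Patches are connected components of edge-adjacent same-bin
faces (edge adjacency, not vertex adjacency, which would leak patches
through single points), and OPC counts patches with at least
`min_patch_size` faces. The default of 5 follows established usage on
meshes simplified to ~10,000 faces and is always user-settable; OPC is
non-increasing in this parameter.

OPC is then evaluated at eight Z-rotations of 5.625° (total span 45°) and
averaged into OPCR. A 45° rotation permutes the eight bins cyclically, so
OPC at 45° equals OPC at 0° exactly — which makes the "does the series
start at 0° or 5.625°?" reading ambiguity moot, and gives the exact
45°-rotation invariance the suite asserts. Rotation is implemented as a
constant aspect offset, mathematically identical to rotating vertices and
re-deriving normals but cheaper; equality with literal mesh rotation is
tested end to end. A fine sphere yields OPC 8 at every rotation (one
patch per compass direction), the saturation benchmark used throughout.

## Synthetic fixtures

The generators exist so every metric has an analytic oracle without any
specimen download: planes (DNE 0, RFI 1, OPC 0; tilted: one patch,
cos-foreshortened projection), icospheres (closed manifolds, area
$\to 4\pi r^2$ from below, DNE $\to 8\pi$, OPCR 8), open hemispheres
(single boundary rim for the boundary rule, RFI $\to 2$), and Gaussian
cusp fields $h(x,y) = \sum_i h_i e^{-d_i^2/2\sigma_i^2}$ with exported
analytic height and gradient, whose relief a quadrature oracle
reproduces and whose complexity responds monotonically to cusp count.
Optional scanner-like noise is applied along vertex normals, seeded, and
bit-reproducible; the generator restores the caller's RNG state.

These fixtures emulate geometry, not data collection: they have no
scanner artifacts beyond isotropic Gaussian noise, no simplification or
cropping history, and no enamel-specific structure. Green tests establish
the algorithms' correctness and invariances, not field accuracy on any
particular scanned sample.

Problem sizes were chosen to keep every analytic check comfortably inside
its tolerance at interactive runtimes: subdivision-3/4 icospheres (1,280 /
5,120 faces) for complexity and bending, a subdivision-5 hemisphere
(10,176 faces — the scale of conventionally simplified molar meshes) at
raster resolution 1000 for relief, and grids of 31²–81² vertices for the
cusp fields.

## Statistical validation layer

The published comparison of mesh-based OPCR against elevation-grid OPCR
rests on 36 second mandibular molars from four cercopithecoid species
(*Cercocebus atys* n=7, *Cercopithecus mitis* n=10, *Colobus guereza*
n=10, *Theropithecus gelada* n=9). Those meshes are not distributed, and
neither is the per-specimen value table in a plain-text form. The package
therefore reconstructs a **synthetic, moment-matched** specimen table
(`synthetic_specimen_table()`): within each species, deterministic scores
with exact sample moments reproduce the published per-species means and
SDs of both treatments, with the within-species correlation between
treatments solved so the SD of their difference matches too. Every
statistic in the validation layer — one-way ANOVA, Tukey HSD
(Tukey–Kramer for these unbalanced groups, matching mainstream software),
and OLS of the treatment difference on each treatment — depends on the
sample only through exactly those moments, so all published test
statistics are recovered up to the rounding of the published summary
table (e.g. F = 5.489 vs 5.486 printed). Individual rows are *not* the
real specimens; only the moment structure is. `load_specimen_table()`
accepts a real per-specimen TSV in the same layout and always recomputes
the treatment difference rather than trusting a file column.

## Degenerate inputs and edge cases

Zero-area faces are flagged and excluded with a warning, never fatal to a
batch. A mesh whose faces are all excluded (e.g. a lone triangle, which
is entirely boundary) is an error naming the cause. A perfectly flat
horizontal mesh has OPC 0 with a warning (every normal is vertical) and a
zero-XY-extent mesh is a projection error. Batch processing isolates
per-file failures as `NA` rows (exit status 2 from the command-line
driver) and is byte-reproducible across runs.

## Known limitations

- DNE on noisy meshes is resolution-dependent by construction; only
  equal-face-count comparisons are meaningful.
- Rasterized `2da` is a biased (slightly inclusive) estimator at finite
  resolution; the bias is below the documented tolerance at the default
  resolution but not zero.
- The patch-count phase convention (bins anchored at +X) differs from
  compass-oriented raster implementations; OPCR's rotation averaging
  makes this immaterial, but single-rotation OPC values are not directly
  comparable across tools.
- The statistical layer's specimen table is synthetic (moment-matched);
  row-level quantities other than the moments it pins (e.g. medians,
  ranges) are not meaningful.
- Mesh repair, simplification, cropping and occlusal orientation are
  upstream responsibilities; only a rigid-rotation utility is provided.
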