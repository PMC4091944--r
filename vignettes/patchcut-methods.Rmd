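---
title: "Patch-graph continuous min-cut segmentation: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-graph continuous min-cut segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchcut)
```

## The problem

B-mode ultrasound images are corrupted by speckle: a granular interference
texture whose local variance grows with the local mean brightness.  Intensity
thresholds and parametric texture models transfer poorly between probes,
organs and gain settings.  `patchcut` instead represents the image as a graph
of intensity *patches* — each pixel is described by the small square
neighborhood around it — and segments by cutting this graph where patches stop
resembling each other, under a convex relaxation that makes the result
independent of the initialization.

The user supplies scribbles: at least one mark on the object, optionally
marks on the background.  These become hard constraints, and everything else
is decided by the energy.

## The image model

### Patch graph

Every pixel $i$ carries a patch $P_i$ of $(2r+1)^2$ intensities (default
$r = 1$, a $3\times3$ patch).  Pixels $i, j$ within a search window of radius
$R$ (default 5, an $11\times11$ window) are joined by an edge of weight

$$ w_{ij} = \exp\!\big(-d(P_i, P_j)/\sigma^2\big) \in (0, 1], $$

stored in a sparse symmetric matrix.  Patches at the image border are
completed by mirror reflection, which adds no artificial intensity jumps;
windows are clipped at the border so edges only connect real pixels.
Self-weights $w_{ii}=1$ are stored for convenience — they cancel in the
Laplacian and in every cut.

### Speckle-adapted patch distance

For fully-developed, log-compressed speckle the observed intensity is well
described by $v = u + \sqrt{u}\,\sigma_n\, n$ with $n$ standard normal: the
noise *variance is proportional to the mean*.  A plain squared difference
would therefore count bright tissue as "more different" than dark tissue at
equal underlying contrast.  The package uses a symmetrized chi-square
(Pearson-type) distance,

$$ d(p, q) = \frac{1}{N}\sum_{k=1}^{N} \frac{(p_k - q_k)^2}{\max((p_k+q_k)/2,\ \varepsilon)}, $$

which divides each squared difference by the local intensity.  It is
symmetric, nonnegative, zero only for identical patches, and
scale-equivariant ($d(\alpha p, \alpha q) = \alpha\, d(p,q)$), exactly
matching the variance-proportional-to-mean noise law.  An asymmetric variant
with denominator $q_k$ (non-local-means style) is available behind
`graph_config(symmetric = FALSE)`.

### Kernel bandwidth

$\sigma$ plays the role of the typical distance between same-tissue patches.
Intensities are normalized to the 0–255 range on load, and the default
$\sigma = 3$ is calibrated so that the median within-region weight on the
bundled disk phantom (speckle scale $\sigma_n = 1.5$) is about 0.6, while
weights across its 140-versus-60 boundary fall below $10^{-3}$.  Noisier
images want a larger $\sigma$, cleaner images a smaller one.

## The segmentation energy

A binary labeling $u \in \{0,1\}^n$ pays the weight of every edge it cuts;
that cut equals the Laplacian quadratic form $u^\top L u$ with $L = D - W$.
Because pure min cuts favor small sets and ragged boundaries, an isotropic
total-variation term on the pixel grid (forward differences, replicate
boundary) penalizes boundary length:

$$ E(u) = u^\top L u + \lambda\, \mathrm{TV}(u), \qquad
   u_i = 1 \text{ on object scribbles},\ u_i = 0 \text{ on background scribbles}. $$

The binary constraint makes this combinatorial, so it is relaxed to the box
$u \in [0,1]^n$.  The relaxed energy is convex: the minimizer is unique and
independent of the initial condition — an important usability property,
verified directly by the test suite (three very different initializations
produce masks agreeing to Dice $\ge 0.99$ on the bundled phantom).  The
final mask thresholds $u$ at 0.5, the symmetric midpoint of the box, with
scribbled pixels forced.

## The solver

`solve_cmc()` minimizes $E$ by augmented-Lagrangian splitting with three
auxiliary variables: $v$ duplicates $u$ for the TV coupling (penalty
$r_1$), $d$ duplicates $\nabla v$ (penalty $r_2$), and $w$ duplicates $u$
for the box-and-label constraint (penalty $r_1$ again).  Each outer
iteration solves four easy subproblems exactly and performs multiplier
ascent:

1. **Graph subproblem** $(2L + 2r_1 I)\,u = r_1(v - \mu_1) + r_1(w - \mu_3)$,
   a sparse SPD system solved by warm-started conjugate gradient (C++ inner
   loop) to relative residual $10^{-6}$.
2. **Field subproblem** $(r_1 I - r_2 \Delta)\,v = r_1(u + \mu_1) - r_2\,
   \mathrm{div}(d - \mu_2)$, a screened Poisson equation with Neumann
   (replicate) boundary, diagonalized exactly by the orthonormal DCT-II.
   Neumann is preferred over periodic FFT because images are not periodic.
   The divergence is the exact negative adjoint of the forward-difference
   gradient, which the tests verify to $10^{-10}$ — the discrete
   Euler–Lagrange identity depends on it.
3. **Gradient subproblem** $d = \mathrm{shrink}(\nabla v + \mu_2,\
   \lambda/r_2)$, the isotropic (vectorial) soft-thresholding; isotropic to
   match the isotropic TV choice.
4. **Constraint subproblem** $w = \Pi_{[0,1]}(u + \mu_3)$ with the scribbled
   pixels set to their labels — the exact proximal step of the constraint
   indicator.

An obvious shortcut — skipping $w$ and simply clipping the CG solution in
place, as interactive implementations often do — looks harmless but is not:
the clipped iteration is an *inexact* ADMM whose fixed point is a biased
point near, but not at, the constrained minimizer.  On 12-node problems
where the exact optimum is computable by enumeration, the clipped variant
settled a few percent *above* the best binary energy, violating the
feasible-set-inclusion bound that any true relaxed solution must satisfy.
Carrying the constraint on its own splitting variable restores exactness;
the tests verify the bound on twenty such problems.

Iterations stop when the relative change of the feasible iterate $w$ falls
below `outer_tol` *and* all RMS splitting residuals ($\|u - v\|$,
$\|\nabla v - d\|$, $\|u - w\|$, each over $\sqrt n$) fall below
`residual_tol`.  Everything is deterministic; identical inputs give
bit-identical masks.

### Numerical choices that mattered

* **Penalty scaling.**  With an $11\times11$ window the weighted degree of a
  pixel is of order $10^2$, so the operator $2L$ dwarfs a unit penalty and
  consensus between $u$ and $v$ develops extremely slowly — slowly enough
  that any iterate-change stopping rule triggers on a transient.  The
  default `r1 = r2 = NULL` therefore resolves to the mean weighted degree of
  the graph.  Penalties affect only the path taken, never the minimizer.
* **Over-relaxation.**  The update of $v$ uses
  $\hat u = 1.8\,u + (1 - 0.8)\,v$ (`relax = 1.8`), the standard ADMM
  acceleration; it roughly halves the iteration count on the bundled
  phantoms, most visibly from deliberately bad initializations.
* **Stopping tolerance.**  `outer_tol = 2e-4` is deliberately tighter than
  what a pleasing mask needs: from an all-ones initialization the iterates
  traverse a long slow transient, and a looser tolerance stops inside it.
  The default guarantees that all three initializations land on the same
  mask, at the price of roughly 900 outer iterations on the bundled
  $128\times128$ phantom instead of roughly 350.
* **Degenerate inputs.**  A fully-labeled image returns the labels verbatim
  in one iteration.  An empty foreground is a configuration error.  A
  perfectly circular mask gets orientation 0 by tie-break in the biometry
  module.

## The synthetic phantoms

`make_phantom()` draws a piecewise-constant tissue map (disk, ellipse, or a
bright ring) and corrupts it with the signal-dependent noise
$v = u + u^{1/2}\sigma_n\, n$, clipped at zero; the exponent is configurable
for sensitivity studies.  The speckle *grain* is controlled by Gaussian
filtering of the noise field, renormalized to unit variance so the
pointwise variance law is preserved; each tissue region receives its own
independent field, since distinct scatterer populations decorrelate across
a boundary.  The test suite verifies the variance law (empirical
$\mathrm{Var}(v)/u$ within 10% of $\sigma_n^2$ over $128^2$ pixels).

Three canonical fixtures:

* `default_phantom()` — $128\times128$ disk, radius 30 px, mean 140 on 60,
  white speckle $\sigma_n = 1.5$, seed 0, one object line scribble and one
  background line.  The recovery protocol segments 20 noise seeds of this
  phantom and asks Dice $\ge 0.95$ in at least 18.
* `texture_phantom()` — equal means (300) inside and outside the disk; the
  regions differ *only* in speckle (amplitude 8 versus 0.3, grain 10 px),
  and the labels follow the click-drag elliptic protocol (filled inner
  ellipse, outer contour).  This is the demonstration that the patch
  representation captures speckle statistics beyond mean intensity.
* `head_phantom()` — a bright elliptic band around a speckled interior; the
  enclosed ellipse is the ground truth whose circumference biometry must
  recover.

### What the texture phantom can and cannot show

Two design facts, found the hard way, shape `texture_phantom()` and are
worth recording.  First, if both regions share one spatially-smooth noise
field scaled by different amplitudes, the boundary is porous: wherever the
field passes near zero the two textures are locally identical and strong
edges bridge the boundary — hence the independent per-region fields.
Second, same-texture patches are only similar when the speckle field is
correlated across the pair's offset; with fine-grained speckle the
high-variance region is internally *dissimilar* at window-scale offsets, the
boundary weight valley disappears, and the min cut collapses around the
scribble no matter how the parameters are tuned.  The fixture therefore uses
a grain comparable to the search window and a strong variance contrast, and
the generous elliptic initialization a clinician would actually draw.
Passing this test shows the graph separates coarse-grained speckle of
different strength; it does *not* show that equal-mean tissues with fine,
uncorrelated speckle are separable — with this distance and window they are
not, consistent with the method's documented low discrimination between
tissues of close density.

Real ultrasound additionally has depth-dependent attenuation and gain,
anisotropic point-spread functions, shadowing and reverberation artifacts —
none of which the generator emulates.  Phantom results bound what clean
speckle permits; they do not certify clinical performance.

## Biometry

For fetal-head measurements the segmentation mask is summarized by image
moments: the centroid and the axis of elongation
$\theta = \tfrac12\,\mathrm{atan2}(2\mu_{11},\ \mu_{20}-\mu_{02})$ (degrees
in $(-90, 90]$, measured from the column axis, counter-clockwise in display
orientation; rows increase downward).  The occipito-frontal diameter is the
mask's chord through the centroid along $\theta$, the biparietal diameter
the chord at $\theta + 90^\circ$, both converted to millimetres through the
anisotropic pixel spacing, and the head circumference uses the
ellipse-perimeter approximation

$$ \mathrm{HC} = \tfrac{\pi}{2}\,(\mathrm{OFD} + \mathrm{BPD}), $$

with a configurable multiplier (`hc_coef`) for chart conventions such as
$1.62\,(\mathrm{BPD}+\mathrm{OFD})$.  Chords are sampled at quarter-pixel
steps; rasterization limits accuracy to about one pixel per diameter, which
the tests encode as $\pm1$ mm on a 60/40 px reference ellipse and 2% under
rotation.

## Problem sizes used by the checks

The test-suite and the acceptance script work at the scales the fixtures
define: operator oracles on $8\times8$ grids and graphs up to 50 nodes
(dense solves), exhaustive binary enumeration on 10–12 node graphs,
relaxation-tightness on twenty 12-pixel two-cluster problems, and the full
pipeline on the three $128\times128$ phantoms (20 noise seeds for the
recovery protocol, $3\times3$ scribble styles/users for the robustness
protocol).  These sizes make every oracle exact or exhaustive while keeping
a complete run in the minutes range.

## Known limitations

* Graph construction is quadratic in the window radius; $11\times11$ windows
  on images much beyond $512^2$ get slow and memory-heavy in this pure
  R/sparse-matrix implementation.
* One object at a time: the model is binary (object versus background).
* The relaxation is not guaranteed tight in general; on well-separated
  graphs the tests verify the thresholded mask attains the exhaustive
  minimum cut, but weakly-separated problems may round a genuinely
  fractional optimum.
* Biometry assumes a roughly convex, roughly elliptic mask; chords through
  the centroid of a crescent would not be meaningful diameters.
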