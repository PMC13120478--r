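---
title: "Functional-shape analysis of macular GCIPL thickness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-shape analysis of macular GCIPL thickness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model, its assumptions, the tunable parameters, what the synthetic
generator does and does not emulate, the numerical choices, and the known
limitations. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The problem

Multiple sclerosis thins the macular ganglion cell–inner plexiform layer
(GCIPL), and the thinning concentrates in a horseshoe-shaped annulus
around the fovea rather than spreading uniformly. Classifiers built on
ETDRS sector means (nine averages over a 6 mm disc) blur away exactly this
spatial structure, and they depend on an anatomical reference (the foveal
center). The functional-shape approach keeps the pointwise detail: each
eye is a pair $(X_i, f_i)$ of a triangulated patch of the inner limiting
membrane (ILM) surface and the GCIPL thickness signal on its vertices, and
all eyes are brought into spatial correspondence before comparison.

## From thickness maps to F-shapes

Inputs are per-eye GCIPL thickness maps and ILM elevation fields on a
common pixel lattice (µm values, isotropic pitch in mm; the default pitch
is a 6 mm scan width divided by the grid width). Left eyes are mirrored
about the vertical midline so every map is in right-eye convention
(nasal on +x). The analysis region is an annular frame between two
rectangles — a closed outer rectangle minus the open interior of an inner
rectangle around the fovea — chosen to cover the horseshoe while excluding
the foveal pit; both rectangle boundaries are retained, and the default
coordinates (outer x 65..395, y 75..360; inner x 205..275, y 200..250, as
0-based lattice indices) give 91,285 lattice points.

The frame is decimated to a triangular mesh: the outer rectangle is cut
into near-square cells of ideal side $s = 1/\sqrt{\text{fraction}}$
lattice units (one retained vertex per $s^2$ original points; $s = 5$ at
the default 4% subject density, $s \approx 4.7$ at the 4.5% template
density). Each axis is divided into `round(span/s)` equal ideal intervals
snapped to the nearest lattice integer, so every cell side is 4 or 5
lattice units at the default densities, and cells overlapping the inner
open interior are dropped whole — never clipped — keeping every face a
right triangle with axis-aligned legs in {4, 5}. Each cell splits along
its main (lower-left to upper-right) diagonal. Because the cuts depend
only on the frame and the fraction, all subjects share one connectivity by
construction. We chose equal-interval snapping over cutting at raw
multiples of $s$ from the low edge because the latter produces a
degenerate terminal cell (a 2-unit sliver at the template density on the
default frame) whenever the span is not close to a multiple of $s$.

Vertices carry x, y in lattice units and the subject's ILM elevation as z;
the subject's thickness at the vertex lattice point is the signal. Before
registration all coordinates are converted to a single unit (mm; z from µm
to mm, x and y via the pixel pitch) so that one kernel width applies to
all three axes.

## The atlas model

The cohort is registered to a mean template $(X_m, f_m)$ by minimizing

$$J = \gamma_f \|f_m\|^2_{L^2}
  + \sum_i \left[ H(X_m, p_i) + \gamma_\zeta \|\zeta_i\|^2_{L^2}
  + \gamma_w A(\tilde X_i, \tilde f_i; X_i, f_i)\right]$$

* $H(X, p) = p^\top K(X)\, p$ is the deformation energy of a kernel
  diffeomorphism with Gaussian kernel
  $K_{jk} = \exp(-\|x_j - x_k\|^2/\sigma_V^2)$, parameterized by initial
  momenta $p$ (one 3-vector per template vertex) and realized by geodesic
  shooting: explicit Euler integration of the Hamiltonian point system
  ($\dot x = K(x)p$, momenta co-evolved by the Hamiltonian gradient) in
  `shoot_steps` steps.
* $\zeta_i$ is the per-vertex signal increment; the registered F-shape is
  $\tilde X_i = \phi_{p_i}(X_m)$ carrying $\tilde f_i = f_m + \zeta_i$.
  Signals are pointwise thicknesses, so they are transported without
  Jacobian rescaling.
* $A$ is the functional-varifold dissimilarity
  $A(a,b) = \langle a,a\rangle - 2\langle a,b\rangle + \langle b,b\rangle$
  with
  $\langle a,b\rangle = \sum_{f \in a}\sum_{g \in b}
  e^{-\|c_f - c_g\|^2/\sigma_W^2}
  \left(\tfrac{n_f \cdot n_g}{|n_f||n_g|}\right)^2
  e^{-(\bar f_f - \bar f_g)^2/\sigma_{sig}^2} \, \text{area}_f\,\text{area}_g$
  over face pairs (centroid $c$, normal $n$, mean vertex signal $\bar f$).
  It needs no vertex correspondence, which is what allows template and
  subject meshes to have different densities.
* $\|v\|^2_{L^2} = \sum_j v_j^2 w_j$ with $w_j$ the vertex's one-third
  share of incident face area, so the penalties are surface integrals, not
  bare sums.

The dissimilarity form (Gaussian position × squared-cosine normal ×
Gaussian signal) and the initial-momentum energy are the standard
instantiation of functional-shape metamorphosis metrics; the squared
cosine makes the term orientation-free.

The atlas starts from a hypertemplate at the 4.5% density with zero
signal; its geometry is the pointwise mean ILM surface of the training
eyes, which is a neutral initial geometry consistent with "same ROI
geometry, zero thickness". The template is denser than the subjects (4.5%
vs 4%) so that registration has spare resolution to align detail.

## Optimization

All gradients are exact: the varifold term is differentiated analytically
with respect to face centroids, normals and signals and chained to
vertices, and the shooting map is differentiated by a hand-derived
reverse-mode adjoint of the Euler scheme. Both are verified against
central finite differences in the test suite (`test-kernels-shooting.R`,
`test-varifold.R`, `test-registration.R`). The pair loops (varifold sums
and shooting) are compiled (RcppArmadillo), with symmetric self-block
variants at half cost.

Minimization is block-coordinate descent: per subject a $\zeta$ update and
a $p$ update, then a template-signal update, then (optionally) a
template-geometry update. The momentum and geometry blocks propose a
safeguarded Barzilai–Borwein secant step along the raw gradient (clamped
to a multiplicative trust range of the last accepted step, because the
other blocks move the landscape between a block's visits and can make the
secant estimate arbitrary); the signal blocks ($\zeta$, $f_m$) instead
move along the normalized gradient direction by a multiplicatively
adapted step in µm — the varifold signal term is wide and shallow, and
the bolder normalized moves traverse it far faster than curvature-scaled
steps. Every proposal backtracks (halving, up to 40 times) until the
objective strictly decreases; a block whose proposals all fail leaves the
state unchanged. Acceptance-only updates
make every reported objective trace non-increasing by construction — a
property the tests assert on randomized inputs rather than trust. Because
a $\zeta$ or $f_m$ trial changes no geometry, its re-evaluation reuses the
cached geometric kernel blocks and recomputes only signal kernels (and
vice versa for $p$ trials), which is what makes the desk-scale atlas
affordable. Iteration stops when the objective decrease between
consecutive (outer) iterations falls below `tol` (absolute by default,
`1e-4`; a relative variant is available) or at the iteration cap.

First-step scales are per-block (`step_zeta`, `step_p`, `step_f`,
`step_x`): 20 µm for signal-like blocks, 0.01 for momenta, 0.02 mm for
geometry — the natural magnitudes of each parameter. They only seed the
first proposal; Barzilai–Borwein adapts from there.

Template-geometry updates are on by default at a tenth of the signal step
(the template's geometry is far better conditioned than its signal); the
desk-scale preset freezes geometry at the hypertemplate, trading a small
amount of geometric fidelity for a large amount of stability and time.
During a geometry step the area weights $w$ are treated as frozen in the
gradient (they are recomputed after acceptance); the backtracking
acceptance test uses the exact objective, so descent is never violated.

Degenerate (zero-area) faces are skipped in all varifold sums with a
warning; a momentum trial that changes the set of degenerate faces is
rejected outright. Geodesic shooting that produces non-finite states
raises an error, which backtracking treats as a rejection.

## Classification

Residuals $f_m - \tilde f_i$ on the template vertices form the feature
matrix. When the feature dimension exceeds the sample count (always, for
residuals) it is reduced by PCA on the mean-centered rows; the retained
dimension is the last component before the cumulative eigenvalue-ratio
curve flattens (marginal gain below 0.01), a reproducible proxy for
reading a scree plot; a fixed `k` can be forced. The sectoral baseline
uses the nine ETDRS sector means directly, with no PCA.

The SVM is selected by leave-one-out grid-search cross-validation: for
each candidate kernel/hyperparameter combination, N models are fit each
leaving one training eye out, the CV score is the fraction of held-out
eyes classified correctly, and the best score (ties to the earlier grid
entry) is refit on all N eyes. The default grid spans linear and RBF
kernels with $\gamma \in \{10^{-3},\dots,1\}$ and $C \in \{0.1,\dots,100\}$
log-spaced. Note one property of LOO worth knowing when interpreting null
experiments: under label permutation the LOO score is pessimistically
biased (the held-out eye's class is under-represented in its fold), so
chance-level data scores below 0.5 rather than at it; the suite tests the
absence of optimism, which is the property that protects model selection.

Metrics are the standard confusion ratios with MS as the positive class
(ACC, SEN, SPE, PREC, F1, FPR) plus the ROC curve obtained by sweeping the
SVM decision score and its trapezoidal AUC, which is invariant under
monotone score transformations. At test time each eye is registered to the
*frozen* template (only its own $p$, $\zeta$ optimized), its residual is
projected with the stored PCA, and the stored SVM predicts; part (c) never
mutates part (b)'s artifacts.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes:

* a deterministic healthy template with foveal-pit topography
  ($0.004 + r^2 e^{-r/0.5}$ in mm radius — near-zero center, annular peak
  at 1 mm, peripheral decay, ~35-fold dynamic range), rescaled to a 75.9 µm
  mean;
* MS thinning confined to a horseshoe: an annulus 0.5–2.5 mm with a 90°
  temporal gap, smooth 0.2 mm/10° tapers, with the multiplicative depth
  calibrated so the map mean drops to 62.9 µm;
* between-eye variability injected at the subject level — a scalar
  multiplier drawn so map means are Normal(class mean, class SD) with the
  published SDs (6.2/5.4 µm), because those SDs are across eyes, not
  pixels;
* a smooth random anatomical warp (Gaussian-filtered displacement field,
  default 0.1 mm RMS amplitude, 1.5 mm correlation length — the scale of
  plausible inter-eye foveal displacement) applied to both the thickness
  map and the ILM dome (300 µm height over the field), plus i.i.d. pixel
  noise (2 µm SD) clipped at zero;
* alternating right/left eye assignment, with left eyes stored mirrored.

What it does **not** emulate: OCT speckle, B-scan registration artifacts,
segmentation error, inter-eye correlation within a subject (eyes are
independent draws), or pathology that changes shape rather than scale
(focal wedge defects, asymmetric thinning). Passing tests on this cohort
therefore demonstrate that the pipeline recovers the structure it models —
group-mean separation under smooth anatomical variability — not that it
would classify any clinical population at the reported operating point.

## Problem sizes and study conditions

The full-resolution geometry (461-px lattice, ~3,800-vertex subject
meshes) is available through `study_config()`. The package's own desk
preset (`desk_study_config()`) — used by the test suite and the
acceptance script — scales the lattice to 150 px, which scales the
annular frame proportionally and yields ~450-vertex subject meshes and
~480-vertex templates at the same 4%/4.5% densities, with 5 shooting
steps, 4 atlas outer iterations, 5 registration iterations per eye with
the momentum block visited every third iteration,
frozen template geometry, and a 60 µm signal-kernel width (the signal
kernel must see a zero-signal hypertemplate against ~70 µm subjects, so a
width of the same order as the signal range keeps the early gradient
alive). Cohort sizes are the study's: 37 healthy and 35 MS eyes, 28+26
training, 9+9 test. The residual-vs-raw significance comparison runs at a
100-px lattice with 12+12 eyes and 0.15 mm jitter; deformation-recovery
experiments use an 8×8 heightfield with attachment-dominant weighting
($\gamma_w = 50$), since recovering a known deformation is a
data-attachment problem, not a regularized-estimation problem.

## Defaults worth knowing

| parameter | default | unit | why |
|---|---|---|---|
| `gamma_f` | 1e-4 | – | weak template-signal shrinkage; the template should follow the data |
| `gamma_zeta` | 1e-2 | – | mild increment penalty; large enough to keep residuals identified |
| `gamma_w` | 1 | – | attachment weight; raise for recovery-style experiments |
| `sigma_V` | 1.5 | mm | deformation kernel: smooth, macula-scale warps |
| `sigma_W` | 0.5 | mm | varifold position kernel: local geometry matching |
| `sigma_sig` | 15 (60 in desk preset) | µm | signal kernel width |
| `shoot_steps` | 10 (5 desk) | – | Euler steps of geodesic shooting |
| `tol` | 1e-4 | objective units | absolute stop on the objective decrease |
| PCA gain threshold | 0.01 | – | scree flattening rule |

All are configuration, none are fitted; the weights were set so the three
objective terms have the same order of magnitude on the default synthetic
cohort.

## Known limitations

* Explicit Euler shooting is first-order; very large momenta can need
  smaller steps (the error path reports divergence rather than silently
  continuing).
* The objective is non-convex; block descent finds a local minimum that
  depends on the update order (which is fixed, so runs are deterministic).
* The varifold sums are quadratic in face count; full-resolution cohort
  atlases are compute-heavy and the desk preset exists for exactly that
  reason.
* With a strongly scalar group effect and mild anatomy, sector means are
  already sufficient; the F-shape advantage appears in pointwise
  discriminability (the residual-vs-raw comparison) and under anatomical
  variability, which is where the registration earns its cost.
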