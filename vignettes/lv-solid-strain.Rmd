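---
title: "Trivariate B-spline solids and isogeometric strain analysis of the left ventricle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trivariate B-spline solids and isogeometric strain analysis of the left ventricle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cine cardiac MRI yields, after segmentation, stacks of short-axis contour
rings on the endocardial (inner) and epicardial (outer) surfaces of the
left-ventricular myocardium, one stack per cardiac phase. Finite-element
meshes built from such data represent the wall as a union of discrete cells;
a spline solid instead represents it as a single smooth map, so strain and
stress can be evaluated *continuously* at any material point rather than per
element. `lvspline` builds that map — a trivariate (volumetric) tensor-product
B-spline — from the contour points, carries inter-phase motion on its control
lattice, and differentiates the motion isogeometrically: the geometry's own
spline basis serves as the displacement basis.

## Model

A degree-$k$ B-spline basis $N_{i,k}(t)$ is defined by the Cox–de Boor
recursion over a nondecreasing knot vector, with the convention $0/0 = 0$ and
half-open spans closed at the right end of the domain so the boundary is
evaluable. The solid is

$$V(t_c, t_l, t_r) = \sum_{i}\sum_{j}\sum_{k} p_{ijk}\,
  N_{i,k_1}(t_c)\, N_{j,k_2}(t_l)\, N_{k,k_3}(t_r),$$

with parameter directions named circumferential ($t_c$), long-axis ($t_l$),
and radial ($t_r$, endocardium to epicardium). The circumferential direction
is closed: it uses a uniform periodic knot vector and control-point wrapping
(the first $k_1$ control columns repeated), giving $C^{k_1-1}$ continuity
across the seam. Degrees default to cubic in all three directions; the
ventricle-like geometries this package targets are smooth, and cubics are the
lowest degree giving $C^2$ fields, hence continuous strain gradients.

A cylindrical representation is available for shape reporting: control
points are transformed to $(r, \theta, z)$ with the azimuth unwrapped along
the circumferential control index (adding $2\pi$ multiples) so the angular
control values form a smooth spline. The unwrap is essential — raw angles in
$[0, 2\pi)$ jump at the seam and would corrupt the spline. Mechanics is
always evaluated in Cartesian coordinates; the cylindrical form is a
representation of geometry, not a strain operator.

## From points to solid

1. **Parameterization.** Each point gets a circumferential parameter
   $t = \theta / 2\pi$ from its azimuth about the long axis and a
   longitudinal parameter $w$ shared per slice, from normalized chord length
   along the slice centroids (chord length, not slice index, so unevenly
   spaced slices parameterize proportionally to distance).
2. **Surface fitting.** The control net minimizing
   $\sum_p \lVert S(t_p, w_p) - x_p \rVert^2$ is found by QR-based linear
   least squares; rank deficiency aborts with a suggestion to reduce the
   net. Interior longitudinal knots are placed by knot averaging
   (Riesenfeld) over representative parameters; chord-length-weighted
   (Hartley–Judd) and uniform placements are options. The fitting method
   itself is a design choice of this package: fixed-parameter linear least
   squares is the simplest scheme consistent with a B-spline surface model,
   and it makes phase-sequence fitting a linear operation (see below).
3. **Sweeping.** The hexahedral control mesh is built by linearly blending
   matched control points of the two fitted surfaces across `radial_layers`
   layers; layer 0 *is* the endocardial net and the last layer the
   epicardial net. With the default 4 cubic radial layers the blend
   parameters coincide with the Greville abscissae of the clamped cubic knot
   vector, so the radial geometry is exactly the linear wall-thickness
   interpolation.
4. **Solid.** The swept lattice is adopted directly as the solid's control
   grid (the surfaces' knot vectors are reused; the radial knots come from
   knot averaging over uniform layer parameters). Fitting the solid to
   volumetric samples instead is possible through the same least-squares
   machinery, but the adopted contract is the swept grid: it is exact for
   matched surfaces and keeps all phases on identical control topology.

**Phase sequences.** Strain from control-point differences presumes material
correspondence: control point $(i,j,l)$ must track the same tissue across
phases. The pipeline therefore computes the $(t, w)$ parameterization once,
on the first phase, and reuses it (with the first phase's knot vectors) for
every later phase. Because least squares is linear in the data, an affine
deformation of the cloud then maps the control points through exactly the
same affine transformation — which is why rigid and dilational patch tests
recover strain to machine precision through the entire pipeline. Phases are
paired adjacently ($t \to t+1$); no Lagrangian accumulation against a fixed
reference is performed in this version.

## Strain, stress, and the Jacobian

Displacements live on the control lattice:
$\mathrm{Disp}(t_c,t_l,t_r) = \sum d_{ijl} N_i N_j N_k$. Infinitesimal
strain needs physical derivatives, obtained from parametric ones through the
isoparametric Jacobian

$$J = \begin{pmatrix}
\partial x/\partial t_c & \partial x/\partial t_l & \partial x/\partial t_r\\
\partial y/\partial t_c & \partial y/\partial t_l & \partial y/\partial t_r\\
\partial z/\partial t_c & \partial z/\partial t_l & \partial z/\partial t_r
\end{pmatrix},
\qquad \nabla_x N = J^{-\mathsf T}\, \nabla_t N .$$

Note the transpose: with $J$ laid out as above (rows physical, columns
parametric), the chain rule gives $\nabla_t N = J^{\mathsf T} \nabla_x N$,
so the parametric-to-physical transform is the inverse *transpose*. This is
verified in the test suite against finite-difference oracles that know
nothing of the analytic derivative path. Basis derivatives use the standard
two-term difference of degree-$(k-1)$ bases with vanishing denominators
contributing zero.

Strain is packed in Voigt order with *engineering* shears,
$\varepsilon = (\varepsilon_x, \varepsilon_y, \varepsilon_z,
\gamma_{xy}, \gamma_{yz}, \gamma_{xz})^{\mathsf T}$,
$\gamma_{xy} = \partial u/\partial y + \partial v/\partial x$ etc. Stress
follows from the isotropic stiffness $\sigma = D\varepsilon$ with

$$D = \frac{E(1-\mu)}{(1+\mu)(1-2\mu)}
  \begin{pmatrix} A & 0 \\ 0 & H I_3 \end{pmatrix},
  \quad A_{qq}=1,\; A_{q\ne r}=\tfrac{\mu}{1-\mu},\;
  H = \frac{1-2\mu}{2(1-\mu)} .$$

Principal strains/stresses are eigenvalues of the symmetric $3\times 3$
tensor rebuilt with $\gamma/2$ (strain) or $\tau$ (stress) off-diagonals.
Because "principal strain in the $X$ direction" is ambiguous in common
usage, field exports carry *both* the raw $\varepsilon_x$/$\sigma_x$
component fields (`epsx`, `sigx`) and the eigen-principal fields, labelled
distinctly.

The analysis is **kinematic**: strain and stress are evaluated from the
observed (fitted) motion, not by solving a boundary-value equilibrium
problem. No equilibrium, boundary traction, or active contraction enters.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| degrees $k_1,k_2,k_3$ | 3, 3, 3 | — | lowest degree with $C^2$ fields |
| surface net | 8 × 6 | control points | resolves an ellipsoidal wall without chasing segmentation noise |
| radial layers | 4 | control points | minimum carrying a cubic; exact linear thickness blend |
| $E$ | 11 | kPa | passive myocardial elastic modulus |
| $\mu$ | 0.49 | — | near-incompressibility of myocardium; $D$ singular at 0.5, so 0.5 is excluded |
| quadrature order | 4 | points/knot span | volume integrand is piecewise-polynomial; composite per-span Gauss–Legendre is near-exact (order-4 vs order-6 volumes agree to < 0.1 %) |
| resolution | 16 × 12 × 4 | samples | display lattice; strain can equally be evaluated at quadrature points |

## The synthetic ventricle

No wall point data ship with the package, so `ventricle_spec()` /
`generate_walls()` emulate segmented short-axis contours on truncated
prolate spheroids — the standard analytic stand-in for the left ventricle.
Defaults: inner semi-axes 20 × 20 × 45 mm, outer 30 × 30 × 55 mm (10 mm
equatorial wall thickness), basal 15 % of the inner long axis truncated
(`truncation = 0.85`), 12 slices × 32 points, matching typical short-axis
coverage of an adult ventricle at end diastole. Isotropic Gaussian noise
(default off; 0.2 mm models segmentation jitter) is added in Cartesian space
after on-surface placement, from a single seeded stream restored after use.

Prescribed deformations (`deformation_spec()`) — translation, dilation,
torsion (rotation angle proportional to height, in rad/mm), radial
contraction — have closed-form infinitesimal strains
(`ground_truth_strain()`), so every stage of the pipeline is testable
against exact expectations. What the generator does *not* emulate:
non-elliptical cross-sections, papillary muscles and trabeculae, fiber-driven
twisting with transmural shear profiles, through-plane slice misregistration,
and breath-hold offsets. Passing recovery tests therefore demonstrate the
correctness of the *machinery* on smooth ventricle-like geometry, not
accuracy on any individual clinical segmentation.

## Validation conditions and numerical choices

The end-to-end recovery studies run at 12 slices × 32 points per slice,
8 × 6 cubic nets, 4 radial layers, with dilation fraction 0.05 and torsion
rate 0.001 rad/mm. The torsion rate is set so the peak engineering shear
($\tau \cdot r \approx 0.03$) stays in the small-strain regime where the
infinitesimal ground truth applies; at rates much beyond this the
finite-rotation map and the linearized strain measure themselves diverge by
$O(\tau z)$, which is a property of infinitesimal strain, not of the
implementation. Recovery error is the median over a 7 × 7 × 5 lattice of the
interior parameter sub-cube $[0.1, 0.9]^3$, normalized by the peak imposed
strain; the margin excludes least-squares edge effects near the open ends of
the fitted surfaces, which are fitting artifacts rather than method error.
Noisy-data studies apply $\sigma = 0.2$ mm once at generation and deform the
same noisy points, i.e. tracked material points carrying segmentation noise.

Other numerical conventions: evaluation at the exact domain right endpoint
uses the closed-at-right span (all other spans half-open); $0/0 = 0$ in both
the recursion and derivative denominators; basis indices are 0-based in the
user-facing API; the on-axis azimuth ($x = y = 0$) is assigned $\theta = 0$;
ring order, when absent, is recovered by nearest-angle ordering about the
slice centroid; `jacobian_at()` refuses $|\det J| < 10^{-12}$ and names the
parameter point; model JSON is written with 17 significant digits so control
grids round-trip bit-identically.

## Limitations

- Infinitesimal (small-strain) theory only; no Green–Lagrange or other
  finite-strain measures, so large inter-phase motions should be split into
  adjacent-phase increments.
- Isotropic linear elasticity; no fiber architecture, anisotropy, or active
  stress.
- Kinematic stress estimate (stiffness applied to observed strain), not an
  equilibrium solution.
- Single-patch topology: left ventricle only; no right ventricle,
  papillary/valve anatomy, or trimmed patches.
- NURBS weights, knot refinement, and degree elevation are out of scope; the
  basis is polynomial B-spline throughout.
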