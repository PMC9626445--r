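---
title: "A biphasic poroelastic model of brain tumour growth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A biphasic poroelastic model of brain tumour growth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
continuum model, the discretization, the synthetic inputs, the numerical
choices, and the limits of what the shipped tests demonstrate. Units are
fixed globally as **mm / day / MPa**; all rates are per day.

## The continuum model

### Mixture kinematics and growth

Brain tissue (healthy and cancerous alike) is treated as a saturated binary
mixture: a solid phase of cells with volume fraction $\phi_s$ and an
interstitial fluid with $\phi_\ell = 1 - \phi_s$, both incompressible as
materials and of equal true density. Saturation $\phi_s + \phi_\ell = 1$
holds at every point and time by construction.

The solid displacement $u_s$ defines the deformation gradient
$F_s = I + \mathrm{Grad}\,u_s$, which is split multiplicatively into an
inelastic growth distortion and an elastic accommodation,
$$F_s = F_e F_g, \qquad F_g = g\,I,$$
with a scalar growth stretch $g \ge 1$. Growth is taken isotropic: the
mitotic spindle orientation is assumed insensitive to fibre alignment, and
the mechanical response of brain tissue is experimentally near-isotropic even
where diffusion is strongly anisotropic. The intermediate ("natural") state
reached by pure growth is stress-free; only $F_e = F_s/g$ stores energy. The
volume ratios satisfy $J_e = J_s / g^3$ exactly, an identity the test suite
asserts to $10^{-12}$.

The tumour is delimited by a smooth indicator $\chi \in [0,1]$ on the
*reference* mesh; the tumour region is its upper level set
$\{\chi > 0.1\}$. Because the whole problem is solved in the Lagrangian
frame, $\chi$ is never advected: the material region simply deforms with the
solid.

### Constitutive behaviour

The solid Cauchy stress derives from a strain energy per natural-state
volume, additively split into an isochoric Mooney–Rivlin part in the
unimodular elastic Cauchy–Green invariants and a logarithmic volumetric
part:
$$W = \tfrac12 \mu_1 (I_{\bar C_e} - 3) + \tfrac12 \mu_2 (II_{\bar C_e} - 3)
    + \tfrac12 \kappa (\ln J_e)^2 .$$
The resulting stress separates into a traceless deviator and a spherical
part $\kappa \ln(J_e)/J_e \, I$. Tumour and healthy parameters differ
(defaults: tumour ten times stiffer, $\mu_1^t = 1.53\times10^{-3}$,
$\mu_2^t = 2.97\times10^{-3}$, $\kappa^t = 1.4\times10^{-3}$ MPa, healthy
one tenth of each); across the diffuse interface the *stresses* are blended,
$T_s = \chi T_s^t + (1-\chi) T_s^h$, a literal pointwise convex combination
— not a blending of parameters. For this particular energy the two coincide
(the energy is linear in $\mu_1,\mu_2,\kappa$), which the implementation
exploits; the distinction would matter for non-linear parameter dependence.
Viscoelasticity is deliberately neglected: growth-induced strain rates are
tiny.

The fluid is ideal; eliminating its momentum balance yields Darcy's law
$v_\ell = v_s - (\hat k A / \phi_\ell) \nabla p$ with the scalar Holmes–Mow
mobility
$$\hat k(J_e) = k_0 \Big(\frac{J_e - \phi_{sn}}{1-\phi_{sn}}\Big)^{\alpha_0}
  e^{m (J_e^2 - 1)/2},$$
which equals $k_0 = 2.17\times10^{5}\ \mathrm{mm^2\,MPa^{-1}\,day^{-1}}$ in
the natural state and vanishes at pore closure $J_e \to \phi_{sn}$. The
dynamic viscosity never appears on its own: every governing equation uses
the mobility $\hat k A$, so that is what the code stores. The
preferential-direction tensor $A$ shares the eigenvectors of the diffusion
tensor; its leading eigenvalues are enhanced by the weights
$a_1(r) = r a_l + r a_p + a_s$ and $a_2(r) = a_l + r a_p + a_s$ built from
the linear/planar/spherical anisotropy indices, then the whole tensor is
rescaled to trace 3. At $r = 1$ (the default; no enhancement is applied
unless the user asks for it) $A$ is just the trace-normalized diffusion
tensor.

### Growth law and nutrients

The net cell proliferation rate is
$$\Gamma_s = \gamma\, \phi_s (\phi_{max} - \phi_s) (c_n - c_0)_+
  \Big[1 - \frac{\delta_1 \Sigma_+}{\Sigma_+ + \delta_2}\Big],$$
with the bracket present only in the stress-inhibited variant.
$c_n \in [0,1]$ is the nutrient (oxygen) concentration normalized by its
physiological value, $c_0 = 0.3$ the hypoxia threshold,
$\phi_{max} = 0.85$ the packing limit (contact inhibition), and
$\Sigma = -\mathrm{tr}(T_s)/3$ the compression measure: compression slows
proliferation (down to the fraction $1 - \delta_1$), traction does not.
Defaults $\gamma = 0.5$, $\delta_1 = 0.8$, $\delta_2 = 10^{-4}$ MPa.

Nutrients are transported by the fluid, diffuse through the reoriented
tensor $D$, and are exchanged with the vasculature only inside the tumour
region:
$$G_n = -\zeta \phi_s \phi_\ell c_n + S_n (1 - c_n)\phi_\ell,$$
with the consumption rate derived from the oxygen diffusivity
$D_n = 86.4\ \mathrm{mm^2/day}$ and uptake length $l_n = 0.1$ mm as
$\zeta = D_n / l_n^2 = 8640$, and supply $S_n = 10^4$. Setting $G_n = 0$
gives the interior balance concentration
$c^\ast = S_n / (S_n + \zeta \phi_s)$ ($\approx 0.794$ at
$\phi_s = 0.3$), which the solver must reproduce away from the boundary on
a uniformly cancerous phantom — one of the end-to-end checks.

Growth closes with two pointwise identities: mass conservation of the
growing solid, $J_s \phi_s = g^3 \phi_{sn}$ (with natural-state fraction
$\phi_{sn} = 0.3$), and the evolution law
$\dot g / g = \Gamma_s / (3 \phi_s)$ inside the reference tumour region.

### Fibre reorientation

Tumour expansion displaces white-matter tracts. Only the *directions* of the
fibres change, not the diffusivities along them: each eigenvector of the
initial tensor is pushed forward by $F_s$ and renormalized,
$$D = \sum_i \lambda_i \frac{F_s e_i \otimes F_s e_i}{|F_s e_i|^2},$$
which preserves the trace (mean diffusivity) unconditionally. The same
construction with the weights $(a_1, a_2, 1)$ and a final trace-3 rescaling
gives the deformed $A$; the anisotropy weights are always built from the
*initial* eigenvalues. The Lagrangian solver uses the pullbacks
$D^\ast = J_s F_s^{-1} D F_s^{-T}$ and $K^\ast/\mu = J_s \hat k(J_e)
F_s^{-1} A F_s^{-T}$, which share the eigenvectors of the initial tensors
(the pushforward and pullback cancel directionally) with rescaled
eigenvalues.

Anisotropy change is reported as the per-cell fractional-anisotropy
difference $\Delta FA$ and as leading-eigenvector change metrics: the axis
mismatch $s = 1 - |e_1^0 \cdot e_1^f|$ and the folded spherical-angle
differences $|\Delta\theta|, |\Delta\varphi| \in [0, \pi/2]$ (eigenvectors
are axes, so angles differing by multiples of $\pi$ are identified). These
metrics are only computed where the initial FA exceeds 0.1; in nearly
isotropic cells the leading eigenvector is numerically meaningless, and 0.1
is this package's operational threshold for "anisotropic region".

## Discretization and numerics

The coupled unknowns per node are $u_s$ (3), $p$ and $c_n$: equal-order P1
tetrahedral elements, matching fields clamped at the outer boundary
($u_s = 0$ always; by default $p = 0$ and $c_n = 1$, with a zero-flux
alternative for tumours near the skull). Time is advanced by a semi-implicit
Euler scheme with $\Delta t = 0.1$ day by default: at each step the discrete
mass balance, momentum balance and nutrient transport are solved
monolithically for $(u, p, c)$ by Newton's method with $g$, $\phi_s$,
$\chi$ and $\Sigma$ frozen at the previous level; afterwards $g$ is updated
by explicit Euler using previous-level quantities (including the
previous-level concentration — the scheme is ambiguous on this point and the
package freezes $c$ at level $k$ for the growth update), $\phi_s$ follows
from $J_s \phi_s = g^3 \phi_{sn}$, and stresses and tensors are refreshed
from the new deformation. $\Sigma$ entering the inhibition factor is the
previous step's converged stress evaluated with the updated growth stretch,
which keeps the growth law explicit and Newton's system free of stress
derivatives of $\Gamma_s$.

Numerical choices worth knowing:

* **One-point quadrature.** All element integrals use the barycentre value;
  with P1 elements every gradient is elementwise constant, so this is exact
  for the diffusion/Darcy stiffness terms. The storage and reaction terms of
  the *nutrient* equation are evaluated nodewise (lumped quadrature): the
  consumption/supply reaction is stiff ($\Delta t\,(\zeta\phi_s + S_n)
  \gg 1$) and the lumped form keeps it monotone, avoiding interior
  oscillations below the plateau concentration.
* **Numerical tangent.** The Newton matrix is assembled from central finite
  differences of the element residual in the displacement dofs (the
  pressure and concentration columns are exact — the residual is linear in
  both). No fourth-order elasticity tensor is hand-coded; the tangent is
  only a means to convergence and the residual defines the physics. An
  independent test multiplies the assembled matrix against a random
  direction and compares with a global directional difference
  (relative error $\sim 10^{-10}$).
* **Newton controls.** Blockwise scaled residual norms (displacement rows
  scaled by $\kappa h^2$, mass/nutrient rows by $h^3$) with relative
  tolerance $10^{-8}$, absolute $10^{-10}$, at most 25 iterations, and a
  backtracking line search that rejects steps inverting an element. The
  undeformed, source-free state is an exact fixed point (zero residual), and
  typical growth steps converge in 2–3 iterations.
* **Linear solver.** Direct sparse LU on the monolithic Jacobian; the
  sparsity skeleton is computed once and refilled each iteration. At
  phantom scale (a few thousand free dofs) each solve is tens of
  milliseconds.
* **Equal-order stabilization.** P1–P1 displacement–pressure pairings can
  oscillate at small time steps; a pressure-gradient
  (Brezzi–Pitkäranta-type) stabilization term can be switched on
  (`stabilize = TRUE`), but it is off by default, matching the plain element
  choice. On the shipped phantoms the default is well-behaved because the
  mobility is large.
* **CFL reporting.** There is no single CFL condition for the coupled
  system; the package reports the cellwise advective number
  $|v_\ell| \Delta t / h_{cell}$ (shortest-edge $h_{cell}$) after every step
  and flags values above one. On the default phantoms it stays below
  $10^{-2}$.
* **Degenerate inputs.** Inverted elements, pore closure
  ($J_e \le \phi_{sn}$) and saturation violations ($\phi_s \notin (0,1)$)
  abort the step with the offending cell reported. Eigenvalue ties in the
  spectral decompositions are handled by the stable symmetric eigensolver;
  the descending-order convention tolerates equality.

## The synthetic phantom

The phantom module replaces the clinical imaging pipeline. It emulates:

* a **ball "brain"** of radius 40 mm (large enough that the outer boundary,
  which stands for the rigid skull, is far from the default tumour — the
  boundary conditions assume this), meshed by mapping a structured
  Freudenthal tetrahedralization of a cube smoothly onto the ball, with
  damped Laplacian smoothing (boundary pinned) and a radial grading that
  refines the tumour region by a requested factor. The generator calibrates
  the grading so the delivered median-edge contrast matches the requested
  factor. Mesh quality is checked against the usual bar (at least 95% of
  tets with normalized aspect ratio below five);
* a **tumour indicator** $\chi(X) = \tfrac12 (1 - \tanh((|X - c| - r_0)/w))$
  with default radius $r_0 = 7$ mm and interface width $w = 1$ mm. The tanh
  profile and the 1 mm width are this package's regularization choices (the
  underlying model only requires a smooth indicator); the 0.1 level-set
  threshold is part of the model. The $\{\chi > 0.1\}$ ball then has radius
  $r_0 + w\,\mathrm{atanh}(0.8)$;
* **voxel DTI grids** with controllable anisotropy: isotropic (mean
  diffusivity $86.4\ \mathrm{mm^2/day}$ everywhere), uniform-axis (a fixed
  eigenframe), or radial (leading eigenvector pointing away from the domain
  centre). Cells inherit the tensor of the voxel containing their
  barycentre, with half-open voxel intervals so face-sitting barycentres are
  assigned deterministically.

What the phantom does **not** emulate: cortical folding and realistic brain
geometry, grey/white matter segmentation, spatially heterogeneous
diffusivity magnitudes, imaging noise, and the intratumoural signal loss
real DTI shows. Passing the shipped tests therefore demonstrates the
correctness of the mechanics, transport, growth and reorientation machinery
on controlled geometry — not predictive fidelity for any patient.

## Problem sizes used by the tests

The acceptance-style experiments run the isotropic phantom at coarse
resolution (40 mm ball, ~10 mm nominal spacing with 2x tumour refinement,
about 3000 tetrahedra) for 10 simulated days at $\Delta t = 0.1$; unit and
property tests use a 20 mm ball at ~7 mm spacing. These sizes were chosen so
the entire suite runs on a single CPU in minutes while leaving the
qualitative behaviour — compression in the tumour core, a traction annulus
outside the interface, negative interstitial pressure in the tumour, slower
growth under stress inhibition, faster growth for stiffer tumours — clearly
resolved. The time-step study (halving $\Delta t$ changes the day-10 volume
by under 1%) supports the first-order scheme at this resolution.

## Known limitations

* Quantitative patient-scale values (peak displacement of a few mm after 45
  days, cm^3-scale final volumes, specific FA-change percentages) depend on
  the clinical geometry and anisotropy and are not reproduced by the desk
  phantoms; the package asserts orderings and analytic identities instead.
* The skull is modelled as a clamped boundary, not contact; vascular
  collapse, perfusion loss, therapy and resection are out of scope.
* Growth is isotropic ($F_g = g I$); anisotropic growth would require a
  tensorial evolution law.
* The coarse-mesh tumour volume inherits an interface bias from the P1
  indicator (upper level set measured on cells), which inflates the
  *initial* volume on coarse meshes; volume *orderings* and growth rates
  are unaffected, but doubling-time estimates on the coarsest phantom are
  conservative.
* Equal-order elements without stabilization are adequate at the shipped
  mobilities and time steps; very low permeability or very small time steps
  would call for the stabilized variant.
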