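---
title: "Model and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ecmigrate` is an individual-based, force-based simulator of endothelial
cell invasion into three-dimensional cross-linked collagen networks. This
vignette is the package's own account of the model: the governing
equations, the assumptions behind each module, the tunable parameters with
their units and defaults, what the procedural generators emulate (and do
not), and the numerical choices that were genuinely open.

## The physical picture

A cell at the interface between a culture medium and a collagen gel
extends filopodia into the gel. Each filopodium probes the fiber network;
when its tip comes close to a fiber it forms a focal complex (FC) — a
cluster of integrin–ligand bonds — and myosin motors along the shaft load
that adhesion. Depending on how the surroundings respond, the filopodium
either builds traction and contracts, pulling the cell body forward, or
the adhesion fails and it retracts. Membrane-proximal proteases degrade
the matrix locally, softening the path. All structures obey overdamped
(inertialess) mechanics, `C dx/dt = F(x)`, with per-node drag coefficients.

Units throughout the package: lengths in um, forces in pN, time in s,
stiffness in pN/um, drag in pN s/um, pressure in pN/um^2 (numerically
equal to Pa), concentrations in M.

## Fiber network: generation

The generator emulates a collagen gel as a graph of straight elastic
fibers joined at crosslink nodes:

* Crosslink seeds sit on a jittered cubic lattice at the target pore
  spacing (jitter amplitude 0.1 of the pore size). The jitter amplitude
  was chosen once so that the measured mean nearest-crosslink spacing
  stays within about 10% of the nominal pore size — comfortably inside
  the generator's 20% contract — while still breaking lattice symmetry.
* Candidate fibers are the mutual k-nearest-neighbour edges between seeds
  (k = 4, capped at 1.8 pore lengths). This replaces a CAD/CFD meshing
  pipeline with a reproducible procedure whose statistical targets (mean
  spacing, coordination) are tested directly. A Delaunay triangulation
  would serve equally; the kNN rule needs no geometry dependency and
  gives direct control of the coordination number.
* Each crosslink-to-crosslink line is divided into `n_div` fiber segments
  plus two 30 nm crosslink segments, carrying `n_div + 1` fiber nodes.
  The three presets couple pore size, fiber diameter and segmentation:
  0.5 um/28 nm/1, 1.0 um/34 nm/2, 1.5 um/41 nm/3, mimicking gels
  polymerized at pH 9, 7 and 5.
* At each crosslink node, a fraction `P_f = 0.7` (rounded) of the
  incident fiber ends is actually crosslinked; the rest dangle free.
* Two segment sets meeting at a crosslink continue as one longer fiber
  when their directions are closer to collinear than to folded — the
  interior bend deviates less than 60 degrees from straight. The pairing
  among eligible continuations is random. The 60-degree convention is
  stated here explicitly because an "angle above 60 degrees" rule is
  directionally ambiguous; this reading is the one that produces
  extended multi-segment fibers.
* Every fiber node carries a ligand pool of 300 collagen molecules and
  the initial ECM concentration `C_ECM0` = 10 uM.

What the generator does **not** emulate: fiber-length and pore-size
polydispersity beyond lattice jitter, curved or bundled fibers, and the
element counts of the original tetrahedral meshes (a stated non-goal).
Passing tests on these networks therefore demonstrate the mechanics and
kinetics on a statistically controlled idealization, not on
reconstructed gel images.

## Fiber network: mechanics

Each fiber chain stores stretching and bending energy
\[
H_i \;=\; \frac{\kappa_s}{2}\sum_j \frac{(L_{ij}-L^0_{ij})^2}{L^0_{ij}}
   \;+\; \frac{\kappa_b}{2}\sum_j \frac{(\theta_{ij}-\theta^0_{ij})^2}{L^0_{ij}},
\]
with `kappa_s = E_f A_f` and `kappa_b = E_f I_f`, `A_f = pi r^2`,
`I_f = pi r^4/4`, `E_f` = 1 MPa by default. Angles are taken only between
coaxial neighbour segments within a chain,
`theta = acos(t_k . t_k+1)`. Nodal forces are the exact negative gradient
(virtual work); the test suite pins them against a central-difference
oracle at 1e-6 relative tolerance.

Two numerical notes:

* The angle gradient contains `1/sin(theta)`, singular at collinearity —
  the generator's common case. The force prefactor
  `(theta - theta0)/sin(theta)` tends to 1 for straight rest angles, so
  the implementation evaluates that ratio with the denominator floored at
  1e-8; the limit is exact where it matters and the floor only caps the
  (physically divergent) force of a fully folded triple with a bent rest
  angle.
* Quoted bending-modulus values for this parameterization are sometimes
  a factor of ten below `E_f pi r^4/4` evaluated from the same radii
  (with matching mantissas — an exponent slip). `kappa_b` is therefore
  computed from first principles (0.030–0.139 pN um^2 for 28–41 nm
  fibers), with `fiber.kappa_b` as an override.

## In-silico rheology

`run_stretch_test()` emulates a uniaxial gel test: the boundary node sets
on two opposing faces are displaced symmetrically; between strain
increments the interior is relaxed to mechanical equilibrium; the axial
stress is the summed boundary reaction force divided by the undeformed
cross-sectional face area (the normalization the plots leave implicit).
The bulk modulus is the least-squares slope of stress versus strain
restricted to strains 0.2–0.7, the linear regime of these networks.

Relaxation uses FIRE (fast inertial relaxation engine), the standard
athermal minimizer for fiber and granular networks, with the residual
force tolerance `1e-4 kappa_s`. A wall-clock-faithful boundary drive at
0.5 nm/s up to strain 0.7 would take ~10^7 engine steps; only the relaxed
fixed point enters the quasi-static curve, and FIRE reaches it in
O(10^4) evaluations. Samples whose residual exceeds the tolerance within
the iteration budget are flagged in the returned curve.

The package reproduces the *trend* — the fitted modulus increases with
fiber diameter (28 to 41 nm) and with fiber modulus — on 4.5 um domains.
Absolute moduli depend on network size, boundary conditions and the
original meshes, and are out of scope.

## Filopodium: adhesion kinetics

The tip FC is a cluster of `n_b` ligand–receptor bonds, each a spring of
stiffness 1 pN/nm and rest length `lambda` = 30 nm:
`F_FC = n_b kappa_LR (L_b - lambda) n_R`, with the reaction distributed
to the anchor segment's end nodes so that every pair sums to zero
exactly. The anchor's parametric position is re-projected to the closest
point on its segment every evaluation, so the binding site migrates along
the fiber as forces evolve — tip crawling is emergent rather than
scripted.

Bond formation is Monte-Carlo: each free receptor binds within `dt` with
probability `1 - exp(-k_on dt)`, `k_on = k_f (C_L - C_b) A_L`, the free
ligand count taken from the 300-molecule pool of the nearest fiber node
(so bound plus free is conserved exactly). FCs can only form while the
tip-to-fiber gap is below 100 nm. Rupture follows Bell's slip-bond law,
`k_off = k_off0 exp[kappa_LR (L_b - lambda) x_b / k_B T]` with
`k_off0` = 1/s and `x_b` = 0.02 nm, giving a maximum per-bond rupture
force `k_B T / x_b` of about 214 pN at 310 K; compressed bonds dissociate
at the unstressed rate. Focal adhesions on the cell membrane use the same
machinery with a five-fold slower unstressed off-rate (their turnover is
minutes rather than tens of seconds) and a 100-bond cap per node.

## Filopodium: contraction and phases

The shaft is divided into 8 acto-myosin (AM) compartments whose rest
lengths shorten at both ends with the myosin sliding speed,
`dL/dt = -2 v_m`, and whose stiffness is `E_AM A_AM / L_AM`
(about 20–34 pN/nm for 0.5–0.8 um compartments). The sliding speed obeys
the muscle-type force–velocity law
\[
v_m = v_{m0}\,\frac{F_{stall}-F_{TR}}{F_{stall}+c_m F_{TR}},
\]
with `v_m0` = 10 nm/s, `F_stall` = 1 nN, `c_m` = 0.1, clamped to zero at
stall; `F_TR` is the current FC force magnitude at the tip.

The phase machine has seven states — inactive, active, outgrowing,
tugging, contractile, retractile, decay. Outgrowing tips receive the
2 nN polymerization force along the local VEGF gradient (falling back to
the growth axis in a uniform field) and the chain rest length grows at
`v_poly`; an FC switches the filopodium to tugging; timeout (60 s) or the
4.5 um length cap sends it to retraction. Tugging matures into the
contractile phase when the tip tension exceeds the threshold while bonds
survive the Bell rupture test; complete bond loss falls back to
outgrowing; the dwell budget (60 s) gives up into retraction. Retraction
proceeds at the unloaded sliding speed and ends in decay at the 2 um
length floor, freeing the root for renucleation.

Parameter decisions the sources leave open, fixed here once:

* **Contractile gate.** The threshold is quoted per unit length
  (3–4 nN/um). Converting with the 0.3 um filopodium diameter, the
  midpoint (1.05 nN) exceeds the 1 nN stall force — tension built by the
  motors alone saturates at stall, so the gate could never fire. The
  default uses the low end: 3 nN/um x 0.3 um = 0.9 nN, still a
  configurable scalar.
* **FC maturation dwell (5 s).** At formation, freshly bound receptors
  inherit the full 50–100 nm gap extension, so the first-step tension
  transiently spikes above any gate regardless of anchor stiffness. A
  short maturation dwell before the contractile gate lets that elastic
  transient relax, so the gate senses motor-built tension. Without it the
  soft/stiff anchor regimes are indistinguishable.
* **Phase time budgets** (60 s) and the **polymerization speed**
  `v_poly` = 50 nm/s: the state diagram names the timers but prints no
  constants; 50 nm/s lets a filopodium traverse its 2–4.5 um working
  range within one outgrowing budget, consistent with observed filopodial
  extension rates (tens of nm/s).
* **Nucleation**: new filopodia seed at membrane nodes whose outward
  normal is within 45 degrees of the cell polarization axis, at a capped
  count (6 by default) and Poisson rate 0.2/s.

With a stiff elastic anchor (10 pN/nm, the hard-substrate scale) the tip
builds tension to the gate within seconds and holds the contractile phase
at 1–4 nN; with a very soft anchor (0.02 pN/nm) tension cannot reach the
gate, and the filopodium exhibits repeated load-and-fail cycles — load,
adhesion failure or give-up, retraction, regrowth, re-binding. Both
regimes are acceptance-tested.

## Cell body

Three concentric triangulated membranes share one icosphere topology:
cell membrane, transduce (cortex) layer, and nuclear membrane. The
default refinement is 642 nodes per layer — the closest icosahedral
refinement to the 549-node reference meshes, which were CFD artifacts not
reachable by icosphere subdivision; scaled-down scenes use 42 or 162
nodes. Forces:

* edge springs (5e-5 N/m) on every layer, with a volume-preservation
  penalty for the nucleus;
* Kelvin–Voigt cortex elements (spring 8e-3 N/m; the dashpot enters the
  mobility) pairing each membrane node with its transduce partner;
* a constant 300 pN lamellipodium force on leading-edge nodes (outward
  normals within 60 degrees of the polarization axis);
* focal adhesions as above, anchored to the nearest fiber within 100 nm;
* stress fibers: single AM compartments nucleated from mature FAs
  (>= 30 bonds) toward the nearest nucleus node, contracting under the
  same force-velocity law. This is a deliberately minimal stand-in for
  full adhesion-maturation/stress-fiber remodeling models, which are
  outside this package's scope; it preserves the force-balance structure
  and every action–reaction coupling.

The membrane and cortex equations are coupled through the cortex drag;
per node the velocities solve the 2x2 mobility system
\[
\begin{pmatrix}\dot x_c\\\dot x_t\end{pmatrix}
 = \frac{1}{C_cC_t + C_{cort}(C_c+C_t)}
 \begin{pmatrix}C_t+C_{cort} & C_{cort}\\ C_{cort} & C_c+C_{cort}\end{pmatrix}
 \begin{pmatrix}F_c\\F_t\end{pmatrix}.
\]
The polarization axis follows an exponential moving average of the
centroid displacement direction.

## Reaction–diffusion and degradation

Seven species on a regular Cartesian grid (1 um spacing) with zero-flux
boundaries: VEGF (chemotaxis; fixed concentration on the far +x face
sustains the orienting gradient — 1.31 nM, i.e. 50 ng/ml at 38.2 kDa, a
documented assumption), MMP-2, TIMP-2 and soluble ligand diffuse;
MT1-MMP and the ternary complex are membrane-bound and live in the cells
containing filopodial-root secretion sources; the ECM concentration is
carried on network nodes. The reaction network is the simplified
activation scheme: TIMP-2 inhibits MMP-2; TIMP-2 binds MT1-MMP into the
ternary complex; the complex reacting with further MT1-MMP releases
active MMP-2; MT1-MMP and TIMP-2 are secreted at filopodial roots with
`alpha * C_Ligand` source terms (a constant-rate alternative is
selectable via `rd.secretion_model`, since the ligand factor in the
constitutive form may be a units device); MMP-2 degrades ECM at `k_deg` = 1.04e6 /M/s, and ligand is
released in proportion.

Numerical and calibration choices:

* Diffusion advances by implicit finite volumes, solved by conjugate
  gradients to a relative residual far below the model's 1e-3 criterion
  (1e-10), which makes the symmetric stencil conserve mass to rounding —
  the conservation test requires drift below 1e-6 per 1000 steps.
* Reactions advance by Heun sub-steps with the rate-limited step
  `rate x dt <= 0.02`, which meets the closed-form decay oracle at 1e-4
  relative accuracy over 1e5 s.
* No decay constant is specified for MT1-MMP; the MMP-2 value
  (0.0017/s) is used for it.
* **Protease ceiling.** The simplified activation network is
  autocatalytic with no saturating sink: the complex gains a term
  proportional to (complex x MT1-MMP), which grows exponentially once
  MT1-MMP exceeds `k_off/k_on` = 10 nM — and the secretion terms reach
  that within seconds. The four protease species are therefore capped at
  `rd.C_max` = 200 nM, a physiological ceiling standing in for the
  saturating sinks the simplified network omits. The value was fixed once
  so that matrix degradation develops gradually on the minutes scale of
  an invasion run (local integrity falling to ~0.5–0.7 over 3–4 minutes
  on the test domains); it was fixed before any acceptance measurement
  was run.
* Integrity `I = C_ECM/C_ECM0` is integrated exactly per step with the
  frozen local MMP-2. Crosslink detachment then makes
  `N_uf = round((1-I) N_0f)` (round-half-up), choosing the newly detached
  ends uniformly at random; detachment only removes the 30 nm coupling,
  never nodes or chains, and never reverses.

On the small test domains the MMP-2 diffusion length far exceeds the box,
so degradation is near-uniform in space; on larger domains it localizes
around the cell. This is a known scaled-down distortion and the reason
degradation comparisons are made between runs (proteolysis on versus
off) rather than against spatial patterns.

## Engine

All positions are packed into one matrix and advanced by an embedded
adaptive explicit pair (Heun/Euler) with the local position error kept
below `ode_tol (1 + max|x|)` (`ode_tol` = 1e-4) and the step clamped to
[1e-3, 1e-2] s. The stiffest couplings (300-bond FC clusters, 30 nm
crosslink segments, contact springs) have drag/stiffness time constants
of a few milliseconds, inside the pair's stability region at the step
cap, so a Jacobian-based Rosenbrock scheme is not needed to meet the
tolerance contract; the self-convergence of the integrator under
tolerance refinement is tested. Stochastic bond events are applied once
per accepted macro-step with the accepted dt (jump-adapted splitting);
new-anchor searches and cell-side adhesion events run on 0.1 s cadences
(bond kinetics equilibrate at `k_on` ~ 300/s regardless). Fiber nodes
beyond 15 um of the cell centroid and filopodial tips are frozen
boundaries, refreshed every 10 s of simulated time.

Contact handling: nodes repel fiber cylinders within the fiber radius
plus a surface-thickness pad (discrete nodes stand in for a continuous
surface; without a pad, fibers pass between mesh nodes and pore size has
no steric meaning). The pad is resolution-dependent and
adhesion-constrained: filopodial shaft nodes use 0.15 um (the filopodium
radius), cell-membrane nodes use 0.05 um — the membrane pad must leave
the node inside the 100 nm focal-adhesion formation gate, or adhesions
can never form and the cell becomes an unanchored balloon (observed and
fixed during development). Filopodial *tip* nodes repel only within the
bare fiber radius: the 30 nm bond rest length must lie inside the
repulsion-free zone, or an adhered tip is pushed off its own anchor and
the measured tension is an artifact of the pad rather than of the
motors.

The hot kernels (network elasticity, membrane springs, contacts, the
whole-scene velocity evaluation) are compiled C++; the R module functions
remain the documented interface, and a test pins the compiled kernel
against their independent assembly on a randomized scene.

## Study conditions and problem sizes

The full-scale conditions are a cell of radius 7.5 um with 642-node
membranes in 10+ um domains over 10–20 simulated minutes. The test suite
and examples run scaled-down versions of the same conditions, stated here
as the package's chosen study sizes: invasion runs use 4.5 um domains, a
2 um cell with 42-node membranes, up to 3 filopodia and 60 simulated
seconds with 5 replicate seeds per preset; the rheology sweep uses
4.5 um domains; the single-filopodium regime probes run up to 1000 s
(stopping early once the monotone cycle count witnesses its bound); the
proteolysis comparison runs 160 s at pore 0.5 um on a 4 um domain. At
these sizes the *orderings* (faster invasion in larger pores, stiffer
gels from thicker fibers, soft-versus-stiff anchor regimes,
degradation-enabled versus deficient advance) are the reproduction
targets; absolute speeds and moduli depend on scale and are not
comparable to full-scale values.

Two of those orderings are genuinely scale-limited, and the test suite
reports them honestly rather than weakening the check:

* **Invasion-speed ordering.** The path-length speed carries a
  stochastic-adhesion jitter floor (bond-count fluctuations, grab/release
  events, phase cycling) that *grows* with network density. At full
  scale the directed advance over 10-20 minutes dominates this floor; on
  60-second desk runs the two are comparable, so the replicate-mean
  path-length orderings are at the mercy of jitter even though the
  directed centroid advance into the gel already orders with pore size.
* **Proteolysis-deficient comparison.** MMP-2's diffusion-decay length
  (~200 um) dwarfs a 4 um box, so desk-scale degradation is spatially
  uniform: instead of clearing a path ahead of the lamella while the far
  matrix stays intact, it decomposes the entire gel into free chains and
  removes the cell's traction substrate altogether. Under that
  distortion disabling proteolysis can *help* net advance — the opposite
  of the full-scale behavior, where localized degradation relieves
  steric blockage that a fine membrane mesh actually feels.

## Known limitations

* Cell morphology stays rounded; elongated mesenchymal shapes would
  need much finer membranes (mesh spacing near the ~80 nm adhesion
  scale) and adhesion-limited protrusion.
* Fiber mechanics are elastic (no viscoelasticity or plasticity);
  degraded fibers persist as free chains.
* Catch-bond adhesion kinetics, filopodium buckling and branched
  filopodia are out of scope.
* Diffusivities are homogeneous; pore-size- and stiffness-dependent
  transport is not modeled.
* Speeds measured by the path-length rule on 1 s samples include a
  stochastic-jitter floor from bond-count fluctuations; at the scaled
  sizes this floor is comparable to the directed component, which is why
  replicate means, not single trajectories, carry the acceptance
  orderings.
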