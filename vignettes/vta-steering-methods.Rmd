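---
title: "Modelling the volume of tissue activated by directional pallidal DBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the volume of tissue activated by directional pallidal DBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Deep brain stimulation (DBS) of the globus pallidus pars interna (GPi)
treats Parkinson's disease and dystonia. Directional leads split the two
middle contact rows into three 90-degree segments, so the clinician can
steer current azimuthally as well as along the lead. The quantity this
package computes is the *volume of tissue activated* (VTA): the region
around the lead within which model axons fire an action potential at a
given stimulus setting, partitioned into the anatomical compartments
that matter for pallidal programming — inside the GPi, in the medial
medullary lamina between the pallidal segments, inside the GPe, and
outside the pallidum (where the internal capsule and optic tract sit and
side effects arise).

The pipeline has five stages, each exposed as ordinary functions:

1. `build_pallidum_phantom()` — a synthetic voxel head region,
2. `build_lead()` / `place_at_target()` / `rasterize_lead()` — the
   directional lead,
3. `solve_potential()` — the quasi-static field with
   electrode-tissue-interface (ETI) impedance and current scaling,
4. `generate_axon_grid()` / `evaluate_population()` — myelinated-axon
   activation,
5. `build_vta()` / `partition_vta()` / `run_sweep()` — VTA construction,
   partition, and the orchestrated study sweep.

## The synthetic phantom

High-fidelity segmented head models are not redistributable at package
scale, so the anatomy is a parametric phantom
(`phantom_spec()`): nested GPe/GPi ellipsoids separated by a 1 mm
lamina shell, an internal-capsule slab medial to the pallidum, an
optic-tract cylinder below it, CSF compartments standing in for the
ventricles (dorsomedial) and the basal cisterns (ventral), a dorsal
white-matter cap, a subarachnoid CSF rim and an outer case shell that
serves as the monopolar return. Dimensions follow adult pallidal scale
(GPi about 440 mm^3, GPe about 1.5 cm^3 around it); everything is
configurable. The phantom emulates the *kind* of heterogeneity a
segmented head model provides — conductivity contrasts at realistic
distances — but not its anatomical detail: passing the directional
tests here says the method responds correctly to heterogeneity, not
that absolute volumes transfer to any individual anatomy.

Default conductivities (S/m): grey matter and both pallidal segments
0.275, white matter (and lamina, internal capsule, optic tract) 0.126,
CSF 1.654, encapsulation 0.1, case shell 0.17. These are configuration
defaults from widely used low-frequency tissue-property compilations,
overridable through the TSV conductivity table. Polyurethane insulation
is a perfect insulator (sigma = 0, excluded from the conductance grid) —
a deliberate relaxation of the "all labels conduct" rule for electrode
materials. Inactive contact metal is likewise excluded rather than
floated at platinum conductivity: a 10^7-fold contrast destroys the
conditioning of the iterative solve, and an equipotential floating
constraint is beyond scope; the geometric effect of a 1.5 mm passive
metal band on the field is small at the resolutions used.

## The lead

The lead follows the common directional family: 1.27 mm diameter,
1.5 mm contact height, a 1-3-3-1 layout (ring, two segmented rows,
ring), 90-degree segments with 30-degree gaps, and an edge-to-edge row
gap of either 0.5 or 1.5 mm — the two vertical spacings under study.
The published study does not print contact dimensions; these defaults
are stated assumptions, all configurable in `build_lead()`. The implant
pose is 23 degrees anterior in the sagittal plane and 11 degrees
lateral in the coronal plane with segment A facing anterior, and
`place_at_target()` translates the lead so the row-2 contact surface
sits 2.25 mm from the lateral and 2.3 mm from the posterior GPi border,
in the ventral posterolateral ("sensorimotor") octant. A 0.5 mm
encapsulation sheath surrounds the whole lead.

"Vertical spacing" is read as the edge-to-edge inter-row gap, so the
row-centre pitch is contact height + spacing (3.0 mm and 2.0 mm for
the two leads). Rasterization resolves ties with precedence
metal > insulation > encapsulation > tissue.

## The field solve

The potential obeys the quasi-static (ohmic) equation
`div(sigma grad phi) = 0`. The stimulus pulse is long compared with
tissue charge relaxation, so the operator is purely resistive: relative
permittivities are carried in the tissue table but unused. This is a
documented limitation, not an approximation switch.

Discretization is cell-centred finite volumes on the voxel grid with
harmonic averaging of sigma across faces — the standard choice for
discontinuous coefficients — solved by Jacobi-preconditioned conjugate
gradients to a relative residual of 1e-8 (absolute 1e-10). Cathode
contacts are clamped to -V (co-activated contacts share the potential),
anode contacts or the case shell to 0 V, and the outer box is zero
normal current.

Resolution is graded with a two-level composite: a coarse full-domain
solve (default 1 mm) supplies Dirichlet boundary values for a refined
region of interest around the contact array (default 0.25 mm, margins
8 mm radial / 6 mm axial), where the lead is re-rasterized
analytically. Because the coarse rasterization makes the electrodes
effectively fatter, the raw coarse solution carries more current than
the refined one; the far field of a source scales with its delivered
current, so the coarse field is rescaled to the self-consistent refined
cathode flux. The ROI flux is affine in that boundary scale, so two
ROI solves determine the fixed point exactly and a third applies it —
after which the monopolar case-return current balances the cathode flux
to numerical precision.

The solve is voltage-controlled; the cathode flux is integrated over
the cathode boundary faces, the ETI impedance is `V / I`, and
`scale_to_current()` rescales the whole field to the requested
equivalent current (exact by linearity). Desk-scale grids are far
smaller than the ~10^8-element meshes used with commercial solvers, so
absolute potentials within a voxel or two of electrode edges are less
accurate; the oracle tests pin the behaviour that matters (point-source
far field within 3%, two-conductivity interface within 5%, conservation
within 1%).

## The axon model

Axon trajectories are straight fibres on planes perpendicular to the
lead, 0.5 mm apart, with 0.25 mm lateral spacing, replicated at six
orientations (0-150 degrees in 30-degree steps; 180 degrees would
duplicate 0 for straight fibres). Fibres run only perpendicular to the
lead; parallel fibres exist in the pallidum and their omission
underestimates activation — a known limitation shared with the modelled
study. The default fibre is 20 mm long and 5.7 um in diameter; 4.7 um
(suggested by the counter-balancing argument in the source study's
discussion) is supported through linear extrapolation of the geometry
table, and both are first-class options rather than a silently resolved
choice.

The membrane model is a double-cable myelinated axon in the style of
the standard DBS fibre model: nodes of Ranvier with fast Na+,
persistent Na+, slow K+ and leak conductances (3.0, 0.01, 0.08,
0.007 S/cm^2; reversals +50/-90 mV; 2 uF/cm^2; 36 C with Q10
corrections), passive internodes (axolemma 1e-4 S/cm^2 under a myelin
sheath of 2N lamella membranes in series, N diameter-dependent), a
70 ohm cm axoplasm, and a thin periaxonal space opening to the
extracellular medium at the flanking nodes. The published study does
not name its membrane model; this one is the field's default for DBS
axon populations, with one simplification: each internode is a single
compartment rather than the full MYSA/FLUT/STIN chain. That shifts
absolute thresholds slightly (the package's thresholds are ~0.1 mA at
1 mm and ~0.3 mA at 2 mm for 5.7 um fibres at 60 us) but preserves the
monotonicities the analysis rests on, which are tested directly.

Integration is semi-implicit backward Euler: channel gates advance by
Rush-Larsen using the previous membrane potential, then the coupled
voltage system (intracellular plus periaxonal unknowns) is solved
directly as a banded system. The default step is 5 us; halving it moves
thresholds by under 2% (tested). The leak reversal is balanced at
initialization so the fibre rests exactly at -80 mV — drift is below
1 mV over 10 ms.

The stimulus is one rectangular cathodic phase (60 us default) followed
by a charge-balanced exponential recharge (500 us time constant), at
130 Hz nominal rate; a single pulse decides activation, the
conventional VTA criterion. Activation requires a propagating spike:
the membrane crossing 0 mV at three or more consecutive nodes including
an end node. The action-potential initiation (API) site is the node
with the earliest crossing. `evaluate_population()` skips fibres whose
peak extracellular magnitude is under 5 mV; activating profiles in this
regime peak above ~60 mV, so the prescreen is an order of magnitude
below threshold, and a test verifies it changes nothing.

## VTA construction and partition

The VTA is a *direct bounding* of the API sites. The bounding algorithm
is not fully specified in the modelled study, so two modes are
provided and every comparison states its mode:

* `"hull"` — the 3-D convex hull of the API sites (quickhull, with a
  deterministic sub-nanometre jitter to break lattice degeneracies),
  voxelized on the tissue grid;
* `"alpha"` (default) — a morphological closing of the sites with a
  ball of radius alpha (default twice the axonal plane spacing, i.e.
  1 mm: the concavity scale the sampling supports), intersected with
  the convex hull. A simplicial alpha-shape would need a Delaunay
  tetrahedralization, for which no installed library exists; closing is
  the classical morphological counterpart, and because closing is
  increasing and convex sets are closing-invariant, the alpha volume is
  *provably* contained in the hull volume — the containment the
  analysis relies on. Absolute volumes are bounding-method-dependent
  either way; only within-mode comparisons are meaningful.

Masks are voxelized on the tissue model's lattice so the four-way
partition (GPi / lamina / GPe / outside) is exact in voxel counts; the
partition uses the pre-lead anatomy, so tissue under the encapsulation
is attributed to its anatomical compartment. Fewer than four
non-coplanar sites give a flagged zero-volume result. Steering is
quantified by an asymmetry index: the fraction of VTA volume in the
half-space toward the active segment's azimuth through the lead axis.

## The study sweep

`default_sweep_spec()` enumerates the 19 cells of the modelled study:
six configurations — 2B-/Case+, 2A-2B-/Case+, 2B-3B-/Case+,
2A-2B-2C-/Case+, 2B-/3A+3B+3C+, 2A-2B-2C-/3A+3B+3C+ — at 1 and 2 mA on
the 1.5 mm lead, the three vertically active configurations (2b, 4, 5)
at both amplitudes on the 0.5 mm lead, and one homogeneous-tissue cell
(configuration 4, 1.5 mm, 1 mA, all internal tissue at 0.3 S/m). The
2 mA cells reuse the 1 mA solve rescaled — exact under linearity — and
each unique (configuration, spacing, tissue mode) is solved once.

Because the phantom is not the segmented anatomy of the source study,
its printed percentages are not reproduction targets; what the package
asserts are the directional results: heterogeneity shrinks the
configuration-4 VTA relative to the homogeneous model; the 1.5 mm lead
produces larger but less GPi-concentrated VTAs than the 0.5 mm lead for
the vertically active configurations; the single-segment monopole is
the most asymmetric of the row-2 monopoles; switching the bipolar
cathode from one segment to the ring raises the GPi share; and 2 mA
VTAs exceed 1 mA VTAs everywhere.

## Numerical choices and problem sizes

The default phantom is a 60 mm cube at 0.5 mm (1.7 M voxels); the
coarse solve runs at 1 mm and the refined ROI at 0.25 mm (~1.5 M
unknowns); the sweep's axon sheet is thinned to a 10 mm plane extent
(~6,300 fibres per lead), and the oracle grids run at 0.2 mm. These
sizes were chosen so the full sweep completes on a single CPU in
minutes while keeping every tested property resolution-stable; all of
them scale up through `solver_settings()` and `axon_grid_spec()`
(electrode-edge refinement down to 0.04 mm is available via
`electrode_resolution_mm`, though not default).

Tie-breaks and degenerate inputs: rasterization precedence is fixed
(metal > insulation > encapsulation > tissue); hull construction
jitters by 1e-6 mm deterministically; a zero-flux field cannot be
current-scaled (error); an unconverged solve is an error carrying the
final residual, never a silent result. The pipeline contains no random
numbers — the sweep seed is recorded for provenance and the breakdown
CSV is byte-identical across reruns.

## Known limitations

* Purely resistive solve; no capacitive/dispersive tissue behaviour.
* Isotropic conductivities; no anisotropy tensors.
* Perpendicular straight fibres only; no parallel, curved or branched
  axons, and no cell bodies or synapses.
* Single-compartment internodes in the double cable.
* The phantom is parametric; absolute volumes and percentages do not
  transfer to segmented individual anatomy.
* Voltage-controlled solve converted by ETI impedance; no explicit
  electrode double-layer model.
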