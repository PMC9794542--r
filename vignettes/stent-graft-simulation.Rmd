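---
title: "Desk-scale simulation of thoracic stent-graft mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-scale simulation of thoracic stent-graft mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tevarsim` simulates the structural mechanics of self-expanding
thoracic stent-grafts (TEVAR endografts): superelastic Nitinol ring
frames sewn to a polyester (PET) fabric tube, crimped into a delivery
sheath, tracked along the aorta and deployed against the vessel wall.
This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the design
was open, and what the test problems do and do not demonstrate.

## The superelastic wire model

Stent rings are laser-set Nitinol wire. At body temperature the alloy
is austenitic and deforms superelastically: loading beyond a threshold
stress transforms austenite to detwinned martensite along a nearly flat
stress plateau, accumulating a recoverable transformation strain;
unloading reverses the transformation along a lower plateau, so a full
cycle closes at the origin with a hysteresis loop.

The package implements the classical one-dimensional flag-shaped law
with linear transformation kinetics in the driving stress. With
martensite fraction $\xi \in [0,1]$ and transformation direction
$s = \pm 1$,

$$\varepsilon = \frac{\sigma}{E(\xi)} + s\,\xi\,\varepsilon_L, \qquad
  \frac{1}{E(\xi)} = \frac{1-\xi}{E_A} + \frac{\xi}{E_M},$$

with forward transformation active while
$|\sigma| = \sigma_L^S + \xi(\sigma_L^E - \sigma_L^S)$ and reverse
transformation while $|\sigma| = \sigma_U^E + \xi(\sigma_U^S -
\sigma_U^E)$. Between the plateaus the response is elastic at the
phase-mixed modulus. In compression the plateau stresses are scaled by
$(1+\alpha)$, the standard tension-compression asymmetry parameter.
The strain-driven update solves the plateau consistency condition in
closed form (a quadratic in $\xi$), which makes the update exactly
rate-independent: refining a monotone strain path changes stresses at
machine precision only (`test-constitutive.R` checks this against a
ten-times-finer path).

Two modelling choices the parameter set does not determine were made
once and exposed as code, not options the data could tune:

* **Reuss (series) mixing** of the phase moduli, the common choice for
  flag-shaped models; and
* **temperature is absorbed** into the isothermal parameter set, since
  all the bench conditions the parameters describe are at body
  temperature.

The default preset `nitinol_preset("valiant_captivia_table2")` is the
calibrated wire parameter set for the Valiant Captivia ring stent
($E_A = 57{,}500$ MPa, $E_M = 47{,}800$ MPa, plateaus 550/620 and
450/250 MPa, $\varepsilon_L = 0.063$, $\nu = 0.3$, $\alpha = 0.0279$);
`"kleinstreuer2008"` is the literature starting point used by the
calibration routines.

## The graft fabric

Woven PET carries tension but offers essentially no resistance to
in-plane compression: it wrinkles. The membrane law is isotropic plane
stress ($E = 1080$ MPa longitudinal, $\nu = 0.35$, thickness 0.1 mm)
evaluated in the principal frame; compressive principal stresses are
multiplied by a `compressive_stiffness_factor` that defaults to zero
(true fabric) and recovers the classical linear membrane at one. The
verification matrix uses the factor-one variant at 1.84 MPa and
1.84 GPa, the two moduli in circulation for linearized graft models.

## Discretisation and the explicit kernel

* **Stent wire**: two-node corotational beams. The section response is
  integrated at a 2x2 Gauss rule: four fibres at $(\pm r/2, \pm r/2)$,
  which reproduces the elastic axial stiffness $EA$ and both bending
  stiffnesses $EI$ of the circular section exactly, each fibre driven
  through the superelastic (or linear) law at two Gauss stations along
  the element; torsion stays elastic at $G = E_A / 2(1+\nu)$. Local
  rotations are extracted relative to the corotated element frame, so
  rigid-body motion produces no force (verified to $10^{-9}$ N). A
  tip-loaded cantilever matches $PL^3/3EI$ within 2 percent at 20
  elements, and the discretisation error of a distributed-load case
  falls by more than a factor of three when the element count doubles.
* **Graft**: constant-strain triangles through the fabric law, no
  bending stiffness. A uniaxial patch test transfers the exact stress
  resultant.
* **Integration**: central differences with lumped masses
  (Nitinol $6.45\times 10^{-9}$, PET $1.4\times 10^{-9}$ tonne/mm^3),
  mass-proportional damping, and mass scaling to a 0.001 ms target
  step. The scaled nodal mass sums the stiffness contributions of all
  attached elements with a factor-four margin (sixteen for membranes,
  whose geometric stiffening under the large stretches of crimp and
  springback would otherwise outrun the estimate). A small
  stiffness-proportional bulk viscosity (5 percent of the elastic
  stress increment by default) damps element-local modes; without it
  the force assembly's corotational approximation can pump energy into
  high-frequency modes over long runs. Its dissipation is tracked in
  the energy ledger, which closes (external work against kinetic +
  internal + dissipated energy) within 2 percent over a full
  crimp/release protocol.
* **Quasi-statics**: loading is ramped smoothly over a pseudo-time
  long enough that kinetic energy stays far below internal energy,
  and phases end with kinetic-energy-based dynamic relaxation. The
  desk-scale pseudo-times are much shorter than a production solver
  would use, so the damping defaults of the protocol drivers
  (500-20000 /s depending on phase) are chosen for critical damping at
  these pseudo-times rather than the 0.1-1 /s a longer-duration run
  would use; they are configuration, not physics.

## Contact

Crimper jaws are twelve rigid planes tangent to the commanded cylinder
at 30-degree increments, translating radially; the radial force is the
sum of the twelve plane normal forces. Catheters, sheaths and the
idealized vessel are rigid tubes around a centerline polyline; the
sheath exposes an active arc-length window (retraction moves the
window), and the virtual-catheter tube can morph its centerline during
a phase. Contact is node-to-surface penalty with automatic stiffness
$0.1\,m/\Delta t^2$ per node (stable by construction under mass
scaling) and elastic-predictor Coulomb stick-slip friction. Defaults
follow the bench and deployment conditions: 0.3 stent-plane, 0.1
graft-plane and stent-catheter, frictionless tracking, 0.1 against the
vessel. Beam self-contact uses sphere-swept segment pairs at the wire
radius.

## Device geometry

Rings are sinusoidal zig-zags on a cylinder,
$z(\theta) = (h/2)\cos(n\theta)$. The catalogue does not print crown
heights; they are fixed, once, by requiring that the 8- and 5-peaks
rings of the 30 mm device mesh to 240 and 160 one-millimetre beam
elements at the stress-free diameter - the converged mesh counts - and
scale linearly with diameter elsewhere. The stress-free diameter is
1.17 times the sutured diameter (the +17 percent springback measured
when sutures are cut). The thin proximal ring is a circle of 0.2 mm
wire; it carries a 0.2-percent-of-diameter harmonic out-of-plane
imperfection that seeds its physical buckling mode under radial
compression (a numerically perfect circle builds up axial strain
instead of buckling, which no real wire does).

Devices assemble rings at their stress-free diameter with a graft
cylinder meshed at the sutured diameter. Sutures are merged nodes:
graft nodes are snapped onto the ring apex positions of the sutured
configuration and the pairs share translational degrees of freedom
once the ties are activated. Free-Flo devices leave the proximal
peaks ring uncovered but sewn at its distal apexes, matching how the
bare ring attaches at the graft edge; the thin ring is sutured at
every node.

The sutured configuration itself is computed by a length-preserving
"scissor" fold (`fold_ring_nodes()`): in-plane coordinates scale
radially, axial increments are recomputed so every wire segment keeps
its length. A plain radial map would compress the wire axially by the
fold ratio and store a large artificial membrane-energy term that
discharges violently when the boundary condition is released.

## Pre-stress

`apply_prestress()` moves every ring from stress-free to sutured
diameter through a prescribed displacement ramp (the fold above),
accumulating superelastic history; suture ties are then activated and
the assembly relaxed. Rings settle within a few percent of the sutured
diameter - they bow outward slightly between suture points, as the
real device does - and retain a residual stress field. A zero
pre-stress ratio reproduces a numerically stress-free assembly, and
the no-pre-stress verification variant rebuilds the device at nominal
diameter.

## Deployment protocols

* **Tracking** (the high-fidelity procedure): (I) the pre-stressed
  device is crimped into a straight catheter tube by contact; (II) the
  crimped device is advanced along the vessel centerline by a
  piecewise prescribed map built from parallel-transported centerline
  frames, bending the device - and its material history - around the
  arch; (III) the sheath window retracts proximal-to-distal so rings
  release sequentially against the vessel, while the bare ring's
  proximal apexes stay pinned (tip capture); (IV) the tip is released
  last and the device relaxed.
* **Virtual catheter** (literature comparator): a contact tube whose
  centerline morphs from the device axis onto the vessel centerline
  while its radius shrinks, crimping and bending the device in one
  phase; the tube is then removed at once. The **modified** variant
  retracts the tube gradually instead.

Runs end `"Negative"` when the bad-deformation guards trip: any wire
fibre strain beyond 40 percent; a stress-bearing membrane element
collapsed below 5 percent of its reference area, or stretched beyond
100 percent tensile strain, sustained over three consecutive checks
(single-check excursions are dynamic bounce at desk meshes; fabric
membranes are exempt from the collapse check - wrinkling collapse is
their intended stress-free response); energy divergence; or a
contact-enforcement failure, when the device still violates the
commanded catheter envelope by more than a quarter after the
crimp/morph phase. Together these operationalize the "fatal error from
extremely high and bad deformations" by which production explicit
solvers abort distorted runs.

Two desk-scale limits of the verification matrix are worth stating
plainly. The stiff linearized grafts (1.84 GPa) pleat isometrically in
this bending-free membrane formulation, so instead of crashing the
solver they complete with a device that never opens (opening-area
errors of 75-90 percent against the reference deployment); a
production solver's abort on such runs is a contact/timestep failure
that the deliberately robust desk-scale kernel does not exhibit. And
the soft linearized graft (1.84 MPa) sustains beyond-100-percent
stretch during any contact-driven crimp here, whether the crimp
belongs to the tracking or the virtual-catheter protocol, so the two
methods fail alike for that material at this scale.

## Ring crimp curves and the calibration surrogate

`run_crimp_release()` produces phase-labelled radial-force-diameter
curves from the twelve-plane bench simulation; per-plane forces are
averaged between records to suppress dynamic ringing.

Calibration re-runs a ring model at every optimizer iterate, which a
full explicit simulation cannot afford. The surrogate
(`ring_crimp_surrogate()`) freezes the *kinematic path* of one full FE
crimp/release - the fibre strain histories recorded along the run,
computed once at the literature parameter preset so the surrogate is a
well-defined model independent of the candidate - and re-drives every
fibre through the superelastic law at the candidate parameters; the
radial force is recovered from work conjugacy with the commanded
diameter, $F = -2\,\mathrm{d}W/\mathrm{d}d$. An evaluation costs
milliseconds. Its loading force runs systematically below the full FE
plane force - by roughly a third at desk-scale pseudo-times - because
the FE signal additionally carries damping and friction work that a
work-conjugate force excludes; both sides of the parameter-recovery
experiments use the same surrogate family, so this model error cancels
there.

`calibrate_nitinol()` is bounded Levenberg-Marquardt least squares on
a log/log-gap reparametrisation ($\log E_A$, $\log E_M$,
$\log \sigma_U^E$ and the logs of the three plateau gaps), which
enforces the plateau ordering structurally. Plateau gaps vary over an
order of magnitude across the literature, so they get wider
multiplicative bounds than the moduli. On noiseless synthetic curves
every free parameter is recovered with below one percent bias; with
one percent multiplicative force noise the moduli come back well
within five percent.

The working-range percent error between two curves resamples both on a
uniform 50-point diameter grid per phase (the resampling the error
statistic needs but no convention fixes) and reports mean and standard
deviation across the grid of $|F_{sim}-F_{ref}|/F_{ref}$.

## Validation metrics

Ring opening areas (OA) are evaluated exactly as in the imaging
comparison: the proximal apexes of each ring (local axial maxima of
the wire; sixteen uniform samples for the thin ring) are projected on
their principal-component best-fit plane, a chord-length-parametrised
periodic cubic spline is fit through them, resampled at 1000 points,
and the enclosed area taken by Green's theorem. Percent errors are
absolute values, summarised as mean, standard deviation, minimum and
maximum. Strut alignment uses the one-sided Hausdorff distance from
simulated strut vertices to the reference polyline, reported in
millimetres (and interpretable against the wire diameter); deployed
length is the arc-length extent of the stent nodes projected on the
vessel centerline.

In place of the CT segmentations (not published as data),
`gen_pseudo_segmentation()` perturbs the simulated strut polylines and
apex sets with seeded isotropic Gaussian noise - a synthetic stand-in
that exercises the metric pipeline but carries no imaging physics.

## Problem sizes

The package's test problems are deliberately desk-scale, chosen so the
full suite runs on a single CPU in minutes: single-ring bench
simulations use the full 240-element 8-peaks ring; deployment and the
verification matrix run a reduced five-ring Free-Flo device (24 mm x
60 mm, 2 mm wire elements, 2.5 mm graft elements, about 1100 nodes)
inside an analytic curved tube of 21 mm diameter with a 7.5 mm
catheter. Full-size devices mesh and export identically
(`device_preset("A")` through `"C"`); only their transient simulations
exceed a desk budget. Consequences of the reduced scale worth keeping
in mind: suture spacing is coarser, so rings bow more between ties;
deployment opening areas carry a larger dynamic scatter; and the
Positive/Negative pattern of the verification matrix is a qualitative,
not quantitative, reproduction.

## What the synthetic generators do and do not show

`gen_synthetic_curve()` adds multiplicative Gaussian noise to a model
curve - it emulates the magnitude structure of a bench radial-force
measurement but not drift, hysteresis of the rig, or temperature
excursions. The pseudo-segmentation emulates segmentation jitter but
not systematic imaging artefacts. Passing the recovery and metric
tests therefore demonstrates identifiability and correctness of the
pipelines under the stated noise model, not robustness to real
instrument error.

## Known limitations

Hughes-Liu beams are replaced by corotational Euler-Bernoulli fibre
beams (same section integration contract); the proprietary "soft
constraint" contact scaling is replaced by the explicit mass-based
penalty; the aorta is rigid and analytic; guidewire, blood pressure
and vessel compliance are out of scope; taper and curved device
variants are not generated. The sheath retraction speed and
tip-capture timing are schedule parameters with package defaults, not
manufacturer values.
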