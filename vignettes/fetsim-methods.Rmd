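---
title: "Models and numerical methods in fetsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in fetsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`fetsim` simulates the mechanical environment at the distal edge of a
frozen elephant trunk (FET) prosthesis in an idealized aorta: the elastic
recoil of the stented segment against the wall, and the pulsatile flow
through the recoiled lumen. This vignette is the package's own account of
the models, the numerical choices, and what a green test does and does not
establish.

## The stated world

All inputs are parametric; the geometry module is the synthetic-data
generator for every downstream stage. Defaults:

| quantity | value | unit |
|---|---|---|
| arch centerline radius | 50 | mm |
| descending length | 400 | mm |
| inner diameter / wall | 30 / 2 | mm |
| device wall / skeleton length | 1.75 / 50 | mm |
| oversizing sweep | 0–30 (step 5) | % |
| E wall / skeleton / polyester | 1 / 5 / 1780 | MPa |
| Poisson ratio | 0.48 | – |
| luminal pressure | 100 | mmHg |
| viscosity / density | 0.004 / 1050 | Pa s, kg/m^3 |
| heart rate / stroke volume | 75 / 53 | bpm, ml |

Three quantities the idealization needs but the stated world leaves open
were fixed once and are configurable:

* **Arch span 180 degrees** — the ascending limb plus arch as a half
  circle, matching the model's silhouette.
* **Skeleton landing**: half of the 50 mm skeleton on the distal arch,
  half on the straight descending segment. Some arc coverage is a
  *requirement*, not a preference: a straight device deployed into an
  entirely straight segment stores no bending energy and cannot recoil.
  The proximal anastomosis sits at 90 degrees of arch.
* **Branch anatomy**: three equal 10 mm branches on the superior arch at
  100/115/130 degrees, symmetric about the sagittal plane, each serving as
  a 50 mm outlet extension.

## Structural stage

### Reduction

The deploy–release problem is solved in the sagittal symmetry plane. The
aorta and the skeleton are planar **co-rotational Euler–Bernoulli beams**
with thin-walled-tube section properties (A = 2 pi r t, I = pi r^3 t); the
constitutive law is linear elastic, the kinematics are large-rotation —
linear kinematics cannot represent straightening, the co-rotational frame
can (the element suite rolls a beam into a closed circle under a tip
moment of 2 pi EI / L to machine precision). Cross-section behaviour
(pressurization, press-fit, local denting) is carried by classical
ring/shell theory, anchored to an axisymmetric thick-wall finite-element
solution of the pressurized annulus. The full 3-D parametric geometry
(swept meshes, branch stitching, watertightness, volume meshing) is
retained for model export and checks; the equilibrium solve itself is
planar.

What this keeps: the bending equilibrium between device and wall, the
contact force distribution along the edge, the hoop-stress field on both
curvature paths. What it gives up: non-axisymmetric ovalization, the exact
circumferential footprint of the edge, torsion.

### Contact as physics, not as a numerical trick

Contact between the skeleton and the wall is frictionless, compressive
only, node-to-curve with a two-sided clearance band (the pressurized lumen
radius minus the device outer radius). The penalty stiffness is **not**
arbitrary: it is the lateral ring stiffness of the wall per unit length,
k = (pi/2) E' t / r (cosine-weighted ring compression over the loaded half
circumference, E' = E/(1-nu^2)). Band penetration therefore *is* the local
radial wall distension, and is exactly what the stress recovery consumes.
There is no residual-penetration error to apologize for; the trade is that
contact stiffness carries a mechanical idealization rather than a
numerical one.

### Protocol

1. **Deploy**: the skeleton (stress-free straight, root clamped at the
   graft junction) is forcibly displaced so its axis interpolates onto the
   aortic centerline over N increments (default 10). Contact is inactive
   during this fictitious intermediate path — clinically the device is
   sheathed while positioned — and engages at release. At 0% oversizing
   the deployed state is a conforming fit with ~zero tractions.
2. **Release**: the retaining reactions are unloaded over N continuation
   steps; each step is equilibrated by damped Newton (line search on the
   residual norm, relative tolerance 1e-6 with an absolute floor of
   1e-8 N). Internal pressure is held throughout; on the beam the lateral
   pressure resultant of a capped curved tube cancels against wall axial
   tension, so pressure enters through the ring reference state only.
3. The rigid polyester graft clamps the skeleton root; the elastic
   variant (E = 1.78 GPa) replaces the rotation clamp by the graft's
   bending-spring stiffness, three orders stiffer than the skeleton — the
   two variants agree on the stress profiles to a few percent, which the
   suite asserts at 5%.

### Stress recovery

The hoop stress on a curvature path is reconstructed from the wall
distension field w(s):

* pressurization: w_p and the through-thickness average stress from the
  axisymmetric FEM (which reproduces the Lamé closed form and whose
  average equals the Laplace value p r_i / t);
* press-fit in the stented region: linear two-ring contact compatibility
  between the pressurized skeleton and the pressurized wall;
* recoil: the contact penetrations deposited at their wall stations, each
  decaying with the shell boundary-layer shape function
  e^(-beta s)(cos + sin), beta = (3(1-nu^2)/(r^2 t^2))^(1/4) (decay length
  about 4.6 mm); overlapping deposits combine by envelope since each
  penetration already includes its neighbours' contribution. The step
  between stented and free regions is smoothed by the same kernel.

Stress scales linearly with distension, anchored at the verified FEM
state: sigma(s) = sigma_avg * w(s) / w_p. The lesser-curvature path sees
only pressurization and press-fit (the device pulls away from it), which
is why it barely changes after recoil — the suite asserts its change is
under 20% of the greater-curvature change.

## Flow stage

### Reduction

Two streamfunction–vorticity modes share one architecture (explicit
first-order upwind advection, implicit diffusion via a prefactored sparse
Helmholtz solve, Thom wall vorticity):

* **axisymmetric** (z, r) on a straight tube — the untreated descending
  aorta and all closed-form benchmarks (steady tube flow within 1% of the
  Poiseuille wall shear; oscillatory flow within 2% of the analytic
  pulsatile profile at Womersley number 3, converging under refinement);
* **planar**, on a body-fitted grid between the two sagittal wall lines of
  the recoiled lumen — bore of the device centered on the deformed
  skeleton axis, native wall displaced by the beam solution and distended
  by the recovered fields, the lesser-curvature step at the edge forming
  the notch pocket (the step is smoothed over ~2 mm, about one cell). The
  FEM Laplacian of the mapped grid serves both the streamfunction Poisson
  solve and the diffusion operator, so no orthogonality assumption is
  made.

The planar discharge is scaled as Q2 = 2 Q / (pi r_bore) so the mean inlet
velocity matches the tube value; 2-D wall shear then carries tube-like
boundary-layer physics (the Stokes layer is a near-wall phenomenon), at
the price of an O(r_native/r_bore) distortion (~6% at 15% oversizing) in
the downstream plateau. Locations (the argmax of WSS along the
greater-curvature path) are the robust planar outputs; absolute treated
WSS levels are indicative.

### Boundary conditions and 0D coupling

The inlet waveform is a half-sine systole over 35% of the cycle, zero
diastolic flow, integral exactly one stroke volume; the inlet profile is
parabolic (plug available). Walls are rigid and no-slip. Each outlet
carries a three-element Windkessel model, backward-Euler in time, which
matches its exponential and impedance closed forms to first order in dt.

Calibration is from first principles: total resistance = mean pressure /
mean inflow (2.012e8 Pa s m^-3 at the defaults); splits 5/5/5/85% across
the three branches and the descending outlet; the proximal fraction is
characteristic-impedance sized (5% nominal, automatically reduced — to 3%
at the defaults — when the systolic spike alone would overshoot the
window); total compliance is tuned by bisection on a lumped 0D simulation
until the converged systolic peak sits at the window top (120 mmHg), and
the diastolic minimum is verified above the floor (80 mmHg). Because
resistance and compliance are split proportionally, all outlets share one
RC time constant: the instantaneous flow split then equals the calibrated
fractions exactly, the 0D arch junction conserves mass identically, and
the branch Windkessels can be advanced from the same split — this is the
reduced form of the 0D–3D exchange, whose contract (flows in, pressures
back, order-independent, values exchanged exactly) is tested directly.
With rigid walls and prescribed inflow, the velocity field is independent
of the pressure level, so the coupled single-outlet tube reproduces the
pure-0D pressure solution to round-off — also asserted.

Runs start from the cyclically converged 0D state and from fluid at rest;
two cycles suffice for the pressure traces to repeat within 1% (checked by
`check_cyclic_convergence`) and for the field transient to decay. All
metrics are taken on the last cycle; "peak systole" is the stored frame
nearest t_peak of that cycle (40 frames per cycle).

## Metrics

OSI is the canonical 0.5 (1 - |integral tau dt| / integral |tau| dt), in
[0, 0.5], 0 where shear never reverses; WSSD is the tangent-plane
divergence of the wall shear (P1 finite elements on a triangulated
surface for 3-D fields; the streamwise derivative along a path in the
planar reduction). Path profiles are sampled at 1 mm; threshold crossings
for the high-WSS length (threshold 1.7 Pa, the untreated plateau) are
located by linear interpolation and samples exactly at the threshold do
not count. The notch is measured geometrically in the sagittal plane
(area between the device's outer lesser wall and the native wall), with a
flow corroboration: the cycle-mean speed in the pocket relative to the
core (about 0.5 at 0% oversizing, rising with rate — less stagnation for
larger devices). The reported WSS figures are peak-systolic (consistent
with reading streamline fields at peak systole); time-averaged WSS is
also emitted.

Monotone trends over the seven-rate sweep are asserted as Spearman rank
correlations with |rho| >= 0.6. Measured at the coarse preset: hoop-stress
maximum +1.0, bending angle +1.0, notch area -1.0, high-WSS length -0.96,
WSS maximum -0.68. The last is the one genuinely soft trend: at high
oversizing the stiffer, more interfering device recoils harder, and the
sharper jet deflection partially offsets the slower bore velocity, so the
maximum WSS plateaus rather than falling monotonically between 15% and
30%. We report this as a property of the reduced model rather than
adjusting it away.

## Numerical choices and degenerate inputs

* Structural Newton: relative residual 1e-6, absolute floor 1e-8 N (for
  vanishing-stiffness limit checks), backtracking line search, 10 deploy
  and 10 release increments at the coarse preset.
* Flow time step 0.5 ms at the coarse preset, halved automatically (with a
  warning) on CFL violation; diffusion implicit so the near-wall grid does
  not constrain dt; radial/wall clustering by tanh stretch (strength 1.3
  axisymmetric, 1.8 planar).
* Zero wall thickness yields an empty wall mesh and a valid lumen; zero
  pressure zeroes the reference distension; zero descending length ends
  the centerline at the arch with a vertical tangent; all-zero shear
  series define OSI = 0 (logged).
* Meshing is deterministic; the `--seed` accepted by the acceptance
  script is set for contract compliance but does not alter results.

## What a green suite establishes — and what it does not

The suite establishes that the implemented equations are solved correctly
(closed-form oracles at 1–5%), that the pipeline reproduces the
qualitative mechanics of device recoil (edge stress concentration growing
with oversizing; WSS elevation displaced ~10 mm downstream and growing
with undersizing; notch shrinking with oversizing; physiological pressure
envelope), and that the headline numbers of the idealized experiment are
recovered at desk scale. It does **not** establish patient-level validity:
the geometry is idealized (no torsion, no dissection flap), the wall is
isotropic linear elastic with no residual stress, the flow is laminar with
rigid walls, and the planar flow reduction cannot resolve secondary
(Dean-type) vortices or true circumferential WSS variation. Those are the known limits of the idealization itself, plus the
dimensional reductions specific to this package.
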