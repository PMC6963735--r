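---
title: "Methods: two-DOF fin kinematics and vortex-wake analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-DOF fin kinematics and vortex-wake analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(finwake)
```

## The kinematic model

A two degree-of-freedom swimmer model pitches its tail section through
`theta_T(t) = theta_T0 sin(2 pi f t + phi)` about the tail pivot and its
caudal fin through `theta_C(t) = theta_C0 sin(2 pi f t)` about the peduncle
joint, the tail leading the fin by the phase offset `phi` (degrees). The
lateral trailing-edge (TE) excursion follows from the two-link geometry,

```
a(t) = L_T sin(theta_T(t)) + c sin(theta_T(t) + theta_C(t)),
```

with `L_T` the tail length and `c` the midspan fin chord. Angles are kept
in degrees throughout the interface (the convention of the pitching-foil
literature) and converted to radians only inside trigonometric
evaluations.

Measured angle traces sit about a non-zero mean because of mounting
misalignment; the package models the misalignments `delta_theta_T`,
`delta_theta_C` as additive constants. They are included in the angle
traces (that is what a protractor on the rig would read) but excluded from
the excursion evaluation by default, since the tabulated excursion
amplitude `A` describes the oscillatory motion; `include_misalignment =
TRUE` switches them in. `fit_sinusoid_with_offset` recovers amplitude,
phase and misalignment by linear least squares with the frequency fixed at
the commanded value (1 Hz here) rather than fitted — the comparison of
interest is against the prescribed motion, and fixing `f` keeps the model
linear and the fit exact on its own model class.

Nondimensional numbers: `St = f A / U` uses the peak TE excursion as the
wake-width scale; `Re = U L / nu` uses the body length. `L_T = 0.26` m,
`c = 0.105` m, `L = 0.285` m and `nu = 1e-6` m²/s are package estimates
chosen for consistency with the tabulated cases: the two single-DOF rows
of the case table pin the lever arms (`c sin(12.90°) ≈ 25 mm` for pure fin
motion, `(L_T + c) sin(3.4°) ≈ 22 mm` for pure tail motion), and `L`
reproduces the reported Reynolds numbers of 17,000 and 23,000 at the two
tunnel speeds. These lengths are configuration inputs, not measured
constants, and can be overridden per case in the table (`LT_m, c_m, L_m,
nu_m2_s` columns).

The cycle is segmented into acceleration and deceleration intervals by the
sign of `d|v|/dt` of the TE velocity, with boundaries at local extrema of
the speed; a pure sinusoid yields four alternating quarter-cycle
intervals. TE velocity is differentiated by centred differences with
periodic wraparound, appropriate because phase-averaged traces are
periodic by construction. Amplitude extrema (the half-cycle boundaries)
are located as linearly interpolated zero crossings of the velocity.

Nonsinusoidal, square-like TE motion is represented by `dwell_waveform`: a
sinusoid time-warped to hold at each amplitude extreme for a prescribed
fraction of the half-cycle (`dwell_fraction`, default 0; 0.3 in the
square-like scenario preset). The warp is piecewise linear in phase, so
the waveform stays periodic and odd-symmetric, reduces exactly to the
sinusoid at zero dwell, and has an analytic derivative for oracle tests.
No parametric form of the real drive-compliance discrepancy exists, so
this is a declared stand-in with one interpretable parameter.

## Field operators

Spanwise vorticity and the two-dimensional Q-criterion are computed from
the in-plane 2×2 velocity-gradient tensor with second-order centred
differences, falling back to one-sided differences at domain boundaries
and mask edges (mask-adjacent values are therefore first-order accurate),
and propagating the mask where no neighbour exists. The centred scheme is
exact for linear fields — solid-body rotation gives `wz = 2 Omega` and
`Q = Omega^2` to round-off, pure shear gives `Q = 0` — and both operators
are invariant under uniform velocity offsets to 1e-12.

Two-dimensional Q (no out-of-plane derivatives) is used even when a third
velocity component is carried: planar data provides no `d/dz`, and the
figure-style contours this reproduces are explicitly two-dimensional.

For a Gaussian-core (Lamb-Oseen) vortex resolved at five grid cells per
core radius, the discretisation error of the centred scheme is about 2 %
of the peak for vorticity and 4 % for Q in max norm, and about 0.1 % in
peak-normalised RMS; the max-norm error falls to 1 % at roughly seven
cells per core radius. The tests freeze these oracle-computed bounds
rather than a nominal figure, and headline comparisons use the
peak-normalised RMS, the natural norm for field agreement.

Phase averaging bins frame `k` (0-based, rate `f_s`) of a motion at
frequency `f` into bin `(k n f / f_s) mod n` of an `n`-bin cycle and
requires the stride `n f / f_s` to be integral (12.5 Hz frames of a 1 Hz
motion with 25 bins give stride 2: every other phase is sampled
instantaneously and the cycle fills over two periods). Non-commensurate
requests fail with the nearest valid bin counts. Stitching of two
overlapping measurement domains requires a common grid lattice and phase
set; overlap nodes are averaged by default (`overlap = "primary"` keeps
the first series), since no blending rule is canonical. The time-averaged
momentum surplus is the per-node phase mean of `u/Uinf - 1` with occluded
phases excluded from the mean.

## Vortex structures

Structures are 8-connected components of `Q >= threshold` over unmasked
nodes; 8-connectivity is used because contour-like regions fragment under
4-connectivity on coarse grids. The default threshold is 1 % of the global
maximum Q over the whole series (not per frame), floored at a configurable
absolute minimum — on the experimental scale this reproduces the 1 1/s²
lowest contour. Per structure the package records the Q-weighted centroid,
peak Q, area, the vorticity integral over its nodes (with its sign), and
physical node coordinates.

Because Q > 0 only inside the rotation-dominated core (radius ≈ 1.12 rc
for a Lamb-Oseen vortex, holding ~71 % of its circulation), the
structure-node vorticity integral systematically understates per-vortex
circulation. `vortex_circulation` therefore integrates vorticity over the
connected sign-matching region `|wz| >= 1` 1/s around the structure — the
same floor used by the circulation budget — and recovers resolved,
well-separated vortices to better than 10 %.

LEV attachment: a structure is attached while no gap separates its lowest
contour from the fin, operationalised as a minimum grid (Chebyshev)
distance of at most one cell between structure nodes and fin-mask nodes.
Tracking is greedy nearest-predicted-centroid matching (prediction =
previous centroid + advection guess × bin width) with a same-sign
constraint and a configurable gating radius; ties break by distance, then
circulation magnitude. The shedding time of a tracked vortex is the
midpoint of the interval between the last phase at which its structure
lies within `gap_cells` (default 1) of a TE disk (default 3 cells) and the
first phase at which it does not — the geometric proxy for pinch-off of
the feeding shear layer — reported with a half-bin uncertainty, the
temporal resolution of the dataset. Trajectories are total-least-squares
lines through track centroids (principal component), with the angle
reported against the downstream axis in (-90°, 90°].

## Circulation budget

The production history integrates vorticity above a 1 1/s magnitude
threshold, per sign, inside a rectangle whose upstream and transverse
boundaries are fixed while the downstream boundary advects at the
approximate vortex advection speed — by default the freestream, the
simplest defensible estimate, overridable by a speed fitted from tracks.
The transverse extent defaults to the full domain height. Because the
boundary moves with the shed vortices, circulation captured in one
half-cycle neither leaves nor is double-counted later; the history rises
during the half-cycle and plateaus, and the per-half-cycle total is the
maximum over a window from the half-cycle start (optionally led by
`onset_lead = 0.12` cycles, since vorticity production begins slightly
before the TE reverses) to `lag = 0.25` cycles past its end — a windowed
maximum rather than slope-based plateau detection, which is fragile at 25
samples per cycle. Histories that never rise above their window-start
value are flagged. Half-cycle boundaries come from the TE-trace extrema.

With a 1 1/s floor, a Lamb-Oseen vortex loses exactly `pi rc^2 × 1` m²/s
of sub-threshold tail (2.5e-4 m²/s at rc = 9 mm) regardless of strength,
so the relative bias of a half-cycle total scales with the number of
vortices over the injected circulation; the scenario strengths below keep
it under ~3 %.

## The synthetic wake generator

The generator emulates the statistical structure of phase-averaged planar
wake data: 25 phases per cycle, 1.78 mm grid spacing, a 0.34 m × 0.26 m
domain, a rotating-rectangle fin mask (pivot at the peduncle, chord c,
6 mm thickness — the real planform is only drawn, never tabulated), a
freestream of 81.5 or 59.5 mm/s, and iid Gaussian velocity noise per node
per phase (default 0.2 mm/s, the order of phase-averaged residual
turbulence at ~0.5 % intensity). Vortices are Lamb-Oseen, chosen for the
regular core and analytic circulation. Output is a pure function of
(scenario, seed); the caller's RNG state is untouched.

Each scripted trailing-edge vortex has a life cycle: from
`formation_phase` its total circulation ramps linearly to the prescribed
value at `shed_phase`; during formation it is represented as a core at a
standoff that migrates from 8 mm to ~20 mm downstream of the shedding
origin plus two small feeder vortices along the feeding shear layer, so
the thresholded Q region stays connected to the TE; at `shed_phase` the
feeders are entrained into the core (circulation conserved) and the core
advects ballistically. Copies from previous cycles (`n_history = 2`) and
the next cycle's pre-onset formation populate the field so the sampled
cycle is in periodic steady state. Scripted LEVs ride the fin at a fixed
chordwise station while attached and, at `detach_phase`, jump one
detachment length clear of the fin and decay — the discrete-phase
equivalent of the gap opening within one phase bin.

Preset layouts: *case-4-like* (sinusoidal TE; one primary of 1.6e-2 m²/s
plus two secondaries of 5e-3 m²/s per half-cycle, shed at t/T = 0.70,
0.80, 0.88, cores rc = 9 mm ≈ 5 cells) exercises the circulation budget;
*case-1-like* (square-like TE, dwell fraction 0.3; a weak early secondary
on an inclined path shed at 0.56 and a strong late primary at 0.81)
exercises tracking and trajectory recovery; *shedding* (one primary per
half-cycle shed at 0.70 plus an LEV detaching at 0.80) exercises
shedding-time and attachment recovery. Strengths put peak core vorticity
at 20–60× the 1 1/s threshold, as in well-resolved measurements, and the
shed vortices organise into two rows at ±10 mm about the wake axis — the
relaxed reverse-Kármán street — which keeps opposite-sign tail overlap
small enough that the injected circulation is recoverable. The street
spacing is one wake wavelength `U/f` per cycle, so the slower tunnel
speed packs structures more tightly and is the harder recovery case.

What the generator does *not* emulate: viscous core growth and
dissipation over the cycle (an optional decay acts only on detached
LEVs), deformation and merging of real vortices, shear-layer braids
between structures (ideal shear layers are invisible to Q in any case),
three-dimensional effects across planes, and correlated measurement noise
near the mask. Passing recovery tests therefore demonstrates that the
estimators are unbiased at the scripted geometry and noise level, not
that real-wake interaction effects are negligible.

## Numerical and design choices

- Coordinates: x downstream, y lateral (TE motion), z spanwise; origin at
  the fin pivot's streamwise station; SI units (m, s); angles in degrees
  at the interface.
- The TE waveform of a scenario places the positive amplitude extreme at
  t/T = 0.5, so half-cycles are [0, 0.5) and [0.5, 1).
- Connected components by vectorised 8-neighbour minimum-label
  propagation; iterations scale with component diameter, which is tens of
  cells here.
- The phase-series container is a self-describing delimited text file
  (versioned schema line, JSON attribute header, long-format node table at
  17 significant digits, so roundtrips are bit-identical); per-phase
  delimited exports carry 7 significant digits. One container per
  spanwise plane per case, `plane_z` recorded in metres.
- A case table stores A in mm and U in mm/s (as tabulated) and converts
  to SI on read; a missing phase offset ("-") reads as zero; the stored
  Strouhal column is recomputed and mismatches beyond 0.001 warn.
- Degenerate inputs: all-zero TE velocity yields a single flagged
  "constant" interval; both component amplitudes zero makes the resultant
  phase undefined and flagged; an all-subthreshold Q field yields an empty
  structure list; an empty fin mask is an error for attachment tests.

## Problem sizes

The test suite and acceptance script run the full 192 × 147 × 25 grid for
scenario-based recovery (about 1 s to generate and 2 s to analyse per
scenario) and small analytic grids (41–101 nodes per side) for operator
checks; recovery studies use ten seeds per scenario and three per
freestream comparison arm. The whole suite completes in about a minute on
one core.

## Known limitations

- The shedding-time estimator assumes the tracked structure stays a
  single connected component; when same-sign structures merge (close
  packing at low freestream), the connectivity proxy can report late.
- Per-vortex circulation via the 1 1/s region assumes vortices are
  separated by more than the sum of their threshold radii; overlapping
  regions are attributed to the containing component.
- `half_cycle_totals` reads a windowed maximum; for histories that decay
  quickly after shedding (strong dissipation) the plateau reading biases
  low, and the no-rise flag should be checked.
- The sinusoid fit fixes the frequency; drifting motor frequency would
  alias into the residual rather than the fit.
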