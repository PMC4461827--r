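---
title: "A static kinematic model of 3-D head-free gaze shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A static kinematic model of 3-D head-free gaze shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazekin)
```

## The problem

When the head is free to move, redirecting the line of sight to a visual
target is a coordinated act: a rapid saccade of the eye in the head, a
slower head rotation that carries the eye with it, and a vestibulo-ocular
reflex (VOR) that counter-rotates the eye while the head finishes its
movement so that gaze stays on target. Because 3-D rotations do not
commute, the torsional state of the eye and head after such a movement is
not arbitrary: behaviorally, the final eye-in-head orientation obeys
Listing's law (its rotation axis from primary position lies in a
head-fixed plane, i.e. zero torsion in axis-angle coordinates) and the
final head orientation obeys the Fick strategy (zero torsion when the
orientation is decomposed as vertical-axis, then horizontal-axis, then
torsional rotations). `gazekin` implements a static kinematic model that
plans gaze shifts satisfying both constraints exactly while foveating the
target, and simulates the resulting trajectories.

## Frames, orientations and inputs

All orientations are active 3 x 3 rotation matrices acting on
reference-condition vectors. The frame is right-handed with $x$ forward
(the reference gaze direction), $y$ left and $z$ up; angles are degrees at
every interface. The eye-in-head orientation $E$, head-in-space
orientation $H$ and gaze (eye-in-space) orientation $G$ satisfy

$$G = H\,E ,$$

and the gaze direction is $\hat g = G\,[1,0,0]^T$. A direction with
azimuth $\gamma$ (positive leftward) and elevation $\eta$ is
$[\cos\eta\cos\gamma,\ \cos\eta\sin\gamma,\ \sin\eta]$. Targets may be
given three ways, all converging on a desired gaze direction $\hat g_d$:

* **screen offsets** $(a, b)$ in cm on a flat screen orthogonal to $x$ at
  distance $t$ (default 100 cm, configurable — the choice only scales the
  cm-to-degree conversion): $\hat g_d \propto [t, a, b]$. The inverse map
  used for reporting gaze-screen intersections is the central projection
  $a = t\,g_y/g_x$, which is the exact inverse of the forward map; a raw
  component scaling $a = t\,g_y$ is retained as an explicitly labelled
  `"orthographic"` variant because it appears in the literature, but it is
  not self-consistent and is never used internally.
* **angular position** $(\gamma, \eta)$ directly.
* **retinal error**: an eye-fixed direction $\hat g_{RE}$, mapped to space
  by the current gaze orientation, $\hat g_d = G_i\, \hat g_{RE}$. This is
  the physiologically primary input: the same retinal stimulation from
  different initial orientations demands different movements, and the
  model performs that reference-frame transformation exactly.

## The three-stage model

A planned shift is decomposed into three sequenced mechanisms:

| stage | eye-in-head | head | gaze |
|---|---|---|---|
| initial | $E_i$ | $H_i$ | $H_iE_i$ |
| 1 saccade | $R_eE_i$ | $H_i$ | $H_iR_eE_i$ |
| 2 eye-carrying head rotation | $R_eE_i$ | $R_hH_i$ | $R_hH_iR_eE_i$ |
| 3 VOR-stabilized head rotation | $R_vR_eE_i$ | $R_wR_hH_i$ | $R_wR_hH_iR_vR_eE_i$ |

so the desired orientations are $E_d = R_vR_eE_i$, $H_d = R_wR_hH_i$,
$G_d = H_dE_d$. The solver works backwards from the constraints:

1. **Head goal.** The desired 2-D head direction interpolates between the
   initial head direction $b_i$ and the desired gaze direction $c_d$
   componentwise: $b_d = b_i + (\alpha, \beta)\odot(c_d - b_i)$, where
   $\alpha$ and $\beta$ are the horizontal and vertical head-contribution
   weights. $H_d$ is then the unique zero-Fick-torsion orientation
   pointing along $b_d$.
2. **Single head rotation.** The head executes one fixed-axis rotation
   $R_t = H_dH_i^{-1}$, split about its axis into a gaze-contributing
   phase $R_h$ (magnitude $\delta\tau$) and a VOR-cancelled phase $R_w$
   (magnitude $(1-\delta)\tau$), $R_t = R_wR_h$.
3. **Eye goal.** The remaining direction $\hat e_d = H_d^{-1}\hat g_d$ is
   assigned the unique Listing orientation $E_d$ (rotation axis in the
   $x = 0$ plane) pointing along it.
4. **Predicted VOR and saccade.** Perfect gaze stability during stage 3
   forces $R_v = H_i^{-1}R_h^{-1}R_w^{-1}R_hH_i$; the saccade then
   pre-compensates it, $R_e = R_v^{-1}(E_dE_i^{-1})$. The saccade
   therefore carries transient torsion out of Listing's plane that the
   oncoming VOR exactly cancels — a prediction, not a correction.

Two structural consequences are worth stating because the test suite
asserts them: the endpoints $E_d, H_d, G_d$ do not depend on $\delta$ at
all (only the saccade/VOR split does), and they do not depend on the
timing of execution.

## Parameters

| parameter | meaning | units | default |
|---|---|---|---|
| $\alpha$ | horizontal head contribution | — | 0.5 |
| $\beta$ | vertical head contribution | — | 0.5 |
| $\delta$ | fraction of head rotation inside the gaze shift | — | 0.5 |
| $t$ | eye-screen distance | cm | 100 |

$\alpha, \beta, \delta$ are naturally open-interval $(0,1)$ quantities;
the boundary values are accepted and closed by their exact limits
($\alpha=\beta=0$: head-fixed saccade, $H_d = H_i$; $\alpha=\beta=1$: head
on target and eye back at primary position, $E_d = I$; $\delta=1$: no VOR
stage). The defaults are the mid-range values used for all headline
simulations.

## Trajectories

`simulate()` on a plan discretizes time (default 200 samples): the
saccade is a partial fixed-axis rotation of magnitude
$g(s)\,\tau_{R_e}$; the head is a partial fixed-axis rotation along the
$R_t$ axis, covering $\delta\tau$ during phase 1 and the remainder during
phase 2; during phase 2 the eye is re-solved every sample as
$E(t) = H(t)^{-1}G_d$ — an ideal VOR whose rotation axis is determined
online by the instantaneous head orientation, which keeps the full 3-D
gaze orientation (not merely its direction) frozen. Growth functions
$g(s)$ (smoothstep default, linear available) are monotone 0-to-1 maps;
their shape is immaterial to every endpoint property, which is why no
attempt is made at physiological velocity profiles. One growth function is
applied per head phase rather than across the union of both phases: the
phase boundary must fall exactly at the fraction $\delta$ of the head
magnitude for the VOR stage to be well-defined under independently chosen
phase durations, so the boundary is a position-continuous, labelled time
point. Default timing (saccade 0–100 ms, head phase 1 0–150 ms, phase 2
150–400 ms) is arbitrary and configurable; the only structural requirement
is that the saccade ends no later than phase 2 begins.

```{r}
plan <- plan_gaze_shift(eye_head_state(), list(gamma = 40, eta = 40),
                        gaze_params(0.5, 0.5, 0.5))
df <- as.data.frame(simulate(plan, n = 200))
range(df$eye_tor)          # transient saccadic torsion, zero at both ends
max(abs(df$head_fick_psi)) # head leaves the Fick surface mid-flight
```

## Orientation ranges and the bow-tie

Sweeping a grid of targets from the reference condition
(`run_range_scan()`) reproduces the characteristic final-orientation
ranges: the eye-in-head torsion is identically zero (Listing), while the
head's rotation-vector torsion traces a "bow-tie" against its horizontal
component. On the zero-Fick-torsion surface this bow-tie is exact, not
approximate: writing the orientation as a unit quaternion, the torsional
component equals $-\sin(\theta/2)\sin(\phi/2)$ for Fick angles
$(\theta, \phi)$ — the acceptance suite checks this identity to $10^{-12}$
across the full scan. `twist_score()` summarizes a range by the
least-squares coefficient $k$ in
$\text{torsion} \approx k\cdot(\text{horizontal}\times\text{vertical})$;
under this package's sign conventions $k<0$ is Fick-like and $k>0$
Helmholtz-like. Gaze torsion is an emergent property: near-zero head
contribution gives a near-Listing gaze range, near-full head contribution
makes the gaze range inherit the head's bow-tie, and opposite
horizontal/vertical head anisotropies ($\alpha=0.95,\beta=0.05$ versus
$\alpha=0.05,\beta=0.95$) flip the sign of the gaze twist — the system
degenerates towards a true Fick gimbal or a Helmholtz arrangement,
respectively.

## Numerical choices

* Angle recovery uses `atan2` throughout (`asin`/`acos` only where the
  argument is bounded away from 1); the Listing orientation's magnitude is
  $\operatorname{atan2}(\|e_{yz}\|, e_x)$, well-conditioned at primary
  position, which makes the $\alpha=\beta=1$ closure exact to machine
  precision.
* `axis_angle_of` resolves degeneracies deterministically: the identity
  returns axis $(0,0,1)$ with zero magnitude; within $10^{-4}$ rad of
  180° the axis is extracted from the well-conditioned symmetric part
  $\tfrac12(R+R^T) - \cos\tau\, I = (1-\cos\tau)\,uu^T$, with the sign
  fixed by the antisymmetric part when it is nonzero and by the
  largest-magnitude-component-positive convention at exactly 180°.
* `orthonormalize()` projects drifting products back onto the rotation
  group via the SVD polar factor; the planner itself never needs it
  (products of at most six exact rotations stay orthonormal to ~1e-15).
* Reachability: the planner raises an error whenever the desired gaze,
  head, or eye-in-head direction leaves the front hemisphere rather than
  extrapolating beyond the model's domain.
* Gimbal lock ($|\phi| = 90°$) and the 180°-from-primary eye direction are
  rejected with specific errors.

## What the generator emulates

`random_fixtures()` draws initial states as a natural fixation would leave
them: eye-in-head orientations exactly in Listing's plane, head
orientations with exactly zero Fick torsion, eye and head direction
eccentricities uniform on spherical caps bounded at 45°, and targets
uniform on the central ±40° square — the target range used for all
range-scan simulations. It does not emulate measurement noise, constraint
violations (real fixation data scatter about Listing's plane with ~1°
thickness), vergence, or translations of the rotation centers; passing
tests therefore demonstrate the internal consistency and exactness of the
kinematic model, not its fit to recorded behavior. Initial fixations for
the accuracy suite (`run_fig4`) are constructed by planning a preparatory
shift from the reference condition to the initial fixation point with the
same coordination parameters, which distributes eccentricity between eye
and head the way the model itself would.

## Problem sizes

The packaged tests run the full 41 x 41-target scan for the
Listing/Fick/bow-tie checks, 21 x 21 scans for the coordination-strategy
comparisons, 100-sample trajectories, and batches of 20–300 random
problems for the property sweeps; all sizes are set for figure-quality
coverage of the target range and complete in well under a minute.

## Limitations

The model is purely kinematic (level 1 of a motor hierarchy): no torques,
muscle mechanics, motoneuron signals, or velocity realism, and no
half-angle-rule implementation — those are assumed downstream. The VOR is
ideal (gain 1, perfect prediction). Eye and head rotation centers are
treated as coincident, and binocular/vergence geometry is out of scope.
Head strategies other than zero-Fick-torsion (e.g. Listing-like head
constraints observed under pointing training) are not modelled, and the
provision for initial head position to influence the final head position
beyond the $\alpha,\beta$ interpolation is not simulated.
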