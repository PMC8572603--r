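---
title: "An improved planar neuromusculoskeletal model of elbow muscle torque"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An improved planar neuromusculoskeletal model of elbow muscle torque}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elbownms)
```

## The problem and the model

Elbow joint torque cannot be measured directly in vivo, so it is
estimated by driving a musculoskeletal model with quantities that can be
measured: the flexion angle and per-muscle activations derived from
surface EMG (or, as here, emulated from a muscle-driven tracking
simulation). `elbownms` implements a planar (sagittal-plane) model with
six muscles — the long and short heads of biceps brachii and the
brachialis as flexors, and the three heads of triceps brachii as
extensors — together with the traditional two-line biceps/triceps model
as a baseline. The elbow is treated as a pure hinge; brachioradialis and
anconeus are omitted because their torque contributions are small
relative to the modelled muscles, and shoulder motion is excluded (the
shoulder-side segments of the biarticular heads are frozen into a fixed
path length `l_0`).

Each muscle is a Hill-type actuator assembled as

$$F_M = \left(a\, f_l\, f_v + f_{PE}\right) F_0 \cos\varphi .$$

The components, all dimensionless except $F_0$ (N):

* **Activation** $a = (e^{Au} - 1)/(e^{A} - 1)$ maps normalized
  excitation $u \in [0,1]$ to activation. The shape $A$ is a subject- and
  protocol-dependent constant with no consensus value; the package
  default is $A = -1$, mid-range of the literature's $[-3, 0)$. When
  activations come from a tracking simulation (as in every shipped
  example) they are used directly and this map is bypassed, but it is
  exported for EMG-driven use.
* **Force–length** $f_l = \exp(-(l_m/l_m^{opt} - 1)^2/\gamma)$, a
  Gaussian peaking at the optimal fiber length; $\gamma = 0.5$.
* **Force–velocity** $f_v$: for shortening ($v_n \le 0$)
  $(1 + v_n)/(1 - v_n/A_s)$; for lengthening the hyperbolic branch that
  saturates at $f_M = 1.8$; $A_s = 0.25$. Velocity is normalized by the
  maximum contraction speed $8\,l_m^{opt}$ per second, with shortening
  negative — forced by the shortening branch vanishing at $v_n = -1$.
  Velocities below $-1$ are clamped to zero force rather than
  extrapolated negative.
* **Passive force** $f_{PE}$, exponential in fiber strain with shape
  $k_{PE} = 4$, reaching 1 at the maximum passive strain
  $\varepsilon_0^M = 0.5$, and exactly zero at or below the resting
  length.
* **Pennation** follows the constant-thickness model
  $\varphi = \arcsin(l_m^{opt}\sin\varphi_0/l_m)$, conserving
  $l_m \sin\varphi$. Viscous fiber damping is negligible at
  physiological elbow speeds and is not modelled.

The force assembly groups the active and passive terms before the
pennation cosine, $(F_{CE} + F_{PE})\cos\varphi$ — the standard Hill
assembly, in which only the along-tendon component of fiber force is
transmitted.

## Geometry

Coordinates are right-handed and elbow-centred: x anterior, y medial, z
superior; the forearm points along $-z$ at full extension and rotates
about $+y$ by the flexion angle $\theta$ (degrees, 0 = full extension,
physiological range [0, 150]).

**Flexors** run straight from a humeral origin $A$ to a forearm insertion
that rotates with the ulna, $C = R(\theta) B$. The musculotendon length is
$|AC| + l_0$ and the moment arm is the perpendicular distance from the
rotation centre to the line $AC$ in the sagittal plane, computed from the
slope-intercept form with a vertical-line fallback $r = |x_A|$ (the exact
perpendicular distance when the line of action is vertical). These two
quantities are not independent: for a point rotating about the origin,
$|\mathrm{d}l_{mt}/\mathrm{d}\theta_{rad}|$ equals the moment arm (the
tendon-excursion/virtual-work identity), which the test suite verifies to
$10^{-6}$ m across $\theta \in [0, 120]$ degrees.

**Extensors** insert on the olecranon, whose path wraps the humeral
trochlea, so the three triceps heads share a single moment arm that
shrinks slightly and linearly with flexion, $r = r_0 - k_s\,\theta/90$
with $k_s = 0.004$ m per 90°, and the path lengthens by the swept arc
$\theta_{rad}\, r$. Two deliberately exposed variants exist here:

* `literal_extensor_arc = TRUE` uses $\theta\, r/180$ (no $\pi$), a
  degree-based form some sources print; the default is the dimensionally
  consistent radian arc.
* `extensor_baseline` sets the extensor path length at full extension.
  The default `"musculotendon"` uses $l_m^{opt} + 1.02\,l_t^{opt}$, which
  places the fiber exactly at its resting length at 0° so that passive
  extensor force appears only as flexion stretches the path — with the
  shipped triceps-long parameters the fiber reaches about
  $1.23\,l_m^{opt}$ near 90°, exactly the behaviour expected of the long
  head near peak flexion. The `"fiber"` variant uses $l_m^{opt}$ alone
  before the tendon subtraction; it is kept for auditability but is
  physically inconsistent for realistic triceps parameters
  ($1.02\,l_t^{opt} > l_m^{opt}$ for the long head gives a negative fiber
  length, which the pipeline rejects as an infeasible posture), which is
  why it is not the default.

Tendon length change over the elbow's range is small and is held at
$1.02\times$ the resting tendon length, so $l_m = l_{mt} -
1.02\,l_t^{opt}$. Fiber velocity is obtained by differentiating the
fiber-length series (central differences in the interior, one-sided at
the ends) — the only cross-sample coupling in an otherwise per-sample,
stateless pipeline.

The extension-pose moment arm $r_0$ of the shared triceps path is not
part of the anatomical tables the other parameters come from; it is a
required per-extensor field, and the shipped fixtures use 0.022 m, a
representative adult value. The default parameter set (`arm_muscles()`,
also shipped as `inst/extdata/arm_default.yaml`) carries the per-muscle
optimal fiber lengths, resting tendon lengths, maximum isometric forces,
pennation angles and flexor path points; `scale_muscles()` applies one
uniform length scale for subjects of different stature (forces are left
unscaled — they should be measured per subject).

## Torque assembly and the baseline

Per muscle, $\tau_i = \pm r_i F_M^i$ with flexors positive and extensors
negative — the sign is applied at assembly by muscle group, keeping
forces nonnegative — and the resultant is
$\tau_{sum}(\theta, t) = \sum_i r_i(\theta) F_M^i(\theta, t)$. The
resultant is therefore exactly additive across muscles and linear in the
maximum isometric forces, two conservation properties the tests enforce
to $10^{-12}$.

The two-muscle baseline (`simulate_double_muscle()`) runs the identical
engine with both lumped muscles on straight-line paths. The straight
triceps line is the baseline's known anatomical defect: the olecranon
insertion really travels an arc around the trochlea. No lumped parameter
set exists in any anatomical table, so the shipped baseline
(`baseline_muscles()`, `inst/extdata/baseline_double_synthetic.yaml`) is
constructed and labelled synthetic: biceps sums the two biceps-head
forces on the long-head path; triceps sums the three head forces on a
posterior line from the humerus to the olecranon, with its $l_0$ chosen
so the lumped fiber is at rest at full extension. Baseline activations
are the $F_0$-weighted mean of the per-head traces
(`baseline_activations()`).

## Synthetic inputs

The packaged study motion is $\theta(t) = 45 + 45\sin(\pi t - \pi/2)$:
flexion from 0° to 90° and back within 2 s, sampled at 0.01 s (201
samples — a sample count that also fixes the agreement-ANOVA degrees of
freedom at (1, 400), critical value 3.865). `synthetic_activations()`
emulates what a muscle-driven tracking procedure (e.g. computed muscle
control) produces for this motion: smooth unimodal Gaussian bumps,
floored at 0.02 because trackers keep a small nonzero activation for
conditioning, clipped to [0.02, 1], with optional seeded Gaussian noise.
The default profiles place the flexor peaks mid-flexion (biceps long head
largest, peak 0.55 near t = 0.6 s) and small triceps bumps (0.08–0.15)
centred at peak flexion where the extensors stabilise the joint; timings
scale with the motion duration. These are shape emulations chosen once as
plausible for this motion: passing tests show the pipeline's mechanics
and statistics are correct under CMC-like inputs, not that any specific
tracker's output is reproduced. A `.sto`/`.mot` reader is provided so
genuine tracking exports can replace the generator without code changes.

## Agreement statistics

Two predictions are compared as in the field's model-validation
protocol: Pearson correlation for trend agreement, labelled by the
conventional bands ($|r| \ge 0.8$ "extremely strong", ESC), and a
fixed-effects one-way ANOVA at $\alpha = 0.05$ treating the two series
as independent groups, with verdict NSD when $F < F_{crit}$. Applying
ANOVA to autocorrelated time samples overstates the effective sample
size; it is reproduced here because it is the established comparison
convention for these models, and `agreement_report()` documents the
caveat. The correlation bands themselves are a design choice — the
protocol only ever names ESC — but any standard banding gives the same
labels for correlations above 0.94.

## Numerical choices and degenerate inputs

* Continuity: the force–velocity branches agree at $v_n = 0$ exactly;
  tests check continuity to $10^{-12}$.
* Near-vertical flexor lines of action switch to the exact
  perpendicular-distance fallback below an x-spread of $10^{-12}$ m.
* Infeasible postures (fiber length $\le 0$, or shorter than the
  transverse thickness $l_m^{opt}\sin\varphi_0$) raise errors naming the
  muscle and angle rather than propagating NaNs.
* Trajectories must be uniformly sampled (tolerance $10^{-9}$ relative);
  velocity estimation and the ANOVA df inference both rely on it.
* File round trips write 15 significant digits, preserving values to
  $10^{-12}$ relative error.

## Problem sizes and limitations

The shipped examples and test suite run the 201-sample, six-muscle
configuration (about a thousand Hill evaluations per simulation), which
keeps every check under a few seconds while exercising the full
pipeline; the property suites use randomized grids of 20–100 draws per
invariant and a 10,000-shuffle permutation oracle for the ANOVA p value.

Known limitations: the model is planar and single-joint — shoulder
motion changes the biarticular heads' `l_0` and is out of scope; tendon
compliance is fixed at the 1.02 scaling rather than modelled elastically;
no activation dynamics (excitation–activation filtering) are included;
and no parameter calibration (least-squares or evolutionary) is
performed — parameters are taken as given. Within those bounds the
package reproduces every self-contained analytic property of the model
and the complete torque-estimation workflow.
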