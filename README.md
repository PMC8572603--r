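# elbownms

An EMG-driven neuromusculoskeletal model of the human elbow for estimating
flexion–extension muscle torque. Joint torque is hard to measure in vivo,
yet it is the key quantity for rehabilitation assessment, exoskeleton
control and prosthesis design. `elbownms` predicts it from two inputs a
lab can obtain — the elbow flexion angle θ(t) and per-muscle activations
a(t) (from processed sEMG or a muscle-driven tracking simulation) — using
a planar six-muscle model whose geometry follows elbow anatomy more
closely than the classic two-line biceps/triceps model, which it also
implements for comparison.

## The model

Each musculotendon unit is a Hill-type actuator. Fiber force is

  F_M = (a·f_l·f_v + f_PE) · F₀ · cos φ

with the activation a mapped from normalized excitation u by
a = (e^{Au} − 1)/(e^{A} − 1); the active force–length factor
f_l = exp(−(l_m/l_m^opt − 1)²/γ); a Hill force–velocity factor f_v that is
1 at rest, 0 at the maximum shortening speed (v_max = 8·l_m^opt per
second) and saturates at f_M = 1.8 for fast lengthening; an exponential
passive factor f_PE that engages only above the resting fiber length; and
a constant-thickness pennation model φ = arcsin(l_m^opt sin φ₀ / l_m).

Muscle paths live in the sagittal plane with the elbow rotation centre at
the origin. The three flexors (long/short biceps heads, brachialis) run on
straight lines from a fixed origin to an insertion that rotates with the
forearm; their musculotendon length is the origin–insertion distance plus
any shoulder-side segment l₀, and their moment arm is the perpendicular
distance from the joint centre to the line of action. The three triceps
heads converge on the olecranon tendon, which wraps the humeral trochlea:
they share one moment arm r(θ) = r₀ − k_s·θ/90 and lengthen by the swept
arc θ_rad·r. Tendon length is held at 1.02× its resting value, so
l_m = l_mt − 1.02·l_t^opt. Per-muscle torques τ_i = ±r_i·F_M^i (flexion
positive) sum into the resultant

  τ_sum(θ, t) = Σ_i r_i(θ)·F_M^i(θ, t).

Model agreement between two torque or force predictions is quantified the
standard way for this protocol: Pearson correlation (with conventional
strength labels, |r| ≥ 0.8 = "ESC") and a one-way ANOVA at α = 0.05
reporting F, p, the critical value and an NSD/ESD verdict.

## Worked example

```r
library(elbownms)

tr  <- planned_trajectory()                 # 0 -> 90 -> 0 deg over 2 s
act <- synthetic_activations(tr, seed = 7)  # CMC-like activation bumps
res <- simulate_elbow_torque(tr, act)       # improved six-muscle model
res
#> <torque_result> 6 muscles, 201 samples over 2 s
#>   peak resultant torque 16.644 N m at t = 0.68 s
#>   muscles: biceps_long, biceps_short, brachialis, triceps_long, ...

base <- simulate_double_muscle(tr, baseline_activations(act))
agreement_report(res$resultant$tau_sum, base$resultant$tau_sum)
#> Pearson r = 0.968 (ESC)
#> One-way ANOVA: F(1, 400) = 27.89, p = 2.118e-07,
#>   F-crit(alpha = 0.05) = 3.865 -> ESD
```

The resultant torque rises through the flexion phase (0–1 s), peaking at
about 16.6 N·m shortly before peak flexion as the forearm is lifted, and
decays through extension. The two models' resultants share the trend
(r = 0.97, an extremely strong correlation) but differ systematically in
level (F well above the 3.865 critical value): the straight-line triceps
path of the two-muscle baseline misplaces the extensor geometry, which is
exactly the deviation the six-muscle model corrects. Per-muscle state
histories (lengths, force factors, forces, arms, torques) are in
`res$samples`; `write_torque_result(res, "results/")` exports them as
tidy CSV.

A thin command-line wrapper with `synth`, `simulate` and `compare`
subcommands is installed at
`system.file("cli", "elbow-nms.R", package = "elbownms")`, and packaged
parameter files (the default six-muscle arm and the synthetic two-muscle
baseline) under `system.file("extdata", package = "elbownms")`.

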