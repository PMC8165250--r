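# armbalance

Simulation of human standing balance recovery with an arm strategy, for
researchers in computational biomechanics and motor control who want a
tested, scriptable model of how ankle, hip and arm joints share the work
of staying upright after a push.

## The model and controller

The body is a three-joint, five-link sagittal-plane chain: a foot welded
to the ground, a lower body pivoting about the ankle (angle `q1`, forward
positive), an upper body about the hip (`q2`), and the two arms -- which
share one shoulder joint and one common angle (`q3`) -- lumped into a
single link hanging from the top of the trunk. Defaults describe a
1.7 m, 69.3 kg adult. The equations of motion `M(q) q̈ + C(q, q̇) = τ`
come from Lagrangian mechanics; a horizontal push applied at the
upper-body centre of mass enters through the transpose of that point's
velocity Jacobian.

Balance is maintained by nonlinear model-predictive control: at each
sampling instant the controller minimises

    J = Σ_{k=0}^{Nt-1} ½ (x_kᵀ Q x_k + τ_kᵀ R τ_k) + ½ x_Ntᵀ Qf x_Nt

over an `Nt`-step horizon subject to the discretised dynamics, joint
torque boxes (ankle ±120, hip ±500, arm ±200 N·m) and joint-angle boxes
(ankle [−0.2, 0.4], hip [−0.35, 1.3], arm [−2.5, 0.5] rad), then applies
the first torque of the optimal sequence. The solver is an iterated LQR
with a projected-Newton box QP for the torque limits and an augmented
Lagrangian for the angle boxes; "no solution" from the solver is the
model's way of falling. Three arm conditions -- active, passive
(unactuated arm) and fixed (arms locked to the trunk) -- let you measure
what arm rotation contributes to recovery.

## A worked example

```r
library(armbalance)

model <- build_model(anthropometric_model(), "active")
traj  <- simulate_closed_loop(model, nmpc_config(),
                              push_protocol(70, max_sim_time = 6))
print(traj)
print(balance_metrics(traj))
```

prints

```
Closed-loop trajectory (active arms, push 70 N): 95 samples, recovered, recovery at 2.77 s
Balance metrics: recovered, recovery 2.77 s, total RMS 0.0554 rad, TEC 21.48 J
```

A 70 N forward push acts on the chest for one second; the controller
recovers upright stance 2.77 s after push onset. The total RMS deviation
(0.055 rad, the root-mean-square of ankle and hip angles over the
recovery -- the motion-intensity index) and the total energy consumption
(21.5 J of absolute mechanical work by all actuators) summarise how hard
the recovery was. The same run yields an arm RMS deviation of 0.30 rad
and 7.4 J of arm work -- the arm strategy in action -- and
ankle–hip/hip–arm angle correlations of 0.96 and 0.94, the joint-synergy
indexes.

Higher-level drivers reproduce whole studies:

```r
run_force_sweep()            # all arm conditions x pushes -80..80 N
run_ankle_capacity_cases()   # five ankle-torque-capacity cases, active arms
```

At ±80 N the passive- and fixed-arm models report `no_solution` while the
active-arm model still recovers: actively swung arms widen the range of
survivable pushes. Weakening the ankle torque box (±80 N·m instead of
±120) under a 56 N push lengthens recovery from about 2.6 s to 4.2 s and
multiplies arm work several-fold -- the arm compensating for the weak
ankle.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/balance-sim.R simulate --mode active --force 70 --out run1
Rscript inst/cli/balance-sim.R sweep --out sweepdir
```

with YAML run configuration (`inst/extdata/default_config.yaml`
documents the schema) and JSON run records for reproducibility.

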