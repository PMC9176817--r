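---
title: "Approximate stochastic optimal control of muscle-driven movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximate stochastic optimal control of muscle-driven movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(socmove)
```

## The model

socmove solves stochastic optimal control (SOC) problems of the form

$$\min_{e_{ff}(t),\,K(t)} \; E\Big[\int e(t)^\top e(t)\,dt\Big]
\quad \text{s.t.} \quad \dot x = f(x, e, w_m), \qquad
e = e_{ff} + K\, y_{fb}(x, w_s),$$

where $x$ collects joint kinematics and muscle activations, $e$ are muscle
excitations composed of a deterministic feedforward part and linear feedback
of a noisy sensory signal, and $w_m$, $w_s$ are independent zero-mean
Gaussian disturbances described by continuous-time power spectral densities
(PSDs). The generally non-Gaussian state distribution is approximated by a
Gaussian one, so the stochastic problem becomes deterministic in the pair
(mean state $x_{mean}(t)$, state covariance $P(t)$):

* mean dynamics: $\dot x_{mean} = f(x_{mean}, e, 0)$;
* covariance dynamics (Lyapunov): $\dot P = A P + P A^\top + C \Sigma'_w C^\top$,
  with $A = \partial f_{cl}/\partial x$ and $C = \partial f_{cl}/\partial w$
  the Jacobians of the *closed-loop* right-hand side at the mean state;
* chance constraints: a scalar requirement $g(x) \ge 0$ is imposed as
  $g(x_{mean}) - \gamma \sqrt{\nabla g\, P\, \nabla g^\top} \ge 0$
  ($\gamma = 2$: nominal 95% two-sided satisfaction; $\gamma = 3$: 99.7%);
* expected effort: because the feedback term is zero-mean and uncorrelated
  with the feedforward,
  $E\|e\|^2 = \|e_{ff}\|^2 + \mathrm{trace}\!\big(K (H P H^\top + \Sigma_s) K^\top\big)$
  with $H = \partial y_{fb}/\partial x$.

Noise discretization follows the PSD convention: integrating over a step
$dt$ uses the discrete variance $\mathrm{PSD}/dt$, which makes covariance
propagation step-size invariant for linear systems (the bundled 1D
point-mass fixture reproduces this: a velocity PSD of 2 (m/s)^2/Hz gives a
position variance of exactly 2 m^2 after 1 s for any step).

A consequence of the same convention: a white sensory noise has unbounded
instantaneous variance, so the $\Sigma_s$ entering the *effort* (the variance
of the feedback excitation) must be the PSD discretized at the control
interval. We use the 10 ms mesh interval, and the Monte-Carlo effort
consistency checks simulate at that step so that both sides of the
comparison are defined on the same discretization.

## Solver design

The original formulation of this class of problems is a sparse NLP
(direct collocation, trapezoidal scheme, 10 ms mesh) solved with a
large-scale interior-point solver and automatic differentiation. socmove
instead uses *reduced-space* transcriptions that exploit the structure of
each problem class, with an augmented-Lagrangian outer loop and L-BFGS-B
inner iterations:

* **Stationary problems** (standing balance). The task is encoded as
  $\dot x_{mean} = 0$, $\dot P = 0$ at a single node. Rather than carrying
  the $n(n+1)/2$ covariance entries as decision variables with a Lyapunov
  defect, the stationary covariance is eliminated *exactly* by solving the
  algebraic Lyapunov equation at every objective evaluation (Kronecker
  solve). The remaining variables are the mean activations and the feedback
  gains; upright torque balance is affine in the activations and is
  eliminated by a linear solve, and activation stationarity fixes
  $e_{ff} = a_{mean}$. Symmetry of $P$ holds by construction and positive
  semidefiniteness is monitored post hoc (it is guaranteed when the
  closed loop is Hurwitz); non-Hurwitz iterates receive a smooth penalty
  proportional to the spectral abscissa.
* **Finite-horizon problems** (reaching). Stage A parameterizes the mean
  hand path in task space (minimum-jerk profile plus three timing and three
  lateral basis functions that vanish with zero slope at both ends, so the
  boundary conditions hold identically), maps it through inverse kinematics
  and inverse dynamics, distributes torques over the six muscles by
  a per-node minimal-norm static optimization with non-negativity, and
  inverts the first-order activation dynamics in closed form
  ($e = a + \tau \dot a$). The mean-dynamics collocation defects are
  therefore satisfied identically. Stage B freezes the mean, evaluates the
  closed-loop linearization at the mesh nodes, propagates $P$ with the
  discrete Lyapunov recursion $P_{k+1} = \Phi_k P_k \Phi_k^\top + dt\,Q_k$
  (positivity-preserving), and optimizes piecewise-linear feedback gains
  (nodes every 0.1 s) under the accuracy constraints with *exact adjoint
  gradients* of the augmented Lagrangian. The two-stage split is an
  approximation to full co-optimization: it is exact in the limit where the
  optimal mean path is insensitive to the gains, which holds here because
  feedback excitations vanish along the reference.

Derivatives of the model right-hand sides (the $A$, $C$, $H$ Jacobians
inside the Lyapunov propagation) are computed by **complex-step
differentiation**: every model function is written with complex-analytic
primitives, so a step of $10^{-20}$ on the imaginary axis yields derivatives
exact to machine roundoff, with no subtractive cancellation. This plays the
role automatic differentiation plays in compiled toolchains; finite
differences appear only as independent oracles in the test suite. The outer
optimizer uses central finite differences on the low-dimensional reduced
objective (balance) or the analytic adjoint (reaching).

Convergence tolerances: stationarity and Lyapunov residuals below 1e-7 at
balance solutions (achieved at machine precision by the eliminations),
augmented-Lagrangian constraint tolerance 1e-8 (balance) and 1e-5 relative
(reach accuracy constraints). Non-convergence and infeasibility (for
instance a 0.2 cm accuracy bound, which the sensory-noise floor makes
unattainable) are reported in the solution status, never silently accepted.

## The standing-balance instantiation

Inverted pendulum (70 kg, 1 m) on a rotatable/translatable platform,
actuated by soleus and tibialis anterior through Hill-type rigid-tendon
muscles; first-order excitation-activation dynamics with $\tau$ = 150 ms
lumping sensorimotor delays. Feedback is a constant gain matrix on four
channels: proprioceptive (platform-relative angle and velocity) and
vestibular (space-fixed), each corrupted by its own noise. Platform
rotations are modeled as random constants (angle, velocity) whose covariance
is pinned to the schedule values; translations enter as an acceleration PSD
in the pendulum equation. Because the pendulum angle is measured from
vertical, the lever arm of the translational inertial force is $l\cos q$
(at upright, $\cos 0 = 1$, so translations genuinely perturb the body).

Parameters that matter and their defaults:

* Sensory PSDs (deg-based, converted to rad internally): proprioceptive
  0.1^2 and 0.2^2, vestibular 0.3^2 and 0.6^2 (position, velocity);
  motor noise 0.01^2 per muscle; the 7-level rotation and translation
  schedules as packaged.
* Pendulum inertia about its COM is not separately identifiable from the
  printed mass/length; the default uses the slender-rod correction
  $I = ml^2/12$ on top of the point-mass term $ml^2$, configurable.
* Muscle-tendon geometry is a fitted quantity in the source models and is
  shipped as plausible defaults: length $l(q) = aq + b\sin(cq) + d$ with
  moment arm $-dl/dq$ (the energy-consistent sign: a stretched muscle must
  resist stretch), soleus -5 cm and tibialis +4 cm near neutral, fibers at
  optimal length when upright. These are replaceable through the config.
* Limits of stability: $|q| \le 10^\circ$ at $\gamma = 2$, which caps the
  stationary sway SD at 5 deg — consistent with reporting loss of balance
  at RMS sway above 5 deg. A 5-deg bound at $\gamma = 2$ would cap sway at
  2.5 deg and contradict the ~4 deg sway expected at the largest
  translation magnitude, which is why the larger bound was chosen.
* Short-range stiffness: an activation-proportional parallel spring
  $F_{SRS} = k_{SRS} F_{iso}\, a\, (\tilde l - \tilde l_{mean})$
  ($k_{SRS} = 1$), referenced to the upright fiber length, with no
  break-away threshold.

Outcome measures: sway SD (deg, from $P_{qq}$), proprioceptive weighting
$\|K_{prop}\|_F / (\|K_{prop}\|_F + \|K_{vest}\|_F)$ (Frobenius norms of the
2x2 gain blocks — the matrix extension of the scalar experimental measure),
the co-contraction index $\min(a)/\max(a)\cdot(a_{SOL}+a_{TA})$, and the
feedback share of expected effort.

Two known quantitative gaps, both traced to unprinted model ingredients and
documented rather than tuned away: (i) with the packaged geometry the
optimal quiet-stance sway is ~0.85 deg rather than ~0.3 deg — a noise-source
decomposition shows the sway budget is dominated by motor-noise feedthrough,
whose scale is set by the (unprinted) moment arms and operating fiber
lengths; (ii) the proprioceptive weighting solves to 0.90, which is the
exact effort-optimal allocation $k_p \sigma_p^2 = k_v \sigma_v^2$ for two
cues carrying the same signal at the packaged 1:9 noise-variance ratio — a
0.7–0.8 weighting is not reproducible from that ratio alone.

## The reaching instantiation

Planar two-segment arm (upper arm 1.4 kg/0.3 m/0.025 kg m^2, forearm
1.0 kg/0.33 m/0.045 kg m^2, COM mid-segment) in a horizontal plane (no
gravity torque, matching the cited arm-control models; the gravity vector is
configurable), driven by six muscles: brachialis/lateral triceps (elbow),
anterior/posterior deltoid (shoulder), biceps/long triceps (biarticular).
Normalized fiber lengths are linear-plus-sine functions of the joint angles;
moment arms are the scaled negative derivatives of the same expressions
(1e-8 consistency enforced in tests). The feedback signal is the noisy hand
position/velocity relative to the nominal (noise-free mean) trajectory, with
time-varying gains. Motor noise acts as joint-torque PSD 0.05^2 (Nm)^2/Hz;
sensory noise 0.6^2 mm^2/Hz (position) and 4.8^2 (mm/s)^2/Hz (velocity).

Task geometry: the printed mid-range start posture places the hand where a
25 cm reach would leave the workspace, so the package starts the hand at
(0, 0.35) m (shoulder at the origin; joint angles ~(30, 113) deg) and
reaches to (0, 0.60) m. Accuracy is imposed directly as SD bounds (0.4 cm)
on the terminal hand coordinates per task kind; the obstacle task
additionally bounds the horizontal SD for t > 0.25 s and keeps the mean path
on the straight line; the force-field task adds a 200 N/m divergent field
whose zero axis is the straight start-target line. The initial covariance is
1e-8 I (near-deterministic start of a point-to-point movement).

## Monte-Carlo forward simulation

`simulate_episode()` integrates the full nonlinear closed loop with
Euler-Maruyama at 1 ms (default), drawing each source fresh per step with
variance PSD/dt; episode $i$ of an ensemble uses seed + i - 1, and episodes
are bitwise reproducible. Excitations are *not* clipped at zero by default:
the Gaussian approximation the optimizer uses has unbounded feedback
components, and the forward simulation matches that approximation (clipping
is available with the discrepancy then visible in the ensemble measures).
Derived measures: 95% confidence ellipses of the terminal hand position
(chi-square(2) quantile of the empirical covariance), corrective activations
(perturbed minus mean unperturbed), per-episode co-contraction statistics,
and endpoint stiffness by simulated 150 ms force probes (applied force
change divided by the resulting displacement at the end of the interval).

## What the validation fixtures do and do not show

The analytic fixtures pin the machinery to closed-form truths: the
point-mass worked example (exact), a scalar LQ problem whose effort-optimal
stationary gain coincides with the algebraic-Riccati gain (pipeline matches
to 1e-4), the zero-noise reduction to the deterministic problem (1e-6), and
statistical consistency of the Lyapunov propagation, expected-effort formula
and confidence ellipses against independent Monte-Carlo oracles (3 SE).
Passing these shows the *approximation machinery* is implemented correctly.
It does not show that the Gaussian approximation is accurate for a given
nonlinear model — that is checked separately by forward-simulating each
optimized policy (balance sway within 15% of the Lyapunov prediction;
reach terminal SDs within the 25% modeling allowance), nor does it certify
the unprinted geometry defaults, whose influence on the two quiet-stance
outcome gaps is described above.

Problem sizes used throughout (chosen to keep every check statistically
meaningful at interactive runtimes): 1e4-episode ensembles for the scalar
Lyapunov and coverage checks, 2e5 samples for the effort oracle, 100
episodes for the reach accuracy verification, 6 x 25 s episodes for balance
sway, 81-node meshes for reaching, 7-level warm-started magnitude sweeps for
balance.

## Known limitations

* First-order sensorimotor delay only; no true time-delay dynamics.
* The Gaussian transport is first-order: activation non-negativity is not
  reflected in the covariance dynamics, so optimal policies may implicitly
  rely on negative excitation excursions (visible when comparing clipped
  forward simulations against the approximation).
* The two-stage reach transcription forgoes exact mean-gain co-optimization
  (see Solver design); stationary balance solves are exact reduced-space
  solutions of the single-node problem.
* No compliant tendon, no visual channel, no iLQG baseline, and no
  experimental-data ingestion: comparisons against published experimental
  gain/EMG datasets are out of scope.
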