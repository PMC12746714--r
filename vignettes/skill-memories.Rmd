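---
title: "Skill memories in a temporal predictive coding network: model, plant and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skill memories in a temporal predictive coding network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the generative model
and its two phases, the monitoring and evaluation machinery built on top of
it, what the synthetic sensorimotor plant does and does not emulate, and the
numerical and design choices that shape the results. Nothing here states an
empirical number that the test suite or `scripts/acceptance.R` does not
itself compute.

## The model

A sensorimotor skill is a stereotyped multichannel time series
$x^\mu \in \mathbb{R}^{C}$, $\mu = 0, \dots, T-1$: joint angles, end-effector
coordinates, gripper state, force/torque readings, and (in the reaching
task) one-hot context cues, concatenated into one observation vector per
time step. The package stores a *repertoire* of such skills in a single
two-layer temporal predictive coding network whose graphical structure is
that of a hidden Markov model: hidden value neurons $z^\mu$ predict both the
next hidden state and the current observation through two weight matrices,

$$F_\mu(z^\mu) \;=\; \lVert z^\mu - W_H f(\hat z^{\mu-1}) \rVert_2^2
  \;+\; \lVert x^\mu - W_F f(z^\mu) \rVert_2^2 ,$$

where $f$ is the activation (tanh by default; a linear option exists purely
so inference can be validated against the closed-form ridge solve that the
linear case admits), $\hat z^{\mu-1}$ is the converged hidden state of the
previous step, and $F_\mu$ — the *energy* — is the sum of squared hidden
temporal and observation prediction errors
$\epsilon_z = z - W_H f(\hat z^{\mu-1})$, $\epsilon_x = x - W_F f(z)$.

**Memorisation.** For each step of each demonstration the hidden state is
inferred by explicit-Euler descent of $F_\mu$,
$\dot z \propto -\epsilon_z + f'(z) \odot W_F^\top \epsilon_x$, starting
from the temporal prediction $W_H f(\hat z^{\mu-1})$ (so the hidden-temporal
error term is exactly zero at initialisation; the first step of a sequence
starts from $\hat z^{-1} = 0$). After convergence the weights take one
local, Hebbian-like gradient step,
$\Delta W_H \propto \epsilon_z f(\hat z^{\mu-1})^\top$ and
$\Delta W_F \propto \epsilon_x f(z^\mu)^\top$ — one update per time step,
one sweep per presentation, each update touching only quantities available
at that step. All skills share one weight set; an epoch presents every
demonstration once in round-robin order, so `epochs_per_skill = 1000` means
1000 presentations of each skill. The recorded energy curve logs the
converged energy after inference, before each weight update.

**Recall.** With weights frozen, *offline recall* infers the hidden state
from the first $T_n$ cued observations (the queries) and then generates the
remainder ballistically by the forward pass $z \leftarrow W_H f(z)$,
$x \leftarrow W_F f(z)$; for this two-layer model the forward pass is the
fixed point of the observation-settling dynamics
$\dot{\hat x} \propto -\epsilon_x$, so the iterative settling is skipped.
*Online recall* instead clamps each incoming ground-truth observation,
infers $z^\mu$, and emits the one-step-ahead prediction; its converged
per-step energy is the monitoring signal used for fault detection, and the
per-channel $\lvert \epsilon_x \rvert$ is the isolation signal. Cued
inference acts as motor preparation: it is what lets the network *implicitly
recognise* which stored skill the cue belongs to, with no skill label ever
supplied.

### Hyperparameters

| parameter | default | units / meaning |
|---|---|---|
| `n_hidden` | 256 | hidden value neurons |
| `inference_lr` | 1e-2 | Euler step of the value-neuron dynamics |
| `inference_iters` | 100 | inference iterations per time step |
| `weight_lr` | 1e-4 | learning rate of both weight matrices |
| `epochs_per_skill` | 1000 | presentations of each skill |
| `batch_size` | 1 | sequences per weight update |

Weights are initialised Kaiming-uniform from the configuration seed; one
integer seed makes every model, dataset and experiment bit-reproducible.
Channels are Z-scored (pooled mean and standard deviation over the training
trials, floor 1e-6) before entering any network, and recalled outputs are
mapped back to original units.

Two numerical properties are worth knowing. First, with `inference_lr`
$\le$ 1e-2 the energy is non-increasing across inference iterations on all
tested instances (a property test enforces this), and divergence raises an
error naming the iteration. Second, because the first step of every
sequence starts from $\hat z^{-1} = 0$, its converged energy is structurally
about an order of magnitude above later steps — the hidden state must build
the whole observation from nothing, and the $\lVert z \rVert^2$ penalty
bounds how well it can. Pooled per-step thresholds (below) therefore sit
near the edge of this first-step cluster. This is a calibration property of
the monitoring design, not a defect of a particular fit; it shrinks slowly
with training.

## Fault detection, isolation, correction

Detection is out-of-distribution detection on the monitoring energy: a
threshold is fitted as the nearest-rank percentile (the
$\lceil p/100 \cdot n \rceil$-th order statistic) of per-step energies
pooled over fault-free trials, which makes the false-positive arithmetic
exact — with 300 pooled values and $p = 95$, exactly 15 sit above the
threshold. A trial is flagged when any step's energy crosses the threshold
(grid evaluations count crossings at or after the fault step). Isolation
reports the joint channel with the largest $\lvert \epsilon_x \rvert$ from
the detection step onward; isolation is a per-trial judgement, and the
alternative of reading errors only at the detection step is available as
`window = "at_detection"` (it is measurably worse, because at the first
threshold crossing the locked joint's own deviation is often still small).

The Z-score baseline plays the role of a traditional associative skill
memory: it stores, per skill, the expected signal statistics of the
demonstrations and scores a trial by $z_{it} = (x_{it} - \bar x)/\sigma$,
with $\sum_i z_{it}^2$ as its detection statistic and the largest
$\lvert z \rvert$ joint channel as its isolation call. Unlike the energy
monitor it must be told the true skill label. Three granularities of the
stored statistics are implemented — per (step, channel) mean and sd (the
default: skill memories keep statistics aligned to the movement phase),
per-step mean with per-channel sd, and fully pooled. On this plant the
choice matters enormously: pooled statistics barely detect anything, while
time-aligned statistics are a strong detector. The pooled reading is the
most literal transcription of a per-channel normalisation formula, but only
the time-aligned reading produces a baseline whose detection behaviour
resembles a usable skill-memory monitor, so it is the default.

Reactive correction closes the loop: the skill memory's predicted joint
trajectory (2 Hz) is linearly interpolated to a 40 Hz low-level rate and
tracked by a proportional controller that minimises proprioceptive
prediction error in joint space, so an impulsive disturbance decays
geometrically at rate $1 - \text{gain}$ per low-level step.

## The synthetic plant

No robot-simulator data ships with the package; a seedable kinematic plant
generates everything. Its defaults are the package's study conditions and
were fixed at design time.

**Pick-and-place demonstrations.** A 7-joint serial-chain arm with scripted
joint keyframes (reach, grasp at $t = 3$ s, lift, transport, place)
interpolated to 15 steps at 2 Hz; 25 channels = 7 joint angles +
3 end-effector coordinates from forward kinematics + 3 gripper channels +
12 force/torque components carrying a load profile while grasping. Skills A
and B differ in pick and place locations. Demonstration variability has two
components, both emulating a teleoperation-proxy pipeline: i.i.d. Gaussian
channel noise with sd equal to 2% of each channel's dynamic range, and
per-trial execution-timing jitter (speed factor $\mathcal N(1, 0.04)$,
phase offset $\mathcal N(0, 0.15)$ steps). The timing jitter matters: with
perfectly time-locked trials, a per-step statistics baseline is a
near-perfect detector, which no real demonstration set would permit.

**Joint-lock faults.** From the fault step the locked joint holds its
desired-plus-overshoot angle while the other joints keep tracking their own
references — the plant models joint-space position control, where a locked
joint does not propagate to other joints (an optional
differential-inverse-kinematics compensation mode exists for
end-effector-servoing controllers, off by default). End-effector channels
are recomputed by forward kinematics. Two exteroceptive consequences are
modelled because they carry most of the real-world fault signature: a fault
that displaces the hand more than 5 cm from the object's pose at grasp time
makes the pick fail (the gripper stays open and no load profile ever
appears), and an end-effector excursion below the floor adds a decaying
collision spike to the force/torque channels. The keyframes keep the
nominal approach 0.08–0.16 m above the floor, so only proximal-joint locks
(large end-effector levers) can strike it — collisions are the severe
exception, not the rule.

What the plant deliberately does not model: dynamics and torque control,
contact physics beyond the collision spike, grip slip, and the
controller-fighting transients a physical arm would superimpose on a locked
joint. Consequences for interpretation: deviations are purely geometric, so
a lock whose held angle happens to coincide with configurations the
movement visits later is genuinely hard to see in position channels alone,
and a label-given time-aligned statistics baseline faces much friendlier
conditions here than on a physical system. Passing grid-level tests on this
plant shows the pipeline's logic and calibration are correct, not that the
same rates would be obtained on a robot.

**Follow-through reaching.** A planar two-link arm reaches 10 cm from S to
T; each context ("cw", "ccw") has a pre-defined optimal compensatory plan —
the straight path plus a 2 cm half-sine lateral bow, leftward for the
clockwise field, rightward for the counter-clockwise one; the two plans are
mirror images. One-hot cue channels carry the context: from step 0 in the
two planning conditions (`planning_and_execution` additionally appends the
follow-through leg to the context's secondary target), and only from
mid-movement (step $\lceil T/2 \rceil = 8$) in `execution_only`, so in that
condition the first observation carries no context at all. Joint channels
come from two-link inverse kinematics; cue channels are never noisy (they
stay one-hot).

## Metrics and statistics

**Directional compensatory deviation (DCD).** With $\hat u$ the unit vector
from S to T and $\hat n$ its +90° rotation, the signed perpendicular
deviation at step $t$ is $d_t = \hat n \cdot (P_t - S)$. The DCD is the
deviation of maximum magnitude over the pre-target window — steps up to the
path's closest approach to T, so a follow-through leg cannot dominate —
projected onto the context's correct compensation axis: $c \cdot d_{t^*}$,
$t^* = \arg\max |d_t|$, with $c = +1$ for "cw" and $-1$ for "ccw". A bow of
amplitude $a$ in the correct direction scores $+a$; the same bow in the
wrong direction scores $-a$; the metric is invariant to rigid motions
applied jointly to path and anchors and negates under mirroring. Taking the
signed deviation at the magnitude peak, rather than the maximum of
$c \cdot d_t$, matters: the latter is non-negative for any path that
wiggles on both sides of the line, which would bias the null (no-context)
condition upward by construction.

**Separation testing.** Recall is averaged over 24 noisy cue draws per
context; each seed contributes its mean DCD over contexts; a one-sided
Wilcoxon signed-rank test across 6 seeds (exact, $\alpha = 0.05$) asks
whether DCD exceeds zero. With 6 seeds the smallest attainable p-value is
1/64, so significance requires essentially every seed to separate in the
correct direction.

**Speed–accuracy.** Offline recall is repeated with the number of cued
inference iterations swept over a grid; fewer iterations leave the hidden
state short of convergence and recall less accurate, so the median recall
error falls as iterations grow. The recurrent baselines have no iterative
inference phase, so their probe returns a constant by construction — the
package's formalisation of the prediction that they exhibit no such
trade-off.

## Recurrent baselines

Two sequence-to-sequence vanilla tanh recurrent networks bracket the model
in the reaching comparison: sensory-to-motor (inputs: end-effector and cue
channels; outputs: joint channels) and
sensorimotor-to-sensorimotor (all channels to all channels). Both are
trained by backpropagation through time *in the offline-recall regime
itself*: the network receives a real input only at the first step — zeros
afterwards for the sensory-to-motor network, its own fed-back predictions
for the sensorimotor one (the gradient flows through the feedback path) —
and minimises the mean squared error of the generated sequence. Gradients
are verified against finite differences in the test suite. Plain SGD at the
skill memory's learning rate is the configured default; at that setting the
sensorimotor network does not approach convergence within a
1200-presentation budget, so the experiment pipeline uses Adam at 1e-3,
chosen once for convergence and recorded here. The sensory-to-motor
network's recalled end-effector path is obtained by forward kinematics of
its predicted joints.

## Problem sizes

The shipped experiments are scaled-down reproductions chosen to run on one
CPU core in minutes; all sizes are package defaults, stated here as the
package's own choices:

* Fault pipeline: 10 demonstrations per skill, 2 skills, 20 held-out
  fault-free trials for calibration, the full default training budget of
  1000 epochs, and a 462-cell grid (7 joints × fault times 1–6 s in 0.5 s
  steps × overshoots ±5/±10/±15°; zero overshoot is excluded because a lock
  with no overshoot at the goal is not a detectable fault on a kinematic
  plant). The exact-FPR check uses a reduced 200-epoch model.
* Follow-through pipeline: 12 trials per context, 64 hidden units for all
  three networks, 400 skill-memory epochs and 2400 baseline presentations
  per condition and seed, 6 seeds, recall averaged over 24 cue draws.
* Speed–accuracy: iteration grid 1, 2, 5, 10, 30, 100 on the
  planning-only fits.

## Known limitations

* The capacity of a single weight set is limited by the one-step-local
  learning rule; long or many skills degrade recall fidelity before they
  degrade detection.
* Offline recall cannot react to information arriving after the cue
  window; online recall tracks it but the package does not demonstrate
  skill switching mid-sequence.
* The first-step energy transient (above) makes pooled-percentile
  thresholds conservative; per-trial or transient-excluding calibrations
  would be more sensitive but are not what the monitoring design specifies.
* White-noise "sequences" are close to worst-case inputs for the temporal
  dynamics; memorisation guarantees in the tests are stated for smooth,
  trajectory-like sequences, which is what sensorimotor data are.
* All plant-level caveats listed above: kinematic-only fault signatures,
  benign conditions for time-aligned baselines, Gaussian noise in place of
  simulator noise.
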