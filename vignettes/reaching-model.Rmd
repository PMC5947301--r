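---
title: "How reaching emerges from motor babbling: the model behind reachnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How reaching emerges from motor babbling: the model behind reachnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Infants begin reaching toward visual targets at 3–5 months, reach
successfully without seeing their own hand by about 7 months, and around
9 months start extending an arm toward objects that are plainly out of
reach — the precursor of pointing. `reachnet` implements a computational
account of how all three can emerge from one learning history that contains
**no targets at all**: random arm movements under intermittent visual
observation of the hand (motor babbling, "hand regard").

The claim embodied in the model is architectural. If an infant acquires

* a **forward transformation** — predict the visual consequence
  $y(t{+}1)$ of a motor command $u(t)$ given an internal estimate of the
  current hand position — and
* an **inverse transformation** — recover the command $u(t)$ that carries
  the hand to an observed position $y(t{+}1)$ from the current situation,

then wiring the output of the inverse into the input of the forward
transformation yields a feedback controller that operates on *internal*
state: presenting any visual position as if it were a post-movement hand
position makes the loop emit a sequence of small commands that carry the
hand toward it. Nothing in the system represents "target", "reach" or
"distance"; out-of-reach pointing-like extension falls out of the same
loop because the broadly tuned visual code still responds, weakly but
systematically, to positions the hand has never occupied.

## The plant

The arm is two rigid segments of unit length in the horizontal plane.
The shoulder sits at the body center (body width neglected), `alpha` is the
shoulder angle from the rightward axis, `beta` the interior elbow angle
(180° = fully extended), both confined to $[0, 180]$° — a command that
would exceed a limit leaves the joint at the limit. The hand is seen in
body-centered polar coordinates: distance $r$ from the shoulder and azimuth
$\theta$ from the straight-ahead axis, positive toward the side of the
modeled (right) arm. Under this convention

$$\text{elbow} = (\cos\alpha, \sin\alpha), \qquad
  \text{hand} = \text{elbow} + (\cos(\alpha + 180 - \beta),
                                \sin(\alpha + 180 - \beta)),$$

so $(\alpha, \beta) = (30, 60)$ puts the hand at Cartesian $(0, 1)$, i.e.
$(r, \theta) = (1, 0)$, and the maximum reach is $r = 2$, attained exactly
when $\beta = 180$. This is the unique simple convention under which those
anchor correspondences and the joint ranges are all consistent, and it is
asserted analytically in the test suite. All angles are degrees end to end;
radians appear only inside trigonometric calls. Positions behind the body
($|\theta| > 90$) are legal plant outputs and are passed to the encoder
unmodified — only the joints clip, never vision.

## Place coding

Commands and positions enter the networks as population codes over grids
of broadly tuned units. A unit with preferred vector $p$ responds to input
$v$ with

$$a = \prod_{d=1}^{2} g(v_d - p_d; w_d), \qquad
  g(\delta; w) = \begin{cases}\cos\!\big(90^\circ \,\delta / w\big) & |\delta| < w \\ 0 & \text{otherwise,}\end{cases}$$

a truncated cosine per dimension, multiplied across dimensions so that
activations stay in $[0,1]$ and a unit centered on the input fires at 1.
The half-widths are *broad*: 90° in azimuth (the one value the source
architecture prints) and, by the same "half the definition range" rule,
1.5 arm-units in distance and 20° per joint for commands. This breadth is
not a nuisance parameter — it is what lets units respond to signals they
do not prefer, and therefore what lets the trained loop extrapolate to
out-of-reach positions.

Preferred vectors sit on a regular lattice spanning **twice** the
definition range of each dimension, centered on it, endpoints included:
10×10 motor units over $[-40, 40]^2$° for commands defined on
$[-20, 20]^2$°, and 10 distances × 20 azimuths over
$[-1.5, 4.5] \times [-180, 180]$ for vision defined on
$[0,3] \times [-90, 90]$. Units with out-of-range preferred vectors exist
so the population can represent the *edge* of the space: with a lattice
that stops at the edge, the center-of-gravity readout of an edge input is
dragged toward the middle (a ~30° azimuth bias in our control experiment);
with the doubled lattice the bias is under one lattice spacing (~0.6°).
The test suite verifies both the interior round-trip bound (error below
half a lattice spacing) and the doubled-vs-plain edge comparison.

Decoding is the standard population vector, the activation-weighted mean
of preferred vectors. It is deliberately dumb plumbing: learning never
sees decoded values — teachers are population codes — and the decoder is
used only to report positions and to drive the physical joints.

## The two networks

Both transformations are three-layer logistic networks without biases,
momentum or any optimizer refinement; the learning mechanism is one
online gradient step of the squared error between output and teacher
populations per experience, at a fixed rate $\eta = 0.05$. Layer sizes:
100 motor, 200 visual, 400 hidden per network.

The **forward network** is a simple recurrent (Elman) network. Its hidden
layer receives the motor population $\tilde u(t)$, the visual population
$\tilde y(t)$ of the pre-movement hand position — a zero vector on steps
where the hand was not observed — and its own previous activation as a
frozen context. The output layer predicts the visual population of the
post-movement position. Because vision is intermittently absent (80%
availability during learning), the recurrence is forced to carry an
internal estimate of the hand position across visual gaps; this is what
later substitutes for sight during reaching in the dark. Backpropagation
treats the context as constant input (no unrolling through time): the
model predicts one step, it does not learn sequences.

The **inverse network**'s hidden layer receives the visual population of
the post-movement position and the forward network's hidden state
representing the situation *before* the movement — the Elman context,
i.e. the state that has not yet absorbed the command being learned. This
timing is essential, and it is the one place the package's design was
genuinely open. Feeding instead the same step's post-command hidden state
looks superficially closer to a literal reading of the architecture, but
it hands the inverse network a copy of the very command it is being
taught to produce; gradient descent then learns to echo the state input
and ignores vision entirely. We verified this empirically: with
post-command state input the decoded-command error stays at the
uniform-babble baseline (~12° per joint) and reaching collapses, while
with the context input it falls to ~2–4° and reaching works. The context
convention is also the only one consistent with the reaching loop, where
the inverse necessarily consumes the state settled *before* the command
it is about to generate. Inverse-error gradients stop at the forward
hidden boundary: the connection from the forward hidden layer is trained,
the forward network's own weights are never touched by inverse errors,
keeping the forward model purely predictive.

Weights are initialized i.i.d. uniform on $[-0.1, 0.1]$ (a standard small
symmetric choice for bias-free logistic nets; the magnitude is
configurable), in a fixed matrix order so a seed pins the whole model.

## The learning phase

One babbling iteration: draw $u(t)$ uniformly on $[-20,20]^2$°, apply it
to the arm with clipping, observe the post-movement position with
probability 0.8, run the forward network, and — only if the observation
arrived — update the forward network toward the encoded observation and
the inverse network toward the encoded command. Availability gates both
teachers because both need $y(t{+}1)$; this also means an unobserved step
trains nothing, which matches the rate being defined per learning
iteration. Babbling is one continuous random walk from a uniformly drawn
interior posture (an episodic-reset mode exists but is off by default);
the initial hidden state is 0.5 everywhere, the fixed point of a
zero-input logistic unit.

The reference run length is 1,200,000 iterations. The package's test
suite and the bundled experiment defaults use 200,000-iteration models
(about one minute each on a single core with the compiled trainer) at
three seeds with a majority rule; at that length the forward probe error
has fallen roughly tenfold from initialization and the inverse direction
cosine on the standard probe grid exceeds 0.9, so the scaled models
exhibit every qualitative property of interest. The trainer itself is a
C++ inner loop that consumes R's global RNG stream in a documented
per-iteration order (command, command, availability), which is what makes
a pure-R reimplementation of the loop — built from the package's exported
step functions — reproduce it bit-for-bit-near (the equivalence is a test).

## The experiments

Every experiment first settles the network state: 20 forward iterations
with vision fixed to the initial hand position and the zero command, after
which the hidden layer holds the internal representation of that position
(the settling is contractive — checked in the tests).

* **One-step forward test.** From posture (30, 60) (hand at $(r,\theta) =
  (1,0)$), each of the 25 commands
  $\{-20,-10,0,10,20\}^2$ is fed once; the decoded prediction is compared
  with the plant's true outcome. Predictions are good in the interior and
  visibly worse for commands at the limits of the range — edge commands
  are both rarer under clipping and harder for the edge of the population
  code, a property the suite asserts as interior-vs-edge mean error.
* **One-step inverse test.** Same settled state; the 25 positions
  *reached* by those commands are presented as visual inputs. The network
  interprets each as a post-movement hand position and emits a command;
  executing it should move the hand toward the position. On scaled models
  ≥ 20 of 25 decoded commands strictly reduce the distance, and the
  current hand position itself elicits only a small command (a near
  fixed point).
* **Reaching loop.** From posture (20, 40), seven targets at azimuths
  $\{-90, \dots, 90\}$ in 30° steps (the azimuths are the package's
  choice — the source figures show seven symmetric targets without
  printing values). Each loop iteration feeds the target population and
  the current hidden state to the inverse network, decodes its output
  population to drive the arm, and feeds the *same population* (not a
  decode–re-encode, avoiding a second quantization; a re-encode mode
  exists behind a flag) into the forward network with vision zeroed —
  the same convention as an unobserved babbling step, so the loop is a
  movement in the dark. Four iterations for targets at distance 2, seven
  for distance 3. Hand vision is never encoded anywhere in the loop.

On scaled models the loop reproduces the expected developmental
signature: within-reach targets end substantially nearer than they
started, ipsilateral targets are reached better than contralateral ones
(the contralateral targets are farther in joint space from the relatively
extended initial posture), and for out-of-reach targets the arm extends
toward full stretch ($r \approx 1.9$–$2.0$) with the final hand azimuth on
the correct side for lateral targets but less lateral than the target
itself — an inaccurate but correctly *oriented* pointing-like action,
including a modest bias of the kind seen in dark-pointing experiments.

## Numerical and design notes

* **Degenerate inputs.** An all-zero population cannot be decoded
  (error); a zero-weight network outputs 0.5 everywhere, which decodes to
  the lattice centroid — for the motor grid that is the zero command, a
  safe default. Logistic outputs never reach 0 or 1 for finite weights.
* **Tolerances.** Analytic kinematics identities are asserted at 1e-12;
  backprop is validated against central finite differences at relative
  error 1e-5 on a small dense instance; the C++/R trainer equivalence is
  asserted at 1e-8 after 150 iterations (the two paths differ only in
  floating-point summation order).
* **Determinism.** Everything downstream of `train()` is deterministic;
  the reach loop and all tests consume no RNG. `(seed, config)` is the
  complete provenance of a model, and the model file records both plus a
  hash.
* **What the synthetic conditions do not show.** Babbling covers the
  within-reach annulus densely; nothing validates behavior for visual
  inputs far outside the doubled grids, and the model deliberately omits
  arm dynamics, neural noise, 3-D kinematics, finger extension and any
  account of how the social meaning of pointing is acquired. Passing
  tests certify the computational mechanism, not infant data.

## Reproducing the experiment tables

```{r, eval = FALSE}
library(reachnet)
cfg <- default_config()
cfg$training$n_iterations <- 200000   # scaled; 1200000 for the full run
run_experiment_suite(cfg, seed = 1, out_dir = "reachnet-results")
```

writes the training log, both one-step test tables, both sets of reaching
trajectories and a summary of the headline metrics as CSV.
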