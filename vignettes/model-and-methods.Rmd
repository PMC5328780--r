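---
title: "The three-leg coordination model: equations, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The three-leg coordination model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

stickwalk simulates three ipsilateral legs of a stick insect — front (FL,
prothoracic), middle (ML, mesothoracic) and hind leg (HL, metathoracic) —
each governed by three local control networks: protractor–retractor (PR,
thorax–coxa angle $\alpha$), levator–depressor (LD, coxa–trochanter angle
$\beta$) and extensor–flexor (EF, femur–tibia supplement $\gamma$).  The
angles work within fixed ranges, $\alpha \in [28°, 128°]$ (protracted to
retracted), $\beta \in [30°, 60°]$ (on the ground to maximally elevated) and
$\gamma \in [45°, 110°]$ (extended to flexed).  $\beta$ doubles as the
ground-contact signal: the leg is in stance while $\beta$ is near its floor.
This vignette documents the model equations, the meaning and calibration of
every parameter that matters, what the synthetic fixtures emulate, and the
design decisions taken where the published description leaves the
implementation open.

## Neurons and synapses

All units are nonspiking; transmission is graded through a shared sigmoid
$s(V) = 1/(1+\exp(-(V-\theta_s)/\sigma_s))$ with $\theta_s = -43$ mV and
$\sigma_s = 1$ mV.  Each CPG is a half-center: two neurons coupled by mutual
graded inhibition ($g_{cc} = 1.5$, $E_{inh} = -80$ mV).  CPG neurons carry a
persistent inward current with slow inactivation $h$:

$$C \dot V = -g_L (V - E_L) - g_P\, m_\infty(V)\, h\, (V - E_P) - I_{syn} - I_{drive},$$
$$\dot h = (h_\infty(V) - h)/\tau_h(V),$$

with $m_\infty$ a rising sigmoid (midpoint $-40$ mV, slope 6 mV),
$h_\infty$ a falling sigmoid (midpoint $\theta_h = -62$ mV, slope 3 mV), and
$\tau_h(V) = \tau_{h0}/\cosh((V - \theta_\tau)/(2\sigma_\tau))$ with
$\tau_{h0} = 1620$ ms, $\theta_\tau = -30$ mV, $\sigma_\tau = 5$ mV.  Two
properties of this parameterisation carry the whole model:

* **The $\tau_h$ peak sits at burst voltages** ($\theta_\tau = -30$ mV), not
  at the inactivation midpoint.  Burst fatigue is therefore the slow process
  and its rate depends on how far the burst voltage sits above
  $\theta_\tau$ — which the tonic drives set.  This is what makes the
  stepping period monotonically *decrease* with the central drives over the
  operating range, the lever used for calibration and for the two gaits.
* **$h_\infty$ is steep around the hyperpolarised operating range**, so a
  neuron held down by inhibition accumulates $h$ quickly (its $\tau_h$ there
  is short) and fires a strong post-inhibitory rebound when released.  The
  front leg steps exclusively through this rebound.

Premotor interneurons (INs), intrasegmental sensory INs and motoneurons
(MNs) are single-variable leaky units.  Premotor INs are tonically
depolarised (conductance `g_in_tone` toward 0 mV) and sit under tonic
inhibition `g_d` (baseline 0.9) plus inhibition from their CPG neuron; each
IN inhibits one MN, and all MNs share the uniform excitatory drive `g_MN`.
The chain is sign-inverting twice, so an active CPG neuron *activates* its
MN, while removing `g_d` from an IN (full disinhibition) clamps its MN off
regardless of the CPG — the handle used by the premotor decoupling
mechanism.

## Muscles, joints and intraleg coordination

Muscle activations follow MN output with first-order dynamics
($\tau_{act} = 20$ ms), and each joint moves at a velocity proportional to
the difference of its antagonists (gains 0.56, 0.55, 0.3 deg/ms for
$\alpha$, $\beta$, $\gamma$), hard-clamped to the printed ranges.  The
clamps are intended: the published traces are square-to-trapezoid waves that
saturate at the range limits every cycle.

Intraleg coordination is sensory.  Two Schmitt-trigger latches per leg read
$\beta$: the stance latch engages when $\beta$ falls through 33° while
descending (ground contact) and routes gating excitation to the retractor
CPG neuron; the flexion latch engages earlier in the descent, at 45°,
reflecting that the tibia switches before ground contact; both clear on
lift-off ($\beta$ rising through 34°).  A permanently lifted leg therefore
protracts and extends ($\alpha \to 28°$, $\gamma \to 45°$) and a permanently
grounded one retracts and flexes — the two complementary postures every
decoupling experiment ends in.  The metathoracic tibia works half a period
out of phase with the front legs, implemented as an inverted EF routing for
the hind leg; this is why a stopped hind leg is *stretched* on the ground
(or flexed when lifted) rather than the front-leg way around.

Two phasic position-sense interneurons per leg close the step cycle: a
touch-down signal fires when $\alpha$ completes protraction (crossing 36°
during swing) and excites the depressor CPG neuron (conductance 2.5 — strong
enough to terminate swing crisply), and a weaker lift-off signal fires at
full retraction (crossing 120° during stance, conductance 0.05).  Each
trigger charges an adaptation trace that decays with $\tau_p = 150$ ms, so
the signals are edge-like: a leg parked in a posture stops emitting them.
Swing duration is consequently nearly constant (~330 ms, the protraction
travel time), and the stance duration carries all period differences — the
same division of labour reported for walking insects.

## Inter-leg coordination

Each posterior LD system inhibits the levator CPG neuron of the next
anterior segment (HL→ML through `g_inh9` onto C9, ML→FL through `g_inh3`
onto C3; nothing projects onto the hind-leg LD pair, which is the rhythm
source).  The synaptic strength is a memoryless steep sigmoid of the
posterior $\beta$ (midpoint 45°, slope 1.5°): effectively "inhibit the
anterior levator while my leg is in the air".  The anterior leg can
therefore lift only after the posterior leg touches down, and its lag behind
the posterior leg is that leg's swing duration plus a short rebound latency.

Both gaits use this one mechanism; they differ only in the drive sets:

* **Tetrapod** (period ≈ 1184 ms): low LD drives; swing is a third of the
  long period, so the lift-off order is HL, ML, FL with lags near 1/3.  The
  front leg's levator carries a small *inhibitory* tonic drive
  (`g_app3` = −0.76, the sign convention for negative drive values), which
  makes the front leg silent without intersegmental input: it steps purely
  by rebound at each release.  This reproduces the observation that blocking
  its intersegmental synapse leaves the front leg standing on the ground.
* **Tripod** (period ≈ 617 ms): high LD drives; the ~330 ms swing is half
  the short period, so adjacent legs alternate and front and hind leg move
  in phase.  The front leg is intrinsically rhythmic in this mode and the
  chain phase-locks it.

A mode switch rewrites drives (and nothing else); the network graph is
identical in both modes.  The committed control transition runs tripod →
tetrapod.  The reverse direction is a known limitation: with the high tripod
levator drives a switch landing in mid-swing can leave the hind-leg levator
in a drive-sustained lifted plateau instead of re-entering the cycle.

## Calibration

The committed baseline (`inst/extdata/baseline.yaml`) was calibrated by
drive sweeps to the two printed control periods: 1184.4 ms tetrapod (target
≈ 1180) and 617.1 ms tripod (target ≈ 615), measured as the mean hind-leg
lift-off interval over a 20 s run at dt = 0.1 ms after a 5 s transient.
`calibrate()` re-runs this adjustment as a deterministic bisection on a
common scale factor over the six LD drives; doubling the drives roughly
halves the slow period, and the search exploits that monotone dependence.
Problem sizes throughout (20–28 s simulated per run, 16–28 onsets per
sweep) were chosen to give at least five complete slow cycles to every
classification window.

## Decoupling mechanisms

All three mechanisms are scheduled conductance rewrites, applied at an onset
time (absolute or anchored to a hind-leg lift-off) and optionally restored
later; because nothing projects forward-to-backward, manipulating a leg can
never perturb the legs behind it.

1. **Intersegmental synapse**: `block` zeroes the conductance; for
   `make_excitatory` the implementation distinguishes pinning a constant
   conductance with reversal potential 0 (`fixed = TRUE`, the front-leg
   experiment — the levator is held up, the leg parks lifted/protracted/
   extended) from flipping only the reversal potential while the strength
   stays $\beta$-weighted (`fixed = FALSE`, the middle-leg experiment — the
   middle leg then steps in synchrony with the hind leg, since it is
   *excited* exactly while the hind leg swings).
2. **Central drive to the LD CPG**: the `lift` variant applies tonic
   excitation to the levator neuron and tonic inhibition to the depressor,
   each 2.3 × a fixed reference conductance (0.76, the front-leg baseline
   levator magnitude) so that the same command means the same physical
   conductances in either starting mode.  The magnitude matters: well above
   this value the levator is simply drive-locked and the command succeeds at
   every onset phase; the committed value lies in the bistable regime where
   the entrained step cycle and the parked posture coexist, and the outcome
   depends on the onset phase.  Success hinges on whether the depressor can
   still answer its touch-down kick when the overrides land — the phase
   enters through the depressor's slow variable and through where the next
   inhibition pulse falls.  Measured windows: a contiguous 691 ms of the
   1184 ms tetrapod period succeeds (somewhat over half, in line with the
   reported 600–650 ms), but only 66 ms of the 617 ms tripod period
   (reported ≈ 50 ms, 8%) — the faster rhythm recaptures the leg at almost
   every phase; the two arcs tile the period exactly.
3. **Premotor interneurons**: `lift` sets `g_d` of the depressor-path IN to
   0 (full disinhibition, depressor MN clamped off) and raises the
   levator-path IN's `g_d` to 4 (levator MN tonically on); `ground` is the
   mirror image.  Acting downstream of the CPG, this works at every onset
   phase and in both modes, and restoring the two `g_d` values immediately
   re-admits the CPG rhythm — the most reliable mechanism, as the behavioral
   interpretation (search movements of the front legs) suggests it should
   be.

Setting both LD drives of the hind leg to zero does *not* stop the hind leg
in this implementation: its rhythm is sensory-sustained, so the leg
continues slow stepping instead of parking in one of two phase-dependent
postures.  Attempts to make the oscillator strictly drive-dependent (shifting
the PIC activation or inactivation midpoints) destroyed the calibrated
control rhythms, so the behaviour is documented as a limitation rather than
forced.  Similarly, the $\beta$-weighted excitatory middle-leg synapse in a
tetrapod start produces 1:1 synchrony with the hind leg here, not the
reported 2:1 slow stepping.  The hind leg is still parked faithfully by the
`ground` drive variant and by the premotor mechanism in both modes.

## Gait analysis

Lift-off and touch-down are threshold crossings of $\beta$ through 33° with
a ±1° hysteresis band (debouncing ripple without shifting square-wave event
times by more than a sample).  Phases are circular means of lift-off lags,
in fractions of the reference period.  Tripod is declared when the front-
hind lag is within 0.1 of zero and the middle leg within 0.1 of anti-phase;
tetrapod when both successive lags are within 0.1 of 1/3 in hind–middle–
front order; a leg without events for two reference periods is stopped, and
anything else is an unusual pattern.  The 0.1 tolerance (configurable) was
retained from the outset and classifies both committed control runs
correctly.  Steady postures are matched against the canonical triples with
a 5° tolerance after requiring every angle to vary less than 1° over the
window.

`make_fixture()` generates square-wave $\beta$ triplets with configurable
period, elevation duty cycle, per-leg lags and seeded Gaussian noise.  The
fixtures emulate exactly what the classifier consumes — event timing — and
deliberately nothing else: no transients, no entrainment dynamics, no
angle kinematics.  A classifier validated on them is validated as an event
geometry reader, which is the claim the round-trip property tests make; it
says nothing about whether the dynamical model produces such geometries
(the control-run tests cover that separately).

## Numerical choices and degenerate inputs

Classical RK4 at dt = 0.1 ms (halving dt moves the slow period by < 0.5%);
states sampled every 1 ms.  Latches and phasic triggers update once per
step between RK4 steps, and scheduled rewrites apply at step boundaries, so
runs are bit-reproducible; the only randomness in the package is fixture
noise under an explicit seed.  Slow variables are clamped to [0, 1] and
membrane potentials are checked against a sanity bound every step — a
violation aborts with the offending unit and time.  Conflicting rewrites of
one conductance at the same time, commands naming the hind-leg
intersegmental synapse, unknown drive keys and non-uniformly sampled traces
are all rejected with explicit errors.

## Known limitations

* Three ipsilateral legs only; after decoupling, any surviving coordination
  is necessarily read as a tetrapod-like pattern, and wave gait cannot be
  distinguished.
* No ground-reaction forces or body mechanics; ground contact is purely the
  $\beta \le$ threshold condition.
* The quantitative window anchor: the successful-onset arc is anchored
  mid-period here rather than starting right at a hind-leg lift-off; the
  window *length* is the calibrated quantity.
* The two red catalogue outcomes discussed above (hind-leg zero-drive stop,
  middle-leg 2:1 slow stepping), plus the tripod-direction mode switch.
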