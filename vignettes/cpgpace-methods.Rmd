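---
title: "cpgpace: models, tuning procedures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cpgpace: models, tuning procedures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`cpgpace` emulates, in software, a central-pattern-generator network of
spiking neuron populations running on a mixed-signal neuromorphic
processor, and the semi-automatic procedures needed to turn that noisy,
mismatched substrate into a controllable three-chamber cardiac pacemaker:
frequency tuning, phase-shift tuning, explicit period setting through a
fitted current-to-period mapping, and a closed-loop respiratory-feedback
mode that modulates the heart rate with the breathing phases (respiratory
sinus arrhythmia, RSA).

The package has three layers:

1. **Substrate** — adaptive exponential integrate-and-fire (AdExp) neurons
   and exponential current synapses whose per-element parameters are drawn
   with the measured device-mismatch statistics; a fixed-step
   exponential-Euler integrator (Rcpp).
2. **Network & readout** — the E/I oscillator building block, the ring of
   three coupled oscillators with external inhibitory feedback inputs, and
   the population-activity readout (exponential moving average, threshold
   crossings = chamber activation times).
3. **Procedures** — iterative and explicit tuning, the RSA calibration
   chain (breathing coefficient C, quadratic R-R model G(C), inhibitory
   rate map H with exponential correction and per-oscillator scaling), and
   a synthetic generator standing in for the non-public dog recordings.

## The substrate model

Each neuron integrates

$$\tau_m \dot V = -(V - E_L) + \Delta_T e^{(V - V_T)/\Delta_T} + R\,(I_{syn} + I_{DC} - w)$$

with a hard spike cutoff, reset and absolute refractory period; the
adaptation variable $w$ is available but disabled by default (the
pacemaker configuration switches spike-frequency adaptation off).
Synapses are exponential current synapses: each presynaptic spike adds
`gain x weight` (signed) to the postsynaptic current, which decays with
its realized time constant.  Units are ms / mV / nA / nS / pF throughout.

Nominal parameters are not printed for the emulated chip, so the defaults
are biologically plausible stand-ins, exposed via configuration:
$E_L = -70$ mV, $V_T = -50$ mV, $\Delta_T = 2$ mV, cutoff $-30$ mV, reset
$-70$ mV.  The excitatory membrane time constant is 50 ms — matching the
stated correspondence between the 50 ms activity-trace constant and the
neuron time constant — with $g_L = 20$ nS; the inhibitory population is
faster (30 ms) with a long refractory period (120 ms) so that each
inhibitory neuron contributes one spike per cycle and the inhibition
delivered per cycle is stereotyped.

**Where the slow rhythm comes from.**  With 50 ms membranes alone, a
200–700 ms oscillation period is unreachable at robust drive margins.
The slow timescale is carried by the inhibitory-to-excitatory synapse
class (`c`), given a nominal time constant of 90 ms (a slow, GABA-B-like
synapse type; the emulated processor provides such a type).  One cycle
is: the E population climbs under its DC drive, the first crossing
recruits the population explosively through the self-excitation `a`, the
burst drives the I population (`b`), the four inhibitory neurons fire
once each and reset the E population with a large, slowly decaying
current; the next burst occurs when that current has decayed back to the
DC margin.  The period is therefore approximately
$\tau_c \ln(B / (I_{DC} - I_{rheo}))$ plus burst overheads — smoothly and
monotonically controlled by the DC current (coarse knob, exponential
sensitivity) and by the E-to-I weight `b` (fine knob: stronger drive
activates the inhibition earlier).  Ring-coupling synapses (`d`, `e`) use
a 120 ms time constant (NMDA-like) so that the excitatory kick from a
predecessor can still act at the 110 ms chamber lag.

**Mismatch.**  Per-element parameters are truncated-Gaussian draws around
their class nominal: membrane time constants with CV 15% (midpoint of the
reported 13–18% range, applied through the capacitance; the input
resistance is shared per core), synaptic weights with CV 22% (14–30%),
synaptic time constants at the 30 ms core calibration with an absolute
4 ms sd (the measured 30 ± 4 ms over 256 synapses), other synapse classes
with CV 8.5% (7–10%).  Non-positive draws are resampled; if more than 1%
of draws need resampling a warning is raised.  Identical seeds give
byte-identical instances; there is no hidden randomness in the simulator.

## Readout

Population activity is an exponentially weighted spike sum
($\tau = 50$ ms; each spike peaks at 1), computed off the emitted spikes
— never from membrane state — on the integration grid with a recursive
update that is exact at grid points.  A population is activated when the
trace crosses `fraction x population size` upward (50% of n=16 for E, 25%
of n=4 for I), with hysteresis (the trace must fall below threshold
before a new activation) and a 100 ms debounce: at some drive levels the
population recruits in two waves a couple of milliseconds apart and the
trace briefly dips below threshold mid-burst; the debounce treats this as
the single chamber activation it physiologically is.  The activation
timestamp is the linearly interpolated crossing time.

## Iterative tuning

The four-step procedure: unused components off (adaptation, unused
synapse classes), dispensable parameters at defaults (time constants and
gains fixed; only weight terms and DC are tuned), per-oscillator
frequency tuning in isolation, then phase tuning on the coupled ring.

*Frequency*: the DC input is stepped multiplicatively (×1.1, halving on
overshoot; increase DC if too slow) until within 50 ms of target, then
the E-to-I weight (×1.05 steps) until within the fine tolerance.  The
weight's excursion is limited to one octave around nominal — pushing it
further distorts the inhibitory burst elsewhere in the DC range — and a
small DC vernier step (×1.008) absorbs what the weight cannot.

*Master-clock detuning.*  On the deterministic substrate an excitatory
kick can only advance, never delay, a successor.  A stable
delay-locked ring therefore requires the first oscillator (the right
atrium) to be strictly the fastest: it free-runs as the master clock and
the marginally slower successors are entrained by the coupling kicks.
The frequency stage deliberately tunes successors +3 ms slower per ring
position (0.5% — well within "roughly the same frequency"); on hardware,
substrate noise resolves this ambiguity instead.

*Phase*: the warm-up stagger (one small inhibitory pulse per oscillator
at t = 1 ms, weight derived from the requested delay and the DC margin)
starts the deterministic ring near the target phase arrangement — the
role played by noise on hardware.  Delays are then measured signed
against their targets, together with their per-cycle drift.  The
controller distinguishes three situations per ring edge: a *slipping*
pair (persistent drift — the successor is not entrained) is corrected
through its coupling weight `d` (proportional multiplicative steps with
halving, counteracted on the opposite-sign partner edge so the total
excitatory input and hence the period is preserved); an *entrained but
misplaced* pair is moved by adjusting the warm-up placement (the lock
position beyond the kick-response peak is quasi-neutral); pairs that
ignore placement changes are trigger-pinned and routed back to the
weight channel.  The edge into the master oscillator closes the ring and
serves as the counteraction dump.  Convergence requires all delays
within the phase tolerance *and* residual drift small over the full
verification window; the result is verified (and if needed polished) at
the 30 s window.

## Explicit period setting

A probe of the DC-to-period response (0–200 nA; unstable points, detected
by irregular activation intervals, are recorded as missing and trend
outliers dropped) is fitted per oscillator with the double exponential
decay $f(T) = x_1 e^{-x_2 T} + x_3 e^{-x_4 T}$ (weighted for relative
error; single-exponential-plus-constant fallback when the two rates
collapse).  Setting a period applies $f(T)$ feed-forward — no iterative
correction — plus three deterministic, once-calibrated corrections that
keep the ring ordered away from the tuned period:

* coupling weights are rescaled by $e^{(T_0 - T)/90}$, keeping the
  kick-to-drive-margin ratio (and so the entrainment geometry) invariant
  as the DC margin grows exponentially toward short periods;
* the second ring edge gets an extra boost $\min(4.5, (T_0/T)^{1.8})$ —
  its kick acts at an older synaptic age and loses authority faster;
* successors are commanded slower by an absolute stagger
  $8 + 0.03\,\max(0, 555 - T)$ ms (the analogue of the master-clock
  detuning, widened to beat mapping errors of ~1%), with the third
  oscillator's extra stagger compressed to 1.4x and all commanded
  targets clamped into the fitted range;
* the short end (below 300 ms) is genuinely marginal and its best
  correction differs between substrate draws, so `calibrate_explicit()`
  tries a small preset family of corrections once per instance at the
  shortest target — alongside the mapping fit, not per command — and the
  chosen variant is applied feed-forward thereafter.

With these, commanded periods between 200 and 700 ms are met within
about 1–2% with the ring order preserved; accuracy is, as expected,
lower than with iterative tuning.

## RSA feedback chain

The breathing coefficient C is computed from phase-onset times only
(robust to drift and offsets): a logistic ramp pinned to 0 at each
exhalation onset, a mirrored logistic decay during inhalation.  The
logistic form is one consistent reading of the description; its
parameters are explicit, exposed, and optimized (Nelder–Mead) to
maximize the R² of the quadratic fit $T_h = G(C) = x_1C^2 + x_2C + x_3$
of R-R intervals on the interval-averaged coefficient.

The inhibitory rate map H is non-parametric: the constant-rate probe
table (rate → period, isotone-regressed since the period is physically
non-decreasing in the rate) is inverted into a monotone interpolated
period → rate table, anchored at rate 0 for the unperturbed period, flat
beyond the probed range.  Because time-varying input reaches shorter
effective inhibition than a constant rate of the same nominal value, the
base map cannot produce the longest delays; `T_thr` is measured as the
maximal delay achieved under realistic input, and the additive
exponential correction $e^{(T_h - T_{thr})k}$ is escalated over a k-grid
until the longest delays seen in the (synthetic) data are achieved —
refined by a short bisection so the achieved maximum does not vastly
overshoot the target (which would make high-C intervals bimodal), and
stopping early if the oscillation collapses.  Rates are capped at
2000 Hz; without a cap the exponential term can request unbounded rates.
A final harmonization adjusts per-oscillator scaling factors s from
pairwise order checks on the coupled system (reference oscillator fixed
at s = 1).

Rate profiles are encoded into spike trains by deterministic
time-rescaling (spike at every integer crossing of the integrated rate),
matching an interface that consumes explicit inter-spike intervals; a
Poisson mode exists behind a flag with a mandatory seed.  The ventricular
population's activation times serve as the R-peak analogues.

## Synthetic validation data

The original validation recordings (surface ECG + respiration of healthy
dogs at rest) are not public.  The generator emulates their statistical
structure: raised-cosine breathing cycles of 5 ± 0.5 s (exhalation
fraction 0.55), linear drift, slow wander and additive noise; R-peaks
are placed sequentially so that each interval equals
$G_{true}(\bar C) + \varepsilon$, solved per beat by fixed-point
iteration.  $G_{true} = 320 C^2 + 180 C + 450$ spans roughly 450–950 ms,
consistent with resting-dog R-R intervals and with 900–1000 ms longest
delays.  The noise sd was calibrated once (sd = 94 ms, over three seeds)
so that the default analysis pipeline attains R² ≈ 0.64 on the 2.3 min
G-fit trace, and then frozen.  What a green test establishes is
therefore that the *pipeline* reproduces the assumed statistical
structure — not that the generator is a faithful dog; in particular the
generator has no ECG morphology, no apneas or arrhythmias, and its
breathing-cycle statistics are physiologically motivated stand-ins.

## Numerical choices

Fixed step dt = 0.1 ms, exponential-Euler for membrane and synaptic
states (exact for the leaky dynamics between events); spikes registered
at step boundaries, so measured periods are accurate to well below the
1% oracle tolerance; the exponential spike-initiation term is frozen
over a step and its argument capped to avoid overflow.  Simulations are
deterministic given (instance, inputs); all randomness flows through
recorded seeds (a single master seed fans out via a fixed integer hash).
Measurement windows: 30 s for final verification (as in the reference
measurements), 8–12 s inside iteration loops for speed; the initial
lock-in transient (up to ~10 s at the warm-up start) is excluded.

## Known limitations

* The emulation reproduces the *class* of behaviours, not the chip's
  exact parameter values (which are not published); all nominal circuit
  values are stand-ins.
* Stability of the ring order under explicit period setting relies on
  calibrated feed-forward corrections; occasional transient order swaps
  remain near the short end of the range and at a few isolated targets.
* The closed loop reports order violations during the deepest
  modulation excursions; they are reported, not fatal, and do not
  prevent the R-R/C relation from being reproduced.
* Only a directed ring of oscillators is supported; the two ventricles
  are modelled as one combined oscillator.
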