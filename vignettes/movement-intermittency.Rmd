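---
title: "Movement intermittency from optimal feedback control: model and analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement intermittency from optimal feedback control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

During slow visuomotor tracking, movement speed fluctuates in
quasi-regular pulses -- submovements -- at roughly 2--3 per second.
`ofctrack` implements a minimal closed-loop account of this
intermittency: a stochastic optimal feedback controller whose delayed,
noisy visual feedback passes through intrinsic state-estimation
dynamics.  Submovements arise without any internal clock, from
constructive interference between broadband motor noise and delayed
feedback corrections.  The package simulates behavioral sessions
(human-style circular tracking, monkey-style center-out torque tasks
with multichannel field potentials) and provides the complete analysis
chain used to characterize the phenomenon: velocity power spectra and
submovement-peak regression, perturbation transfer functions, controller
architecture inference, Welch coherence suites, submovement-triggered
averages, and principal-component trajectories.

## The model

The controlled state is the 1D relative position of cursor and target,
in task units (1 unit = 1% of the target-circle radius).  Time advances
in steps of $\Delta t$; motor noise is white acceleration,

$$
\begin{bmatrix} x_k \\ v_k \end{bmatrix} =
\begin{bmatrix} 1 & \Delta t \\ 0 & 1 \end{bmatrix}
\begin{bmatrix} x_{k-1} \\ v_{k-1} \end{bmatrix} +
\begin{bmatrix} 0 \\ \Delta t \end{bmatrix} a_k,
\qquad a_k \sim N(0, \sigma_a^2),
$$

and vision supplies a delayed, noisy position measurement
$y_k = x_{k-D} + \epsilon_k$, $\epsilon_k \sim N(0,\sigma_\epsilon^2)$,
where the loop delay $D$ combines an intrinsic visuomotor latency
$\tau_{int}$ with an experimentally imposed extrinsic display delay
$\tau_{ext}$.

Four coupled ingredients close the loop:

1. **Steady-state Kalman estimation** (`design_kalman_gains()`).  The
   constant innovation gains $(K_{pos}, K_{vel})$ solve the discrete
   algebraic Riccati equation for the plant above; they depend only on
   $\Delta t$ and the noise ratio $\rho = \sigma_a/\sigma_\epsilon$,
   which sets the estimator's cutoff near $\sqrt{\rho}/2\pi$ (2.5 Hz at
   the default $\rho = 250\,\mathrm{s^{-2}}$).  The per-step estimate
   increments $\Delta\hat{x}, \Delta\hat{v}$ double as the synaptic
   input to two notional neural populations and drive the simulated
   field potentials.
2. **Forward projection** (`project_estimate()`).  The measurement
   reflects the past; the controller acts on
   $\hat{z} = \hat{x} + \tau_{int}\hat{v}$, the linear prediction one
   intrinsic delay ahead.  This gives the loop its predictive,
   frequency-dependent phase behavior: corrections to slow errors occur
   earlier than a fixed-latency servo would allow.
3. **PI control from LQR** (`design_pi_gains()`).  The cost penalizes
   squared position error plus the squared *rate of change* of the motor
   command ($q x^2 + r (\Delta u/\Delta t)^2$, defaults $q = 1$,
   $r = \Delta t^2$); the optimal policy integrates to a
   proportional-integral law, whose fast-loop transfer
   $H_{PI} = (K_P + K_I/i\omega)/(1 + K_P + K_I/i\omega)$ equals 1 at DC
   and $K_P/(1+K_P)$ at high frequency.
4. **Smith-Predictor delay compensation** (`simulate_tracking()`).  An
   internal copy of the motor command, delayed by the known loop delay,
   is subtracted from the measurement, so corrections do not reverberate
   around the external loop.  The closed loop is then formally
   equivalent to a feedforward comb filter: the displayed cursor is the
   motor noise plus a delayed, filtered, sign-inverted copy of itself.
   Noise components with period $2(\tau_{int}+\tau_{ext})/N$ (odd $N$)
   interfere constructively, producing submovement peaks at
   $f = N / (2(\tau_{int}+\tau_{ext}))$; even fractions interfere
   destructively.

The analytic force and cursor responses are
$H_{force}(i\omega) = e^{-i\omega(\tau_{int}+\tau_{ext})} H_{PI} H_{y\to\hat{z}}$
and $H_{cursor} = 1 - H_{force}$ (`closed_loop_transfer()`).  The
equality of the full loop with the feedforward rearrangement is asserted
sample-for-sample in the test suite, and the Riccati solutions are
checked against independent value-iteration oracles.

One consequence of the literal composition deserves note: the forward
projection amplifies a sinusoid of frequency $\omega$ by
$|1 + i\omega\tau_{int}|$, so the model's force amplitude response
exceeds unity around the estimator resonance even though measured human
force responses are sub-unity.  The alternative composition (closing the
fast loop around the estimator as well) normalizes the magnitude but
abolishes the frequency-dependent phase delay that the perturbation data
show.  We keep the composition with the correct phase signature and
treat the magnitude excess as a known limitation of the 1D abstraction.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `dt` | 0.01 | s | simulation step (100 samples/s) |
| `tau_int` | 0.26 | s | intrinsic visuomotor delay (26 samples) |
| `tau_ext` | 0 | s | extrinsic display delay |
| `rho` | 250 | 1/s^2 | process/measurement noise ratio; sets the 2--3 Hz intrinsic resonance |
| `sigma_eps` | 1 | task % | measurement noise SD (sets the scale; responses are scale-free) |
| `q`, `r` | 1, `dt^2` | -- | LQR weights on position error and command rate |
| `f_target` | 0.2 | rot/s | target rotation rate |
| `r_target` | 100 | task % | target radius |
| `delta` | 50 | task % | score tolerance |

Delays are buffered with round-to-nearest-sample.  Estimation starts
from rest; human-style analyses begin 5 s into each trial so the
estimator transient never enters a spectral window.

## What the synthetic sessions emulate

**Human sessions** (`generate_human_session()`): 20-s trials at 50
samples/s of 2D circular tracking.  The delay study runs 70 trials (14
at each of 0--400 ms extrinsic delay); the perturbation study runs 144
trials (12 per cell of perturbation frequency 0--5 Hz crossed with 0 and
200 ms delay).  Each trial embeds a fresh 1D simulation as the
along-track angular error; the radial coordinate stays on the target
circle, because the kinematic analyses only use the angle subtended at
the screen center.  Rotation direction alternates pseudorandomly and
signs the in-loop perturbation.  The model runs at 100 samples/s and the
error trace is decimated to the behavioral rate by band-limited
resampling; bare subsampling would alias the broadband measurement-noise
feedthrough of the force velocity into the submovement band.  Display
perturbations are sinusoidal phase modulations of the target angle whose
peak angular velocity equals the target's for every frequency; they
displace the displayed cursor and the measurement, never the plant.

**Monkey sessions** (`generate_monkey_session()`): delay blocks (0, 200,
400, 600 ms) of center-out trials.  Radial torque is a stereotyped reach
profile (rise to 70% of full scale, hold, return) plus the scaled
simulated tracking error (2 task % per model unit, giving radial-speed
fluctuations around 115 %/s so that submovement rates under the 100 %/s
threshold resemble recorded sessions).  Twelve field-potential channels
mix the two unit-variance synaptic-input components through fixed,
channel-specific gains and phases (a chronic array sees the same two
populations from different vantage points), plus a shared 1/f background
(SD 0.5) and independent white noise (SD 0.3); channels are resampled to
488 samples/s by polyphase band-limited interpolation.  Because the
closed-loop drive is red below the estimator cutoff, the
position-population input inherits the unbounded random-walk drift of
the 1D motor error -- an artifact of the abstraction; a 1 Hz
second-order zero-phase acquisition high-pass (AC coupling, standard in
field-potential recording) is applied to the components before variance
normalization so that delta-band content carries the channel variance,
as it does in recorded potentials.

What the generator deliberately does **not** emulate: off-trajectory
(radial) error, force-sensor or tremor noise on the cursor,
biomechanics, eye movements, learning within trials, or
inter-subject variability beyond seeds.  Two consequences matter for
interpreting green tests.  First, with no cursor-private noise, cursor
speed and field potentials are linear mixtures of the same two noise
sources, so their coherence cannot show comb-tracking peak shifts -- the
synthetic check asserts the presence of coherence alongside the
delay-dependent cursor-power shifts, while the peak-shift phenomenon
belongs to real recordings.  Second, passing tests validate the model
and the chain, not the claim that real subjects are Smith Predictors.

## Analysis-chain conventions

* **Velocity spectra** (`velocity_power_spectrum()`): averaged
  periodograms of non-overlapping 512-sample rectangular windows (10.24
  s at 50 samples/s) starting 5 s into each series; window means removed
  (the target-rotation component); Parseval-consistent scaling.
* **Peak readout**: peak *lists* come from strict local maxima of the
  7-point moving-average smoothed spectrum, localized on the raw
  spectrum by argmax within 3 bins plus quadratic interpolation
  (`find_spectral_peaks()`); plateau ties resolve to the first bin.  The
  *primary* submovement frequency is read out as the power-weighted
  centroid of the smoothed spectrum above 60% of the band maximum
  (`primary_peak_frequency()`): the constructive-interference peak is
  broad and rides the red noise-velocity background, so a bare argmax
  jitters across near-tied bins (SD ~0.1 Hz across seeds) while the
  centroid is stable to ~0.02 Hz.
* **Transfer estimates** (`estimate_transfer()`): complex demodulation
  of cursor and force angular velocities at the perturbation frequency
  over a fixed window, normalized so a pure perturbation gives unity;
  complex means across trials.  The force response is stored in the
  closed-loop convention in which a delayed correction *opposing* the
  displayed perturbation has positive gain and is referred to the
  displayed (extrinsically delayed) timeline -- the only convention in
  which $H_{cursor} = 1 - H_{force}$ holds in the data and the intrinsic
  phase delay follows by subtracting $\tau_{ext}$.  The phase branch
  places the intrinsic delay in $[0, 1/f_{pert})$; it wraps if the true
  latency exceeds one perturbation period, so raw complex responses are
  always stored.
* **Welch suite** (`spectral_suite()`): Hanning windows of
  $2^{\mathrm{round}(\log_2 34 f_s)}$ samples (about 34 s) with 75%
  overlap on task-locked-removed per-trial sections; magnitude-squared
  coherence $|S_{ab}|^2/(S_{aa}S_{bb})$; imaginary coherence
  $\mathrm{Im}(S_{ab})/\sqrt{S_{aa}S_{bb}}$ smoothed per pair in signed
  form (16-point Hanning) *before* magnitude-averaging across pairs --
  rectifying unsmoothed pair estimates floors the average at the
  estimator noise level.  Power and coherence are smoothed last with the
  same 16-point window.
* **Resonance readout** for broad flat-topped spectra (field-potential
  power, imaginary coherence): power-weighted centroid above 50% of the
  band maximum (`peak_frequency(method = "centroid")`).
* **Submovements** (`detect_submovements()`): strict local maxima of the
  zero-phase 10 Hz low-passed, task-locked-removed radial speed
  exceeding 100 %/s; plateaus resolve to their first sample; no
  refractory interval.  Removing the task-locked profile first prevents
  the stereotyped reach transients from registering as delay-independent
  pseudo-submovements.
* **Triggered averages** (`smta()`): symmetric windows around event
  times, edge events dropped.  The delayed second feature is located per
  block on the across-block-mean residual by matched filtering with the
  block's own central template (`smta_second_feature()`), since the
  central potential and the delay-independent intrinsic cycle are common
  to all conditions.
* **Component plane** (`lfp_pca()`): channel-covariance
  eigendecomposition of the no-delay block, signs fixed by the dominant
  loading, the same plane reused for all conditions and for
  impulse-response projections so rotation directions are comparable.
* **Architecture inference** (`infer_gain_smith()`,
  `infer_gain_simple()`): algebraic inverses of the two closed-loop
  decompositions,
  $G_{SP} = H_{force} e^{+i\omega\tau}$ and
  $G_{FB} = H_{force} e^{+i\omega\tau}/(1 - H_{force})$; near-singular
  denominators are flagged, never dropped silently.
* **Cursor-target lag** (`cursor_target_lag()`): least-squares alignment
  of unwrapped angles (a normalized correlation is offset-invariant and
  blind to a delay of the dominant rotation ramp).

## Numerical choices and degenerate inputs

Riccati iterations run to a 1e-14 fixed point and error out rather than
return an unconverged value.  $\omega = 0$ in the PI transfer is the
analytic limit 1.  Transfer functions are evaluated in discrete time at
$z = e^{i\omega\Delta t}$ with the discretized (round-to-sample) delay,
so analytic curves match simulations exactly.  Zero-variance synaptic
inputs, all-masked channels, empty bands, windows exceeding trials,
origin-crossing trajectories, and flat signals all raise typed errors.
All stochastic outputs are bit-reproducible from (seed, configuration);
session generators fan a single seed into per-trial/per-block child
seeds.

## Problem sizes

The shipped tests and the acceptance script use ensembles of 12
independent 400-s simulations per delay condition for spectral peaks
(about 30 s of compute for five delays), and one synthetic monkey
session of four 120-trial blocks (6 min of simulated behavior per block)
for the neural analyses.  These sizes put the primary-peak readout's
seed-to-seed variability near 0.02 Hz and the resonance centroids within
about 0.2 Hz across delay blocks.

## Example

```{r example}
library(ofctrack)

study <- delay_peak_study(seed = 42, duration = 400, n_runs = 12)
study$peaks
study$regression

session <- generate_monkey_session(task_config(), ofc_config(),
                                   seed = 7, n_trials = 120)
analysis <- analyze_monkey_session(session, half_window = 1.2)
sapply(analysis$blocks, function(b)
  peak_frequency(b$suite$freqs, b$suite$imcoh_lfp_lfp, c(0.5, 5),
                 "centroid"))
smta_second_feature(analysis)
```

## Known limitations

* The 1D abstraction makes the motor-error random walk unbounded; the
  acquisition high-pass absorbs this for the field-potential synthesis,
  and the force-response magnitude excess noted above is the kinematic
  side of the same artifact.
* The primary submovement peak of the *model's* velocity spectrum sits
  slightly below the noiseless constructive-interference frequency
  (about 1.66 Hz rather than 1.92 Hz at zero extrinsic delay) because
  the peak is weighted by the red motor-noise background; measured human
  primary periods show the same displacement.
* Intrinsic phase delays are only identified modulo one perturbation
  period; at 5 Hz the true ~0.3 s latency wraps.
* Coherence between synthetic field potentials and cursor speed is
  present but cannot reproduce the comb-tracking coherence peaks of real
  recordings (no cursor-private noise is modeled).
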