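# ofctrack

Simulation and analysis of movement intermittency under optimal feedback
control, for researchers in sensorimotor neuroscience who want a tested,
reproducible implementation of the closed-loop account of submovements.

During slow visuomotor tracking, movement speed pulses 2–3 times per
second. `ofctrack` implements the parsimonious explanation that these
submovements are neither a clock nor discrete motor events: they are
constructive interference between broadband motor noise and continuous,
delayed feedback corrections filtered by intrinsic state-estimation
dynamics. The package contains

* **the controller**: a discrete-time loop combining a steady-state
  Kalman filter for the constant-velocity plant
  `x_k = x_{k-1} + Δt v_{k-1}`, `v_k = v_{k-1} + Δt a_k` with
  position-only measurement; forward projection of the estimate over the
  intrinsic delay, `ẑ = x̂ + τ_int v̂`; a proportional–integral law from
  the LQR cost `Σ q x² + r (Δu/Δt)²`; and Smith-Predictor compensation
  of the loop delay. Its closed-loop responses are
  `H_force(iω) = e^{-iω(τ_int+τ_ext)} H_PI(iω) H_{y→ẑ}(iω)` and
  `H_cursor = 1 − H_force`, a comb filter with constructive-interference
  peaks at `f = N / (2(τ_int + τ_ext))`, odd `N`;
* **synthetic sessions**: human-style circular tracking (delay and
  sinusoidal-perturbation designs) and monkey-style center-out torque
  blocks with 12-channel field potentials synthesized from the
  estimator's synaptic inputs;
* **the analysis chain**: velocity power spectra, submovement-peak
  extraction and period-versus-delay regression, perturbation transfer
  functions and intrinsic phase delays, controller-architecture
  inference, Welch power/coherence/imaginary-coherence suites,
  submovement-triggered averages, and principal-component trajectories.

## Worked example

Simulate the default model (Δt = 0.01 s, τ_int = 0.26 s, ρ = 250 s⁻²)
over five extrinsic delays and regress the primary submovement period on
the delay:

```r
library(ofctrack)
study <- delay_peak_study(seed = 42, duration = 400, n_runs = 12)
study$peaks
#>   tau_ext      freq    period
#> 1     0.0 1.6588024 0.6028446
#> 2     0.1 1.3051148 0.7662161
#> 3     0.2 1.0238769 0.9766799
#> 4     0.3 0.8637747 1.1577092
#> 5     0.4 0.7612071 1.3137029
study$regression
#> Period-vs-delay regression (harmonic N = 1, 5 points)
#>   slope = 1.813 [1.654, 1.973] (predicted 2/N = 2.000)
#>   intercept = 600.8 ms; implied tau_int = 300.4 ms; R2 = 0.998
```

The primary submovement peak falls from about 1.7 Hz with no display
delay to about 0.76 Hz at 400 ms, and the period grows linearly with the
delay: the slope near 2 identifies the peaks as the first
constructive-interference harmonic, and the intercept implies an
intrinsic visuomotor latency of about 0.30 s. The analytic counterpart:

```r
cfg <- ofc_config()
closed_loop_transfer(2, cfg)$cursor$h
#> |H_cursor(2 Hz)| = 4.44   # > 1: amplification at the interference peak
```

For the neural side, `generate_monkey_session()` +
`analyze_monkey_session()` produce, per delay block, submovement events,
triggered averages (whose flanking troughs and delayed second feature
shift with the extrinsic delay), and spectral suites in which the
cursor-speed peak is delay-dependent while the field-potential
delta-band resonance (~3 Hz imaginary coherence) is not — the central
dissociation between extrinsic and intrinsic dynamics.

See `vignettes/movement-intermittency.Rmd` for the model assumptions,
estimator conventions, and known limitations.

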