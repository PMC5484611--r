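# oscibin

Oscillations in mesoscopic brain signals modulate not only how often neurons
fire, but also how *jointly* they fire: pairwise spike covariances lock to
the ongoing cycle. `oscibin` is an R package for studying this effect in the
simplest analytically tractable setting — recurrent random networks of
binary (0/1) neurons under Glauber dynamics, driven by a global sinusoidal
input `h_ext sin(ωt)`. It is aimed at computational neuroscientists who want
closed-form, ODE and simulation views of the same model, side by side.

The package implements three consistent layers:

1. **Closed-form linear response.** Around the self-consistent stationary
   state (`solve_stationary()`, with `calibrate_thresholds()` to hit target
   activities `m = τν`), the first-harmonic response of the mean activities
   is a low-pass filter per eigenmode of the effective connectivity
   `W = diag(S) (K∘J)`:

   `M¹ = U diag(1 / (iτω + 1 − λ)) U⁻¹ S h_ext`,

   and the covariance response `C¹` (in `covariance_response()`) solves the
   linearized covariance equation in the same eigenbasis. `C¹` decomposes
   *exactly* into three mechanisms: the **direct drive** (the input
   modulates the susceptibility via the gain curvature, filtered once), the
   **recurrent drive** (network feedback of the oscillating means, filtered
   twice), and the **modulated autocovariances** (binary units' variances
   `a = m(1−m)` follow the mean and drive the covariances, filtered twice).
   In balanced networks the first two partially cancel at low frequency;
   complex eigenvalue pairs produce resonances at
   `f_res = |Im λ| / (2πτ)` (`resonance_frequency()`).

2. **Full mean-field moment ODEs.** `integrate_moments()` integrates the
   coupled equations for `m(t)` and `c(t)` without linearization (stiff
   `lsoda`, rtol 1e-8), and `extract_harmonics()` projects trajectories onto
   drive harmonics 0–2.

3. **Stochastic simulation.** `build_network()` realizes the fixed
   in-degree random graph, `simulate_glauber()` runs exact event-driven
   Glauber dynamics (Rcpp core, reproducible by seed), and
   `cyclostationary_stats()` estimates the phase-resolved ensemble
   statistics `m(φ), a(φ), c(φ)` with standard errors, plus the
   population-activity error ellipse (`population_ellipse()`).

`run_frequency_sweep()` ties the layers together over a frequency grid and
returns one tidy tibble; result objects have `tidy()`, `glance()` and
`autoplot()` methods. Three presets ship with the package
(`preset_network()`): a single inhibitory population, a homogeneous E-I-X
network, and a biologically parameterized E-I network (layer 2/3 barrel
cortex constants). Network configs serialize to JSON
(`write_spec_json()` / `read_spec_json()`), and a thin command-line
interface wraps the same functions (`inst/cli/oscibin.R`, subcommands
`stationary`, `linear-response`, `ode`, `simulate`, `sweep`, `presets`).

## Worked example

The biologically parameterized preset, solved and probed at 80 Hz:

```r
library(oscibin)

spec <- preset_network("biological_EI")   # thresholds calibrated to m = tau * nu
st <- solve_stationary(spec)
tidy(st)
#>   population kind         m nu_hz      a     mu sigma sigma_network sigma_shot
#> 1 E          dynamic 0.0450  18.0 0.0430 -11.4   10.3          2.55       2.79
#> 2 I          dynamic 0.270  108.  0.197    8.30  11.0          4.47       4.56
#> 3 X          clamped 0.1     40   0.09     0      0            0          0
```

The dynamic populations sit at 18 and 108 Hz (`m = τν` with τ = 2.5 ms) by
calibration; the shot-noise part of the network-generated input width comes
out at 2.79 (E) and 4.56 (I) input units on top of `sigma_noise = 10`.

```r
glance(st)
#>   n_pop max_re_lambda stable f_res_hz iterations residual
#> 1     3             0 TRUE       158.         32 2.11e-13
```

The effective connectivity has one complex-conjugate eigenvalue pair
(λ = −0.194 ± 2.485i), hence a damped resonance of the mean activities near
158 Hz (and covariance kernels also near 316 Hz). The first-harmonic
response at 80 Hz, with its three-term decomposition:

```r
tidy(covariance_response(st, f = 80, h_ext = 1))
#>    kind       component term   f_hz   amplitude  phase
#>  1 mean       E         total    80 0.00187      0.697
#>  2 mean       I         total    80 0.0197      -0.172
#>  4 covariance EE        total    80 0.000000956  2.53
#>  5 covariance EI        total    80 0.00000337   0.930
#>  6 covariance II        total    80 0.0000209    2.07
#>  ...
```

so at 80 Hz the E-E covariance is modulated with amplitude ~9.6e-7
(comparable to its stationary value of 7e-6) and leads the drive by 2.5 rad.
Sweeping frequency and taking the peak of the conventional Fourier
coefficient of the rate modulation, `|M¹| / (2τ)`:

```r
f <- exp(seq(log(1), log(1000), length.out = 200))
amps <- vapply(f, function(fk) Mod(mean_response(st, fk, h_ext = 1)), numeric(3))
apply(amps, 1, max) / (2 * spec$tau) * 1000
#>     E      I      X
#> 0.784  4.855  0.000   # Hz
```

i.e. a unit-amplitude drive maximally modulates the excitatory rate by
~0.8 Hz and the inhibitory rate by ~4.9 Hz. All of these numbers are
asserted (against simulation or independent numerics) in the test suite.

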