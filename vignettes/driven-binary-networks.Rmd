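---
title: "Cyclostationary moments of periodically driven binary networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cyclostationary moments of periodically driven binary networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscibin)
```

## The model

`oscibin` analyses recurrent random networks of *binary* neurons: each unit
is either inactive ($n_i = 0$) or active ($n_i = 1$). The network evolves
under asynchronous Glauber dynamics: update events arrive as a Poisson
process of rate $N/\tau$, and the chosen neuron is set active iff

$$\sum_k J_{ik} n_k + h_\mathrm{ext}\sin(\omega t) + \xi_i \;\ge\; \theta_i ,$$

with fresh Gaussian noise $\xi_i \sim \mathcal N(0, \sigma_\mathrm{noise}^2)$
at every update. The time constant $\tau$ is both the mean inter-update
interval and the duration for which a unit's state influences its targets,
so the single-unit transfer is a first-order low-pass filter. Connectivity
is population-structured: a neuron in population $\alpha$ receives exactly
$K_{\alpha\beta} = \mathrm{round}(p_{\alpha\beta} N_\beta)$ inputs of weight
$J_{\alpha\beta}$ from population $\beta$ (fixed in-degree, senders drawn
uniformly without replacement, no self-connections). *Clamped* populations
(an external pool) have a pinned mean activity, no inputs and no threshold;
their Bernoulli variance still injects shared-input fluctuations.

The observables are the population-averaged mean activities
$m_\alpha(t)$, the single-unit variances $a_\alpha = m_\alpha(1-m_\alpha)$
(a binary unit's variance is fixed by its mean — this is one of the two
mechanisms below), and the population-averaged zero-lag pairwise
covariances $c_{\alpha\beta}(t)$, defined across realizations, with $i \ne j$.

## Gaussian moment closure

Because each neuron pools many weakly correlated inputs, the summed input is
taken as Gaussian with mean and variance

$$\mu_\alpha = \sum_\beta K_{\alpha\beta} J_{\alpha\beta} m_\beta + h_\mathrm{ext}\sin\omega t,
\qquad
\sigma_\alpha^2 = \big[(K{\odot}J)\, c \,(K{\odot}J)^\mathsf{T}\big]_{\alpha\alpha}
 + \sum_\beta K_{\alpha\beta} J_{\alpha\beta}^2\, a_\beta + \sigma_{\mathrm{noise},\alpha}^2 .$$

Two conventions for the "network-generated" width coexist in the
literature, and the package exposes both: `sigma_network` is the full
non-noise part (both terms above; it satisfies
$\sigma^2 = \sigma_\mathrm{network}^2 + \sigma_\mathrm{noise}^2$), while
`sigma_shot` is the shot-noise (binomial) part
$\sqrt{\sum_\beta K J^2 a_\beta}$ alone — the quantity usually quoted as the
intrinsic noise level of a random network. For the biologically
parameterized preset the two differ by ~10% because the covariance term is
negative.

The expected activation is then the Gaussian-smoothed threshold
(`gain_phi`), $\varphi = \tfrac12\,\mathrm{erfc}\!\big((\theta-\mu)/\sqrt{2}\sigma\big)$,
with susceptibility $S = \partial\varphi/\partial\mu$ (`susceptibility`) and
curvature $\partial S/\partial\mu$ (`dsusceptibility_dmu`). Truncating all
cumulants above second order gives the coupled moment ODEs integrated by
`integrate_moments()`:

$$\tau \dot m = -m + \varphi(\mu(t), \sigma(t)), \qquad
\tau \dot c = -2c + \mathrm{diag}(S)\,(K{\odot}J)\,\big(c + \mathrm{diag}(a/N)\big) + (\cdot)^\mathsf{T}.$$

`sigma_dynamics = "full"` (default) lets $\sigma(t)$ follow the
instantaneous moments including the covariance contribution;
`"frozen"` pins $\sigma$ at its stationary value, which is exactly the
approximation the closed-form layer makes and is therefore the right
reference when validating it (the frozen cross-check agrees to <0.1% at
$h_\mathrm{ext}=0.1$; the full equations differ by a few percent at low
frequency through the genuine $\delta\sigma$ pathway).

## Stationary state and calibration

`solve_stationary()` finds the fixed point $\bar m = \varphi(\bar\mu,\bar\sigma)$
together with the stationary covariance relation
$2\bar c = \bar W \bar c_\mathrm{total} + (\bar W \bar c_\mathrm{total})^\mathsf{T}$,
$\bar c_\mathrm{total} = \bar c + \mathrm{diag}(\bar a/N)$, where
$\bar W = \mathrm{diag}(\bar S)(K \odot J)$ is the effective connectivity.
Numerical choices:

* The covariance equation is linear in $c$ given $m$ and is solved
  *exactly* in the eigenbasis of $\bar W$ (componentwise division by
  $2 - \lambda_\alpha - \lambda_\beta$), not by time stepping. The same
  structure is reused by the frequency-domain solution, and zero eigenvalues
  from clamped populations only produce harmless denominators of 2.
* The mean equation is solved by Newton iteration with Jacobian
  $I - \bar W$ and an Armijo backtracking line search. A plainly damped
  fixed-point iteration is not an option here: for the single-inhibitory
  network the loop gain is $\bar W \approx -12$, so any damping factor
  above $\sim 0.15$ diverges, while undamped Newton can cycle between the
  saturated branches of the gain when started far from the fixed point.
  The line search makes the solve initialization-independent (verified to
  1e-9 from random starts).
* Outer iterations alternate the Newton step with the exact covariance
  solve (damping 0.5 on $c$) to joint tolerance 1e-12.
* Stability is reported via $\max\Re(\lambda)$; $\ge 1$ attaches a warning
  rather than an error.
* Repeated eigenvalues (e.g. the double zero mode of a perfectly
  homogeneous E-I network plus a clamped source) can make LAPACK return
  numerically parallel eigenvectors even though the matrix is
  diagonalizable; `eigensystem()` then rebuilds the degenerate eigenspace
  from the SVD null space of $W - \lambda I$ and only errors if the
  geometric multiplicity is genuinely deficient.

`calibrate_thresholds()` inverts the stationarity condition,
$\theta_\alpha = \bar\mu_\alpha + \bar\sigma_\alpha\, q(1 - m_\alpha^\ast)$
with $q$ the standard normal quantile, iterating jointly with the
covariance solve (damping 0.5) because $\bar\sigma$ depends on $\bar c$
which depends on $\theta$. Calibrated networks reproduce their target means
to 1e-8. Rates and activities are related by $m = \tau \nu$; the package
reports rates in Hz with the ms-to-s conversion made explicit.

## Linear response and the three mechanisms

Linearizing around the stationary state and inserting the Fourier ansatz
$\delta m(t) = \Im(M^1 e^{i\omega t})$ gives the closed-form mean response
(`mean_response()`)

$$M^1 = U\,\mathrm{diag}\!\Big(\frac{1}{i\tau\omega + 1 - \lambda}\Big)\,U^{-1} \bar S\, h_\mathrm{ext},$$

a first-order low-pass filter per eigenmode of $\bar W$. Complex conjugate
eigenvalue pairs produce damped resonances at
$f_\mathrm{res} = |\Im\lambda| / (2\pi\tau)$ (`resonance_frequency()`;
implemented this way because $\lambda$ is dimensionless and the resonance
sits at $\tau\omega \approx |\Im\lambda|$); the covariance kernel mixes
modes at $2 - \lambda_\alpha - \lambda_\beta$ and hence also near
$2f_\mathrm{res}$.

The covariance response (`covariance_response()`) solves the linearized
covariance ODE in the same eigenbasis. Its inhomogeneity splits *exactly*
into three mechanistic terms, returned separately:

* **direct drive** (`C1_Sh`): the drive modulates the susceptibility
  through the gain curvature; inhomogeneity
  $h_\mathrm{ext} V \bar c_\mathrm{total}$ with
  $V = \mathrm{diag}(\partial S/\partial\mu)(K \odot J)$ — filtered once.
* **recurrent drive** (`C1_Sm`): the network feedback of the oscillating
  means modulates the susceptibility; inhomogeneity
  $\mathrm{diag}\big((K{\odot}J) M^1\big) V \bar c_\mathrm{total}$ —
  filtered twice (it carries $M^1$).
* **modulated autocovariances** (`C1_a`): the time-varying unit variances
  drive the pairwise covariances; inhomogeneity
  $\bar W\,\mathrm{diag}\big((1-2\bar m) M^1/N\big)$ — filtered twice.

In balanced networks the direct and recurrent drives have opposite phase at
low frequency and largely cancel; their sum peaks at an intermediate
frequency. In a purely inhibitory network the prefactor
$\bar c + \bar a/N$ of the susceptibility terms is itself suppressed by the
negative feedback (it vanishes as $N \to \infty$), so the a-term dominates
throughout the low-pass regime ($\tau\omega \lesssim 10$) and the peak is
invisible in the total: the package's tests assert exactly this — a-term
dominance over the summed susceptibility terms at $\tau\omega \le 10$ and a
total response whose maximum sits at the lowest frequency. At
$\tau\omega \gg 10$ the once-filtered direct drive necessarily takes over;
that regime is far above the frequencies the model is meant for.

The analytic layer neglects the $\delta\sigma$ contribution to both
responses. The package monitors the validity ratio
$\sqrt{2}\,\mathrm{erfc}^{-1}(2\bar m)\,\bar\sigma$ vs $\bar S \bar\sigma$
implicitly through the frozen-vs-full ODE comparison in its test suite; for
all three presets the neglected pathway changes first harmonics by at most
a few percent at unit drive.

## Harmonics and reporting conventions

`extract_harmonics()` projects trajectories onto drive harmonics over an
integer number of periods after discarding a transient of
$\max(20\tau,\,2\,\mathrm{periods})$, with the convention
$x(t) = X^0 + \sum_k \Im(X^k e^{ik\omega t})$, i.e.
$X^k = 2i\,\langle x\, e^{-ik\omega t}\rangle$. A pure
$\beta\sin(\omega t)$ gives $X^1 = \beta$ (phase 0); $\beta\cos(\omega t)$
gives $X^1 = i\beta$. Under this convention $|X^1|$ is the *full* sine
amplitude. The conventional Fourier-series coefficient
$\langle x e^{-ik\omega t}\rangle$ — the quantity spectra are usually
plotted and quoted in — is half that, which is why the acceptance script
reports peak rate modulations as $|M^1|/(2\tau)$ in Hz. Uniform sampling
(64 points per period) makes the projection exact for band-limited signals;
halving the integrator tolerance moves extracted first harmonics by less
than 1e-6 relative.

## Simulator and cyclostationary estimation

`build_network()` + `simulate_glauber()` implement the exact event-driven
dynamics (Rcpp): waiting times are exponential with mean $\tau/N$
(a fixed-step mode with $dt = \tau/N$ is available for cross-checks), the
recurrent input of every neuron is maintained incrementally through
out-edge lists, and identical seeds give identical event streams. Noise is
redrawn independently at every update (white across updates), which is what
makes the Gaussian-smoothed gain exact per update.

`cyclostationary_stats()` estimates $m(\varphi)$, $a(\varphi)$,
$c(\varphi)$ and the population-activity covariance
$c^\mathrm{pop}(\varphi) = \mathrm{diag}(a/N) + c$ on a phase grid. The
ensemble at a phase consists of one state snapshot per (trial, cycle):
snapshots at the same phase of different cycles are at least one period
apart — far beyond the network correlation time of order $\tau$ — and act
as near-independent realizations. Pooling cycles into per-trial time
averages *before* computing covariances would shrink the pairwise
covariance by the number of cycles, which is why the estimator works on raw
snapshots; standard errors are nevertheless computed across trials, so any
residual within-trial dependence inflates the reported SEs rather than
biasing the comparison. Pairwise covariances are averaged over a fixed
random subsample of ordered pairs (default 2000 per population block) drawn
from a tracked pool of neurons; the unbiased divisor $R-1$ is used.
`population_ellipse()` turns $c^\mathrm{pop}$ at a phase bin into the
one-standard-deviation ellipse of the population activity
($\delta m^\mathsf{T} (c^\mathrm{pop})^{-1} \delta m = 1$, restricted to
the dynamic populations): eigenvector axes, square-root-eigenvalue
half-lengths; positive cross-covariances tilt it and enlarge it relative to
the variances-only ellipse.

What the simulator emulates — and what it does not: it realizes exactly the
stochastic model the theory describes (fixed in-degree randomness, binary
units, Poisson updates, Gaussian private noise). Passing tests therefore
validate the *theory-simulation* consistency of this model class, not the
behavior of real cortical tissue: there are no synaptic delays or
conductances, no distributed (heavy-tailed) synaptic amplitudes — flagged
as outside the mean-field approximation used here — no spatial structure,
and no spike shapes. Statistical agreement is the only meaningful
comparison; no attempt is made to reproduce another simulator's RNG or
update order.

## Presets and open parameter choices

* `single_inhibitory` (N = 5000, p = 0.1, J = -1, m = 0.3,
  $\sigma_\mathrm{noise} = \sigma_\mathrm{shot} = \sqrt{105} \approx 10.25$):
  $\tau = 10$ ms is this package's choice — the model only fixes dynamics
  relative to $\tau$, and 10 ms is the customary value for binary-network
  studies; it merely sets the frequency scale.
* `homogeneous_EI` (N = 8192 per population, p = 0.2, m = 0.11,
  m_X = 0.25): the published source of this configuration does not print
  its synaptic weights, so the preset ships placeholder values
  (J_E = 0.1, J_I = -0.6, $\sigma_\mathrm{noise} = 10$), flagged as
  non-source values in its `notes`. Quantitative claims are not tied to
  this preset.
* `biological_EI` (layer 2/3 barrel-cortex parameters; see
  `?preset_network`): target means follow $m = \tau\nu$ with
  $\nu = 18/108$ Hz and $\tau = 2.5$ ms; $\sigma_\mathrm{noise} = 10$. The
  published parameter table lists an external-population mean
  $m_\mathrm{ext} = 0.1$ but no external connectivity; the preset therefore
  carries X as an unconnected clamped population, and the external drive is
  absorbed into the calibrated thresholds. That this is consistent is
  checked quantitatively: the stationary shot-noise widths come out at
  2.79 (E) and 4.56 (I) input units without any X contribution.

## Problem sizes and tolerances used in the tests

The test suite solves all presets at full size for the deterministic layers
(stationary, linear response, ODE; tolerances 1e-8..1e-12 as stated above)
and uses quarter-scale networks (N = 1250 single-population; N = 423/58
E-I) with 24 trials of 2.5 s for the simulation-vs-theory comparisons,
where agreement is asserted within 4 ensemble standard errors and
covariance signs must match. The driven comparison uses the full
biological network (12 trials, 0.8 s, 20 phase bins, f = 80 Hz) against the
closed-form first harmonics within 3 SE. The acceptance script sweeps 200
log-spaced frequencies for the response maxima and integrates the moment
ODEs at 20 frequencies between 10 and 500 Hz for the second-harmonic
bound. These sizes keep the full suite around two minutes while leaving
every stochastic comparison with a comfortable noise margin.

## Known limitations

* The moment closure drops third- and higher-order cumulants; it degrades
  for small in-degrees, strong single synapses, or activities pinned near 0
  or 1 (where the state clipping in the integrator would signal a model
  violation).
* The analytic layer requires a diagonalizable effective connectivity and
  drops $\delta\sigma$; both are monitored, not silently assumed.
* Second harmonics are available numerically (ODE + projection) only; no
  closed form is provided, and non-sinusoidal drives are out of scope.
* The cyclostationary estimator assumes the drive period is resolved by the
  snapshot schedule; very high drive frequencies (period approaching
  $\tau/N$) are not meaningful for this model.
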