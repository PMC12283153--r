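---
title: "megjoint: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{megjoint: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it fits, the
numerical choices behind the implementation, and what the bundled
simulations do and do not establish. It states no empirical number that the
test suite or `scripts/acceptance.R` does not itself compute.

## The generative model

`megjoint` explains an `M`-channel, `J`-trial MEG recording with a small
number `N_s` of current dipoles. Three coupled equations define the model:

* **Locations.** The true dipole locations are fixed in time and shared
  across trials. Because a particle filter needs a transition kernel, the
  locations are given an *artificial* evolution through the Liu–West
  shrinkage kernel: with discount $\delta \in (0,1]$,
  $a = (3\delta - 1)/(2\delta)$, $h^2 = 1 - a^2$, particles move as
  $r_t = a\, r_{t-1} + (1-a)\,\bar r_{t-1} + \mathcal N(0, h^2 \Xi)$.
  Shrinkage toward the weighted mean $\bar r_{t-1}$ exactly compensates the
  variance the kernel noise adds, so the particle cloud does not diffuse.
  $\delta = 1$ recovers frozen locations.
* **Amplitudes.** Source amplitudes follow an order-$P$ MVAR process
  $q_t = \sum_p A_p q_{t-p} + v_t$, $v_t \sim \mathcal N(0, V)$, rewritten
  in companion form $\tilde q_t = \tilde A \tilde q_{t-1} + \tilde v_t$ so
  all inference is first-order. Entry $(i,j)$ of $A_p$ is the lag-$p$
  influence of source $j$ on source $i$ — the object of scientific
  interest.
* **Measurements.** $y_t = G(r_t)\, q_t + e_t$ with the analytic
  spherical-conductor (Sarvas) lead field $G$ and Gaussian sensor noise
  $E = \sigma_m^2 I$, optionally extended by projected white brain noise to
  $E = \sigma_m^2 I + \sigma_b^2 G G^\top$.

Conditioned on a location path the model is linear-Gaussian in the stacked
amplitudes, so a Kalman filter/RTS smoother computes their posterior and
the marginal likelihood exactly (Rao-Blackwellization). Only the
3`N_s`-dimensional location path needs Monte Carlo.

## The estimation loop

Each SAEM iteration runs:

1. **CPF-AS sweep** over location trajectories on the trial-averaged data
   (averaging divides the sensor-noise covariance by $J$, implemented by a
   `noise_scale` of $1/J$). The last particle is pinned to the reference
   trajectory and its ancestor is resampled; the remaining particles are
   propagated by the shrinkage kernel and weighted by the
   Rao-Blackwellized predictive likelihood. Systematic resampling is
   applied at every step. The next reference is drawn from the final
   weights.
2. **Smoothing** of every surviving trajectory, per trial, with the RTS
   smoother (including one-lag cross-covariances and the smoothed initial
   state), accumulated into the sufficient statistics
   $\Phi, \Psi, \Sigma, Z, \Upsilon$ and the particle/time-averaged gain
   $\bar G$.
3. **Stochastic approximation**
   $\mathbb S_k = (1-\zeta_k)\mathbb S_{k-1} + \zeta_k S_k$ with
   $\zeta_k = 1$ for $k \le K_0$ and $(k-K_0)^{-\gamma}$ afterwards
   ($\sum \zeta_k = \infty$, $\sum \zeta_k^2 < \infty$ for
   $\gamma \in (0.5, 1]$).
4. **M-step.** The free top block-row of $\tilde A$ is
   $\Psi_{top}\Sigma^{-1}$; $V$ is the diagonal of
   $(\Phi - \Psi\Sigma^{-1}\Psi^\top)/(JT)$ (a diagonal $V$ keeps the
   free-parameter count at $N_s^2 P + N_s + 1$, the count used by the BIC
   criterion); $\sigma_m^2$ has the closed form
   $\mathrm{tr}(Z - \Upsilon \tilde G^\top - \tilde G \Upsilon^\top +
   \tilde G \Phi \tilde G^\top)/(MJT)$. Under the brain-noise model the
   pair $(\sigma_m^2, \sigma_b^2)$ has no closed form and is updated by
   gradient ascent in log-parameters with backtracking halving; an
   eigendecomposition of $G G^\top$ makes each objective/gradient
   evaluation $O(M)$.

With the locations held fixed (`fixed_locations`) the E-step is exact and
the loop is plain EM; the test suite asserts a nondecreasing likelihood
trace in this case, which is the sharpest end-to-end check of the
sufficient statistics and both M-steps.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `n_particles` | 500 | sweep size; desk-scale studies use 48–64, which the bundled experiments show is enough when the reference is MCMV-initialized |
| `n_iter` | 300 | SAEM budget (the method typically needs a few hundred iterations) |
| `K0_frac`, `gamma` | 0.3, 0.7 | burn-in fraction with $\zeta = 1$, then polynomial decay |
| `delta` | 0.98 | Liu–West discount; no published value exists for this model, 0.95–0.99 is the customary range |
| `kernel_sd` | 5 mm | isotropic $\Xi^{1/2}$ per coordinate; the effective per-step proposal is $h \cdot$ 5 mm $\approx$ 0.7 mm, small against the 10 mm correct-hit radius |
| `noise_model` | `"iid"` | `"brain"` enables the $\sigma_b^2 G G^\top$ term and the gradient noise step |
| `max_smooth` | 16 | cap on smoothed particles per iteration (see below) |
| order `P` | 2 (simulations) | select with `bic_select()` on amplitude estimates |

Units are SI throughout: meters, tesla, seconds. The 3 cm source
separation, 2 cm beamformer peak separation and 10 mm correct-hit radius
are all interpreted in meters.

## Numerical choices

* **Internal standardization.** Sensor data are tesla-scale
  ($\sim 10^{-13}$), so variances like $\sigma_m^2 \sim 10^{-26}$ would sit
  near the square root of the double-precision floor in matrix
  factorizations. `fit_joint()` rescales data by their standard deviation
  and the gain by its median column norm, fits in that space, and maps all
  outputs back exactly. The M-step variance floor ($10^{-12}$ relative to
  the state scale) therefore acts in a sane regime.
* **Woodbury updates.** The innovation covariance
  $\sigma^2 I + G D G^\top$ is inverted through the $N_s \times N_s$
  matrix $I + \sigma^{-2} G^\top G D$ (matrix-determinant lemma for the
  log-likelihood), making each particle-step $O(M N_s^2)$ instead of
  $O(M^3)$.
* **Joseph-form update and symmetrization** in the reference R filter;
  the compiled path symmetrizes covariances every step.
* **Singular predicted covariances** (e.g., $\tilde A = 0$ at
  initialization leaves deterministic companion blocks with zero variance)
  fall back to an eigenvalue pseudo-inverse in the smoother gain.
* **`max_smooth`.** The per-particle, per-trial smoothing pass dominates
  the cost when weights are flat. When more than `max_smooth` particles
  carry weight, the weighted set is collapsed by weight-proportional
  systematic resampling into `max_smooth` equally weighted
  representatives — an unbiased resampling of the same distribution, i.e.
  one more Monte Carlo layer inside an already stochastic E-step, not a
  change of target. $\bar G$ is still averaged over every particle.
* **Ancestor weights** for the pinned particle use the transition kernel
  only, $w_{t-1}^i \, \mathcal N(r^*_t \mid m^i_{t-1}, h^2\Xi)$, omitting
  the Rao-Blackwell future-likelihood correction; the transition-only form
  is the standard practical choice for this sampler. With $\delta = 1$
  (degenerate kernel) the reference keeps its own ancestry.
* **$\theta$ initialization.** $A = 0$; $V$ from the variance of a
  pseudo-inverse amplitude projection of the trial-averaged data at the
  reference locations; $\sigma_m^2$ at 10% of the per-trial data variance.
  The reference trajectory comes from the MCMV scan unless supplied.
* **Initial state prior**: $\mathcal N(0, \Gamma)$ with $\Gamma$ the
  stationary companion covariance when the current $\tilde A$ is stable,
  otherwise a broad diagonal. Stability is advisory during estimation but
  enforced for simulation.
* **Tie-breaks.** The BIC scan returns the smallest order attaining the
  minimum; beamformer peak picking is greedy with a 2 cm separation rule
  (LCMV only — the iterative MCMV scan needs none by construction).

## The forward model and the orientation field

A homogeneous conducting sphere replaces subject-specific BEM head models
so the repository is download-free; externally computed lead fields can be
injected via the TSV gain interface (`read_gain_tsv`, `gain_grid` argument
of `fit_joint`). Dipoles carry one fixed orientation per location — the
local azimuthal tangential direction, a smooth stand-in for
cortical-normal constraints — so the gain has one column per source and is
an analytic, continuous function of position. Particles therefore move in
continuous $\mathbb R^3$ with no grid snapping; the candidate grid is used
only for beamformer scans, source placement, and nearest-neighbour lookup
of imported gains. Two sphere-model identities (zero field for radial or
central dipoles) and an independent free-space radial-component oracle pin
the Sarvas implementation in the tests.

## What the simulator emulates — and what it does not

`simulate_mvar_scenario()` reproduces the structure of the MVAR-based
designs: three dipoles at random grid locations at least 3 cm apart, a
second-order MVAR with unidirectional coupling (Type-I: 1→2 with an
independent third source; Type-II: 1→2→3), pink brain noise from 500
random shell locations scaled *exactly* to the requested brain SNR
(power-trace ratio of signal to projected brain noise), and white sensor
noise scaled exactly to the measurement SNR of signal-plus-brain-noise
against sensor noise. The published design never states its coefficient
values; the package's template uses damped-oscillator self-terms (0.5,
−0.3) and couplings of 0.4 at lag 1, verified stable. The evoked-response
generator substitutes superposed-Gaussian-bump waveforms (clearly labelled
synthetic) for the non-redistributable cortical recordings it mimics, with
per-subject amplitude scaling in [0.75, 1.25] and circular shifts within
±100 ms, brain noise from 2000 locations at SNR 1 and sensor noise at
SNR 3.

Deliberate simplifications, and hence limits on what a green test shows:
true sources sit *on* the candidate grid and the same spherical forward
model generates and fits the data, so there is no forward-modeling error —
the regime the full-scale published experiments probe with mismatched BEM
meshes. Brain noise is spatially correlated at the sensors, but the
default fitting model is `"iid"`; at the simulated SNRs the likelihood
still concentrates at the true dipoles, which is exactly what the
scaled-down acceptance study measures. Consequently the two-step baselines
are strong here (beamformer scans can be exact on-grid), and the
qualitative comparison with the joint fit is conservative.

## Evaluation conventions

Estimated sources are matched to the truth by the exhaustive
minimum-total-distance assignment (at most $5!$ candidates) before any
metric is computed; extra estimated sources stay unmatched and any
significant link touching one counts as a false positive, while quiet
extra-source pairs count as true negatives. The gPDC relative error is the
Frobenius norm of the spectrum difference over the Frobenius norm of the
truth, stacked over frequencies (the published text names the metric
without a formula). Direction convention everywhere: entry $(i, j)$ means
$j \to i$. Link-level significance declares a link present when its gPDC
exceeds the per-entry surrogate threshold at any frequency; surrogates are
independent per-channel phase randomizations of the estimated source time
series, refitted at the same order, and for the joint estimator the
*observed* spectrum is the SAEM maximum-likelihood model rather than a
least-squares refit. Bootstrap summaries follow the two-level scheme:
B = 100 resamples of size S = 50, per-resample means, then mean and SD
across resamples.

## Known limitations

* The compiled sweep supports the iid noise model; the brain-noise rule is
  available in the exact (fixed-location) path and in the noise M-step,
  but inside the particle sweep brain noise is folded into an effective
  iid variance.
* Sources weaker than their neighbours by a large factor can be absorbed
  into the noise estimate (a likelihood-based method shares this with
  other localizers); the amplitude of "extra" sources is the diagnostic.
* Static connectivity only: fitting one MVAR model to an evoked transient
  treats nonstationary data as stationary.
* No EEG forward model, no free-orientation (3-column) dipoles, no
  time-varying or regularized MVAR structure.
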