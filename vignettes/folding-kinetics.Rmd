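---
title: "Chevron fitting and phi-value analysis with foldphi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chevron fitting and phi-value analysis with foldphi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldphi)
```

## The models

foldphi analyses stopped-flow folding kinetics of small proteins in
chemical denaturant. Two reaction schemes are supported.

**Two-state** (U ⇌ N): a single relaxation with
$k_\mathrm{obs}(D) = k_\mathrm{UN}(D) + k_\mathrm{NU}(D)$, giving the
classical V-shaped chevron in $\ln k_\mathrm{obs}$ versus denaturant.

**On-pathway three-state** (U ⇌ I ⇌ N): every microscopic rate constant
follows a kinetic linear free-energy relationship
$k_{xy}(D) = k_{xy}(0)\,e^{\mp m_{xy} D / RT}$ (folding rates decay,
unfolding rates grow; m-values are stored as non-negative magnitudes with an
explicit direction flag, which prevents silent sign errors). The rate matrix
of the linear three-state scheme has eigenvalues $0, -\lambda_\mathrm{slow},
-\lambda_\mathrm{fast}$ with, writing
$s = k_\mathrm{UI}+k_\mathrm{IU}+k_\mathrm{IN}+k_\mathrm{NI}$ and
$p = k_\mathrm{UI}k_\mathrm{IN}+k_\mathrm{UI}k_\mathrm{NI}+k_\mathrm{IU}k_\mathrm{NI}$,

$$\lambda_\pm = \tfrac{1}{2}\left(s \pm \sqrt{s^2 - 4p}\right).$$

The observable of a chevron experiment is $\lambda_\mathrm{slow}$: the fast
U ⇌ I equilibration is complete within the instrument dead time (the burst
phase). `relaxation_rates()` returns the exact eigenvalues by default;
the classical pre-equilibrium approximation
$\lambda_\mathrm{slow} \approx k_\mathrm{IN} K_\mathrm{UI}/(1+K_\mathrm{UI}) +
k_\mathrm{NI}$ is available via `method = "pre_equilibrium"`. We default to
the exact form because it remains valid when the U ⇌ I exchange is only
moderately faster than the I ⇌ N step, which happens for strongly
destabilised variants where $k_\mathrm{NI}$ reaches tens of s⁻¹. Numerically,
the slow root is evaluated as $2p/(s + \sqrt{s^2-4p})$ — algebraically
identical to the textbook form but free of catastrophic cancellation when the
two phases are separated by many orders of magnitude; a (theoretically
impossible) negative discriminant arising from rounding is clamped to zero
with a warning.

Free energies use the convention that the more folded species is more
stable when $\Delta G < 0$: $\Delta G^\circ_\mathrm{UI} = -RT\ln(k_\mathrm{UI}/k_\mathrm{IU})$,
$\Delta G^\circ_\mathrm{UN} = \Delta G^\circ_\mathrm{UI} + \Delta G^\circ_\mathrm{IN}$, so a
stable native protein sits near $-25$ kJ mol⁻¹ and destabilising mutations
give positive $\Delta\Delta G$. Equilibrium m-values add the kinetic
magnitudes ($M_\mathrm{UN} = m_\mathrm{UI}+m_\mathrm{IU}+m_\mathrm{IN}+m_\mathrm{NI}$), and Tanford
$\beta$ values report fractional solvent burial:
$\beta_\mathrm{I} = M_\mathrm{UI}/M_\mathrm{UN}$,
$\beta_\mathrm{TS2} = (M_\mathrm{UI}+m_\mathrm{IN})/M_\mathrm{UN}$.

Temperature defaults to 283.15 K with $R = 0.0083145$ kJ mol⁻¹ K⁻¹
($RT = 2.354$ kJ mol⁻¹), the standard condition for this system; both are
overridable through `fold_conditions()`.

## Amplitude observables

Each state carries a linear fluorescence baseline (intercept + slope in
denaturant, normalised so a denatured reference sample reads 1). The
endpoint signal at denaturant $D$ is the equilibrium population average of
the baselines. The initial signal of a refolding experiment is the signal of
the U/I burst-phase pre-equilibrium (populations $\propto \{1,
K_\mathrm{UI}(D)\}$, N excluded); of an unfolding experiment, the native
baseline. This treats the fast phase as complete within the dead time at
every denaturant concentration — consistent with fixing
$k_\mathrm{UI} = 1574$ s⁻¹, far above stopped-flow resolution.

## Fitting

`fit_chevron_three_state()` / `fit_chevron_two_state()` minimise joint
weighted residuals of $\{\ln k_\mathrm{obs},$ initial signal, endpoint
signal$\}$ by Levenberg–Marquardt (minpack.lm). Choices that matter:

* **Rate residuals on the log scale.** Chevrons span three decades and are
  analysed and plotted in log space; a multiplicative noise model is the
  natural one. Amplitude residuals stay on the linear normalised scale.
* **Block weighting.** With per-point uncertainties (a `kobs_sigma` column,
  a known `signal_sigma`) residuals are scaled by them. Otherwise the two
  blocks are weighted by their estimated per-block residual variance: one
  pass at unit weights, reweight, refit. `weighting = "equal"` disables
  this.
* **Parameter scales and bounds.** Rates are optimised as logarithms
  (positivity built in); m-values are linear with a lower bound of zero.
* **Multistart.** A heuristic start is derived from the data (unfolding-limb
  regression for $k_\mathrm{NI}$/$m_\mathrm{NI}$, low-denaturant refolding
  limb for $k_\mathrm{IN}$/$m_\mathrm{IN}$), then a Latin-hypercube scatter
  of the free log-rates (±1 decade, fixed seed, `n_starts` total starts)
  guards against local minima. Noise-free data are recovered to machine
  precision from the heuristic start alone.
* **Constraints.** `fit_constraints()` fixes parameters (by default the
  burst-phase step at $k_\mathrm{UI}=1574$ s⁻¹, $m_\mathrm{UI}=1.23$
  kJ mol⁻¹ M⁻¹, with the intermediate's stability determined by letting
  $k_\mathrm{IU}$ float), bounds them, or restricts the total kinetic
  m-value to an equilibrium-determined range through a hinge penalty with
  weight $10^3$ — the treatment needed when a chevron alone cannot pin the
  m-values down (e.g. curvature in both limbs).
* **Errors.** 1σ uncertainties come from the Gauss–Newton covariance
  $s^2 (J^\top J)^{-1}$ at the optimum, with $J$ a forward-difference
  Jacobian of the weighted residuals; derived thermodynamic quantities get
  delta-method errors through a numerical gradient. A parameter set is
  reported unidentifiable when $J^\top J$ is rank-deficient (SVD tolerance
  $10^{-10}$ relative) or when an internal-scale σ exceeds 10 — a rate
  uncertain by a factor $e^{10}$ is not measured, however invertible the
  matrix.

`fit_exponential_trace()` fits averaged traces to
$S(t) = \mathrm{offset} + \sum_i A_i e^{-k_i t}$ with a deterministic
log-spaced multistart; rates are returned sorted descending, and a two-phase
fit whose rates collapse within a factor 1.5 falls back to one phase with a
warning (the phases are then not separable and the slow-phase assignment
would be arbitrary).

`fit_equilibrium_curve()` fits the linear extrapolation model
$$S_\mathrm{obs}(D) = f_\mathrm{N}(D) B_\mathrm{N}(D) +
  (1-f_\mathrm{N}(D)) B_\mathrm{D}(D), \qquad
f_\mathrm{N}(D) = \frac{1}{1 + e^{(\Delta G^\circ_\mathrm{UN} + M_\mathrm{UN} D)/RT}},$$
with linear baselines $B_\mathrm{N}, B_\mathrm{D}$. `fraction_native()` is
the exact analytical inverse,
$f_\mathrm{N} = (S_\mathrm{obs}-B_\mathrm{D})/(B_\mathrm{N}-B_\mathrm{D})$,
and deliberately does not clip noisy values outside $[0,1]$. Baseline
parameters are exposed as named intercept/slope fields rather than
single-letter symbols, since the single-letter conventions in the literature
are ambiguous about which symbol is the intercept. Fluorescence and CD
curves share one code path; the probe is metadata. A fit whose midpoint
$-\Delta G^\circ_\mathrm{UN}/M_\mathrm{UN}$ falls outside the measured range is flagged
unidentifiable — the transition is not bracketed.

## Phi-value analysis

For a variant against its reference (wild type, or a pseudo-wild-type such
as an Ile→Val intermediate mutant, resolved per variant through
`reference_map`):

$$\Phi_\mathrm{I} = \frac{\Delta\Delta G^\circ_\mathrm{UI}}{\Delta\Delta G^\circ_\mathrm{UN}}, \qquad
\Phi_\mathrm{TS2} = \frac{\Delta\Delta G^\circ_\mathrm{UI} -
RT\ln(k_\mathrm{IN}^\mathrm{mut}/k_\mathrm{IN}^\mathrm{ref})}{\Delta\Delta G^\circ_\mathrm{UN}},$$

the TS2 numerator being the transition-state destabilisation
$\Delta\Delta G^\circ_\mathrm{U\text{-}TS2}$ itself. Rules applied:

* **Determinability.** $|\Delta\Delta G^\circ_\mathrm{UN}| < 2.5$ kJ mol⁻¹ yields an
  explicit ND (no number) — below that the ratio is dominated by its error.
  An override flag exists for exploratory use.
* **No clamping.** Negative values and values above 1 are reported as
  computed; both are physically meaningful (non-native interactions,
  relative movement of the unfolded baseline).
* **Binning.** `classify_phi()` uses low ≤ 0.4 < mid ≤ 0.7 < high. The
  conventional inequalities are strict on both sides, leaving exact
  boundaries undefined; this package assigns them to the lower bin and
  documents that as its tie-break.
* **m-value QC.** `check_m_value()` flags variants whose total m-value
  deviates from the reference by ≥ 10% (strictly outside the open band;
  5.94 against 5.4 flags). Such variants may not fold to the reference
  topology and their phi-values should be read with suspicion.
* **Error propagation.** First-order (delta-method) propagation treating
  variant and reference as independent experiments; within a variant the
  full fit covariance of $(\Delta G^\circ_\mathrm{UI}, \Delta G^\circ_\mathrm{UN}, \ln
  k_\mathrm{IN})$ is used when the record comes from a fit
  (`as_variant_record()`), and a diagonal approximation when built from
  published values. The unit suite checks the propagated σ against a
  $10^5$-draw Monte-Carlo resampling within 10%.

## The synthetic-data generator

`generate_chevron()`, `generate_trace()` and `generate_equilibrium_curve()`
make every stage testable without instrument data. They emulate:

* urea-dilution design — refolding observations at 0.75–8.0 M (16 points)
  and unfolding at 3.0–8.0 M (11 points), each observation labelled with the
  mixing direction of its grid (the burst-phase initial-signal model depends
  on the direction, so the generator assigns branch by experiment, not by
  the position of the chevron minimum);
* multiplicative lognormal noise on rates (default 3% — rates span decades,
  so relative noise is the right model) and additive Gaussian noise on
  normalised signals (default 0.01) and traces; the defaults are chosen to
  make ±2σ recovery tests meaningful, as the source experiments do not
  report noise magnitudes;
* full rate-matrix relaxation for traces, from all-U (refolding) or all-N
  (unfolding) initial conditions via eigendecomposition — a three-state
  scheme yields the burst + observable double-exponential, a two-state
  scheme is exactly single-exponential.

Generators are pure functions of (parameters, grid, seed): a `noise_model()`
with a seed reproduces a dataset bit-for-bit without disturbing the session
RNG. The packaged scenario library (`scenario_library()`,
`scenario_scheme()`, `scenario_record()`) carries the published per-variant
parameter sets that parameterise the generators; the fluorescence baselines
attached to schemes are synthetic defaults (U dim, I bright, N quenched —
the qualitative signature of a native-state-quenched Trp probe) and are
documented as such.

What the generator does **not** emulate: dead-time truncation of the burst
phase, mixing artefacts, photobleaching, baseline drift, and correlated
residuals from fitting averaged traces. Passing recovery tests therefore
demonstrates the estimator is correct and calibrated under the assumed noise
model, not that real instruments are this kind.

## Problem sizes and calibration checks

The test suite fits 200 replicate chevrons at the default noise to check
that 2σ intervals cover the generating rate ~95% of the time, and 200
replicate equilibrium curves to check mean recovery of $\Delta G^\circ_\mathrm{UN}$;
eigenvalue formulas are cross-checked against numerical eigendecomposition
over 1000 random schemes. These sizes give binomial/Monte-Carlo resolution
comfortably finer than the tolerances being asserted while keeping a full
run near a minute. One calibration fact worth knowing: at 2%-of-span
Gaussian noise on a 41-point curve with a low transition midpoint, the
equilibrium $\Delta G^\circ_\mathrm{UN}$ estimator has a standard deviation of roughly
1.4 kJ mol⁻¹ (the fits are at the global optimum; the reported σ agrees), so
published sub-0.6 kJ mol⁻¹ errors for such curves imply appreciably quieter
data — single noisy replicates are judged against their own reported σ, and
accuracy against the replicate mean.

## Known limitations

* Schemes beyond three states, off-pathway or triangular topologies, are out
  of scope, as are three-state equilibrium fits and thermal denaturation.
* Global fitting across multiple variants simultaneously is not supported;
  each chevron is fitted on its own.
* The burst-phase amplitude model assumes the fast phase is always
  dead-time-complete; it will misrepresent variants whose U ⇌ I exchange
  slows into the observable window.
* Two-state variants expose no $k_\mathrm{IN}$, so $\Phi_\mathrm{TS2}$ is
  undefined for them here even where source tables print a value for the
  folding barrier by other reasoning.
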