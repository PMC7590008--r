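---
title: "Decomposing ITC dilution-quench thermograms into dissolution kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing ITC dilution-quench thermograms into dissolution kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrildis)
```

## The experiment and the model

A dilution-quench ITC experiment injects a concentrated suspension of
self-assembled peptide aggregates (syringe concentration $c_{inj}$, monomer
solubility $c_s$, so an aggregated fraction $f_{agg} = 1 - c_s/c_{inj}$)
into a thermostatted cell. While the cell concentration is below $c_s$, the
injected aggregates dissolve; the instrument records the differential power
$\Delta P(t)$, whose time integral over an injection is the heat of that
injection's processes.

Each injection raises the total cell concentration by
$\Delta c_0 = c_{inj} V_{inj} / V_{cell}$. The concentration added up to
time $t$ is modelled as $\Delta c(t) = \Delta c_0 (1 - e^{-k_{inj} t})$ with
$k_{inj} = 1/15\ \mathrm{s^{-1}}$, an exponential stand-in for the linear
injection ramp (duration $t_{inj} = 30$ s) chosen to avoid a discontinuous
first derivative; `delta_c_ideal()` provides the piecewise-linear ramp for
reference, but all fitting uses the smooth form.

Monomer production by dissolution is described by the sigmoidal test
function implemented in `monomer_concentration()`:

$$c_{mon}(t) = c_{mon}(0) + (1 - f_{agg})\,\Delta c(t)
  + f_{agg}\,\Delta c(t)\,(1 - e^{-kt})^\alpha$$

with dissolution rate constant $k$ and lag exponent $\alpha \ge 1$; for
$\alpha > 1$ the dissolution power — $A$ times the derivative of the third
term, `dissolution_power()` — starts at exactly zero and passes through a
single interior minimum (for exothermic $A < 0$), reproducing the observed
delay. Its total heat is exactly $\Delta H_{dis} = A f_{agg} \Delta c_0$
(`dissolution_enthalpy()`, closed form, no quadrature).

The fast heats of dilution are modelled empirically, as in instrument
practice: an exothermic half-sine $B \sin(\omega t - \delta)$ on its
half-period support (zero outside — the windowing keeps the shape
integrable, with area $2B/\omega$) and, at higher concentrations where two
fast modes are resolved, an endothermic Lorentzian $C/[1 + w(t-\delta_L)^2]$.
The total signal of one injection is the plain sum of its components.

### Sign and unit conventions

All signals are baseline-subtracted differential power in µJ/s; exothermic
events are negative (so the dissolution amplitude $A < 0$). Time is in
seconds, concentration in mM, volume in µL. The molar dissolution enthalpy
is reported per mole of *dissolved* peptide, which with these units is
simply $A / V_{cell}$ in kJ/mol; a per-mole-*injected* normalisation
($A f_{agg} / V_{cell}$) is also reported, since the per-mole reference of
a published $\Delta H_{dis}$ value is ambiguous. The default truth of the
generator, $-1.4$ kJ/mol, is interpreted per mole dissolved.

## The synthetic-data generator

`simulate_experiment()` is the stand-in for instrument data: no public ITC
deposition exists for this system, so all recovery tests run against traces
with known ground truth. Its stated world is the reference experiment:
27 × 10 µL injections of a 30 mM peptide stock into a 1.46 mL cell
(initially pure solvent, experiment A, or 4.4 mM, experiment B), 30 s
injection time, 1 h spacing, preceded by an excluded 2 µL null injection
simulated as a volume-scaled dilution blip. Default truth parameters are
the fitted values reported for this system: $c_s = 5$ mM, $k_0^{-1} = 30$ s,
$\alpha = 10$ at infinite dilution, $\Delta H_{dis} = -1.4$ kJ/mol. Three
choices in the generator are declared conventions rather than measurements:

* **$\alpha(c)$ interpolation.** Only the endpoints are reported (10 at low
  concentration, toward 1 at $c_s$); the generator interpolates linearly in
  $c$. Any monotone interpolation would be as defensible.
* **Rate law.** $k^{-1}(c) = k_0^{-1} c_s/(c_s - c)$, the unique simple
  reversible attachment/detachment form with the two stated limits
  (equals $k_0^{-1}$ at infinite dilution; diverges at $c_s$).
* **Concentration bookkeeping.** Additive, $c_n = c_0 + n\Delta c_0$,
  because it reproduces the instrument's printed checkpoints (5.6 mM after
  27 injections of experiment A; 4.6 mM after the first of experiment B).
  An overflow-displacement variant (each injection also dilutes the cell
  contents by $V_{inj}/V_{cell}$) is available but not the default.

Injections that straddle $c_s$ scale the dissolution amplitude by the
undersaturated fraction $\mathrm{clip}((c_s - c_{before})/\Delta c_0, 0, 1)$.
Baseline drift is a polynomial of degree ≤ 3 and noise is i.i.d. Gaussian;
the default sampling interval is 1 s (the instrument rate is not public).
The generator does **not** emulate the calorimeter's feedback response
time, stirring transients, or correlated 1/f noise — so a green recovery
test establishes that the estimator inverts the model it states, under
drift and white noise, not that it is robust to every instrument artefact.

## Preprocessing

Peak boundaries are detected per injection window as the first and last
time the absolute derivative of the smoothed signal exceeds
$2\times10^{-3}$ µJ s$^{-1}$ per s (the derivative is computed by central
differences after a 5-sample moving average; both knobs are exposed, and
the smoothing window matters — at realistic test noise the derivative floor
is far above this threshold, in which case the detected "peak" spans the
whole window and the correction degrades gracefully to a per-window chord).
The baseline is then corrected in two regimes: inside each peak a straight
line joining the signal at the bounds; outside all peaks one global cubic
fitted to every non-peak sample. The lead-in before the first analysed
injection contains the null-injection blip; the first $3 t_{inj}$ of it are
excluded from the cubic's support so the blip cannot bend the baseline.

A consequence of the chord rule worth knowing: the signal has not fully
returned to baseline at the detected bounds (the tail is merely below the
derivative threshold), so the chord clips ~2% of the true peak area at the
default truth parameters. Integrals of the corrected trace are therefore
drift-invariant to ~0.1% but systematically *smaller* than the true heat by
a few percent. The decomposition fit is immune to this bias — see below.

## The decomposition fit

`fit_dissolution_series()` fits each baseline-corrected window as
dissolution + dilution by least squares (replacing by-eye fitting, for
reproducibility). Numerical choices:

* **Variable projection.** For fixed $(k^{-1}, \alpha)$ every remaining
  parameter ($A$, $B$, $C$, and an affine nuisance) enters linearly, so the
  inner problem is solved by QR and the outer optimisation is only
  2-dimensional (L-BFGS-B, $k^{-1}$ on log scale), multi-started over
  $\alpha \in \{1.5, 3, 10\}$ × three $k^{-1}$ values with best-RSS
  selection. Bounds: $\alpha \in [1, 20]$, $k^{-1} \in [1, 10 \times$
  spacing$]$. Design columns are rescaled to unit maximum so a
  near-degenerate component cannot poison the others.
* **Chord-consistent fitting.** The model prediction is passed through the
  same peak-chord operator as the data before residuals are formed. At the
  optimum the model's chord coincides with the data's, so the ~2% clipping
  bias above cancels exactly instead of propagating into $A$.
* **Affine nuisance.** A per-window offset+slope column absorbs what the
  global cubic baseline leaves behind locally. Inside a peak the chord
  operator annihilates any affine function, so the nuisance cannot absorb
  signal there. The floor this approximation leaves in window residuals is
  a few $10^{-3}$ of the peak amplitude on compressed-spacing traces.
* **Shape calibration.** $\omega, \delta$ (and $w, \delta_L$ for the
  Lorentzian) are fitted freely on the first suitable window and then
  frozen for the series; per-window fits vary only the amplitudes, matching
  instrument practice.
* **Component selection.** The dissolution component is included when
  $c_{before} < \hat c_s$ (config `c_s_estimate`); an `"always"` option
  force-fits it and its amplitude can be tested against its standard error
  (least-squares covariance; a ridge fallback keeps the covariance honest —
  i.e. enormous — for unidentifiable directions).
* **Reliability flag.** Rows with fitted $k^{-1} >$ spacing$/3$ are flagged:
  their dissolution does not complete before the next injection, the
  window truncates the tail, and neither $k^{-1}$ nor $\alpha$ is then
  trustworthy. This mirrors the experimental caveat that values of
  $k^{-1}$ approaching the 1 h waiting time are unreliable. Recovery tests
  assert high-accuracy round-trips only for unflagged rows; truncated
  windows *cannot* be recovered to three digits from the information
  present, and the package says so rather than pretending otherwise.

Component enthalpies: dissolution by the closed form $A f_{agg} \Delta c_0$;
dilution modes by trapezoidal quadrature of the fitted shapes over the
window.

## Secondary analyses

* `fit_rate_model()` fits $k^{-1}(c) = k_0^{-1} c_s/(c_s - c)$; the model
  is linear in $1/k^{-1}$, which supplies exact starting values (machine
  precision on noiseless data), followed by a quasi-Newton refinement in
  $k^{-1}$ space.
* `diffusion_limited_time()` evaluates $t = R_0^2/(2 D v c_s)$ with strict
  SI conversion ($v c_s$ is a dimensionless volume fraction). With
  $D = 2\times10^{-10}$ m²/s, $R_0 = 100$ nm, $v = 550$ cm³/mol
  ($= M/\rho = 829/1.5$) and $c_s = 5$ mM this gives 9.1 ms — the
  diffusion-limited reference that the observed $k_0^{-1} = 30$ s exceeds
  by over three orders of magnitude, the signature of reaction-limited
  dissolution. Note an internal inconsistency in the published account of
  this number: the sentence quoting "9 ms" lists $c_s = 2$ mM, which would
  give ~23 ms; only $c_s = 5$ mM (the light-scattering value used
  elsewhere) reproduces 9 ms. The implementation exposes $c_s$ as a
  parameter and takes no side beyond documenting this.
* `ph_model()` / `fit_ph_deprotonation()`: below $c_s$ the peptide behaves
  as a neutral salt and the pH is the solvent's; above, a fraction $f$ of
  aggregated peptides each release one proton, $pH = -\log_{10}[(c - c_s)f]$
  (base-10, concentrations in mol/L — the standard convention). The fitter
  profiles $\log_{10} f$ out (it enters linearly for fixed $c_s$), scans
  $c_s$ on the full-table residual (solvent branch included, which makes
  the 1-D profile well-posed), then polishes jointly with $f$ constrained
  to $(0,1]$. Solubility values from different probes disagree in this
  system (pH: 2 mM, light scattering: 5 mM, calorimetry: ~8 mM); $c_s$ is
  therefore never hard-coded anywhere in the package.

## Known limitations

* Windows are fitted independently; tails of very slow injections leak into
  the next window and are not modelled there (they are flagged instead).
* No instrument-response deconvolution; the dilution shapes are empirical.
* Standard errors come from the local least-squares covariance only — no
  profile likelihood or Bayesian uncertainty.
* The derivative-threshold peak detector assumes the smoothed derivative
  noise floor is below the threshold; at 2% relative noise with 1 s
  sampling it is not, and detection degrades to whole-window chords (the
  fit tolerates this, but reported peak bounds are then uninformative).
* Proprietary instrument files are not read; input is plain CSV with a JSON
  schedule sidecar.
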