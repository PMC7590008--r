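# fibrildis

Dissolution kinetics of self-assembled peptide fibrils from isothermal
titration calorimetry (ITC) dilution-quench experiments.

## The problem

Short amphiphilic peptides such as alanine-rich A8K self-assemble into
β-sheet ribbon aggregates above a monomer solubility `c_s`. When such a
suspension is injected into a cell held *below* `c_s` (a dilution quench),
the aggregates become unstable and dissolve — surprisingly slowly, on the
scale of minutes rather than the milliseconds expected for diffusion-limited
dissolution. Because the concentrations involved are low, the most sensitive
probe of this process is the heat it releases: an ITC instrument records the
differential power `ΔP(t)` needed to keep the sample cell isothermal, and
every injection leaves a thermogram containing fast heats of dilution
superposed on the slow exothermic dissolution signal.

`fibrildis` is for biophysicists who want to turn such multi-injection
thermograms into per-injection dissolution enthalpies, rate constants and
lag exponents, and to interpret their concentration dependence.

## The model

Each injection raises the cell concentration by
`Δc₀ = c_inj · V_inj / V_cell`, smoothed in time as
`Δc(t) = Δc₀ (1 − e^{−k_inj t})` with `k_inj = 1/15 s⁻¹`. The free-monomer
production after the injection is the sigmoidal test function

    c_mon(t) = c_mon(0) + (1 − f_agg) Δc(t) + f_agg Δc(t) (1 − e^{−kt})^α

where `f_agg = 1 − c_s/c_inj` is the aggregated fraction of the injected
peptide, `k` the dissolution rate constant and `α ≥ 1` a lag exponent. The
slow component of the thermogram is the time derivative of the dissolution
term scaled by an amplitude `A` (µJ/mM; negative = exothermic):

    ΔP_dis(t) = A f_agg Δc₀ [ k_inj e^{−k_inj t}(1 − e^{−kt})^α
                + (1 − e^{−k_inj t}) α k e^{−kt}(1 − e^{−kt})^{α−1} ]

whose total heat is exactly `ΔH_dis = A f_agg Δc₀`. Fast dilution peaks are
modelled empirically as half a sine period (exothermic mode) and, at higher
concentrations, a Lorentzian (endothermic mode); `ΔP = ΔP_dil + ΔP_dis`.

Downstream, the package fits the reversible rate law
`k⁻¹(c) = k₀⁻¹ c_s/(c_s − c)`, evaluates the diffusion-limited reference
time `t = R₀²/(2 D v c_s)` for a spherical aggregate, and fits the
partial-deprotonation pH model `pH = −log₁₀[(c − c_s) f]` above `c_s`.

## Worked example

Simulate a short synthetic experiment (30 mM stock, 10 µL injections into a
1.46 mL cell, baseline drift and instrument noise), fit it, and fit the rate
law to the recovered rates:

```r
library(fibrildis)

sched <- injection_schedule(c_inj = 30, V_inj = 10, V_cell = 1460,
                            spacing = 900, n_injections = 5)
sim <- simulate_experiment(sched, truth_params(),
                           noise_drift_spec(noise_sd = 0.05,
                                            drift_coeffs = c(0.3, 1e-4),
                                            seed = 7))
fit <- fit_dissolution_series(sim$trace)
summary(fit)
```

```
Titration series: 5 injections, 5 with a dissolution component, 0 flagged unreliable
  at the lowest concentration: 1/k = 29.54 s, molar dH_dis = -1.371 kJ/mol
  injection   c_after enthalpy_dis_kJ_per_mol    k_inv     alpha unreliable
1         1 0.2054795               -1.371346 29.53970 10.381314      FALSE
2         2 0.4109589               -1.401100 31.28496  9.624356      FALSE
3         3 0.6164384               -1.363507 31.92939  9.750060      FALSE
4         4 0.8219178               -1.342487 33.19128  9.483713      FALSE
5         5 1.0273973               -1.412811 36.10449  8.414108      FALSE
```

Each row is one injection: the cell concentration after it, the molar
dissolution enthalpy (the generator's truth is −1.4 kJ/mol), the inverse
dissolution rate `1/k` in seconds (truth 30 s at infinite dilution, growing
with concentration) and the lag exponent `α` (truth 10 at low
concentration). Then:

```r
rate <- fit_rate_model(fit$table$c_before, fit$table$k_inv)
print(rate)
#> Reversible dissolution rate law  k^-1(c) = k0^-1 * c_s / (c_s - c)
#>   k0^-1 = 29.5 s (se 0.422)
#>   c_s   = 4.794 mM (se 0.524)
#>   RSS = 1.018 s^2 over 5 points

p <- diffusion_params(D = 2e-10, v = 550, R0 = 100, c_s = 5)
1e3 * diffusion_limited_time(p)
#> [1] 9.090909   # ms: the diffusion-limited reference, vs ~2 min observed
```

The five-orders-of-magnitude gap between the 9 ms diffusion-limited
reference and the measured `k₀⁻¹ = 30 s` is the central observation: the
dissolution is reaction-limited, consistent with a free-energy barrier from
the simultaneous breaking of several β-sheet hydrogen bonds.

## Command line

A thin wrapper over the same functions:

```sh
Rscript inst/cli/fibrildis.R simulate --config cfg.json --out runs/a
Rscript inst/cli/fibrildis.R fit --trace runs/a/trace.csv --config cfg.json --out runs/a
Rscript inst/cli/fibrildis.R analyze --what rate --input runs/a/results.csv --out rate.json
```

The JSON configuration schema (all units in the field names) is documented
in `?default_config`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's checkpoint quantity — the
diffusion-limited dissolution time of a 100 nm spherical aggregate
(`D = 2×10⁻¹⁰ m²/s`, `v = 550 cm³/mol`, `c_s = 5 mM`), reported in
milliseconds — by running the installed package, and writes it as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/dissolution-kinetics.Rmd` describes the model and its
assumptions, the synthetic-data generator and what a passing recovery test
does (and does not) establish, the numerical choices in the decomposition
fit, and known limitations.
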