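# hba1cspec

Estimation of the molar absorption coefficient spectrum of glycated
hemoglobin (HbA1c) from UV-Vis optical measurements.

The fraction of hemoglobin that carries a bound glucose (HbA1c) reflects
average glycemia over roughly three months and is the standard diagnostic
for diabetes (NGSP scale: < 5.7% normal, 5.7-6.4% prediabetes, > 6.4%
diabetes). Optical, noninvasive HbA1c estimation needs the molar
absorption coefficient ε<sub>HbA1c</sub>(λ) — how strongly one mole of
HbA1c absorbs per centimetre of path — across the visible band. This
package implements two complementary ways of obtaining it from
spectrophotometer data, plus the error-grid analysis used to judge the
resulting HbA1c estimates. It is aimed at biomedical-optics researchers
working on optical glycemia sensing.

## The methods

Everything rests on the Beer-Lambert law. With percent transmittance
%T = 100·I/I₀, absorbance is

    A(λ) = 2 − log₁₀ %T(λ) = ε(λ) · c · d

for a species at molar concentration *c* in a cuvette of path length *d*
(cm); absorbances of co-dissolved species add.

**Reference-anchored (theoretical) route.** From solution and solvent
transmittance spectra, the component absorbance
A = A<sub>sol</sub> − A<sub>w</sub> is obtained by solvent subtraction.
Its overall normalization is unknown (published transmittance curves are
often rescaled), but A(λ) remains *proportional* to ε(λ), so a single
literature anchor value ε(λ₁) fixes the whole spectrum:

    ε(λ₂) = A(λ₂) / A(λ₁) × ε(λ₁)

Any positive rescaling of A cancels exactly. Two anchors (e.g. the
literature HbA1c values at 535 and 593 nm) are combined by the geometric
mean of their scale factors, with a warning when they disagree by more
than 1%.

**Concentration-series (experimental) route.** Absorbance spectra of a
dilution series (default: total hemoglobin 0.07, 0.06, 0.05, 0.04,
0.03 mmol/L, d = 1 cm, each cuvette measured three times) give the
*solution* coefficient ε<sub>sol</sub>(λ) as the slope of the
no-intercept regression of A on c·d. The solution is a mixture of
glycated and non-glycated hemoglobin with glycated molar fraction *f*,
so

    ε_HbA1c(λ) = [ ε_sol(λ) − (1 − f) · ε_non(λ) ] / f

removes the non-glycated contribution using a reference
ε<sub>non</sub>(λ) table. The fractions of the bilevel control material
are computed from its stated concentrations (level 1: 0.228/9.43
mmol/L ≈ 0.0242; level 2: 0.488/7.44 ≈ 0.0656). Q-band peaks (the two
hemoglobin absorption maxima between 500 and 600 nm, near 545/579 nm)
are then located and reported.

**Error-grid analysis.** Reference-vs-estimated HbA1c pairs are
classified into three zones: A (estimate within 20% of the reference,
inclusive), C (the estimate crosses diagnostic categories in a way that
would change treatment: a normal subject read as diabetic or vice
versa), and B (everything else). Percentages are reported half-up to
two decimals.

A synthetic-data module (Gaussian Q-band models, Beer-Lambert forward
mixing, additive absorbance noise, optional normalization factors)
generates ground-truth datasets so both routes are testable end to end.
The shipped non-glycated reference table
(`inst/extdata/eps_nonglycated_synthetic.csv`) is likewise synthetic;
supply a literature table for scientific use.

## Worked example

```r
library(hba1cspec)

grid    <- wavelength_grid(440, 710)                      # 1 nm sampling
eps_a1c <- gaussian_band_spectrum(hb_band_preset("level1"), grid)  # ground truth
eps_non <- read_spectrum(eps_non_fixture_path())          # synthetic reference
f       <- glycated_fraction_level("level1")              # 0.228/9.43 = 0.02417815

sim <- simulate_measurement_series(eps_a1c, resample_spectrum(eps_non, grid), f,
                                   noise_sd = 0.002, replicates = 3, seed = 42)
fit <- run_experimental_pipeline(sim$replicates, eps_non, f)
fit$peaks
#> <peak_report>
#>   545 nm: 825143.3 M^-1 cm^-1
#>   579 nm: 720813.6 M^-1 cm^-1

lookup_epsilon(fit$epsilon, c(535, 593))
#> <epsilon_lookup>
#>   535 nm: 510802.6 M^-1 cm^-1
#>   593 nm: 280126.1 M^-1 cm^-1

summarize_zones(c(5.2, 6.1, 7.8, 9.0), c(5.4, 6.9, 7.5, 11.2))
#> <ega_summary> 4 points
#>   zone A: 3 (75.00%)
#>   zone B: 1 (25.00%)
#>   zone C: 0 (0.00%)
```

The pipeline recovers the generator's Q-band peak positions exactly
(545/579 nm for the level-1 preset) and peak coefficients within the
noise floor of the regression; with `noise_sd = 0` the recovery is exact
to ~1e-14 relative.

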