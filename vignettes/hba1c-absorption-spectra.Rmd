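---
title: "Deriving HbA1c molar absorption spectra: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving HbA1c molar absorption spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hba1cspec)
```

## The problem

Optical estimation of glycated hemoglobin (HbA1c) — the diagnostic
marker of long-term glycemia — requires its molar absorption coefficient
$\varepsilon_{\mathrm{HbA1c}}(\lambda)$ in the visible band. Direct
tabulations are scarce; what is available are transmittance spectra of
hemoglobin solutions (often published in normalized form), literature
$\varepsilon$ values at isolated wavelengths, and control materials with
certified glycated fractions. This package turns those inputs into full
$\varepsilon_{\mathrm{HbA1c}}$ spectra by two routes, and provides the
three-zone error-grid analysis used to judge HbA1c estimators built on
them.

## Data model and Beer–Lambert conversions

All spectra are `(wavelength, value)` tables of a declared kind —
percent transmittance, absorbance, or molar absorption — with strictly
increasing wavelengths in nm. Radiant intensities $I$, $I_0$ never
appear individually; only their ratio enters via
$\%T = 100\,I/I_0$ and

$$A = -\log_{10} T = 2 - \log_{10} \%T .$$

Base-10 logarithms are used throughout: the convenient $2-\log\%T$ form
holds only in base 10. $\%T$ is constrained to $(0, 100]$ — zero is
excluded so absorbance stays finite; $\%T > 100$ (negative absorbance)
is physically impossible for a raw measurement and rejected on
conversion unless explicitly allowed, because solvent-subtracted
*difference* spectra can legitimately dip slightly below zero under
noise. Negative values in difference and corrected spectra are preserved
and flagged, never clipped: clipping would silently distort the value
ratios that the anchor method depends on, especially near 700 nm where
hemoglobin absorbance is small.

Two spectra are combined pointwise only when their grids are identical;
the single sanctioned alignment path is `resample_spectrum()` — linear
interpolation, no extrapolation — so there is exactly one interpolation
convention in the package (anchor evaluation and `lookup_epsilon()` use
the same one). Replicates are averaged in the absorbance domain, where
Beer–Lambert is linear, with the sample standard deviation ($n-1$)
attached.

## The reference-anchored route

From solution and solvent transmittance on a common grid, the component
absorbance is $A = A_{\mathrm{sol}} - A_w$. If the transmittance data
were normalized by an unknown factor, the derived absorbance is scaled
by an unknown $k > 0$; but $A$ remains proportional to
$\varepsilon(\lambda)$ with proportionality $k\,c\,d$, so the ratio

$$\varepsilon(\lambda_2) =
  \frac{A(\lambda_2)}{A(\lambda_1)}\,\varepsilon(\lambda_1)$$

cancels $k$, $c$, and $d$ simultaneously. Neither $k$ nor $k\,c\,d$ is
identifiable, and the package does not try to estimate them; the method's
guarantee is exactly the invariance, which the test suite checks to
machine precision for $k \in \{0.1, 1, 7.3\}$.

**Combining two anchors.** With several anchors (e.g. 535 and 593 nm)
each yields its own scale $\varepsilon_i / A(\lambda_i)$. How multiple
anchors should be merged is genuinely open — averaging, piecewise
scaling, and fitting are all defensible. We provide `policy = "single"`
(first anchor only, exact passthrough at its wavelength) and the default
`policy = "geometric_mean"`, chosen because scale factors act
multiplicatively, so their geometric mean is the natural central value
and keeps the result symmetric under inversion of the ratio. On exact
data all anchors give identical scales, so the policies coincide;
per-anchor scales differing by more than 1% indicate inconsistency
between the anchors and the spectrum shape and raise a warning rather
than an error — it is a data-quality signal, not a program defect.

## The concentration-series route

A dilution series at total hemoglobin concentrations
$c \in \{0.07, 0.06, 0.05, 0.04, 0.03\}$ mmol/L in a $d = 1$ cm cuvette,
each measured three times, gives at every wavelength a regression
problem $A = \varepsilon_{\mathrm{sol}}\, c\, d$. We estimate
$\varepsilon_{\mathrm{sol}}$ as the slope of the **no-intercept** least
squares fit of $A$ on $c\,d$: Beer–Lambert forces the line through the
origin, and the fit pools all five concentrations with their proper
leverage instead of averaging the per-concentration ratios $A/(c d)$
(the mean-ratio estimator is available as
`method = "mean_ratio"` for comparison — it weights low concentrations,
where the relative noise is largest, most heavily). The analytic slope
standard error $\sigma / \sqrt{\sum (c_i d)^2}$ and the residual SD are
attached to the result.

The solution is a two-component mixture with glycated molar fraction
$f$, so
$\varepsilon_{\mathrm{sol}} = f\,\varepsilon_{\mathrm{HbA1c}} +
(1-f)\,\varepsilon_{\mathrm{non}}$, inverted exactly by

$$\varepsilon_{\mathrm{HbA1c}} =
  \frac{\varepsilon_{\mathrm{sol}} - (1-f)\,\varepsilon_{\mathrm{non}}}{f}.$$

The default fractions are computed at call time from the control
material's certified concentrations — level 1: $0.228/9.43$, level 2:
$0.488/7.44$ — never stored as rounded decimals. Because $f$ is small
(≈ 0.024 and 0.066), the correction amplifies noise by $1/f$; this is
inherent to the method, and the attached regression errors make the
amplification visible.

Replicate averaging happens *first* (per concentration, across the
three measurements), then the regression, then the correction. Whether
one should instead fit each replicate and average the coefficients is
not determined by the science; the replicate-first order was fixed
because it feeds the regression its best-estimate absorbances and makes
the noise model of the analytic standard error exact.

Three open points are documented rather than resolved: the
concentration basis of $\varepsilon$ (per tetramer vs. per heme) is
taken as "per mole of hemoglobin as supplied" in the stated mol/L; the
oxygenation state implicit in $\varepsilon_{\mathrm{non}}$ is whatever
the supplied reference table encodes; and real analyses must supply a
literature $\varepsilon_{\mathrm{non}}$ table — the packaged CSV is a
synthetic stand-in (see below).

## Q-band peak reporting

Hemoglobin's two visible absorption maxima (Q-bands) lie between 500 and
600 nm. `find_q_band_peaks()` reports the `n_peaks = 2` strongest
*strict* local maxima in the window, at least 10 nm apart. Strict
inequality avoids double-counting plateaus on coarse grids; the 10 nm
separation — well under the ~34 nm Q-band spacing but above noise-scale
wiggles — prevents one noisy band from supplying both reported peaks.
Ties break toward the lower wavelength, making reports deterministic.
Fewer maxima than requested yield a shorter report with a warning, not
an error: a monotone spectrum in the window is valid data.

## Error-grid analysis

Three-zone classification of (reference, estimate) HbA1c pairs on the
NGSP percent scale:

* **Zone A**: $|est - ref| \le 0.20\,ref$. The boundary is inclusive —
  "within 20%" includes 20%.
* **Zone C**: the estimate's diagnostic category (normal < 5.7;
  prediabetes 5.7–6.4 inclusive; diabetes > 6.4) crosses from normal to
  diabetes or diabetes to normal relative to the reference. Both
  directions — unnecessary treatment and dangerous non-treatment — share
  the single C bucket of a three-zone grid. The exact B/C geometry is
  not standardized for HbA1c; this category-crossing rule is the
  package's definition and is configurable via `zone_policy()`. Zone
  *counts* from published plots do not depend on it.
* **Zone B**: everything else.

Percentages are $100\,\mathrm{count}/n$ rounded **half-up** to two
decimals (base R's `round()` is half-even, which cannot reproduce
conventional clinical reporting). The prediabetes upper bound 6.4 is
treated as inclusive ("above 6.4" means diabetes).

## The synthetic generator

`gaussian_band_spectrum()` builds molar absorption spectra as sums of
Gaussian bands plus an exponentially declining baseline,
$b\,e^{-(\lambda-300)/\tau}$. Gaussians are a computational stand-in:
real heme bands are closer to Voigt profiles, but peak-recovery and
round-trip testing only need smooth, controllable band shapes. The
presets place Q-bands at 545/579 nm ("level1") and 544/577 nm
("level2") — the observed peak positions for the two control levels —
with amplitudes chosen so corrected peak coefficients land in the
4–9 × 10⁵ M⁻¹cm⁻¹ range typical of hemoglobin; the baseline
(1.0–1.2 × 10⁵ at 300 nm, 150 nm e-folding) keeps the spectrum well
above zero across 450–700 nm, as real hemoglobin is, so that relative
recovery error is meaningful at the band edges. Band centers are
science-anchored; amplitudes, widths (10 nm SD) and the baseline are
fixture choices, fixed once.

`simulate_measurement_series()` applies the forward Beer–Lambert model
$A = [f \varepsilon_{a1c} + (1-f)\varepsilon_{non}]\,c\,d$ with additive
Gaussian noise in the **absorbance** domain (a detector-domain noise
model would require an instrument model we do not have), and emits
matching transmittance spectra $\%T = 100 \cdot 10^{-kA}$ in which the
normalization factor $k$ multiplies the absorbance — precisely the
arbitrary rescaling the anchored route must cancel. The default noise
SD used in tests, 0.002 absorbance, is a convention (instrument noise
levels are not published for this design); the noise-scaling test
checks the estimator error is linear in this choice, so conclusions do
not hinge on it. One integer seed drives every draw through R's global
generator; identical seeds give bit-identical outputs.

`simulate_ega_points()` realizes prescribed zone counts by rejection
sampling inside each zone's region (references uniform on 4–12%), which
is how published error-grid summaries are rebuilt from their printed
counts alone.

**What passing tests do and do not show.** The generator emulates the
statistical *structure* the analysis assumes: Beer–Lambert linearity,
additive homoscedastic noise, exact mixture composition, a smooth
two-band spectrum. Real cuvette data add stray light, baseline drift,
bandpass convolution, turbidity, and oxygenation heterogeneity — none
simulated here (deliberately: correcting them is out of scope). Passing
recovery tests therefore validates the *algebra and statistics* of the
pipelines, not robustness to instrument systematics.

## Numerical choices and problem sizes

* Tolerances: algebraic identities (mixture inversion, round trips,
  normalization invariance) are tested at 1e-12 relative or tighter;
  end-to-end noiseless recovery at 1e-9 (observed ~1e-14); these are
  floating-point headroom, not statistical slack.
* Fixture grids sample at 1 nm over 440–710 nm (271 points), so the
  450–700 nm reporting band (251 points) survives band restriction with
  margin for resampling. The spectrometer's true sampling step is not
  part of the science; 1 nm is a convention.
* Monte Carlo checks use 100 seeds of the 5-concentration × 3-replicate
  design at noise SD 0.002, compared against the closed-form
  no-intercept OLS standard error propagated through the $1/f$
  correction; the whole suite runs in a few seconds.
* Degenerate inputs fail loudly: non-positive $\%T$, anchors at
  non-positive relative absorbance, repeated concentrations, fractions
  outside $(0,1]$, grids requiring extrapolation, bands catching fewer
  than two samples.

## Known limitations

* The anchored route's accuracy is bounded by the anchors: errors in the
  literature $\varepsilon$ values propagate multiplicatively, and no
  uncertainty propagation from anchor error bars is attempted.
* $\varepsilon_{\mathrm{non}}$ is consumed as given; oxy/deoxy mixture
  state and tetramer-vs-heme basis are the caller's responsibility.
* The $1/f$ noise amplification makes low-glycation materials
  (f ≈ 0.024) intrinsically noisy; the package reports, but does not
  reduce, that variance.
* No stray-light, drift, smoothing, or vendor-format support; inputs are
  plain two-column CSV/TSV spectra.
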