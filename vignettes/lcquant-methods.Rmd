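---
title: "Targeted LC-MS quantification with lcquant: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted LC-MS quantification with lcquant: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcquant)
```

## The quantification problem

Targeted metabolomics asks for absolute concentrations (µmol/L) of a known
panel of compounds from LC-MS runs. Between the raw spectra and a
concentration table sit five steps, each of which `lcquant` automates:

1. **Ingestion** — mzML, mzXML or ANDI-MS netCDF runs (optionally
   zip-wrapped) are reduced to MS1 spectra with retention times in minutes.
2. **Chromatogram construction** — for each metabolite a single quantifier
   m/z (by default the `[M+H]⁺` or `[M−H]⁻` ion of its molecular weight) is
   traced through the run as an extracted-ion chromatogram (EIC).
3. **Peak detection** — each EIC is optionally Savitzky–Golay smoothed and
   split at local intensity minima into peaks; areas come from trapezoidal
   integration.
4. **Retention-time alignment** — in liquid chromatography the drift in
   retention time between runs is *non-linear*, so peak assignment across
   runs uses a RANSAC-fitted monotone polynomial warp rather than a constant
   offset.
5. **Calibration and inversion** — per metabolite, six regression families
   relating area $A$ to concentration $C$ are fitted to standard runs:
   linear $A = a_0 + a_1 C$, logarithmic $A = a_0 + a_1\ln C$, power
   $A = a_0 C^{a_1}$, exponential $A = a_0 a_1^{C}$, and quadratic/cubic
   polynomials. The family with the highest $R^2$ (with a parsimony
   tie-break) is inverted to map sample areas to concentrations.

An internal standard (IS), when one is flagged in the ion list, divides
every analyte area in the same run, cancelling injection-volume and
ionisation-efficiency variability; the normalization is applied uniformly
to standards and samples before any fitting.

## Peak detection

Profile spectra are centroided: local maxima above a `noise_level` become
sticks whose m/z is the intensity-weighted mean over the maximum's
contiguous above-noise neighbourhood and whose intensity is the summit.

EICs carry one point per MS1 spectrum (explicit zeros rather than gaps) so
all traces of a run share one RT grid. Deconvolution treats local minima
as candidate borders, but raw minima over-segment noisy traces, so a
minimum separates two peaks only when its intensity is at most
`min_valley_ratio` times the smaller adjacent apex; shallower valleys are
merged away deepest-first, which keeps the procedure symmetric under trace
reversal. Plateau maxima take the leftmost scan as apex.

Savitzky–Golay smoothing is applied to the EIC (not the spectra) before
border detection; the borders are then used against the *raw* trace for
heights and areas. The filter reproduces polynomials up to its order in
the interior and handles edges by mirrored padding.

Three presets bundle these tunables with a monotone sensitivity ordering;
every field is individually overridable:

| preset    | smoothing | `min_valley_ratio` | `noise_level` |
|-----------|-----------|--------------------|----------------|
| fast      | none      | 0.5                | 20             |
| default   | SG 7/2    | 0.66               | 10             |
| thorough  | SG 11/3   | 0.8                | 2              |

The intensity-valued settings (`noise_level`, `min_peak_height`) are
instrument-dependent; the synthetic scenarios set them from the known noise
level (`noise_level = sd`, `min_peak_height = 6·sd`), which is what an
analyst does from a blank run.

## Retention-time alignment

The warp family is {identity, linear, quadratic}: quadratic is the
smallest family able to express the curved drift seen in LC while
remaining monotonicity-checkable in closed form (its derivative is linear,
so positivity at the span ends suffices). Candidate pairs are all
(reference peak, sample peak) combinations matching in m/z within
`mz_tolerance` and RT within `rt_pre_tolerance` (default 1 min). RANSAC
(default 1000 iterations, inlier band 0.05 min, mandatory seed) fits
minimal subsets, keeps the consensus-maximal monotone model and refits on
its inliers by least squares; when all pairs are clean this reduces
exactly to the direct least-squares fit. Too few pairs degrade
quadratic → linear → identity with a warning, never an error.

Suggestion picks the peak *nearest* to the warped expected RT within
±`rt_window` (default 0.2 min) — not the tallest, because the tallest peak
in a window is not necessarily the right one. Instead, a cell whose
suggested peak is not the highest in the window is flagged `not_highest`
for visual confirmation; a window without peaks yields an empty suggestion
flagged `out_of_window`. Manual integration (`override_selection`) replaces
a suggestion by a trapezoidal integral over analyst-chosen bounds and is
persisted through a selections CSV so projects can be re-quantified after
curation.

## Calibration details

Minimum standards per family equal the parameter count where it binds
(quadratic 3, cubic 4) and two otherwise; fewer than six levels triggers a
warning since six non-zero levels covering the expected range are the
recommended design. Zero-concentration levels are excluded from the
logarithmic/power families (their response is undefined at $C=0$) with a
warning rather than a failure. Fits minimise squared error on the area
scale; power and exponential are initialized by log-linearization and
refined by Levenberg–Marquardt, and the log-scale $R^2$ of the
initialization is reported alongside. Optional 1/C and 1/C² weights are
available — the standard bioanalytical remedy when noise is proportional
to signal. Best-fit suggestion ranks on $R^2$; ties within $10^{-4}$ go to
the more parsimonious family (linear, then the two-parameter transforms,
then quadratic, then cubic), so a perfectly linear panel is reported as
linear even though the polynomials nest it.

Inversion uses closed forms for five families; the quadratic picks the
real root inside the calibration range (else the nearest-to-range root,
flagged), and the cubic does a bracketed root search on the monotone
branch covering the range. Concentrations outside `[c_min, c_max]` are
flagged `extrapolated`; negative inversions are clamped to zero and
flagged. The best family is chosen once at calibration time and recorded
in the calibration report, rather than re-chosen per sample, so all cells
of a metabolite share one curve.

## The synthetic-data generator

`make_scenario()` builds projects with known ground truth: Gaussian
chromatographic peaks (height $= \mathrm{area}/(\sigma\sqrt{2\pi})$,
default $\sigma$ = 0.05 min on a 0.02-min scan grid), a per-run quadratic
monotone RT warp, additive white noise clamped at zero, and spurious
near-baseline peaks Poisson-placed at random target channels with
log-uniform heights below the 25th percentile of the run's true peak
heights — the small-distractor failure mode that motivates the
`not_highest` flag. Isobaric channels (e.g. leucine/isoleucine) are merged
into one m/z stick per scan, and the full-panel scenario forces ≥ 0.6 min
retention separation between near-isobars, as an analyst designing the
assay would.

Scenario conditions:

* `linear_small` — 3 metabolites, 3 standards, 2 samples, noise-free; the
  smoke test.
* `six_family` — one metabolite per calibration family, 6 standards on
  each truth curve.
* `crowded_baseline` — 8 metabolites with heterogeneous response factors,
  2 standards, 3 samples, quadratic drift ≤ 0.5 min over 20 min, and 4
  spurious peaks per minute (about ten times the true peak count) spread
  uniformly — the adversarial alignment design.
* `is_normalized` — 4 metabolites (one IS) with 30% CV log-normal
  injection variability that the IS ratio must cancel.
* `full_panel` — 29 metabolites at real monoisotopic masses, 6 standards
  (5–200 µmol/L), 12 samples drawn log-uniformly in 10–180 µmol/L,
  quadratic drift, signal-to-noise 20.

**SNR convention.** "SNR 20" anchors the white-noise standard deviation at
the apex height of the weakest peak at the *lowest standard level*
(LLOQ-style anchoring, the bioanalytical convention): every quantifiable
peak then has SNR ≥ 20. Sample truths stay inside the calibration range
because a validated assay is designed so that samples fall in range.

What the generator does *not* emulate: peak tailing (exponentially
modified Gaussians), isotope envelopes and adduct series, ion suppression
between co-eluting analytes, and m/z miscalibration. Passing the synthetic
suite therefore demonstrates the *mechanism* — detection, alignment,
calibration, inversion — not performance on any particular instrument's
real data.

## Validation design and numerical choices

The validation suite (and `scripts/acceptance.R`) recomputes, from
scratch, per run:

* the six-family predict-then-invert round trip to $10^{-6}$ and
  noise-free coefficient recovery to $10^{-6}$;
* recovery under 2% multiplicative noise at n = 6 standards, measured as
  the **median over 11 replicate fits**. The identifiable families are
  judged coefficient-wise (power with 1/C² weighting, matched to the
  multiplicative noise); the quadratic and cubic are judged on the fitted
  curve over a 20-point grid, because their raw coefficients are heavily
  collinear at six design points and are not individually identifiable at
  the 10% level no matter the estimator;
* RANSAC recovery of a quadratic drift ($a_2 = 0.002$) with 20% gross
  outliers, which must be excluded from the inlier set;
* pooled peak-suggestion accuracy ≥ 95% on `crowded_baseline` over 50
  seeds (a suggestion counts as correct when the chosen apex is within
  0.1 min — two scan widths — of the true warped RT);
* the end-to-end benchmark: on `full_panel` over 50 seeds
  (50 × 29 × 12 = 17,400 cells), ≥ 99% of quantified cells within 15%
  relative error of simulated truth, reported with 0–5/5–10/10–15/>15%
  bins. This is a desk-scale analogue that validates the pipeline's
  mechanism; it does not reproduce any real-data percentage.

Problem sizes (20-min runs on a 0.02-min grid, 50 replicates) were chosen
so the whole suite runs comfortably on a laptop-class single core.

Numerical corner cases worth knowing: plateau apexes and valley points
take the leftmost scan; integration bounds are linearly interpolated so
adjacent intervals add exactly; a run whose internal-standard peak is
missing has all cells marked missing (flag `is_missing`) rather than
silently unnormalized; EIC channels closer than twice the m/z tolerance
see each other's peaks, which is physical (isobars) and is resolved
chromatographically, not spectrally.

## Known limitations

Only MS1 spectra are used (tandem data are ignored on ingestion).
One quantifier ion per metabolite; no isotope-pattern confirmation. No
baseline subtraction: with zero-clamped noise this leaves a small positive
area bias (~1–2% at SNR 20) that the valley-bounded borders partly offset.
The mzML/mzXML writer emits centroid sticks; profile round-trips are
supported for reading but synthetic profile data use a minimal 3-point
peak shape.
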