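---
title: "Targeted PFAS quantification in wastewater: models, limits and risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted PFAS quantification in wastewater: models, limits and risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfastrace)
```

## The measurement model

Targeted PFAS monitoring by LC-MS/MS in multiple-reaction-monitoring
(MRM) mode quantifies each compound through two precursor-to-product
transitions: the more abundant *quantifier* carries the concentration
information, the *qualifier* confirms identity via the ion ratio
(quantifier area / qualifier area — the direction is a convention and is
fixed and documented here, since the ±40 % identification window is
applied on the linear ratio around the band mean and is only
approximately symmetric in log terms). A handful of compounds (PFBA,
PFOPA, PFDPA, 8:8 PFPiA) yield no usable second transition; they carry
an `NA` qualifier throughout.

Quantification is internal-standard based. With an isotopically
labelled internal standard (ISTD) spiked at constant amount, the
response ratio

$$y = \frac{A_\text{quant}}{A_\text{ISTD}} = b \, c + a$$

is linear in the in-vial concentration $c$ (µg/L). `fit_calibration()`
fits this line by least squares with replicate injections entering as
individual points — not level means — preserving the variance structure
of the triplicate-injection design. Weighting is ordinary least squares
by default with $1/x$ available by configuration; the source method does
not state its weighting, and the choice shifts low-end accuracy, so it
is exposed rather than hidden. `back_calculate()` inverts the line and
flags extrapolation below/above the fitted range and negative
back-calculations (which are kept, because the recovery formula needs
them).

## Instrumental and method limits

The instrumental quantification limit (IQL) is determined empirically by
`determine_iql()`: the lowest measured concentration at which a strict
majority of replicate injections shows quantifier S/N ≥ 10 and
confirmation S/N ≥ 3.3 ("the most injections" is read as a strict
majority; a tie at exactly half fails). The instrumental detection
limit follows as

$$\mathrm{IDL} = 0.33 \times \mathrm{IQL},$$

the ratio of the detection (3.3) to quantification (10) S/N criteria.
A formula circulates in which the IQL is instead *divided* by
$10 \times 3.3$; that form contradicts every published IDL/IQL pair
(all exactly 0.33 × IQL), so this package fixes the multiplicative
relation and does not make it configurable.

Method limits incorporate sample preparation. With recovery $R$ (%) and
matrix concentration factor $C_f$ (100 for influent wastewater: 50 mL of
sample concentrated to 0.5 mL),

$$\mathrm{MQL}\ (\text{ng/L}) =
  \frac{\mathrm{IQL}\ (\text{ng/L}) \times 100}{R \times C_f},$$

and identically MDL from IDL. The IQL is an in-vial µg/L value and the
MQL an in-sample ng/L value; `method_limit()` performs the µg→ng
conversion explicitly and then applies the formula — never a fused
magic constant. Compounds that cannot be recovered (R ≤ 0) have no
defined method limit and are reported unquantifiable. Reproducing a
published limit table from its IQL and recovery columns is exact at the
printed rounding for essentially every compound; the residual mismatches
(one last digit) trace to the recoveries being printed rounded to 0.1
percentage points, and the regression tests allow exactly that much.

## Validation metrics and status classification

* Accuracy (%) $= C_\text{exp} / C_\text{theo} \times 100$.
* Precision is reported as percent RSD $= s / \bar{C} \times 100$. (The
  source formula is typeset as an absolute standard deviation but is
  labelled RSD and reported in percent; the relative reading is the only
  one consistent with the reported values, and is what
  `precision_rsd()` computes.)
* Recovery (%) $= (C_{ss} - C_{us}) / C_\text{theo} \times 100$, with
  the unspiked matrix concentration $C_{us}$ subtracted so native
  background does not inflate recovery. Recovery may exceed 100 %
  (matrix enhancement) or go negative.
* Method recovery is aggregated as mean ± sd across all spike levels
  inside the compound's calibration range; per-level values are
  retained. QC levels may be excluded per (analyte, level) pair by
  configuration only — never automatically.

`classify_quantification()` applies the band rules: fully quantitative
for accuracy 50–120 % and precision < 30 %; semi-quantitative for
accuracy 30–50 % or precision 30–50 %; qualitative beyond. Boundary
conventions (50 and 120 inclusive for quantitative accuracy, 30
inclusive for semi, precision 30 excluded from quantitative) are design
choices pinned by tests, as the prose rules do not state open/closed
endpoints. A compound without a second transition can additionally be
capped at semi-quantitative. The cap is **per analyte**, not global:
published target lists label some one-transition compounds (PFOPA,
PFDPA, 8:8 PFPiA) semi-quantitative for exactly this reason while
leaving another (PFBA) fully quantitative, so a global rule cannot
reproduce practice. Note also that published labels are sometimes
demoted for reasons outside these bands (accuracy above 120 % or poor
calibration linearity); the band rule maps such compounds to
"qualitative", and reproducing those labels requires the analyst's
judgement, not a threshold.

`compare_treatments()` implements the sd-overlap rule for
sample-handling comparisons (dry-down in silanised glass, standing in
HDPE bottles, alternative elution solvents): a drop in accuracy counts
only when it exceeds the standard deviations of both the treatment and
the reference, and material suitability is banded on the absolute drop
(< 15 points suitable, 15–30 medium, ≥ 30 potentially unsuitable). No
t-tests are layered on top; the rule is deliberately exactly the
published one.

## Loads and censoring

Influent concentrations are left-censored: a day is `below_LOD`,
`below_LOQ`, or `detected`. For aggregation, censored days contribute
**zero** (`censor_for_aggregation()`). Substitution at LOD/2 or similar
is deliberately not offered — zero substitution is the convention that
makes cumulative rows reconcile exactly with their per-day entries, and
offering alternatives would silently break that reconciliation.
Detection frequency counts days with any detection, so a `<LOQ` day
counts and a `<LOD` day does not.

Daily loads use each day's own flow:
$\mathrm{DL}\ (\text{mg/day}) = C\ (\text{mg/L}) \times V\ (\text{L/day})$,
and the population-normalised daily load is
$\mathrm{PNDL} = \mathrm{DL} / P \times 1000$, reported in µg/day per
1000 inhabitants — the unit campaign tables report, although the
defining formula is sometimes typeset with mg; the algebra is followed
with the table's units and the discrepancy is not "repaired". The ± on
cumulative quantities is the standard deviation across the detected
per-day values (zero when fewer than two days were detected), which is
the dispersion measure the campaign tables print.

The packaged `site_days_synthetic.csv` is **synthetic**: the real flow
and population records live in non-public supplementary material, so
per-day flows (~2.29 × 10⁸ L/day) were back-derived from single-detection
rows of the published load table and a population chosen to match the
printed PNDL scale. They reproduce the published daily loads to ~1 % and
are good enough to exercise the arithmetic, but they are not site data.

## Environmental risk

`risk_quotient()` computes RQ = MEC / PNEC against the lowest recorded
freshwater PNEC per compound, with an optional dilution factor (tenfold
is a common assumption for the receiving water of a combined sewer
overflow). Bands are low (RQ < 0.1), medium (0.1 ≤ RQ < 1) and high
(RQ ≥ 1). Per-analyte headline values use the **maximum single-day**
concentration: a single day's measurement is an environmental
concentration, a cumulative sum across days is not. Because the
convention (maximum, mean, or per-day) is genuinely open, per-day RQs
are always emitted so any convention can be read off. Display rounding
is two significant figures; full precision is retained internally.

## The synthetic campaign generator

`generate_campaign()` emulates the measurement process so that every
stage is testable without instrument data:

* Areas carry multiplicative lognormal noise (mean 1, CV `noise_cv`) —
  heteroscedastic and positive by construction, matching the observation
  that ion-ratio variability grows toward the IQL. A shared
  per-injection efficiency scales analyte and ISTD areas together, and
  cancels in the response ratio — the reason the assay normalises by an
  internal standard in the first place.
* The quantifier S/N is proportional to concentration
  (`sn_per_conc × c`), with the confirmation trace at 0.33 of it so the
  two S/N rules coincide at the same level. The default
  `sn_per_conc = 12 / IQL` puts S/N = 12 at the configured IQL:
  comfortably above the ≥ 10 rule, while the next level down on the
  19-point grid (a factor ≈ 1.9 lower) falls below it, so the S/N rule
  recovers the configured IQL.
* Matrix samples scale by `true_recovery` (which may exceed 1) on top of
  a configurable native background, exercising the unspiked-sample
  subtraction; influent samples map in-sample ng/L to in-vial µg/L
  through recovery and the concentration factor.
* Randomness is drawn from per-analyte substreams derived from one
  master seed and the analyte name, so runs are byte-identical for a
  fixed seed and adding analytes does not perturb existing draws.

Default design follows the published campaign: 19 log-spaced calibration
levels from 0.01 to 1000 µg/L in triplicate, QCs and matrix spikes at 5,
20, 200 and 500 µg/L in triplicate, and per-day influent samples. The
default noise CV of 5 % is a typical in-batch area RSD for a
well-behaved MRM assay.

What the generator does **not** emulate: chromatographic peak shape and
integration, co-elution and cross-talk, carry-over, between-batch drift,
matrix-dependent ionisation suppression that varies by sample, and
non-linear response at the extremes. Passing tests therefore certify
the *data-analysis* pipeline — calibration algebra, limit rules,
censoring, loads, risk — on data from an idealised instrument; they say
nothing about chromatography.

## Numerical choices and problem sizes

* Calibration r² is computed directly from weighted residuals
  (identical to the usual definition, without `summary.lm`'s
  perfect-fit warnings). On exactly collinear input r² is exactly 1.
  With 5 % multiplicative noise over five decades, unweighted r²
  concentrates near 0.997 — reaching the ≥ 0.999 linearity of the best
  published compounds requires ~2 % noise, and the tests check both
  regimes.
* Unit conversions are single multiplies/divides by exact powers of
  ten; a round trip is bit-exact on representable decimals and within
  one ulp on arbitrary doubles.
* Ties and degenerate input: the IQL majority rule fails ties at
  exactly half; zero-ISTD injections are excluded from calibration with
  a warning; fewer than three distinct levels is an error; RSD of a
  zero-mean replicate set is `NA` with a warning.
* Test problem sizes: convergence checks use 1000 replicate injections
  at 5 % noise (estimates recover truth within 2 % relative) — large
  enough for the law-of-large-numbers bound, small enough that the
  whole suite runs in well under a minute.

## Known limitations

* Analyte matching is exact and case-sensitive by design (PFAS short
  names collide across naming conventions); there is no alias or CAS
  resolution.
* Only zero-substitution censoring is offered (see above).
* No model-based (calibration-residual) LOD estimators — only the S/N
  rule.
* Risk assessment covers single compounds against freshwater PNECs; no
  mixture toxicity, no chronic-exposure modelling.
* The pipeline starts at integrated peak tables; there are no raw-file
  readers.

## A worked run

```{r example, eval = FALSE}
registry <- load_analyte_registry(pfas_extdata("analytes.csv"))
pnec <- load_pnec_registry(pfas_extdata("pnec.csv"))
site <- load_site_days(pfas_extdata("site_days_synthetic.csv"))

out <- run_pipeline(registry, pnec, site,
                    config = pipeline_config(seed = 1),
                    out_dir = "pfas_report")
out$limits
out$risk[out$risk$headline, ]
```

The same stages run individually — `fit_calibration()`,
`determine_iql()`, `limit_set()`, `aggregate_campaign()`,
`assess_campaign()` — for use on real integrated peak tables with the
same column layouts as the packaged fixtures.
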