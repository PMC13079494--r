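# pfastrace

Targeted multi-residue PFAS quantification and risk assessment for
influent wastewater.

Per- and polyfluoroalkyl substances (PFAS) are persistent, bioaccumulative
contaminants monitored at trace levels in wastewater by LC-MS/MS in
multiple-reaction-monitoring (MRM) mode. `pfastrace` is the data-analysis
half of such a monitoring method: it starts from integrated peak tables
(quantifier/qualifier areas, internal-standard areas, signal-to-noise,
retention times) and carries them through to method limits, validation
metrics, population-level mass loads, and environmental risk quotients.
It is written for analytical chemists and wastewater-based-epidemiology
(WBE) practitioners who need the arithmetic between the instrument and
the report to be explicit, tested and reproducible.

## What it computes

With the ISTD-normalised response ratio `y = A_quant / A_ISTD = b·c + a`:

- **Calibration & back-calculation** — `fit_calibration()`,
  `back_calculate()`: least-squares fit over each compound's calibration
  range (replicates as individual points; optional 1/x weighting),
  inversion with extrapolation and negative-value flags.
- **Instrumental limits** — `determine_iql()`: IQL = lowest level where a
  strict majority of injections has quantifier S/N ≥ 10 and confirmation
  S/N ≥ 3.3; `derive_idl()`: IDL = 0.33 × IQL.
- **Method limits** — `method_limit()`:
  `MQL (ng/L) = IQL (ng/L) × 100 / (Recovery(%) × Cf)` with Cf = 100 for
  influent wastewater; MDL identically from IDL.
- **Validation** — `accuracy_pct()` (C_exp/C_theo × 100),
  `precision_rsd()` (sd/mean × 100), `recovery_pct()`
  ((C_ss − C_us)/C_theo × 100), quantification-status bands
  (`classify_quantification()`), ion-ratio windows
  (`ion_ratio_summary()`), and the sd-overlap rule for sample-handling
  comparisons (`compare_treatments()`).
- **WBE loads** — `aggregate_campaign()`: detection frequencies,
  cumulative concentrations with `<LOD`/`<LOQ` days contributing zero,
  daily loads `DL = C × V` (mg/day) and population-normalised loads
  `PNDL = DL/P × 1000` (µg/day/1000 inh).
- **Risk** — `risk_quotient()` RQ = MEC / PNEC with optional dilution,
  banded low (< 0.1) / medium (0.1–1) / high (≥ 1);
  `assess_campaign()` flags the maximum single-day RQ per compound.
- **Synthetic campaigns** — `generate_campaign()` /
  `generate_influent_truth()`: a seeded generator with known ground truth
  (lognormal area noise, concentration-proportional S/N, per-compound
  recovery, censoring), so the whole pipeline is testable end to end.
- **Orchestration** — `run_pipeline()` executes every stage and writes a
  CSV report bundle plus a JSON run manifest.

A 35-compound PFAS target list (MRM transitions, ISTD assignments,
calibration ranges), the matching instrument/method performance tables, a
freshwater PNEC registry, and a 3-day influent campaign ship as
plain-text fixtures under `inst/extdata/` (`pfas_extdata()` lists them;
site flows/population are synthetic stand-ins, see the vignette).

## Worked example

```r
library(pfastrace)

conc <- read.csv(pfas_extdata("influent_days.csv"), check.names = FALSE)
site <- load_site_days(pfas_extdata("site_days_synthetic.csv"))
pnec <- load_pnec_registry(pfas_extdata("pnec.csv"))

aggregate_campaign(conc, site)[1:4, c("analyte_name", "detection_frequency",
                                      "cumulative_conc", "conc_sd")]
#>   analyte_name detection_frequency cumulative_conc conc_sd
#> 1 PFBS                           2            43.9  13.5
#> 2 PFHxS                          0             0     0
#> 3 PFHpS                          0             0     0
#> 4 PFOS                           0             0     0

risk <- assess_campaign(conc, pnec)
risk[risk$headline & risk$rq > 0, c("analyte_name", "day_id", "mec",
                                    "pnec", "rq_2sf", "band")]
#>   analyte_name day_id   mec   pnec  rq_2sf band
#> 1 PFBS              1  31.5 372000 0.000085 low
#> 2 PFOA              1   3.6    178 0.02     low
#> 3 PFNA              3  60.4   1000 0.06     low
#> 4 PFDA              1  22.3   165. 0.13     medium
#> 5 8:2 diPAP         1 176.     73.3 2.4     high
#> 6 PFOPA             1  54.8  9630  0.0057   low
#> 7 PFDPA             1  63.4   290  0.22     medium
```

Reading: PFBS was detected on 2 of 3 days and summed (censored days at
zero) to 43.9 ng/L; 8:2 diPAP's worst day, 176.2 ng/L against a 73.3 ng/L
freshwater PNEC, gives RQ 2.4 — high risk in an undiluted combined sewer
overflow scenario — while PFDA and PFDPA sit in the medium band.

Method limits from an instrumental limit and recovery:

```r
limit_set("PFBS", iql_ugL = 0.01, recovery = 118.2)
#>   analyte_name idl_ugL iql_ugL mdl_ngL mql_ngL  cf recovery_used
#> 1 PFBS          0.0033    0.01  0.0279  0.0846 100         118.2
```

i.e. a 0.01 µg/L in-vial quantification limit and 118.2 % recovery yield
an in-sample MQL of 0.08 ng/L (MDL 0.03).

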