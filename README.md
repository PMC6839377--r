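# doseagree

Dose comparison techniques for patient-specific radiotherapy QA, side by
side.

Patient-specific pretreatment QA (PSQA) for modulated radiotherapy compares
a measured planar dose (diode array, ~1 cm pitch) against the treatment
planning system's calculation (~1 mm grid) and reduces the comparison to an
agreement index — the percentage of evaluated points passing a per-point
test. Clinics using different tests, acceptance criteria or lower dose
thresholds (LDTs) get different numbers from the same delivery, with
different sensitivity to real dose errors. `doseagree` implements the main
techniques on one grid model so those differences can be measured:

* **Global / local gamma evaluation** — per-point minimum of
  `sqrt(dist²/DTA² + δ²/ΔD²)` over the fine reference grid, with percent
  dose differences `δ` normalized to the distribution maximum (global) or
  to the local reference dose (local); pass at γ ≤ 1.
* **MADD (box and quadrature)** — the DTA criterion converted to a dose
  tolerance by the local dose gradient `g`: `ΔD + g·DTA` (box) or
  `sqrt(ΔD² + (g·DTA)²)` (quadrature); the measured-minus-planned
  difference normalized by that tolerance passes at ≤ 1, with no spatial
  search.
* **Divide-and-conquer (D&C) gamma** — gamma run separately in the HD
  (≥90% isodose), HG (50–90%), MD (20–50%) and LD (10–20%) regions of the
  plan, each with a region-specific dose criterion.

A synthetic-cohort generator produces paired planned (1 mm) / measured
(1 cm) grids with controlled delivery errors, and a correlation-study layer
sweeps techniques × criteria × LDTs over a cohort and quantifies pairwise
similarity of behaviour by OLS regression (R² ≥ 0.64 flags correlation,
α = 0.05 with Šidák correction). It is aimed at medical physicists
comparing QA metrics and at anyone needing a reference implementation of
these comparison tests.

## Worked example

A plan delivered with a 3% overall dose scaling plus detector noise:

```r
library(doseagree)

planned <- generate_plan(plan_spec(), seed = 42)
planned
#> <dose_grid> 121 x 121, spacing 1 x 1 mm, origin (0, 0) mm, absolute mode
#>   dose range: [0.115117, 3.98006] Gy

model <- error_model(scale_factor = 1.03, noise_sd_percent = 0.1)
measured <- sample_detector(inject_errors(planned, model, seed = 43))

compare_dose(planned, measured, "gamma_global", dd = 2, dta = 2, ldt = 10)
#> <dose_comparison> technique gamma_global, criteria 2%/2 mm (global)
#>   77 included points (LDT 10%), agreement index 93.51%

compare_dose(planned, measured, "gamma_local", dd = 2, dta = 2, ldt = 10)
#> <dose_comparison> technique gamma_local, criteria 2%/2 mm (local)
#>   77 included points (LDT 10%), agreement index 70.13%

compare_dose(planned, measured, "dnc", dd = 2, dta = 2)
#> <dnc_result> base 2% / 2 mm, local normalization
#>  region delta_d  n n_pass agreement_index
#>      HD       2  4      1              25
#>      HG       3 42     42             100
#>      MD       5  5      5             100
#>      LD       8 26     26             100
#>   overall: 77 points, agreement index 96.10%
```

The same 3% error reads very differently by technique: global gamma still
reports 93.5% (the scaling is within 2% of maximum over most of the field
once the DTA search is allowed), local gamma drops to 70.1% (a 3% relative
error exceeds the 2% local criterion wherever the gradient cannot rescue
it), and D&C localizes the failure to the high-dose region (HD 25%) where
its tightest criterion applies — while still pooling to 96.1% overall.

Cohort level — twenty synthetic plans, three with delivery errors:

```r
man <- generate_cohort(n = 20, errored_fraction = 0.15, seed = 7)
tab <- batch_indices(man, techniques = c("gamma_global", "gamma_local"),
                     criteria_list = list(c(2, 2), c(3, 3)), ldt_list = 10)
summary(tab)
#>                              technique dd dta ldt  n  mean   sd
#> gamma_global|2%/2mm|LDT10 gamma_global  2   2  10 20 99.27 1.88
#> gamma_global|3%/3mm|LDT10 gamma_global  3   3  10 20 99.87 0.40
#> gamma_local|2%/2mm|LDT10   gamma_local  2   2  10 20 96.96 7.47
#> gamma_local|3%/3mm|LDT10   gamma_local  3   3  10 20 98.18 4.50

correlation_matrix(tab)
#> <correlation_report> 6 pair(s); alpha 0.05 (Sidak-corrected 0.0085124), R2 threshold 0.64
#>                      col_x                     col_y  n r_squared  p_value ...
#>  gamma_global|2%/2mm|LDT10 gamma_global|3%/3mm|LDT10 20    0.8657 2.82e-09
#>  gamma_global|2%/2mm|LDT10  gamma_local|2%/2mm|LDT10 20    0.9104 7.22e-11
#>  ...
```

Mean ± SD per column is the familiar QA-report view; the correlation report
says which technique/criteria combinations rank plans the same way (here
global 2%/2mm and local 2%/2mm correlate at R² = 0.91 on this small cohort,
while global 3%/3mm saturates near 100% and correlates poorly with
everything else).

A thin command-line wrapper over the same functions ships in
`inst/cli/doseagree` (`convert`, `compare`, `synth`, `correlate`
subcommands).

## Layout

* `R/` — grid container and textgrid I/O, the three comparison engines,
  the synthetic-cohort generator, the correlation study.
* `tests/testthat/` — unit and property tests per module, including
  brute-force oracle comparisons and whole-cohort invariant sweeps.
* `vignettes/dose-comparison-methods.Rmd` — the models, numerical choices
  and cohort-design rationale in full.
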