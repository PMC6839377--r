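---
title: "Dose comparison techniques for patient-specific QA: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose comparison techniques for patient-specific QA: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doseagree)
```

## The problem

Patient-specific pretreatment quality assurance (PSQA) for modulated
radiotherapy (VMAT, helical tomotherapy) verifies that the dose a linac
actually delivers agrees with the dose the treatment planning system
calculated. In practice a coarse measured planar dose (a diode array with
about 1 cm detector pitch) is compared against a fine calculated grid
(about 1 mm), and the comparison is summarized as an *agreement index*: the
percentage of evaluated points passing some per-point test. Clinics differ
in which per-point test they use, which acceptance criteria they attach to
it, and which lower dose threshold (LDT) they apply — and those choices
change both the numbers and their sensitivity to real delivery errors.
`doseagree` implements the main techniques side by side on a common grid
model so their behaviour can be compared quantitatively.

## The comparison techniques

All techniques compare an **evaluated** grid (measured, coarse) against a
**reference** grid (calculated, fine) at the evaluated points, without
interpolating either grid. Dose differences are expressed in percent of a
normalization dose *N*.

**Gamma evaluation.** For an evaluated point at position $r_e$ with dose
$D_e$, the gamma index is the minimum over reference points $r$ of

$$\gamma(e) \;=\; \min_r \sqrt{\frac{\lVert r - r_e\rVert^2}{\mathrm{DTA}^2}
  + \frac{\delta(e, r)^2}{\Delta D^2}},
  \qquad \delta(e, r) = 100\,\frac{D_e - D_\mathrm{ref}(r)}{N},$$

with $N$ the reference maximum for **global** normalization and
$N = D_\mathrm{ref}(r)$ for **local** normalization. A point passes when
$\gamma \le 1$ (inclusive). Under local normalization, zero-dose reference
candidates are skipped; if every candidate is skipped the point's gamma is
$+\infty$ and it fails. Because the local denominator never exceeds the
global one, global gamma dominates local gamma pointwise — the package's
test suite asserts this over whole synthetic cohorts.

**MADD.** The maximum allowed dose difference converts the DTA criterion
into a dose tolerance through the local reference gradient magnitude $g$
(percent of maximum per mm): $\mathrm{MADD}_b = \Delta D + g\,\mathrm{DTA}$
("box", summation) or
$\mathrm{MADD}_\gamma = \sqrt{\Delta D^2 + (g\,\mathrm{DTA})^2}$
(quadrature). The per-point index is the absolute dose difference in
percent of maximum divided by the local tolerance. There is no spatial
search — the test is pointwise, hence insensitive to grid resolution. Since
$a + b \ge \sqrt{a^2 + b^2}$ for $a, b \ge 0$, the box tolerance dominates
and $\mathrm{MADD}_b$ pass rates are never below $\mathrm{MADD}_\gamma$
ones.

**Divide-and-conquer (D&C) gamma.** The planned distribution is segmented
into four isodose regions — HD ($\ge 90\%$ of maximum), HG ($[50, 90)$),
MD ($[20, 50)$), LD ($[10, 20)$) — and gamma runs separately per region
with a region-specific dose criterion (`dnc_criteria()`), shared DTA.
The regional criteria widen toward lower dose so that the *local* dose
difference corresponds to approximately one *global* difference: a 7%
difference at the 70% isodose equals $0.7 \times 0.07 = 0.049$ of the
maximum dose, within rounding of the matching 5% maximum-dose criterion
(`dnc_global_equivalent(7, 70)`).

## Numerical choices

* **Coordinates.** Cell $(i, j)$ sits at
  `origin + ((i-1) * row_mm, (j-1) * col_mm)`; positions are cell centres.
  Evaluated positions must lie inside the reference extent.
* **Gamma search.** The production search is windowed but *exact*: the
  gamma at the reference node nearest the evaluated point is an upper bound
  $\gamma_0$ on the minimum, and no candidate whose spatial term alone
  exceeds $\gamma_0$ can be the minimizer, so the search window radius is
  $\mathrm{DTA}\cdot\gamma_0$. A fixed-radius cap (e.g. three DTA) would
  not be exactly equivalent to the uncapped search when the local minimum
  exceeds the cap, so it is not used. `search = "exhaustive"` retains the
  full-grid minimum as a cross-check, and the test suite compares both
  against an independent brute-force oracle to $10^{-12}$.
* **Pass boundary.** The pass test is inclusive ($\gamma \le 1$,
  $\mathrm{NDD} \le 1$); ties in the gamma minimization are irrelevant and
  the minimizing location is not reported.
* **Lower dose threshold.** Applied to the *planned* (reference) dose —
  sampled at the evaluated positions — as a fraction of the planned
  maximum, strictly-below exclusion. Thresholding on the plan keeps the
  mask independent of measurement noise.
* **Region membership** (D&C) is likewise frozen from the planned dose;
  boundaries are lower-inclusive. D&C defaults to local normalization,
  matching the construction of its criteria table; global normalization is
  available for sensitivity analysis. The overall D&C index is the pooled
  (count-weighted) pass fraction over the four regions, so with all
  regional criteria set equal it reproduces plain gamma at a 10% LDT
  exactly.
* **Gradients** (MADD) are computed on the fine reference grid — the 1 cm
  measured grid is too coarse — by central differences (one-sided at
  borders, exact for quadratics) via `pracma::gradient`, sampled at the
  reference point nearest each evaluated point, ties toward the lower
  index. MADD dose differences are expressed in percent of the reference
  maximum; the same worked equivalence above supports maximum-dose units
  as the common currency, and the convention is isolated in one place so
  it can be flipped.
* **Degenerate inputs.** All-zero grids cannot be normalized; empty masks
  and empty regressors raise errors; an empty D&C region is reported with
  count 0 and `NA`, not an error.

## The synthetic cohort

There is no public corpus of paired planned/measured PSQA grids, so the
package generates one with the statistical structure the analysis needs.
Plans are *analytic*: a rectangular plateau with error-function penumbra
(scale 6 mm), 3 Gaussian modulation lobes (amplitude 0.25–0.6 of the
plateau, SD 8–18 mm) drawn inside the aperture, and a broad low-amplitude
scatter component (0.12 of plateau, SD 70 mm) that produces the extensive
low-dose regions surrounding clinical fields. Defaults: 120 × 120 mm
extent, 1 mm planned grid, 2 Gy plateau, all four D&C isodose bands
populated (checked at generation). Because the field is analytic, rigid
shifts are exact resamplings, so distance-to-agreement behaviour is tested
free of interpolation artifacts.

The "measurement" is point sampling at 10 mm pitch aligned to the planned
lattice — no volume averaging, angular response or cylindrical geometry;
the comparison mathematics, not detector physics, is the subject. Detector
noise is Gaussian with SD 0.1% of the plan maximum, a typical diode-array
repeatability; at that level noise alone essentially never fails even a 1%
dose criterion, so clean plans pass at 100% apart from pathological draws.

A cohort (`generate_cohort()`) contains 100 plans of which 12% carry
delivery errors, mirroring the realistic clinical failure fraction.
Errored plans receive 3–5 localized Gaussian perturbations (SD 8–14 mm,
amplitude 5–9% of maximum, random sign) centred where the planned dose is
5–7.5% of maximum — the flat low-dose scatter shelf. That placement is the
cohort's deliberate design: discrepancies in a near-gradient-free shelf
cannot be rescued by the DTA search and sit mostly below the 10% isodose,
so raising the LDT from 5% to 10% removes the worst-disagreeing points and
the cohort-mean global pass rate does not fall — the direction reported in
the LDT literature for low-dose-error cohorts. The same placement produces
enormous *relative* errors, so local gamma moves the same way. These LDT
directions are distribution properties of cohort means, not per-plan
theorems: with ~169 detector points per plan, single-point discreteness
makes the per-plan direction unstable at 1%/1mm, so the suite asserts the
mean direction. Global dose scaling and rigid shifts are deliberately
absent from the default cohort (they concentrate failures *above* the 10%
isodose and reverse the LDT direction); they are exercised in dedicated
sensitivity cohorts instead, e.g. the 4% scaling cohort on which the suite
checks that local gamma loses more pass rate than global gamma, and global
more than MADD box.

What passing these tests shows — and does not. The synthetic plans are
smooth, noise is stationary and Gaussian, and errors are injected with
known geometry; real measurements add detector-specific effects (volume
averaging, angular response, array calibration) and real delivery errors
are not confined to any dose band. Results on this cohort validate the
comparison mathematics and the qualitative orderings between techniques,
not clinical action thresholds.

## The correlation study

`batch_indices()` sweeps a cohort over techniques × criteria (default
1%/1, 2%/2, 2%/3, 3%/2, 3%/3, 5%/3 mm) × LDTs (5%, 10%) and tabulates one
agreement index per plan and combination, with a mean ± SD summary per
column. `correlation_matrix()` then regresses column pairs with ordinary
least squares (`ols_r2()`), reporting $R^2$, the slope's two-sided
p-value, and a correlation flag at $R^2 \ge 0.64$ — the square of a 0.8
Pearson coefficient, the conventional minimum for clinically acceptable
agreement. Significance uses $\alpha = 0.05$ with a Šidák correction,
$1 - (1-\alpha)^{1/m}$; the family $m$ is all pairs in the report table
(one family per table, configurable), since the source analyses present
one table at a time. $R^2$ is direction-independent for simple regression;
slope and intercept refer to the regression of the second column on the
first. Plans with an undefined index for a combination are dropped
pairwise and counted, never imputed. D&C runs only at the tabulated base
criteria (1, 2, 3, 5%) and is keyed by its fixed 10% domain.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at the
cohort sizes above (100-plan default cohort, 40-plan scaling-sensitivity
cohort, 200 small random pairs for the search-equivalence check); these
sizes give stable cohort means while keeping a complete run in the tens of
seconds on one CPU.

## Known limitations

Planar grids only (a cylindrical array is treated as an unwrapped plane —
no wrap-around in the DTA search); no sub-point interpolation of the
reference during the gamma search, so discretization bounds the spatial
term at half the reference spacing; no DVH- or anatomy-based metrics; the
MADD normalization convention of the original formulation is not restated
in the source material and is fixed here to maximum-dose units; proprietary
vendor formats are out of scope (the textgrid format plus the programmatic
API are the interchange surface).
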