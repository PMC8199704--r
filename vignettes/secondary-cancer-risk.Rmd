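---
title: "From dose grids to lifetime attributable risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From dose grids to lifetime attributable risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secrisk)
```

`secrisk` evaluates radiotherapy-induced secondary cancer risk from a 3D
dose distribution and organ contours. This vignette is the package's own
account of the science it implements: the models and their assumptions,
the parameters that matter, the numerical conventions, and what the
synthetic fixtures do and do not demonstrate.

## The risk chain

The computation is a pipeline of well-separated stages:

1. **Dose and anatomy.** The dose grid (DICOM RTDOSE, Gy) is resampled by
   trilinear interpolation onto the CT/contour geometry — conventionally
   a 2 mm reporting grid when the dose was computed on a finer
   CT-native grid. Contours (RTSTRUCT) are rasterized to voxel masks.
2. **DVH.** Member-voxel doses are tallied into a differential
   dose-volume histogram: volume $V_i$ at bin-center dose $D_i$, total
   organ volume $V$. The differential form is the natural internal
   representation because every later quantity is a volume-weighted sum
   over dose elements.
3. **Organ equivalent dose.** A DVH summary constructed so that equal OED
   means equal secondary-cancer risk. Three dose-response models:
   $$\mathrm{OED}_{\text{linear}} = \frac{1}{V}\sum_i V_i D_i,\qquad
     \mathrm{OED}_{\text{plateau}} = \frac{1}{V}\sum_i V_i
       \frac{1 - e^{-\delta D_i}}{\delta},\qquad
     \mathrm{OED}_{\text{bell}} = \frac{1}{V}\sum_i V_i D_i e^{-\alpha D_i}.$$
   The plateau model is the default for therapeutic dose levels: the
   excess risk per unit dose saturates at high dose because heavily
   irradiated cells are killed rather than transformed. $\delta$ and
   $\alpha$ (both 1/Gy) are organ-specific dose-response factors.
4. **Excess risks.** Both the excess relative risk and the excess
   absolute risk use the BEIR VII solid-cancer form
   $$\beta_s\, D\, e^{\gamma e^*} (a/60)^{\eta},\qquad
     e^* = \begin{cases}(e-30)/10 & e < 30\\ 0 & e \ge 30,\end{cases}$$
   with their own coefficient sets ($\beta$ in 1/Gy for ERR; per
   $10^4$ person-years per Gy for EAR). For exposure ages of 30 and
   above — the range clinical projections usually report — $e^* = 0$ and
   the exposure-age modifier drops out; several tests exploit this
   simplification.
5. **Lifetime attributable risk.** Inclusive integer-year sums from the
   exposure age $e$ to the projection horizon $a_{\max}$:
   $$\mathrm{LAR} = \Bigl(\sum_{a=e}^{a_{\max}}
       \mathrm{ERR}\,\lambda_I^C(a)\,\tfrac{S(a)}{S(e)}\Bigr)^{0.7}
     \Bigl(\sum_{a=e}^{a_{\max}} \mathrm{EAR}\,\tfrac{S(a)}{S(e)}\Bigr)^{0.3}$$
   where $\lambda_I^C$ is the baseline incidence rate and $S(a)/S(e)$ the
   conditional survival. The 0.7/0.3 combination **on a logarithmic
   scale** (a weighted geometric mean) follows the BEIR VII committee's
   transport recommendation as used in the clinical SCR literature; an
   arithmetic variant ($0.7A + 0.3B$) is available behind
   `lar_config(weighting = "arithmetic")` but is off by default. Both
   sums are carried in per-100,000 units (the EAR term is scaled by 10
   from its per-$10^4$ convention), so LAR per-100k $= 1000 \times$ LAR
   percent identically. If either sum is zero the LAR is reported as 0
   (limit convention).

The cumulative baseline risk
$\sum_{a=e}^{a_{\max}} \lambda_I^C(a)\, S(a)/S(e)$ is computed alongside,
so the radiation-attributable addition can be read against the risk the
patient already carries.

## Tunable parameters

| Parameter | Unit | Default | Meaning |
|---|---|---|---|
| `bin_width` | Gy | 0.1 | DVH bin width; risk outputs record the width used |
| `delta` | 1/Gy | 0.317 | plateau dose-response factor (organ-specific) |
| `alpha` | 1/Gy | 0.5 | bell dose-response factor |
| `a_max` | years | 90 | projection horizon (life expectancy) |
| `exposure_ages` | years | 30–80 by 10 | reporting grid |
| `latency` | years | 0 | years after exposure excluded from the sums |
| `w_err`, `w_ear` | — | 0.7, 0.3 | log-scale LAR weights |
| `hu_bin_width` | HU | 25 | material-database binning |

Risk coefficients, life tables and baseline rates are runtime CSV inputs.
The bundled coefficient registry follows the BEIR VII solid-cancer
incidence conventions (ERR: $\gamma=-0.3$, $\eta=-1.4$; EAR:
$\gamma=-0.41$, $\eta=2.8$, with the larger attained-age powers for lung
and bladder) and exists so the package is usable out of the box; any
serious application should supply its own registry. Unknown sites fall
back to the "all other solid" row with a warning — never silently.

## Stoichiometric calibration

Monte Carlo transport needs elemental composition and mass density per
voxel. The bundled calibration maps CT numbers between −1050 and ~3100 HU
through 27 tissue nodes (air, lung, adipose, soft tissues, a skeletal
series from HU 120 to 1500, and three implant metals), interpolating each
element's weight fraction linearly between nodes and renormalizing the
vector to exactly 100 % — the renormalization preserves the
weight-fraction invariant regardless of how the neighboring rows round.
Out-of-range queries clamp to the end nodes with a warning, since
clinical CT floors at −1024 and metal artifacts exceed any table.

Two bundled choices deserve flags. First, the three highest-HU implant
rows of the source table cannot be parsed unambiguously, so they are
bundled as single-element metals (Ti at HU 1640, Ag at 2923, Sn at 3095);
users with implant-bearing scans should replace them. Second, the mass
density curve is not part of the published table; the bundled
piecewise-linear curve follows the standard stoichiometric-calibration
literature (air 0.00121 g/cm³, water 1.0 near HU 0, rising through
skeletal tissue) and is fully replaceable via a two-column CSV. The
material-database exporter bins the HU range into contiguous, half-open
intervals (one material each, evaluated at the bin center) and emits the
GATE-style materials text plus the HU-interval map.

## Numerical conventions and edge cases

* **Bin centers.** $D_i$ is the DVH bin center — unbiased when dose is
  uniform within a bin. Halving the bin width therefore moves the mean
  dose by at most half a bin width (tested).
* **Half-open bins** $[k\,w, (k+1)\,w)$, with the top bin positioned so
  the maximum dose is included.
* **Voxel-center rasterization, even-odd rule.** A voxel belongs to an
  organ iff its center lies inside the slice's polygon set by even-odd
  parity; holes subtract, vertex orientation is irrelevant, and points
  exactly on an edge count as inside (a deterministic tie-break).
  Contours attach to the nearest grid slice within half a slice spacing;
  farther contours are dropped with a warning. Partial-voxel effects are
  deliberately not modelled.
* **Trilinear resampling** reproduces constant and linear fields exactly,
  clamps outside the source extent, and treats single-slice axes as
  constant. Masks and doses are only ever compared on identical
  geometry; the pipeline resamples the dose onto the mask grid, matching
  the direction (fine Monte Carlo grid → reporting grid) of the
  workflow it supports.
* **Plateau limits.** $(1-e^{-\delta D})/\delta \le D$ by concavity, so
  plateau OED never exceeds the mean dose, and it converges to the mean
  dose as $\delta \to 0$ with truncation error $\delta D^2/2$ — which is
  why the $\delta = 10^{-9}$ limit check is run at doses where that
  bound sits below the assertion tolerance.
* **DICOM.** Files are read and written in Explicit VR Little Endian.
  The RTDOSE writer scales to the full signed 32-bit range
  (quantum $\approx 3\times10^{-8}$ Gy at 70 Gy); the CT writer uses
  rescale intercept −1024 with unsigned 16-bit raws so integer HU
  round-trip exactly. Readers reject wrong modalities and unsupported
  transfer syntaxes with typed errors. Sequences are written with
  defined lengths but parsed in both defined- and undefined-length
  forms, so files from mainstream DICOM toolkits read back correctly.
* **VMAT segments.** N control points make N−1 delivery segments;
  segment MU is the total meterset times the weight increment, so the
  segment MUs telescope exactly to the beam meterset. Leaf/jaw positions
  default to segment start (midpoint interpolation is a flag); control
  points that omit MLC positions inherit the previous ones, per the
  DICOM convention of recording only changes. The macro file is a
  documented tab-separated stand-in (full `%.17g` precision, lossless
  round-trip); no published macro format exists to match.

## What the synthetic fixtures show — and what they don't

No patient data ships with the package; every test input is generated in
code. The phantom is a water cylinder with sphere/box organs of
prescribed HU, chosen because membership then has an analytic oracle.
The analytic beam — exponential depth attenuation, Gaussian lateral
profile, uniform leakage floor $\varepsilon D_0$ — emulates the one
feature of real dose distributions this package most cares about: a
high-dose region plus a low, nearly uniform out-of-field dose from
scatter and leakage. Its closed form makes every downstream quantity
hand-checkable, including an end-to-end check that the pipeline LAR for
a uniform-dose organ equals the closed-form evaluation of the risk
equations to within 10⁻⁹ relative.

Passing these tests demonstrates the *computational chain* is correct.
It does not validate dosimetry on real anatomy: no CT noise or
heterogeneity texture, no realistic organ shapes, no beam model beyond
the analytic form, and bundled (not national) life tables and incidence
rates. The default fixture sizes (64×64×24 voxels at 2 mm, six exposure
ages, 0.1 Gy bins) were chosen so the whole suite and the end-to-end run
complete in seconds on a laptop while still exercising multi-bin DVHs
and both in-field and out-of-field organs.

## Design decisions

* **Tabular-first shape.** Calibration tables, DVHs, coefficient
  registries, life tables and reports are tibbles that pipe through
  dplyr, with `tidy()`/`glance()` methods and `autoplot()`/`plot_lar()`
  figures. The 3D grids themselves stay small S3 objects (geometry +
  array) — forcing ~10⁵ voxels per organ into long data frames would
  cost memory and clarity for no analytic gain.
* **Geometric LAR weighting by default**, arithmetic behind a switch:
  the log-scale combination is what the clinical SCR workflow this
  package follows uses, and the switch documents rather than hides the
  alternative.
* **Maximum-vs-sum reporting.** Published organ tables sometimes report
  the maximum ERR/EAR over attained age rather than the lifetime sum;
  the report carries both (`err_max`/`ear_max` and the survival-weighted
  sums), so either convention can be read off.
* **ERR units.** ERR is conventionally dimensionless (a relative
  excess); where tables print it "per 100,000", that is the
  ERR×baseline product. The report keeps the two factors separate and
  documented.
* **Errors are typed** (`secrisk_invalid_input`, `secrisk_schema`,
  `secrisk_format`, `secrisk_type`, `secrisk_stage`...), so pipelines and
  the CLI can distinguish bad input from bugs, and every pipeline
  failure names its stage.

## Known limitations

Single-fraction radiobiology only: no dose-rate or fractionation
(DDREF) handling, no uncertainty propagation, no latency by default
(configurable), no DVH-metric zoo beyond mean dose, no deformable
registration or frame-of-reference transforms, and the DICOM layer
implements the subset of the standard these four RT objects need —
Explicit VR Little Endian, single frame-of-reference — not a general
toolkit.
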