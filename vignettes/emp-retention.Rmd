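---
title: "Methods: size-dependent lung retention of elongate mineral particles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: size-dependent lung retention of elongate mineral particles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(empdsr)
```

## The problem and the model

Elongate mineral particles (EMPs — aspect ratio at least 3:1) inhaled in an
occupational setting are not retained in lung tissue in proportion to their
airborne abundance: aerodynamic behavior, penetration and clearance all
depend on particle length and width. Lung-burden studies, however, rarely
publish individual fiber measurements; what survives is a binned
length-by-width percent-frequency table for the lung and another for the
exposure. This package quantifies size-selective retention directly from
such tables.

The central quantity is the per-bin **deposition selection ratio**

$$\mathrm{DSR}_i = \frac{f_i(\text{lungs})}{f_i(\text{exposure})},$$

over the fixed 8 x 4 bin grid (lengths <1, 1–2, 2–3, 3–4, 4–6, 6–8, 8–10,
>10 um; widths <0.125, 0.125–0.250, 0.250–0.375, >0.375 um). DSR > 1 means
the size class is enriched in lungs (preferential deposition/retention),
DSR < 1 that it is deselected. The size dependence is modeled by ordinary
least squares on bin-level points,

$$\log_{10}(\mathrm{DSR} + 0.001) = A + B\,\log_{10} L + C\,\log_{10} W,$$

where the 0.001 offset keeps fully deselected bins (DSR = 0) finite at -3.
The log scale is justified empirically: `ks_lognormality()` applied to the
pooled defined DSR values of the packaged tables does not reject
log-normality.

Three population-level morphometric statistics support habit
classification: the *criteria fraction* (share of particles with
$2.99\log_{10}L - 5.82\log_{10}W - 3.80 \ge 0$, a dimensional proxy for
asbestiform morphology), the *Pearson index* (correlation of log width with
log length; mechanical fragmentation couples the two, natural fibrous
growth does not), and a decision rule mapping (criteria fraction, Pearson
index) to asbestiform / undetermined / non-asbestiform. The Timbrell
aerodynamic diameter
$AD = 66\,W\,(AR/(2+4AR))^{2.2}\sqrt{\rho/\rho_0}$ links the dimensional
findings to respirability (cutpoint 4 um). We read the exponent in this
formula as applying to the aspect-ratio term, which yields the expected
long-fiber asymptote $AD \to 66(1/4)^{2.2} W \sqrt{\rho} \approx
3.13\,W\sqrt{\rho}$; this reading is exposed via the `shape_exponent`
argument.

Finally, a cross-mineral potency model
$\log_{10} R_M = a + b\,\log_{10}\overline{\mathrm{DSR}} +
c\,\log_{10}\mathrm{Bioper}$ relates average DSR and biopersistence to the
mesothelioma potency factor across seven mineral fiber types, and the
observed DSR values are compared against pulmonary deposition fractions
from the US EPA MPPD model (consumed as packaged per-bin values; the
deposition physics is not re-implemented here).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_particles` | 2000 | count | reconstruction size of the reference datasets |
| `within_bin_gsd` | 1.5 | — | geometric SD of within-bin log-normals (see below) |
| `length_cap` | 40 | um | finite sampling bound for the open >10 um bin; conservative TEM-visible maximum |
| `width_cap` | 3 | um | bound for the open >0.375 um bin; the global width filter ceiling |
| `min_length` | 2 | um | population filter for criteria fraction / Pearson index; particle-level deselection analyses use 5 |
| `density` | 3.3 / 3.43 | g/cm^3 | crocidolite / amosite; standard mineralogical values, configurable |
| `shape_exponent` | 2.2 | — | aspect-ratio exponent in the aerodynamic-diameter model |
| respirability cutpoint | 4 | um AD | conventional thoracic/respirable boundary |

## The synthetic-data generator

`reconstruct_fibers()` emulates fiber-level TEM datasets whose bin
frequencies match a given percent matrix. Within each bin, length and width
are drawn independently from log-normal distributions — the distributional
form reported for asbestos fiber dimensions — truncated to the bin by
inverse-CDF sampling, with the median fixed at the geometric midpoint of
the (capped) bin interval. The published reconstructions give no within-bin
parameters, so the geometric midpoint is the natural scale-free choice and
the spread is a single explicit knob (`within_bin_gsd = 1.5`, a moderate
within-bin heterogeneity typical of sieved aerosol size classes);
sensitivity to it is exposed, not hidden. Pairs violating the aspect-ratio
>= 3 filter are jointly redrawn (up to `max_resample`), then width is
redrawn conditional on length, so every emitted particle satisfies the
global filter and lies in its source bin. Bin counts are multinomial by
default (honest sampling error); `mode = "quota"` gives largest-remainder
exact counts for regression-style uses. Per-dataset seeds are derived
deterministically from one master seed, so partial reruns reproduce
identical datasets.

What the generator does **not** emulate: within-bin correlation between
length and width (beyond the filter constraint), measurement error,
inter-subject variability, and fiber fragmentation/disaggregation over
residence time. Tests passing on reconstructed data therefore validate the
pipeline's arithmetic and its bin-level contracts, not the biological
fidelity of within-bin microstructure. One visible consequence: the
reconstructed amosite lung population has median width ~0.20 um against a
published 0.21 um, and the crocidolite median length sits in the 2–3 um bin
(published 2.7 um) — bin-level agreement is exact by construction,
within-bin placement is an assumption.

## Numerical and design choices

* **Ratio normalization.** `compute_dsr()` defaults to the ratio of stored
  percent columns. Renormalizing each column to sum exactly to 1 is
  available (`normalize = "column"`) and changes every ratio by the same
  constant (the ratio of column sums, under 1% here), but the published
  per-bin values are reproduced best by the raw ratio, so that is the
  default.
* **Printed-rounding tolerance.** The packaged frequency columns are
  printed at 2 d.p.; ratios recomputed from them can differ from the
  published ratios by more than +/-0.01 where the denominator is small
  (e.g. 0.41/0.05). The test suite therefore bounds each cell by exact
  interval arithmetic on the printed rounding
  (`0.005 + 0.005 (1 + DSR)/exposure%`) instead of pretending to exact
  agreement.
* **N/A semantics.** Exposure frequency 0 makes the ratio undefined (N/A),
  including when the lung frequency is also 0; lung 0 with positive
  exposure is genuine full deselection, DSR = 0. N/A propagates through the
  log transform, projection, correlations (pairwise-complete) and
  regressions (bins dropped).
* **Bin representatives.** The regression needs a representative (L, W) per
  bin; the sources never state one. Default: geometric midpoints of the
  capped intervals (`rep_scheme = "geomid"`); alternative: the packaged
  MPPD geometric-mean widths (`"mppd_gm"`). The choice shifts coefficients
  somewhat — the combined fit gives R = 0.61 under the default — while the
  sign structure (B > 0, C < 0) and the per-mineral |C|/B ratios (~1.7–1.8)
  are stable.
* **MPPD comparison transform.** The headline correlation uses
  log10(DSR + 0.001) (and log10(% + 0.001) for the frequency variant),
  consistent with the log treatment of DSR everywhere else; the
  untransformed variant is always computed alongside, and the
  anti-correlation holds under both.
* **Log-normality check.** The KS test runs on log10 of the positive DSR
  values against a normal with moment-fitted mean and SD. With fitted
  parameters the test is conservative (the Lilliefors situation): exactly
  log-normal data essentially never yield small p-values, so it is a sanity
  check, not a calibrated test.
* **Boundary conventions.** Bins are half-open and lower-inclusive
  ([lo, hi)), so 0.125 um falls in 0.125–0.250 and 2.0 um in 2–3; the <1
  length bin starts at the 0.5 um measurement floor and the <0.125 width
  bin at 0.05 um. The criteria discriminant includes its boundary
  (score 0 is criteria), the habit rule is evaluated asbestiform-first, and
  the undetermined windows are closed intervals. The (<1, >0.375) bin
  admits no particle with aspect ratio >= 3; the samplers treat nonzero
  mass there as a configuration error.
* **Degenerate inputs.** Empty filtered sets, all-zero matrices, collinear
  regression designs, zero-variance Pearson inputs and constant KS samples
  all raise informative errors rather than returning NaN.

## Problem sizes

The reference reconstructions use 2,000 particles per dataset (matching the
published reconstructions); the convergence test uses one 50,000-particle
draw (maximum bin-fraction deviation < 0.01); the stochastic median-width
check averages 20 independent 2,000-particle reconstructions; the
calibration check of the log-normality test uses 40 replicates of 500
draws. The full suite runs in well under a minute.

## Limitations

The exposure matrices are themselves approximate (airborne sampling and a
heterogeneous dimensional database), which caps the attainable fit of the
log-log model (R ~ 0.6 combined). Per-bin DSR values carry no uncertainty
intervals. The average-DSR values for minerals other than amosite and
crocidolite are literature fixtures, not recomputed here (the underlying
particle database is external). Mineral identity is taken as given — no
chemistry-based identification — and the MPPD comparison inherits every
assumption baked into the packaged deposition rates (Yeh/Schum symmetric
airway model, nasal breathing at rest).
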