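---
title: "Scoring paper-based sickle cell screening stains: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring paper-based sickle cell screening stains: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stainscore)
```

## The assay and its readout

The paper-based sickle cell screening test exploits differential transport
in a paper substrate: in a hemoglobin solubility buffer, deoxygenated HbS
polymerizes and is retained where the droplet is deposited, while soluble
hemoglobins (HbA, HbF, HbC) wick outward. A dried stain therefore carries a
dark red center spot (HbS) surrounded by a lighter ring (soluble Hb).
`stainscore` quantifies scanned stains through the red color intensity
*I* = 255 − Blue and two densitometric indices:

* the **S-index**, the quotient of the mean intensity of the center spot
  and the mean intensity of the peripheral ring — a proxy for the HbS
  *fraction* that is by construction insensitive to overall stain
  brightness (hemoglobin concentration, metering);
* the **C-index**, the product of the *total* center-spot intensity and the
  mean intensity at 5 mm from the center — deliberately sensitive to the
  absolute amount of hemoglobin, which is the signal that distinguishes
  typically-anemic HbSC samples from HbAS carriers with similar %HbS.

This vignette documents the synthetic stain model, the analysis and
classification procedures, the statistical machinery, the numerical
decisions, and what the included tests do and do not demonstrate.

## The synthetic stain generator

### Radial two-compartment model

A stain is rendered as a radially symmetric intensity field

$$ I(r) = b + A_c\,D(r) + A_r\,R(r), $$

where $b$ is the paper background, $D$ a smoothed disk of radius $r_c$ and
$R$ a smoothed annulus from $r_c$ to $r_o$. Edges are smoothed on the
radial coordinate with a Gaussian of scale $\sigma$ (an erf profile — the
shape a Gaussian blur imprints on a sharp-edged, radially symmetric stain
when $r_c \gg \sigma$), then independent Gaussian pixel noise is added and
values are clipped to $[0, 255]$. The closed-form expectation is exposed as
`stain_model()`, so tests can integrate the model over the pixel grid
independently of the raster rendering.

With $p$ the HbS fraction, mass partitions through two leak terms:
a fraction $\varepsilon$ (`leak_center`, default 0.15) of the soluble
hemoglobin is retained in the center (incomplete wicking), and a fraction
$\delta$ (`leak_ring`, default 0.05) of the HbS escapes into the ring
(incomplete polymer trapping):

$$ \text{center share} = (1-\delta)\,p + \varepsilon\,(1-p), \qquad
   \text{ring share} = (1-\varepsilon)(1-p) + \delta\,p . $$

The two shares sum to one, so the integral of $I - b$ over the stain is
exactly proportional to the deposited hemoglobin mass
$m = \mathrm{Hb}\times V / (1 + d)$ (blood at concentration Hb g/dL,
droplet volume $V$ µL, blood:buffer ratio $1\!:\!d$), independent of $p$ —
a conservation property the test suite asserts to $10^{-3}$ relative.
Amplitudes $A_c, A_r$ are normalized by the numerically integrated area of
each smoothed shape ($\int 2\pi r\,D(r)\,dr$ by adaptive quadrature), not
by the nominal $\pi r^2$ areas, so conservation holds exactly under the
edge smoothing. The in-memory image keeps continuous intensities;
quantization to 8 bits happens only on PNG export (plateau rounding would
otherwise systematically violate the conservation check).

### Defaults and their rationale

* `dilution = 10`, `droplet_volume = 20` µL: the assay's reference
  metering. Radii scale with $\sqrt{V (1+d) / (20 \cdot 11)}$ relative to
  that reference — a two-dimensional spreading assumption that makes
  metering-jitter experiments (ratios 1:8–1:12, volumes 16–24 µL)
  meaningful.
* `r_center_mm = 2.5`, `r_outer_mm = 7.5`, `dpi = 300`, `background = 10`,
  `noise_sd = 3`, $\sigma$ = 0.2 mm: plausible values for a flatbed scan of
  a centimeter-scale stain; absolute stain dimensions and scanner settings
  are not fixed by the assay itself, so these are package choices, stated
  once and configurable.
* `gain = 180` intensity·mm² per unit mass: the rendering calibration,
  chosen so the dimmest in-band stain (an HbAA sample at 12 g/dL) stays
  well above the detection threshold while the brightest in-band HbSS
  stain stays clear of 255. Parameter combinations that would drive more
  than 1% of stain pixels into saturation are refused with an error,
  because saturation destroys the linearity both indices rely on.
* Cohort bands: %HbS is drawn uniformly per genotype — AA exactly 0,
  AS 38–42, SC 41–50, SS 74–93, S$\beta^+$-thalassemia 60–93 — and total
  Hb from genotype-appropriate ranges (AA/AS 12–16.5 g/dL; SS 6.2–11;
  SC 8–11; S$\beta^+$ 7–12), reflecting that HbSS and HbSC patients are
  typically anemic. Default cohort composition is 18 AA / 17 AS / 20 SS.

### What the generator does and does not emulate

It emulates the features the analyzer consumes: center/ring intensity
partitioning that scales correctly with %HbS and hemoglobin mass, metering
jitter, edge blur, pixel noise, sheet layouts with placement jitter. It
does **not** simulate wicking physics (no Lucas–Washburn transport), buffer
chemistry, stain aging or drying artifacts, scanner illumination gradients
or color profiles, or HbF interference. Tests passing on synthetic stains
therefore validate the *software chain* — detection, geometry, index
arithmetic, classification, statistics — not the biochemical performance
of the assay on real blood.

## Stain detection and geometry

Detection thresholds the sheet at median + 5·MAD (median as background
estimator, MAD for robustness to the stains themselves), labels connected
components (`EBImage::bwlabel`), and keeps components whose equivalent
diameter lies in 4–25 mm. The lower bound is deliberately below the
nominal stain diameter: under noise, the thresholded component of a
high-%HbS stain is its bright ~5 mm center spot only, while low-%HbS
stains threshold at their full ~15 mm extent, so the acceptance range must
span both. Components touching the image border are discarded; components
wider than 1.5× the maximum diameter are reported as possible merges on a
warnings channel. Centers are intensity-weighted centroids (weights are
intensities in excess of the median), which recover generator truth to
well under a pixel on noise-free sheets and within ~1 px at `noise_sd = 3`.

Radii come from the radial profile (0.2 mm bins, arithmetic mean per
annular shell, pixel-center distances converted at 1 mm = dpi/25.4 px):

* $r_c$: the first radius at which the profile falls below
  background + 0.5 × (central-plateau excess), the plateau being the mean
  of bins within 1 mm of the center; clamped to
  $[0.5\,\text{mm}, r_o - 0.5\,\text{mm}]$.
* $r_o$: the last radius at which the profile still exceeds
  background + max(1 intensity unit, 0.1 × ring-level excess), where the
  ring level is the profile maximum beyond $r_c + 1$ mm (the buffer skips
  the smoothed disk-edge falloff). Referencing the *ring* rather than the
  profile peak is essential: for high-%HbS stains the center is an order
  of magnitude brighter than the ring, and a peak-referenced 10% threshold
  would amputate the ring entirely and with it the S-index's dynamic
  range. The 1-unit absolute floor keeps the rule stable under noise and
  defines a sensible outer edge for stains with essentially no ring.

For very flat stains (HbAA, where center and ring differ little) the
half-plateau crossing may not exist before the outer edge; $r_c$ then sits
at the clamp $r_o - 0.5$ mm. This is benign: such stains produce S-indices
near 1 regardless of the split, far below the carrier band.

## Index conventions

Index formulas use raw intensities — no background subtraction — because
the indices are defined on the recorded color values themselves; a
subtraction flag exists but defaults to off. Regions are half-open
($r \le r_c$ center, $r_c < r \le r_o$ ring) so every pixel belongs to
exactly one region. The "circle at 5 mm" of the C-index is a thin annulus
of half-width 0.25 mm, since a zero-width circle contains no pixel
centers; the same center-spot radius serves both indices. Degenerate
inputs are distinguished: a zero ring mean raises an undefined-index
error, geometry outside the image a domain error.

## Classification and calibration

S-index cutoffs are fitted, not hard-coded: for each binary split (AA vs
rest, SS vs rest) the cutoff maximizes Youden's J over midpoints between
adjacent sorted scores, with ties broken toward higher specificity. The
test suite holds this equal to an exhaustive-search oracle. Boundary
values classify to the less severe genotype — a deterministic, screening-
conservative tie rule. S$\beta^+$-thalassemia samples fall in the SS band
(> 60 %HbS) and are reported as SS; separating them is outside the
S-index's power. Likewise the S-index is *not* used to separate HbSC from
HbAS (their %HbS bands overlap almost completely); the score is exposed,
nothing more.

The C-index decision direction encodes the biology: SC calls are made
*below* the cutoff because HbSC samples carry less total hemoglobin. The
`fit_c_cutoff()` helper picks the smallest cutoff with full SC sensitivity
— the screening regime this index is meant for (never miss SC, tolerate
false positives among AS, confirm positives with a reference method). Note
that in the synthetic model, whether AS samples are misflagged depends
entirely on whether the AS and SC hemoglobin ranges overlap; with disjoint
ranges the separation is perfect, which real cohorts — with their
biological spread — do not exhibit.

Calibration of S-index to %HbS uses `stats::lm` on dilution-series pairs:
mixing HbSS blood with Hb-matched HbAA blood makes %HbS exactly linear in
the volume fraction (`mix_dilution_series()`), and
`simulate_calibration_series()` emulates the classical design of 4 source
samples × 11 fractions = 44 points with Gaussian error on the measured
%HbS (defaults: slope 12.1 %HbS per S-index unit, error SD 6.4 %HbS).
Predictions are clamped to [0, 100] %HbS.

## Evaluation statistics

Screening metrics use the standard forms — sensitivity TP/(TP+FN),
specificity TN/(FP+TN), PPV TP/(TP+FP), NPV TN/(TN+FN), accuracy
(TP+TN)/total — with zero denominators flagged as undefined rather than
silently zeroed. Each metric carries a Wilson score interval with
z = 1.96 (the conventional two-decimal critical value, configurable). Two
n conventions are provided: `standard` uses each metric's own denominator;
`cohort_total` uses the total comparison size for every metric, a
convention encountered in published screening evaluations and provided for
comparability with them. The default is `standard`; neither is silently
substituted for the other.

ROC curves sweep every distinct score as a threshold (positive = above)
and integrate by trapezoid; this is algebraically the Mann–Whitney
statistic with ties weighted ½, and the suite property-tests that equality
to 10⁻¹². Fleiss' kappa implements the standard formula for equal-size
rater panels and deliberately refuses unbalanced tables rather than
applying a generalized weighting.

## Problem sizes and numerical choices in the test suite

The acceptance-level checks simulate a 55-stain cohort (seven 2×4 sheets,
22 mm pitch, 300 dpi), fit thresholds on the recovered S-indices and
evaluate by resubstitution; calibration recovery averages 100 independent
44-point series; the kappa null check uses a 2000-subject × 5-rater
uniform-random table. These sizes give comfortably stable statistics at
interactive runtimes. Key tolerances: mass conservation 10⁻³ relative
(quadrature-normalized amplitudes), S-index scale invariance 10⁻⁹, AUC
oracle equality 10⁻¹², geometry recovery within one 0.2 mm profile bin
plus smoothing, detection centers within 2 px of truth on noise-free
sheets.

## Known limitations

* Cohort-level published statistics of the real assay (confusion-matrix
  cells, per-rater mean ± SD tables, a specific kappa or AUC measured on a
  clinical cohort) depend on that cohort's per-sample measurements and
  cannot be recomputed from summary numbers; `read_sample_scores()` loads
  such data when a user has it and declines gracefully otherwise.
* The generator's separability is idealized: synthetic AA/AS/SS cohorts
  are perfectly separable by design at the default parameters, which the
  suite reports as a property of the model (AUC = 1.00), not as a claim
  about clinical AUCs.
* JPEG input is not supported (no reader among the package's
  dependencies); PNG and TIFF are.
* No scanner color-profile or illumination-gradient correction; only the
  Blue channel carries signal.
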