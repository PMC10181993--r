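---
title: "Methods: grapevine embolism vulnerability, from conductivity sweeps to regional risk"
author: "vitisvc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grapevine embolism vulnerability, from conductivity sweeps to regional risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitisvc)
```

## The scientific problem

Under drought, the water column inside xylem conduits is under increasing
tension (xylem pressure Ψ, MPa, negative). Past a genotype-specific
threshold, air is pulled into conduits — embolism — and hydraulic
conductivity is progressively lost. For grapevine this matters twice over:
varieties differ substantially in their embolism thresholds, and the varietal
composition of a wine region therefore sets how exposed that region's
production is to extreme drought. `vitisvc` implements the full chain of
analysis that connects raw measurements to that regional exposure:

1. **PLC curves** from flow-centrifuge conductivity sweeps,
2. **sigmoid vulnerability fits** per plant, with threshold pressures,
3. **optical vulnerability** curves from leaf dehydration image stacks,
4. **xylem anatomy** and theoretical conductivity from vessel tables,
5. **Ward clustering** of varieties into four vulnerability classes,
6. a **regional risk index** weighting bearing areas by those classes.

Because the raw field measurements behind this kind of study are typically
not deposited, the package ships synthetic-data generators that emulate
every input with known ground truth. The generators are first-class, tested
code: every analysis stage is validated by recovering what the generators
injected.

## The vulnerability model

A vulnerability curve is the percentage loss of hydraulic conductivity
(PLC, %) as a function of xylem pressure. From a sweep of conductivities
$k_i$ measured at pressures $\Psi_i$,

$$\mathrm{PLC}_i = 100\,(1 - k_i / k_{\max}),$$

where $k_{\max}$ is the reading at the *first* induced pressure
(−0.8 MPa in the emulated protocol) — never the maximum over the sweep. Under
noise this can make later readings exceed $k_{\max}$; the resulting slightly
negative PLC values are retained for fitting (least squares stays unbiased)
and flagged in QC output.

The curve is fitted with the two-parameter sigmoid standard in plant
hydraulics:

$$\mathrm{PLC}(\Psi) = \frac{100}{1 + \exp\!\big(\tfrac{S}{25}(\Psi - \Psi_{50})\big)},$$

with $\Psi_{50}$ the pressure at 50% loss and $S$ (% MPa$^{-1}$) the slope at
the inflexion point. The onset and near-lethal thresholds follow
analytically:

$$\Psi_{12} = \Psi_{50} + 50/S, \qquad \Psi_{88} = \Psi_{50} - 50/S,$$

at which the sigmoid evaluates to $100/(1+e^{2}) \approx 11.92\%$ and
$100/(1+e^{-2}) \approx 88.08\%$ — the identities the acceptance checks
verify on fitted curves.

```{r}
psi <- default_pressures()
fit <- fit_pammenter(data.frame(psi_mpa = psi,
                                plc = pammenter_plc(psi, -2.5, 50)))
fit
```

### Numerical choices

The fit minimizes $\sum(\mathrm{PLC}_{obs} - \mathrm{PLC}_{model})^2$ by
Levenberg–Marquardt (`minpack.lm::nlsLM`) followed by a bounded L-BFGS-B
polish of the SSE surface, which also serves as rescue when LM fails.
Initialization: $\Psi_{50}$ at the linearly interpolated pressure where the
observed curve crosses 50% (median pressure when it never crosses); $S$ at
50 % MPa$^{-1}$. Bounds: $\Psi_{50} \in [-10, 0]$, $S \in (0, 500]$;
SSE tolerance $10^{-8}$, at most 1000 iterations. Curves with fewer than 4
points or spanning fewer than 30 PLC units are refused rather than silently
fitted — the sigmoid is not identifiable on flat data. Tests verify that the
converged SSE never exceeds a 200×200 grid search over the full parameter
box.

Aggregation is a plain mean ± standard error per variety, season and organ;
seasonal contrasts use a pooled-variance two-sided Student's t-test.
Hydraulic vulnerability segmentation is the difference leaf − stem in
$\Psi_{12}$ and $\Psi_{50}$; positive values mean the leaf embolizes first
and acts as a hydraulic fuse.

## Optical vulnerability

Leaf dehydration stacks (8-bit grayscale frames, 5-minute spacing) are
analyzed by successive-frame absolute subtraction; difference images are
thresholded (default 5 gray levels) and connected components below
20 px (default) are discarded as speckle — embolism events are large and
structured. Components use 8-connectivity by default; both the threshold,
the minimum area and the connectivity are arguments, since the upstream
imaging practice fixes none of them. Embolized pixels are accumulated over
time and normalized to the dehydration total (PEP, %), mapped onto stem
water potential by linear interpolation of the psychrometer timeline, and
the PEP–Ψ curve is fitted with the same sigmoid.

Two cleaning decisions matter. The raw psychrometer series is reduced to its
running minimum before interpolation: embolism cannot reverse during a
drydown, and sensor blips would otherwise locally invert the PEP–Ψ mapping.
And no image registration is applied (the emulated protocol physically
clamps leaves); instead a QC warning is emitted when FFT cross-correlation
indicates a genuine inter-frame translation above 2 px — "genuine" meaning
the normalized correlation peak exceeds 0.5, so unstructured frames or
event-only differences cannot spuriously trigger it.

## Xylem anatomy

From vessel lumen areas (µm²) of a cross-section: equivalent circle
diameters $D_i = 2\sqrt{A_i/\pi}$, the hydraulically weighted diameter
$D_H = \sum D^5 / \sum D^4$ (the conductivity-weighted convention; always at
least the arithmetic mean), vessel density $V_D$ per mm², and the
theoretical specific conductivity by Hagen–Poiseuille:

$$k_{th} = \sum \frac{\pi D^4 \rho}{128\,\eta} \cdot \frac{1}{A_{xyl}},$$

with $D$ in metres, $\rho = 998.2$ kg m$^{-3}$ and
$\eta = 1.002\times10^{-9}$ MPa·s (water at 20 °C; the MPa-based viscosity is
taken at face value and equals $1.002\times10^{-3}$ Pa·s). A single 100-µm
vessel in $10^{-6}$ m² of xylem gives $k_{th} \approx 2.445$
kg s$^{-1}$ m$^{-1}$ MPa$^{-1}$, the hand value frozen in the tests.

## Clustering and the regional risk index

Variety-mean $\Psi_{12}, \Psi_{50}, \Psi_{88}$ are z-scored per column with
the sample (n−1) standard deviation, and varieties are grouped by
agglomerative clustering on the Euclidean distance matrix with the Ward
criterion (Ward.D2, squared-update variant — the common modern default; the
D/D2 ambiguity of older heatmap routes is resolved here as a package
decision). The tree is cut at exactly four clusters, which are ranked by
their centroid raw $\Psi_{50}$ (ties broken by $\Psi_{88}$, then
$\Psi_{12}$): most negative = *low* vulnerability, then *low-to-medium*,
*medium-to-high*, *high*. Slope $S$ is not clustered on — only the three
threshold pressures.

Each class carries the median of its quarter of a 0–1 vulnerability scale:
0.125, 0.375, 0.625, 0.875. For a region whose panel varieties cover
bearing areas $a_c$ (percent of the regional winegrape area),

$$RI = 0.125\,a_{low} + 0.375\,a_{lm} + 0.625\,a_{mh} + 0.875\,a_{high}.$$

The bearing percents are relative to the *total* regional area including
non-panel varieties, so uncovered area dilutes RI — which is why observed
indices can fall below the 12.5 floor that full coverage would impose. No
renormalization by coverage is applied. Regions with panel coverage below
40% (boundary inclusive) are flagged `included = FALSE` but kept in the
table.

```{r}
compute_ri(c(25, 25, 25, 25))
```

## What the generators emulate — and what they do not

* `gen_sweep` / `gen_cohort`: sigmoid-true conductivities with
  *multiplicative* Gaussian noise (`noise_cv`, default 0.05), since
  conductivity errors scale with magnitude; plant-level (Ψ50, S) drawn
  around variety means. The default pressure grid runs −0.8 to −5.3 MPa in
  −0.5 steps. The default panel spans variety Ψ50 of −1.8 to −3.4 MPa —
  the observed summer range in cultivated grapevine — with slope
  50 % MPa$^{-1}$, plant sd 0.15 MPa and 8 % MPa$^{-1}$, and
  $k_{\max,true} = 2$ kg m$^{-1}$ s$^{-1}$ MPa$^{-1}$. Noise magnitudes are
  free parameters of the generator, chosen once as field-realistic.
  Note one faithful subtlety: the −0.8 MPa reference reading already carries
  a little true embolism for vulnerable genotypes, so measured PLC is
  renormalized relative to it, exactly as in the real protocol. Noiseless
  round-trips are therefore exact only when the reference is essentially
  unembolized; at study conditions the induced bias is small (median
  |Ψ50 error| ≈ 0.08 MPa over 200 noisy plants).
* `gen_dehydration_stack`: events are contiguous intensity-step blobs that
  persist once they appear (so subtraction sees each exactly once), with a
  step of at least 5× the background noise sd by default. Scanner optics,
  leaf shrinkage, vein geometry and psychrometer drift are *not* emulated —
  passing recovery tests shows the detection arithmetic is right, not that
  the thresholds are right for any particular scanner.
* `gen_psi_timeline`: linear or exponential monotone drydowns; spans of
  80–130 h at 30-minute spacing emulate observed complete dehydrations.
* `gen_bearing_table`: Dirichlet shares of a partially covered region
  (uncovered fraction drawn per region), matching the long
  region/country/variety/percent schema of regional bearing-area databases.

Every generator is deterministic given its seed and logs its ground truth.

## Pipeline, problem sizes, and limitations

`run_pipeline()` chains simulate → fit → aggregate → cluster → risk, writes
every intermediate as CSV plus a JSON manifest of MD5 checksums, and derives
all stage seeds from one master seed, so identical configs give identical
output files. The documented test and demo sizes — cohorts of 180–200
plants, stacks of 24–61 frames at 56–128 px, panels of 6–30 varieties,
3–12 regions — were chosen so the whole suite runs in seconds on a laptop
while still exercising every code path at realistic parameter values.

Known limitations: no alternative vulnerability models (Weibull, incomplete
gamma); no open-vessel artefact correction; no vein-order classification or
registration in the optical path; clustering offers no bootstrap stability
or automatic cluster-count selection (k = 4 is fixed by design); the risk
index ignores climate — it measures varietal composition, not realized
drought stress.
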