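---
title: "Models and methods behind fapscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fapscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fapscreen)
```

# The assay being modeled

`fapscreen` models a plate-based ratiometric endocytosis assay built on an
endogenously tagged receptor. Surface receptors carry a fluorogen-activating
protein (FAP) that binds a membrane-impermeant tandem dye (a pH-sensitive
Cy3 donor coupled to a malachite-green acceptor). Far-red emission excited
directly at 640 nm is pH-independent and reports total labeled receptor;
far-red emission excited at 561 nm passes through the pH-sensitive FRET
donor and rises several-fold in acidic endosomes. The per-well ratio of the
two (the *561/640 ratio*) therefore measures how much of the surface-labeled
receptor pool has been internalized. The package provides, as separate and
individually testable layers:

1. a **sensor model** — the pH → ratio calibration sigmoid, its fit and
   inversion, and the two-pool mixing model linking a well ratio to an
   endosomal receptor fraction;
2. an **internalization kinetics model** with an In/Sur rate-constant
   estimator;
3. a **synthetic plate generator** producing seeded dual-channel images
   with the design of a phosphatase siRNA screen (80 targets + 8 negative
   + 4 + 4 positive-control wells per plate, 3 plates per replicate);
4. **quantification** of images to background-corrected well ratios;
5. **screen statistics**: Z'-factor, per-well log2 fold change against the
   plate negative-control median, paired SSMD, dual-flashlight tables and
   hit calling;
6. a thin **pipeline** layer chaining these through files.

# Sensor model

The calibration curve is a four-parameter protonation (Hill) sigmoid,

$$R(\mathrm{pH}) = R_\mathrm{base} +
  \frac{R_\mathrm{acid} - R_\mathrm{base}}
       {1 + 10^{\,h(\mathrm{pH} - \mathrm{p}K_a)}},$$

the standard physical model for a single protonatable fluorophore; the Hill
slope $h$ is exposed because deviations from 1 are common in cellular
calibrations. Published calibrations of this reporter class are graphical,
so the defaults ($\mathrm{p}K_a = 6.6$, $h = 1$, $R_\mathrm{acid} = 1.95$,
$R_\mathrm{base} = 0.40$) were fixed once by requiring the observable
constraint the assay is built on — a ~3-fold ratio increase between the
medium (pH 7.4) and endosomal lumen (pH 5.5):

```{r fold}
sp <- sensorParams()
ratioAtPH(sp, 5.5) / ratioAtPH(sp, 7.4)
```

Because the per-receptor 640-excited emission is the same in both
compartments, a well containing a fraction $f$ of its labeled receptors in
endosomes (at pH 5.5) and $1 - f$ at the surface (held at the pH 8 stop
buffer during imaging) has ratio affine in $f$:

$$R_\mathrm{obs} = R_\mathrm{surf} + f\,(R_\mathrm{endo} - R_\mathrm{surf}).$$

`endosomalFraction()` inverts this and clips to $[0, 1]$ with a flag rather
than erroring, since measurement noise can push observed ratios slightly
past the calibration anchors. Calibration fitting uses Levenberg–Marquardt
least squares (`minpack.lm`), with data-derived starting values; an
independent coarse grid search over $(\mathrm{p}K_a, h)$ with profiled
plateaus serves as the oracle in the test suite.

# Internalization kinetics

Receptors move between two pools, surface $S$ and endosome $E$, with
first-order internalization at rate $k$ and recycling at $k_\mathrm{rec}$:

$$\dot S = -kS + k_\mathrm{rec}E, \qquad \dot E = kS - k_\mathrm{rec}E,
  \qquad S(0) = 1,\; E(0) = 0,$$

solved in closed form, $f(t) = \frac{k}{k + k_\mathrm{rec}}
\bigl(1 - e^{-(k + k_\mathrm{rec})t}\bigr)$; the tests verify agreement with
an independent stiff ODE integration to $10^{-8}$. The label is applied
instantaneously to surface receptors and is membrane-impermeant, hence
$E(0) = 0$; degradation and lysosomal dye loss are neglected over the
15-minute assay window.

The effective rate blends three occupancy-weighted components,

$$k(\mathrm{EGF}) = occ \cdot k_\mathrm{CME} \cdot [\text{kinase active}]
  + (1 - occ)\,k_\mathrm{basal} + occ_\mathrm{CIE}\,k_\mathrm{CIE},$$

with $occ = \mathrm{EGF}/(K_d^\mathrm{CME} + \mathrm{EGF})$ and a much
higher half-saturation for the clathrin-independent (CIE) term. Defaults
($k_\mathrm{CME} = 0.50$, $k_\mathrm{basal} = 0.01$,
$k_\mathrm{CIE} = 0.10$, $k_\mathrm{rec} = 0.05$ per minute;
$K_d^\mathrm{CME} = 2$, $K_d^\mathrm{CIE} = 20$ ng/ml) were chosen once to
reproduce three qualitative behaviours of the assay: near-complete block by
a receptor-kinase inhibitor at physiological EGF (≤ 4 ng/ml), a residual
kinase-insensitive component at saturating EGF, and an endosomal-fraction
plateau within 15 minutes. $k_\mathrm{CME} = 0.50$/min is the midpoint of
In/Sur estimates for occupied receptors internalizing through clathrin
pits; the recycling rate is a modeling choice, as cell-line-specific values
are not published for this system.

`estimateKe()` implements the classical In/Sur reading: a least-squares
slope **through the origin** of internalized/surface ligand versus time
over the first few (default 5) timepoints — through the origin because
internalized counts start at zero by construction, early points only
because recycling and depletion bend the curve later. `simulateUptake()`
generates matching radioligand data under a quasi-steady-state surface
pool with multiplicative Gaussian measurement noise.

# Synthetic plate generator

The generator is the package's statement of the study conditions, not a
tuning knob. Layouts follow the screen design exactly: per plate, columns
1–10 hold 80 targets (row-major), column 11 the four clathrin-heavy-chain
and four dynamin-2 positive controls, column 12 the eight negative
controls; three plates cover the 240-target library and replicates reuse
identical positions. (Control positions are not published; this fixed
convention is documented and deterministic.) Robustness plates split
48 unstimulated / 48 stimulated wells; calibration plates assign one pH
per row from 5 to 8 with 7 measurement wells per row, the remaining wells
holding parental (untagged) cells. Screen and robustness plates use all 96
wells, so their background comes from a companion strip of parental wells
rendered per replicate (8 by default) — mirroring the practice of imaging
parental cells for background correction.

Rendered wells draw cells as axis-aligned ellipses on a jittered grid
(emulating the near-confluent monolayer the assay uses; cells touch but do
not stack). The surface pool covers the cell footprint — in a 2-D
projection the plasma membrane spans the whole cell, top and bottom — with
extra weight in an edge rim; the endosomal pool sits in interior puncta
scaled to cell size. Each cell's photon totals are exactly $(1-f)$ and $f$
times its label amount, so the aggregate ratio obeys the mixing model
regardless of geometry. Expected intensities are `photonScale` photons per
receptor-unit in the 640 channel and the same times $R(\mathrm{pH})$ in the
561 channel; Poisson shot noise, Gaussian read noise and per-channel
backgrounds follow, with 16-bit clamping.

Knockdown acts as an efficacy scalar on the CME rate (`keOccCme`), and for
dynamin-2 also on the CIE rate, since dynamin serves both routes while
clathrin heavy chain is CME-specific. Positive controls use efficacy 0.9
(strong depletion, no published number).

Two generator choices deserve emphasis:

* **Well-level factor on the 561 channel.** The dominant well-to-well
  noise is a multiplicative factor $\sim \mathcal{N}(1, \mathrm{wellCV})$
  applied to the 561-excited channel of the whole well. It models
  variation in the FRET-channel response (labeling, residual pH
  differences, excitation balance between the two lasers). Applied to both
  channels it would cancel in the ratio — leaving only negligible shot
  noise and an implausibly perfect assay — so the 561 channel carries it;
  the sample CV of quantified negative-control ratios then converges to
  `wellCV`, which is the statistical structure the screen statistics
  assume. The default `wellCV = 0.03` is validated (not assumed) by the
  robustness simulation reproducing the published Z' range.
* **Photon budget.** `photonScale = 2.5e6` photons per receptor-unit was
  fixed jointly with the cell geometry so that corrected 640-channel well
  means sit far above the low-signal threshold while the brightest
  expected pixels (acidic calibration rims, bright endosomal puncta) stay
  below 16-bit saturation; per-cell label amounts are Gamma-distributed
  (CV 0.15) and truncated at 1.4 for the same reason.

What the generator does **not** emulate: real cell morphology and
segmentation-relevant texture, optical PSF and focus drift, illumination
gradients and plate-edge effects, transfection biology (knockdown is a
scalar), and 3-D acquisition. Passing tests therefore demonstrate the
correctness and statistical calibration of the analysis pipeline under the
stated noise model — not robustness of the pipeline to artifacts the model
excludes.

# Quantification

Well statistics use all pixels of the stitched image (the vendor-software
behaviour the assay relies on), not segmented cells: per channel, the mean
over every pixel of the well's fields, then background subtraction, then
the ratio of corrected means (*ratio of means*, not mean of pixel ratios).
Background is a per-channel scalar estimated as the mean raw intensity of
parental wells; under a scalar-background model the order of stitching and
subtraction is irrelevant. Wells whose corrected 640 mean falls below
`epsilon` (default 1% of the 16-bit range) yield no ratio and are flagged
`low_signal` instead of producing unstable values; wells with more than
0.1% saturated pixels are flagged `clipped`. Pseudocolor ratio renders
clamp the per-pixel ratio to a display range, map it through a blue→red
temperature LUT and modulate brightness by the 640 channel between two
saturation thresholds (black below, full brightness above), which
suppresses regions outside cells.

# Screen statistics

Plate QC uses the Z'-factor,
$Z' = 1 - (3\sigma_{c+} + 3\sigma_{c-})/|\mu_{c+} - \mu_{c-}|$, with
sample SDs; on screen plates the eight pooled positive controls versus the
eight negatives, on robustness plates the 48/48 split. Values in
$[0.5, 1]$ mark an excellent high-throughput assay.

Normalization is per plate per replicate: each well's ratio is divided by
the **median** of its own plate's negative controls and log2-transformed.
Replicate screens are separate plates, so this is required, and the median
is robust to an aberrant control well. Per target, the package reports the
arithmetic mean of the per-replicate log2 fold changes and the paired SSMD
of those values. The reading "average log2 fold change from the median" is
taken as mean-of-per-replicate-log2 values (rather than log2 of a mean
ratio); the two differ only at second order for the small CVs involved.

For SSMD, the UMVUE estimator
$\frac{\Gamma(\frac{n-1}{2})}{\Gamma(\frac{n-2}{2})}
\sqrt{\tfrac{2}{n-1}}\; \bar d / s_d$ is the default, with the
method-of-moments variant $\bar d / s_d$ selectable; the Γ-correction
degenerates at $n = 2$ (Γ(0) diverges), so two-replicate screens must use
the moment form. Zero-variance differences return a signed infinity flag
(or 0 when the mean is also 0). The dual-flashlight table sorts targets by
mean log2 fold change ascending — the most inhibited first, matching how
such screens are reported — and carries the per-plate positive controls as
labeled rows. Hit calling is a configurable double cutoff
(|SSMD| ≥ 1.0 and |log2FC| ≥ 0.2 by default, symmetric for inhibitors and
enhancers); published screens of this kind visualize rather than threshold,
so the defaults are deliberately conservative configuration, not a claim.

# Numerical and design notes

* All stochastic code runs under an explicitly seeded, restored RNG;
  every artifact is a pure function of (inputs, seed), and per-well seeds
  derive from the plate seed so that rendering a subset of wells is
  bit-identical to rendering them within the full plate.
* The kinetics use the closed form rather than a numerical integrator;
  the equivalence is enforced in tests rather than at run time.
* The calibration inverse is analytic; round trips hold to $10^{-9}$.
* Degenerate inputs error early: coincident compartment ratios, ratios at
  the calibration plateaus, unsorted time vectors, non-positive ratios in
  log fold changes, coincident control means in Z'.
* Ties in the plateau detector resolve to the earliest settled sample; the
  final sample always qualifies.
* Problem sizes in the tests: image-based unit tests run 64-pixel fields
  with ~12 cells and a proportionally reduced photon scale (the per-pixel
  densities match the defaults); the statistics-level properties
  (false-positive rate, null centering) use measurement-level simulation
  at the full 240-target design; the acceptance checks run full
  256-pixel, 4-field plates, including one complete 3-replicate screen
  with planted inhibitors.

# Known limitations

* The sensor defaults are package choices consistent with the published
  ~3-fold contrast, not published parameter values; refit with
  `fitCalibration()` for any real instrument.
* The In/Sur estimator assumes the early linear regime; it will
  underestimate rates if fed long time courses.
* The renderer's noise model is deliberately minimal (one well-level
  factor + counting noise); spatial artifacts, edge effects and
  segmentation are out of scope, as is FDR-style multiple-testing control
  (screens of this design rank by SSMD instead).
* Real screens contain biology this generator cannot know — off-target
  effects, toxicity, partial knockdowns with phenotype thresholds — so
  planted-effect recovery validates the pipeline, not any biological hit
  list.
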