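---
title: "From static cytometry snapshots to dynamic cell-cycle expression profiles"
author: "cytocycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From static cytometry snapshots to dynamic cell-cycle expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Flow cytometry of an asynchronous, exponentially proliferating culture
measures every cell once, at an unknown moment of its cycle.  Yet the
*frequency structure* of those static measurements carries time: a cell
population in steady exponential growth has a known age distribution, so
the fraction of events "upstream" of a cell along the cell-cycle
trajectory determines where in the cycle that cell sits.  cytocycle turns
multi-parameter snapshots (DNA content, cyclin A2, cyclin B1,
phospho-S10-histone H3) into dynamic, same-scale expression profiles —
the state-variable trajectories needed, for example, to calibrate ODE
models of the cell cycle.

Two obstacles stand between a 4-parameter listmode file and such
profiles, and the package's two core ideas address them:

1. **Untangling the trajectory.**  No single bivariate display resolves
   the whole cycle.  The package traverses the data through ordered
   region chains — DNA x cyclin A2 through interphase, then three mitotic
   views (pHH3 rise, cyclin A2 degradation, cyclin B1 degradation, pHH3
   return) — with the rule that an average cell can never re-enter a
   region.  Where a phase cluster (G1, G2) hides real expression change
   inside one unimodal histogram, a boundary-anchored Gaussian
   deconvolution recovers it.
2. **Putting markers on one scale.**  Multi-colour fluorescence
   amplitudes are arbitrary per channel.  Two single-colour assays that
   detect each cyclin with the *same* secondary antibody share one
   intensity scale; regressing multi-colour against single-colour medians
   inside DNA-matched S-phase gates yields an affine map onto that common
   scale.

## The age distribution and the frequency-to-time transform

In steady exponential growth one mitotic cell yields two newborns, so the
steady-state density of cell-cycle ages $t \in [0,1]$ declines by exactly
a factor of two across the cycle:

$$\varphi(t) = 2\ln 2\; \cdot 2^{-t}, \qquad
  F(t) = \int_0^t \varphi = 2 - 2^{1-t}.$$

Cumulative event frequency $F$ therefore converts to cell-cycle time by
the exact inverse

$$t = 1 - \log_2(2 - F),$$

implemented in `frequencyToTime()` / `timeToFrequency()` and verified in
the tests as a monotone bijection fixing 0 and 1, self-inverse to
$10^{-12}$.  Each region or fitted component is placed at the midpoint of
its event mass, $x_k = \sum_{j<k} f_j + f_k/2$ (`cumulativePositions()`);
the midpoint convention is our choice — any within-region placement is
defensible, and the midpoint is unbiased for locally linear kinetics.
Loss, death and unequal division would tilt the age distribution away
from the ideal exponential; such corrections are out of scope and the
ideal form is used throughout.

## Gating and segmentation

**Preprocessing.**  Spillover is removed linearly
(`compensate()`; coefficients are an input, as in instrument-calibrated
compensation).  Background is anchored on G1: cyclins are not expressed
in early G1, so the G1 median of each cyclin channel estimates pure
background staining and is subtracted (`subtractBackground()`).  The
median is our choice of statistic (robust against the late-G1 cyclin B1
rise contaminating the gate); negative post-subtraction values are kept
so background clusters stay symmetric for log-domain fitting.  Debris is
removed by a DNA-integral floor and aggregates by a singlet
discrimination line in the pulse height-versus-integral plane: a
through-origin line whose slope is a low quantile (default 1%) of the
height/integral ratio over the 2C cluster, scaled by a 0.8 safety factor
(`excludeDebrisAggregates()`).  A through-origin boundary suffices
because pulse height is proportional to integral for singlets; doublets
carry roughly half the height per unit integral.

**Interphase versus mitosis.**  Mitotic cells have 4C DNA and a pHH3
level an order of magnitude above the interphase band.  The threshold is
data-derived: the modal log10 pHH3 of the 4C cluster (dominated by G2
cells) plus 4 robust SDs (`splitInterphaseMitosis()`).  Four SDs keeps
essentially all interphase cells below the gate while late-mitotic cells
— already partially dephosphorylated — still clear it; cells in the last
instants of cytokinesis, whose pHH3 has fallen back into the interphase
band, are the irreducible loss of any pHH3-high gate.

**S-phase chains.**  Interphase S is segmented on the (DNA, cyclin A2)
view by following the modal backbone of the point cloud (sliding DNA
windows, 64-bin smoothed modal cyclin A2 per window), with segment
boundaries perpendicular to the local backbone direction in
range-normalised coordinates and balanced so each of the default 12
segments holds at least 300 events (`autoSegmentS()`).  Event assignment
is by arc-length projection onto the backbone, stored inside the
`RegionChain`, so it is exactly reproducible and partitions the gated
population; the polygon regions built from the same cuts are the
displayable equivalent.  Thin transition ovals at G1/S and S/G2 supply
the anchor distributions for deconvolution.  Boundary membership is
half-open (lower/left edge inclusive) with chain-order tie-breaking, so
abutting regions never double-count an event.

**Mitotic chains.**  Mitosis is traversed across three views in fixed
biological order — pHH3 rise (cyclin A2 at peak), cyclin A2 degradation
(pHH3 high, cyclin B1 constant), cyclin B1 degradation (cyclin A2 gone),
then pHH3 partial return — using data-derived stage thresholds and
within-stage quantile cuts (`buildMitosisChain()`).  Channels hidden in a
stage's view are read indirectly by their median, which assumes the
exposed/hidden relationship is orthogonal; when cyclin B1 degradation
begins before cyclin A2 is fully lost the relationship curves, and
`curved = TRUE` switches the merged degradation stretch to the same
backbone-following segmentation used for S phase.

## Boundary-anchored deconvolution

The G1 and G2 clusters are unimodal in log intensity, yet each spans real
expression change.  A plain 3-component mixture fit of such a histogram
is degenerate — many weight triples fit one bump.  The package therefore
pins what can be measured and penalises the rest:

- outer components are **anchored**: their means/SDs come from
  single-Gaussian fits (`fitAnchor()`) to the transition ovals (S/G2 and
  G2/M for G2; the G1/S oval plus the histogram peak for G1 cyclin B1,
  with the exit CV transferred to the lower components);
- the centre component's mean is fixed midway between the anchors (its
  SD is free for G2; it inherits the exit CV for G1);
- component masses minimise the histogram least-squares error **plus** a
  continuity penalty: $\lambda \sum_k \big(y_{\text{traj}}(x_k) -
  10^{\mu_k}\big)^2 / y_{\text{scale}}^2$, where $x_k$ is each
  component's cumulative-frequency midpoint and $y_{\text{traj}}$ the
  S-phase expression line extrapolated linearly into the cluster
  (backwards into G1, forwards into G2, floored at zero).

$\lambda$ defaults to 1 in these normalised units: the penalty resolves
the weight degeneracy without overriding the histogram where the data
have structure; `lambda = 0` recovers ordinary constrained least squares
(checked in the tests against EM mixture fitting when the means are also
freed).  Masses are parametrised on the simplex scaled to the histogram
mass, so the penalty can redistribute mass between components but never
create or destroy it.  Optimisation is bounded L-BFGS-B from three
deterministic starts (balanced, entry-heavy, exit-heavy) to step over the
local minima this degeneracy creates.

Numerical choices: all fitting is in log10 intensity; non-positive values
(possible after background subtraction) are floored at $10^{-3}$ of the
channel's 99th percentile; histograms span the central 99.9% of values.
The default bin count targets **~150 events per bin** (clamped to
[32, 256]): least-squares histogram fits are limited by the Poisson noise
floor of the bin counts, and finer grids lower the attainable $R^2$
without adding information — at the floor of 32 bins a component SD of
0.05 log10 over a typical 0.6 log10 range is still resolved about
three-fold.  Anchors closer than 0.25 of the larger anchor SD route to a
single-component fit.  Fit quality is reported as
$R^2 = 1 - SS_{res}/SS_{tot}$ over bin counts (`rSquared()`).

## Same-scale correction

DNA content is measured precisely enough to serve as the cross-file
correlating variable.  Per file, the G1 and G2 modal channels
(512-bin histogram, Gaussian-smoothed with a 3-bin kernel, ties toward
the lower channel) are mapped by the exact two-point linear transform
onto channels 350 and 700 (`rescaleDna()`); two constraints determine the
two parameters, so no regression over further landmarks is needed.  Seven
equal-width, contiguous DNA gates centred on channel 525 (together
spanning 80% of the G1-G2 span by default; count and width configurable)
then select equivalent S-phase cell sets in every file
(`buildEquivalentGates()`).  Ordinary least squares of single-colour on
multi-colour per-gate cyclin medians gives the per-epitope affine map
(`deriveScaling()`).  The intercept is left free although background
subtraction should force it to zero — keeping it free turns that
assumption into a diagnostic instead of an imposition.

## Profile synthesis and boundary heuristics

Region medians (S, M) and component means (G1, G2; ordered by mean, with
sequential frequency mass proportional to their weights) become knots of
a piecewise-linear profile: between consecutive knots,

$$y = \frac{y_{i+1}-y_i}{x_{i+1}-x_i}\,x
      + y_i - \frac{y_{i+1}-y_i}{x_{i+1}-x_i}\,x_i.$$

Because every knot is a *central* value of its region, transitions are
sparsely covered, and `applyBoundaryHeuristics()` improves them: the G1
value also holds at $x = 0$ and is prepended there; for a marker absent
in G1 (cyclin A2) a line through the first three S knots is extrapolated
to its zero crossing and a knot inserted there when the crossing falls in
the G1-S gap (otherwise the transition is left unimproved); the last
value is carried to $x = 1$; and, for cyclins known to be below detection
at the cycle boundaries, endpoint zeroing sets $y(0) = y(1) = 0$ exactly.
Zeroing is a flag (default on for the cyclins only) because it encodes
external biological knowledge, not a measurement.  Profiles carry both
frequency- and time-domain x values; DNA is reported in genome units by
anchoring the population G1 mode at 2 genomes, and pHH3 relative to its
own G1 level (its absolute scale has no meaning relative to the cyclins).

## The synthetic-data generator

No public dataset accompanies this methodology, so the package ships a
generator (`generatePopulation()`, `generateAssayPair()`) whose defaults
*are* the study conditions used by the tests:

- ages sampled exactly from $\varphi$ by inverse CDF;
- piecewise-linear truth kinetics: DNA 2C through G1 ($t < 0.40$), linear
  to 4C across S ($t < 0.80$), 4C through G2/M; cyclin A2 rising through
  S/G2 to a peak of 100 a.u. just after mitotic entry, degraded to zero
  by mid-M; cyclin B1 rising from late G1 (8 a.u. at the G1/S boundary),
  peaking with cyclin A2, constant while cyclin A2 is degraded, then
  degraded to zero; pHH3 basal at 5% of its mitotic peak, doubling
  linearly across interphase, surging over a 0.002-cycle window at
  mitotic entry ($t = 0.95$) and partially dephosphorylated once cyclin
  B1 is gone, ending at twice the G1 level.  The surge width is a free
  parameter — the kinetic form of the "sharp rise" is not constrained by
  data, only its order;
- measurement process, applied in order: per-assay channel gains,
  spectral spillover (default 8% of pHH3 into the cyclin A2 channel,
  emulating A488-into-PE overlap), additive background offsets (3 a.u.
  on the cyclins), multiplicative lognormal noise (CVs: DNA 3%, pulse
  height 4%, cyclins 12%, pHH3 15% — typical immunofluorescence
  precision, with DNA much tighter than antibodies);
- contamination: 3% doublets (summed pairs at 55% pulse height per unit
  integral) and 2% low-DNA debris;
- truth labels in reserved `truth_`-prefixed columns with role
  `"truth"`, so analysis code cannot pick them up by accident.

The generator emulates measurement physics, not biology's full
complexity: there is no cell-to-cell kinetic heterogeneity beyond
measurement noise, no cell death or quiescence, no endoreduplication, and
the truth kinetics are piecewise-linear.  Passing tests therefore
demonstrate that the pipeline inverts the assumed measurement process and
age structure correctly — not that real K562 data would yield profiles of
this fidelity.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use populations of 20 000
multi-colour and 15 000 single-colour events — enough that the 12
S-segments hold the default 300-event minimum with margin, and chosen as
a realistic per-file event count for this assay class.  All randomness
flows through explicit integer seeds; the pipeline itself is
deterministic given its inputs (optimiser starts are fixed), which the
tests verify by re-running it and comparing outputs bit-for-bit.

## Known limitations

- The exponential age distribution ignores death, loss and desynchrony;
  profiles from perturbed or dying cultures will be distorted near M.
- Indirect (orthogonality-assuming) reads in the mitotic chain bias
  medians when the hidden marker co-varies with the exposed one; the
  curved mode mitigates, but does not remove, this.
- The G1/G2 deconvolution resolves three points per cluster; expression
  fine structure inside a phase cluster below that resolution is
  unrecoverable by design.
- The same-scale map inherits the assumptions of the shared-secondary
  design: equal secondary recognition of both primaries, comparable
  primary affinities and epitope exposure.  It transfers relative, not
  molecular, scale; a molecular calibration of any one epitope would
  propagate through the same maps.
- FCS support is a minimal list-mode float reader/writer (TEXT + DATA
  segments); analysis segments and integer/exponent-scaled data are not
  parsed.
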