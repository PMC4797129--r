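---
title: "Methods: automated STR electropherogram analysis and its validation"
author: "forenSTR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated STR electropherogram analysis and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forenSTR)
```

## Scope and model

forenSTR implements a fully automated ("expert system") analysis chain for
short tandem repeat (STR) genotyping from multi-dye capillary
electrophoresis traces, together with a trace simulator that stands in for
instrument data. The analysis chain makes no manual decisions: a run either
passes its quality criteria and produces calls, or fails with named
reasons.

The working objects are:

* `PanelDefinition` — the assay: loci with dye channel, repeat unit,
  allelic-ladder composition (allele designation + nominal size in bases),
  per-locus stutter threshold; the internal lane standard (ILS); and global
  thresholds. The bundled `pp16Panel()` mimics a PowerPlex-16-style 4-dye
  assay: 16 loci on FL/JOE/TMR, ILS on CXR, 210 ladder fragments in total.
  Microvariant alleles (e.g. TH01 9.3) are opaque labels with explicit
  sizes; the code never does arithmetic on designations.
* `Electropherogram` — a scans x channels RFU matrix with metadata. Scan
  coordinates are 0-based; sizes are floats in bases, reported to 0.01
  base.
* `SampleProfile` — all calls (flagged included), per-locus status
  (`called` / `dropout` / `flagged_only`), a `full`/`partial`/`fail`
  category, and the count of called CODIS core loci.

## The simulator

`simulateSample()` builds a trace from a genotype as a sum of Gaussian
peaks plus structured noise. For an allele of size $s$ (bases):

* position: $\mu = w(s)$ scans, where the warp
  $w(s) = a_0 + a_1 s + a_2 s^2 + a_3 s^3$ is a strictly monotone cubic —
  the same functional family conventional sizing software assumes for
  electrophoretic mobility. Default: $(200,\ 8.5,\ 1.2\times10^{-3},\
  2\times10^{-7})$, mapping 60–600 bases onto roughly scans 700–5800.
* width: the peak SD in bases is $\sigma_b(s) = \max(0.12,\ -0.0525 +
  1.486\times10^{-3}s)$, converted to scans through the local warp slope.
  This calibration makes the computed resolution fall from about 1.6 near
  140 bases to about 0.36 near 500 bases, the qualitative profile of a
  single-base-resolution CE system; the floor keeps short fragments
  detectable on an integer scan grid.
* height: $h = h_0\, m\, e^{-\delta s}\cdot \varepsilon$, with
  `heightScale` $h_0 = 10$ RFU/pg, template mass $m = 500$ pg by default,
  degradation $\delta = 0.002$/base, and a log-normal imbalance factor
  $\varepsilon = e^{N(0,\tau)}$ per allele.
* dropout: each allele independently survives with probability
  $1 - \mathrm{logit}^{-1}\!\big(-\beta(\log m - \log m_{50})\big)$,
  $m_{50} = 30$ pg, slope $\beta = 3$. Dropout is per allele, not per
  locus, so heterozygous loci degrade to apparent homozygotes before they
  drop out entirely — the behaviour low-template casework shows.
* stutter: one peak per surviving allele at $s - \text{repeat unit}$, at a
  ratio drawn from $N(0.08, 0.02)$ truncated at zero. Forward (n+1)
  stutter is not modelled.
* channel structure: pure dye signals are mixed through a square,
  diagonally dominant crosstalk matrix (default 5% bleed between adjacent
  channels), a slow sinusoidal baseline (amplitude 40 RFU, period 2000
  scans, random phase) and white noise (SD 8 RFU) are added, and the trace
  is clipped at 30000 RFU.

All randomness flows from the single `seed` slot: one generator stream per
simulated run, so every trace is bit-reproducible.

**Imbalance calibration.** The mean heterozygote peak height ratio (PHR)
observed on low-DNA-content casework is typically 0.7–0.8. With
$\tau = 0.20$, the simulated PHR
$\min(\varepsilon_1, \varepsilon_2 r)/\max(\varepsilon_1, \varepsilon_2 r)$
(including the deterministic degradation ratio $r$ between the two allele
sizes) has mean ≈ 0.78, inside that band; the mean is a continuous,
monotone decreasing function of $\tau$, which the test suite checks.

**What the simulator does not emulate.** PCR kinetics, inhibition,
mixtures of contributors, pull-up beyond linear crosstalk, dye blobs and
spikes, and non-exponential degradation are all out of scope. Passing
tests therefore demonstrate that the *analysis chain* is correct under the
stated noise model — not that it is robust to every artifact class real
casework produces.

## Signal conditioning

Baseline: per channel, a windowed 10th-percentile estimate (window 160
scans ≈ 20 typical FWHM, computed blockwise and linearly interpolated)
is subtracted; a residual median correction then re-centres the non-peak
signal at zero, compensating the downward bias of a low percentile of
noise. The operation is idempotent within tolerance.

Colour correction solves `C · pure = observed` per scan for the known
mixing matrix `C` (from simulation metadata or run configuration). Blind
spectral estimation is deliberately out of scope: on instrument data the
matrix comes from a spectral calibration run.

Peak detection finds local maxima above a floor (half the analytical
threshold in the standard chain), refines apexes by 3-point parabolic
interpolation (plateau maxima use the plateau midpoint and are flagged
saturated when the plateau exceeds 3 scans), and measures FWHM by
interpolated half-height crossings. Maxima narrower than 2 scans are
rejected as noise spikes. Parabolic apex error is below 0.05 scans
(≈ 0.005 bases) even for the narrowest peaks the width model produces.

## Sizing

`evaluateIls()` assigns detected ILS-channel peaks to the expected
fragment sizes by greedy monotone matching with a tolerance of 25% of the
local inter-fragment gap, refined by a cubic refit. Because ILS fragments
are equimolar, candidate peaks below 25% of the median height of the
tallest *n* candidates are excluded first; this rejects baseline artifacts
and small spurs without touching genuine fragments. A run passes only if
every fragment is matched exactly once, scans are strictly increasing, and
the maximum absolute sizing residual is ≤ 0.25 bases. These numbers are
our documented defaults — the production system's exact criteria are
unpublished, so ours are configurable and deliberately strict.

`fitCalibration()` fits scan = cubic(size) by least squares on a
standardised size axis — matching the mobility family the simulator (and
conventional CE practice) assumes — checks monotonicity, and recovers
sizes by Newton inversion of the monotone curve. When the true warp is
cubic and noise-free the residuals vanish to numerical precision. The
classical Local Southern method (two bracketing triplets of
$L = a + b/(x - c)$, averaged) is provided as an alternative; the two
agree to a few hundredths of a base away from the calibrated ends.

## Calling rules

Bins are calibrated from a sized allelic-ladder run: every expected ladder
fragment must match a peak within the bin half-width (default ±0.5 bases)
of its nominal size, else the ladder fails naming the missing fragment.
Bin centres are the observed sizes.

Locus membership of a sample peak is channel + size span; the span extends
one repeat unit below the lowest ladder allele so stutter stays attributed
to its parent locus. Peaks in a span but in no bin are called off-ladder
(`OL`).

Rules fire in a fixed, documented order: analytical threshold (default
100 RFU) → stutter (ratio to the tallest unflagged same-locus call one
repeat unit larger, position tolerance ±0.5 bases, default threshold
0.15) → PHR. When exactly two unflagged calls remain and their ratio is
below the PHR threshold, the *weaker* call is flagged (the choice between
flagging one or both is genuinely open; we flag the weaker and document
it). More than two surviving calls flag the whole locus for review. The
PHR threshold defaults to 0.3: low-DNA-content samples legitimately show
depressed ratios, so only severe imbalance — the likely drop-in or
artifact — is flagged, keeping false allele suppression rare, consistent
with a validated system's near-perfect concordance. Amelogenin is called
like any locus but excluded from PHR aggregation (its ratio is
sex-dependent).

Profile category: `full` iff every panel locus is called, `fail` iff none
is, else `partial`; the count of called CODIS loci annotates searchability
(fewer than 10 is below the usual database threshold) rather than forming
a separate category.

## Validation metrics

* **Precision** — sample SD (n−1) of each ladder fragment's calibrated
  size across injections; pass iff the maximum is below 0.16 bases.
* **Resolution** — $R = (S_2 - S_1) / \tfrac12(W_{b1} + W_{b2})$ with the
  Gaussian baseline width $W_b = 2\,\mathrm{FWHM}/\sqrt{2\ln 2} = 4\sigma$;
  a single peak is scored against a hypothetical equal-width twin one base
  away, $R = 1/W_b$. The exact formula used by the instrument literature is
  not reproduced here, so this convention is documented as a stand-in and
  the printed endpoint values are treated as calibration guidance only.
* **Concordance** — every reference allele is assessed; dropouts count as
  discordant (assessed = concordant + discordant); unflagged calls with no
  reference counterpart are drop-ins, tracked but not assessed; the
  percentage is printed to 3 decimals.
* **Reproducibility** — a replicate-by-sample-type grid of `Y`/`Y*`/`F`
  status codes collapses to full/partial/fail counts.
* **Sensitivity** — Monte-Carlo end-to-end simulation over a template-mass
  ladder; mean called-locus count is non-decreasing in mass.

## Numerical choices and degenerate inputs

Sub-scan apexes are used throughout; sizes are reported to 0.01 base.
Cubic fits are performed on standardised axes. Ties at plateau maxima
resolve to the plateau midpoint. Zero-length traces are rejected on write;
empty peak lists and all-homozygote PHR reports return empty results
rather than errors; a failed ILS is a status, not an exception, and makes
calibration refuse to run. ABIF channel data are 16-bit signed big-endian
integers with clipping, so the write/read round trip is exact for
integer-valued traces (simulated traces are rounded on write).

## Problem sizes used by the tests

The suite runs entirely on simulated data: 20 ladder injections for the
precision study, 100 random genotypes for the end-to-end concordance
oracle, 2000 simulated alleles for the dropout Monte-Carlo, 10000
Hardy-Weinberg draws for the heterozygosity check, and 8–12 replicates per
mass for sensitivity curves. These sizes give Monte-Carlo standard errors
comfortably inside the asserted bands while keeping the whole suite under
a minute on a laptop-class machine.

## Known limitations

Single-contributor samples only; no probabilistic genotyping; no
stochastic-threshold inference of hidden homozygote alleles (one surviving
call is reported as one call); drop-ins exist in the simulator and the
concordance tally but are not modelled by the caller; the bundled panel's
nominal sizes are representative, not vendor-exact; and the conditioning
chain is a documented stand-in for unpublished instrument internals.
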