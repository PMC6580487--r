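---
title: "Methods: disulfide-formation QC from paired LC traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disulfide-formation QC from paired LC traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdpqc)
```

## The measurement and the model

Cystine-dense peptides (CDPs) owe their stability to a core of disulfide
bonds. Production QC therefore runs every purified protein twice through
analytical HPLC/UPLC: once intact and once after dithiothreitol (DTT)
reduction. A formed and reducible disulfide core shows up as a
retention-time shift of the reduced trace; heterogeneous or misfolded
material shows up as extra peaks. `cdpqc` turns the pair of UV traces into
one of four categorical quality calls.

The processing chain is deliberately simple and fully deterministic:

1. **Blank subtraction.** Acquisitions interleave a blank injection before
   every three sample pairs. The blank's absorbance is linearly
   interpolated onto the sample's RT grid and subtracted pointwise
   (`subtract_blank()`). This removes the gradient/system baseline,
   including linear drift, because blank and samples share it. The blank
   may fall short of the sample domain by up to 2 grid steps per end
   (flat extrapolation); more is an error. An alternative reading of the
   protocol — subtracting only a scalar baseline statistic of the blank —
   is *not* implemented; full-trace subtraction is the stricter
   interpretation and reduces to the scalar one when the blank is flat.
2. **Noise estimation.** The signal-to-noise gate needs a noise scale σ
   that the acquisition software leaves undefined. `estimate_noise()` uses
   `1.4826 × MAD` of the normalized trace restricted to the flanks outside
   the peak search window, which is robust to stray peaks in the flanks.
   If fewer than 10 flank points exist it falls back to the lower quartile
   of `|Δy|/√2` over the whole trace — deliberately conservative (it
   underestimates Gaussian σ by ~3×), so the fallback errs toward finding
   peaks rather than hiding them.
3. **Peak detection.** The trace is smoothed with a centered moving
   average (`smooth_window`, default 5 points) and local maxima are
   accepted when height *and* topographic prominence reach `sn × σ`
   (default `sn = 10`) with the apex inside
   `[min_rt, max_rt]` (defaults 5–12 min). The apex is refined to the
   unsmoothed maximum within the smoothed peak's support; plateau ties
   report the midpoint. With σ = 0 (noise-free input) the gate degrades
   to `1e-8 × max(trace)` so that synthetic data cannot divide by zero.
4. **Shoulders.** See below.
5. **Classification.** Rules applied in order (`classify_pair()`):
   Complex if either trace exceeds `simple_max_peaks` (default 2);
   Perfect for a 1/1 pair whose apexes differ by more than `overlap_tol`
   (default 0.1 min); PerfectPartial for 1 intact / 2 reduced with exactly
   one overlap; Simple otherwise. Complex-first precedence prevents a
   3-peak reduced trace with one overlap from passing as PerfectPartial.
   The map is total: empty peak lists classify Simple with a `no_peaks`
   flag, and an unshifted 1/1 pair classifies Simple with a
   `no_reduction_shift` flag — the DTT-resistant case is flagged rather
   than given a fifth category.

## The shoulder criterion

Counting "peaks including shoulder peaks" requires deciding what a
shoulder is; chromatography practice has no single convention. `cdpqc`
uses a *valley-fraction* rule with default `shoulder_valley_frac = 0.7`:
two adjacent maxima whose separating valley descends below 0.7 × the
smaller apex height are two resolved peaks; if the valley stays above the
fraction, the smaller one is flagged a shoulder. Both count toward the
totals.

A genuine shoulder, however, is often *not* a second local maximum at
all: two Gaussians of widths σ\_w separated by less than ~2 σ\_w sum to a
unimodal curve. A valley rule over local maxima alone can never see such
features. `detect_shoulders()` therefore also recruits candidates from
local maxima of the negative second derivative of the smoothed trace
(curvature), computed with a wide stencil (`smooth_window` grid steps)
and re-smoothed. A curvature candidate is accepted as a shoulder when

* its curvature exceeds `max(0.02 × max curvature, 5 × MAD(curvature))` —
  the MAD term is the essential guard: flank noise produces curvature
  wiggles that would otherwise spawn false shoulders at 2% noise;
* it sits more than `2k + 1` grid points from every accepted apex, below
  its parent apex, inside the RT window, and above the `sn × σ` height
  gate;
* the smoothed trace between candidate and nearest apex never descends
  below the valley fraction (for a monotone flank the "valley" is the
  flank value itself, so this reduces to the same criterion).

Numerically, for 0.1-min-wide Gaussians the recruit fires from about
2 σ\_w separation upward; at ~3.5 σ\_w the valley drops below the fraction
and the pair reports as two resolved peaks. Below ~2 σ\_w, with a 60%
secondary component, the mixture's first and second derivatives are both
monotone through the overlap — there is no detectable signature short of
curve fitting, which is out of scope — so such features are (honestly)
reported as one peak.

## Peptide property conventions

* **Masses.** Residue masses are derived from a single elemental
  composition table and two element mass sets (monoisotopic; CIAAW
  conventional atomic weights), so `average ≥ monoisotopic` holds by
  construction. Full oxidation is assumed: `n_SS = ⌊n_Cys/2⌋`, each bond
  subtracting exactly two hydrogen atoms (`2 × m_H` in the respective
  mass convention); an odd cysteine leaves one free thiol. The phrase
  "hydrogen bonds lost at cysteine sites" in assay documentation is read
  chemically: covalent S–S formation releases the two thiol hydrogens.
* **Net charge.** Henderson–Hasselbalch summation with the EMBOSS pKa set
  (N-term 8.6, C-term 3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5,
  Y 10.1). Disulfide-bonded cysteines are excluded from the acidic set;
  free thiols are included. Which pKa set the original registry scripts
  used is unrecorded; EMBOSS is a declared default, selectable by name.
* **Hydrophobicity.** GRAVY convention: the arithmetic mean of
  Kyte–Doolittle values, again a declared (not inferred) default.
* **m/z validation.** Theoretical `m/z = (M + z·m_p)/z` uses the proton
  mass (1.00727646677 Da), not the hydrogen atom mass, for charges
  1..6 at a 20 ppm tolerance — reasonable modern ESI-TOF practice; the
  original system's tolerance is unrecorded. The smallest matching charge
  is reported.
* **WBA.** The standard curve is free-intercept OLS of known dpm on raw
  signal (the prediction direction). Negative predicted dpm is clamped to
  0 with a `below_curve` flag.

## What the synthetic generator emulates — and what it does not

`simulate_trace()` builds Gaussian elution peaks over a 0–15 min grid at
0.01-min steps plus a linear baseline (default 2 + 0.3·t mAU) and i.i.d.
Gaussian noise. `simulate_batch()` arranges one intact/reduced pair per
requested label with a blank before every three pairs, drawing apexes
uniformly in 6–10 min so every constructed peak stays inside the default
5–12 min window: Perfect pairs shift by 0.8 min (8 × `overlap_tol`);
PerfectPartial reduced traces carry an exactly-overlapping 60-unit peak
plus a shifted 100-unit peak; Simple pairs have two intact peaks 1.5 min
apart; Complex reduced traces have three peaks ≥ 0.9 min apart. Peak
width is fixed at 0.08 min (~5 s FWHM ≈ 11 s, typical for analytical
UPLC); heights are 60–100 mAU.

The generator intentionally omits: peak tailing/fronting, retention drift
between runs, carry-over, detector saturation, and correlated (1/f)
baseline noise. A green classifier test therefore establishes that the
decision logic and the SNR gate behave as specified under the stated
noise model — not that the defaults are optimal for any particular
instrument. The acceptance suite runs 100 pairs per class at noise
sd = 0 (expecting 100% label agreement) and at sd = 2, i.e. 2% of the
main apex height (expecting ≥ 95%).

## Numerical choices and degenerate inputs

* Smoothing windows shrink at trace edges rather than padding.
* Plateau maxima (ties after smoothing) report the plateau midpoint.
* Blank coverage tolerance carries a `1e-9` relative slack so that exact
  2-grid-step shortfalls survive floating-point grid arithmetic.
* `classify_pair` is total; `classify_batch` converts per-sample failures
  (missing/unreadable traces) into error records and continues.
* All generator randomness flows through one seed; the global RNG state
  is saved and restored, and equal seeds give byte-identical serialized
  batches (`%.17g` round-trip serialization).

## Known limitations

Shoulders below ~2 peak-widths of separation are undetectable by design
(no deconvolution). Peak *areas* are not computed — classification uses
counts and apex positions only. The filename convention
(`<id>_<INTACT|DTT|BLANK>.<ext>`) is a declared default for an unrecorded
grammar and is overridable by a user regex. Vendor binary trace formats
are out of scope; the canonical input is two-column delimited text.
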