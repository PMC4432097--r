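---
title: "Rendering spectroscopy data to SVG: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rendering spectroscopy data to SVG: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectrachart)
```

## What this package models

Spectra from the common analytical platforms — mass spectrometry (MS),
one- and two-dimensional NMR, infrared (IR) spectroscopy — share a small set
of well-established visual conventions, and almost every spectral database
re-implements them. `spectrachart` encodes those conventions once, as a
static renderer: data series go in as JSON, a standalone SVG 1.1 document
comes out. There is no event loop; everything a user of an interactive
viewer would do with the mouse (zooming, resetting the zoom, highlighting a
series via the legend) is expressed declaratively through chart options
(`view_window`, `highlight`), which keeps the output a pure function of its
inputs and makes renders byte-reproducible.

The architecture separates *data* from *presentation*, mediated by a single
data handler per chart:

* a **dataset** (`new_dataset()`, `add_series()`, `remove_series()`) owns
  the series bound to a chart, tracks their union extents, assigns
  deterministic `series-<k>` identifiers to unnamed series, and carries the
  binning configuration;
* a **chart spec** (`chart_spec()`) is a fixed registry entry per technique
  describing axis directions, render style, bin mode and view-window
  semantics;
* the **renderer** (`render_chart()`) composes the two with scales, signal
  labels, a legend and annotations.

## The chart registry

| type | style | x direction | bin mode | window semantics |
|------------|---------|--------------------|----------|------------------|
| `ms` | impulse | m/z ascending | max | box (x and y) |
| `nmr1d` | line | ppm descending | max | range (x only) |
| `nmr2d` | point | both ppm descending | none | box |
| `ir` | line | 1/cm descending | min | box |
| `timeseries` | line | ascending | max | box |

The reversed axes follow universal spectroscopy convention: chemical shift
and wavenumber are read right-to-left. IR charts plot transmittance, so the
informative features are *valleys*; that is why IR is the one technique
binned by the per-bin minimum. Mass spectra are drawn as impulses from a
zero baseline, and the baseline is treated as part of the chart: automatic
y windows for MS never pad below zero, while every other type pads the y
extent by 5% of its span on both sides.

When an x window is given without a y window — always the case for
range-zoom types such as `nmr1d` — the y window is recomputed from the
points visible inside the x window, so narrowing the view rescales the
intensity axis to the local dynamic range.

## Extremum-preserving binning

A 1D NMR spectrum routinely has more than 60,000 points; a plot area a few
hundred pixels wide cannot show them individually, and emitting them all
makes documents large and slow. `bin_series()` reduces a series to at most
one point per pixel-width bin:

* the view window `[lo, hi]` is split into `n_bins` equal intervals,
  half-open on the right with the final bin closed at `hi`, where
  `n_bins = plot_width_px %/% binwidth_px` (binwidth default 1 px);
* each non-empty bin contributes the **original input point** with extremal
  intensity (maximum or minimum per the chart type) — never a bin centre,
  average or interpolated value;
* ties on the extremal intensity break toward the smaller x.

Keeping original points is the load-bearing choice: peak apexes keep their
exact x positions, so signal labels and annotation anchors computed after
binning still refer to true data coordinates, the global extremum in the
window is always preserved, and binning is idempotent. The half-open/
closed-end partition and the smaller-x tie-break are fixed so that output
is deterministic; the binning itself is recomputed against the current view
window at render time, so zooming in progressively reveals detail.

Binning can be disabled (`bin_config(enabled = FALSE)`), in which case every
point is rendered. 2D point sets are never binned: cross peaks are already
sparse and each one is meaningful.

## Scales and axes

Scales are linear or log10 (log10 is the one logarithmic base offered);
a `reversed` flag flips the pixel range, which implements both the
right-to-left spectroscopy axes and the downward pixel y axis of SVG.
Values outside the domain extrapolate rather than error — view windows
routinely cut series, and clipping is the renderer's job, done by clamping
emitted coordinates to the plot rectangle. Axis ticks are "nice" multiples
of 1, 2 or 5 times a power of ten chosen by rounding `span/target` to the
nearest such value, which keeps the tick count within a factor of two of
the request; log scales get decade ticks, falling back to linear ticks when
the domain spans fewer than two decades.

## Signal labels

With `signal_labels = TRUE`, prominent peaks are labelled with their x
value formatted at the chart's precision (2 decimals for m/z and ppm, 0 for
wavenumber). Candidates are strict local maxima (both neighbours lower);
they are accepted greedily by descending intensity subject to a minimum
x separation of 2% of the view width, up to `max_labels`. The strictness
means a perfectly flat two-sample plateau is not a candidate — acceptable
for measured spectra, where exact ties are noise-free artefacts of
synthesis. Labels are computed on the *binned* series, which is safe
precisely because binning preserves original peak points.

## Annotations, tooltips and structures

Annotation tables are JSON lists of rows `[group, x_lookup, payload...]`.
The first two columns are mandatory: a group name (multiple groups may
coexist in one file; one group is rendered per chart, selected by
parameter) and a lookup position in the x domain. Payload columns are
declared in a schema, each typed `text` (drawn beside the anchored point),
`tooltip` (a `"<key>: <value>"` line in a callout box) or `structure_url`
(a reference to an MDL Molfile, resolved, parsed and drawn as a 2D
depiction inside the callout).

The lookup-to-point matching rule is nearest-x with an acceptance radius of
0.5% of the series x extent (ties toward smaller x). Annotations farther
than that are reported as unmatched rather than being force-attached to an
unrelated peak; anchors that fall outside the current view window are
skipped with a log message. Structure references resolve through a
pluggable resolver whose default reads local file paths; a resolver or
parse failure degrades to an error placeholder line while the remaining
columns render normally.

## The molfile parser and depiction

The V2000 connection table is a fixed-column format, so the parser reads by
column position, not by whitespace: atom and bond counts from columns 1-3
and 4-6 of the counts line, coordinates from 10-character fields, the
element symbol from columns 32-34, bond atom indices and order from the
three leading 3-character fields of each bond line. Files tagged V3000 are
rejected loudly rather than misread. Charges come from `M  CHG` property
lines. A file whose block lengths disagree with its counts line, whose
bond indices fall outside the atom count, or which lacks the `M  END`
terminator raises a parse error naming the problem.

Depiction is deliberately minimal and total: coordinates are normalised
(translated and uniformly scaled, aspect preserved, 10% padding) into the
target square, making the fragment invariant under translation or uniform
scaling of the input; bonds render as 1, 2 or 3 parallel lines by order,
with the "aromatic" type 4 drawn as a solid line plus an inner dashed
parallel — kekulisation is a separate discipline and is not attempted;
heteroatoms and charged atoms get centred text labels with adjoining bond
ends trimmed by a fixed label radius, carbons are bare vertices, and
implicit hydrogens are neither computed nor drawn. Molecules whose atoms
all share one coordinate (no real 2D layout) raise a degenerate-geometry
error instead of inventing a layout.

## Determinism and numerical choices

Golden-file testing requires byte-identical output, so every source of
variation is pinned: pixel coordinates are printed with exactly two
decimals; element order within the document is fixed (background, series,
signal labels, legend, annotations, axes last — also a sane overdraw
order); text extents are estimated at 0.6 em per character since real glyph
metrics vary across renderers (consequently golden files are only
comparable between renders of this implementation); colors come from a
fixed 8-color cycle assigned in series add order. Degenerate inputs are
defined rather than accidental: an empty dataset renders frame and axes; a
single-point extent is widened by 5% of its magnitude; margins that leave
no plot area are a layout error.

## What the synthetic generators emulate — and what they do not

The seeded generators produce data with the right *shape* for each
technique: exponential-intensity peak lists for MS, dense sums of
Lorentzian lines (half-widths 0.002-0.02 ppm) with mild noise for 1D NMR,
a transmittance baseline near 1 with Gaussian absorption dips for IR, and
sparse cross-peak sets for 2D NMR. They make no attempt at chemically
meaningful positions, multiplet structure, isotope patterns or correlated
noise. Tests passing on these fixtures therefore demonstrate the
*rendering and reduction contracts* — binning correctness at realistic
sizes, axis conventions, annotation anchoring — not fidelity to any
particular instrument's output. The molfile corpus is likewise synthetic:
small hand-authored molecules (ethanol, benzene, a uracil-like ring) plus
deliberately corrupted variants for the error paths.

Verification runs use problem sizes chosen to exercise the contracts
without waste: the binning cross-check runs a thousand random series of up
to 10^5 points against an independent per-bin scan, the large-series
contract uses a 60,000-point trace at an 800 px plot width, and scale
round-trips are checked over 10^4 random values per configuration.

## Known limitations

* No interactive behaviour of any kind; this is a static document
  generator by design.
* Emitted SVG carries inline presentation attributes, not CSS classes for
  restyling.
* Tick placement does not avoid label collisions at very small plot sizes.
* The depictor requires meaningful 2D coordinates in the molfile; no
  coordinate generation, stereo wedges, isotopes or reaction files.
* Annotation anchoring is 1D (x only); 2D charts accept annotations but
  anchor them by x alone.
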