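# spectrachart

Static SVG charts for spectroscopy data in the life sciences: mass spectra,
1D/2D NMR, infrared and general time series.

Spectral databases and pipelines constantly need the same handful of plots,
each with its own entrenched conventions — impulse plots with m/z ascending
for MS, line traces with the ppm axis running right-to-left for NMR,
transmittance valleys against a descending wavenumber axis for IR.
`spectrachart` encodes these conventions once, in a chart-type registry,
and renders any combination of overlaid series, legend, signal labels and
annotations to a standalone, byte-deterministic SVG document. It is aimed
at anyone who needs publication- or web-ready spectrum figures from batch
jobs: no browser, no event loop, no external stylesheet.

## The core algorithm: extremum-preserving per-pixel binning

A 1D NMR spectrum can carry well over 60,000 points; a plot a few hundred
pixels wide cannot use them. For a plot of width *W* px and bin width *b*
px (default 1), the view window *[lo, hi]* is partitioned into
*n = ⌊W/b⌋* equal bins (half-open, the last closed at *hi*), and each
non-empty bin contributes exactly one **original** data point
*(x<sub>i</sub>, y<sub>i</sub>)* — the one with maximal *y* in the bin for
NMR/MS/time series, minimal *y* for IR, ties broken toward smaller *x*.
Because emitted points are members of the input, peak apex positions are
exact, the window's global extremum always survives, and the operation is
idempotent. The chart type dictates min vs max; users can only disable
binning or change the bin width.

Around this sit domain→pixel scales (linear/log10, with direction reversal
for the ppm/wavenumber axes), a declarative view-window mechanism replacing
interactive zoom, a grouped annotation framework whose tooltips render
`<key>: <value>` lines and 2D molecule depictions, and an internal
fixed-column MDL Molfile (V2000) parser feeding the depictor.

## Worked example

Overlay two synthetic 60,000-point NMR traces and render the 3-9 ppm
window:

```r
library(spectrachart)

ds <- new_dataset()
ds <- add_series(ds, sim_nmr_trace(60000, seed = 11))
ds <- add_series(ds, sim_nmr_trace(60000, seed = 12))
print(ds)
#> <st_dataset> 2 series, x [0, 10], y [-0.00842361, 1.00336]
#>   series-1: 60000 points (trace)
#>   series-2: 60000 points (trace)

svg <- render_chart(chart_spec("nmr1d"),
                    chart_options(title = "Overlay", legend = TRUE,
                                  view_window = list(x = c(3, 9))), ds)
cat(nchar(svg), "bytes of SVG\n")
#> 23106 bytes of SVG
```

The two unnamed series received the computed identifiers `series-1` and
`series-2`, which also label the legend. Each 60,000-point trace was
reduced to 706 polyline anchor points — one per pixel column of the plot
area — by max-binning against the 3-9 ppm view window, and the intensity
axis was rescaled to the data visible in that window (range-zoom
semantics). Writing `svg` to a file yields a standalone image; omitting
`view_window` shows the full spectrum.

The same render is available from a shell through the installed script:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/spectrachart.R", package="spectrachart"))')" \
  --type nmr1d --in t1.json,t2.json --out overlay.svg \
  --legend --xmin 3 --xmax 9
```

Annotations attach by nearest-x lookup; a `structure_url` column embeds a
molecule drawing parsed from a molfile:

```r
schema <- annotation_schema(c("fragment", "mz"), c("tooltip", "tooltip"))
set <- parse_annotations('[["frag", 113.0, "uracil", "113.00"]]', schema)
build_tooltip(set$annotations[[1]], schema)$lines
#> [1] "fragment: uracil" "mz: 113.00"
```

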