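# Shared golden-render definitions: every golden SVG is produced by exactly
# this fixture + option combination, end to end through generate_fixtures()
# and run_render(). scratch/make_golden.R uses the same helper to (re)write
# the committed files.

golden_cases <- function() {
  list(
    ms = list(fixture = "ms-peaks", file = "ms-peaks.json",
              params = list(n = 15L),
              options = chart_options(title = "Mass spectrum", legend = TRUE,
                                      signal_labels = TRUE,
                                      width_px = 460L, height_px = 260L)),
    nmr1d = list(fixture = "nmr-trace", file = "nmr-trace.json",
                 params = list(n_points = 4000L),
                 options = chart_options(title = "1D NMR", legend = TRUE,
                                         width_px = 420L, height_px = 260L)),
    nmr2d = list(fixture = "nmr2d-points", file = "nmr2d-points.json",
                 params = list(n_peaks = 25L),
                 options = chart_options(title = "2D NMR",
                                         width_px = 420L, height_px = 300L)),
    ir = list(fixture = "ir-trace", file = "ir-trace.json",
              params = list(n_points = 2000L),
              options = chart_options(title = "IR", width_px = 420L,
                                      height_px = 260L)),
    timeseries = list(fixture = "nmr-trace", file = "nmr-trace.json",
                      params = list(n_points = 1500L, shift_range = c(0, 60),
                                    noise_sd = 0.01),
                      options = chart_options(title = "Time series",
                                              width_px = 420L, height_px = 240L))
  )
}

render_golden <- function(type, dir) {
  case <- golden_cases()[[type]]
  do.call(generate_fixtures,
          c(list(kind = case$fixture, dir = dir, seed = 42L), case$params))
  out <- file.path(dir, paste0("golden-", type, ".svg"))
  run_render(type, file.path(dir, case$file), out, options = case$options,
             quiet = TRUE)
  out
}
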