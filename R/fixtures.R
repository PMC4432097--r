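# Seeded synthetic spectra and molfiles. These emulate the qualitative
# shape of each technique's data (discrete exponential-intensity peak lists
# for MS, dense Lorentzian-line traces for 1D NMR, transmittance baselines
# with Gaussian absorption dips for IR, cross-peak point sets for 2D NMR);
# they make no attempt at chemically meaningful peak positions.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
  }
  force(expr)
}

#' Synthetic mass-spectrum peak list
#'
#' `n` peaks at uniform random m/z positions with exponentially distributed
#' intensities, rescaled so the base peak is 100 (relative abundance).
#'
#' @param n Number of peaks.
#' @param mz_range m/z interval.
#' @param seed RNG seed for reproducibility (`NULL` leaves the RNG alone).
#' @return An `st_series` of kind `"peaks"`.
#' @export
sim_ms_peaks <- function(n = 30L, mz_range = c(50, 500), seed = NULL) {
  with_seed(seed, {
    x <- sort(stats::runif(n, mz_range[1L], mz_range[2L]))
    y <- stats::rexp(n)
    y <- y / max(y) * 100
    new_series(NULL, data.frame(x = x, y = y), kind = "peaks")
  })
}

#' Synthetic 1D NMR trace
#'
#' A dense, evenly sampled trace over the chemical-shift range: a sum of
#' `n_lines` Lorentzian lines (half-widths 0.002-0.02 ppm, exponential
#' amplitudes) plus mild Gaussian noise, mimicking the >60,000-point spectra
#' a per-pixel binner exists for.
#'
#' @param n_points Grid size (up to 1e5 is practical).
#' @param n_lines Number of Lorentzian lines.
#' @param shift_range Chemical-shift interval, ppm.
#' @param noise_sd Noise standard deviation relative to the strongest line.
#' @param seed RNG seed.
#' @return An `st_series` of kind `"trace"`.
#' @export
sim_nmr_trace <- function(n_points = 60000L, n_lines = 12L,
                          shift_range = c(0, 10), noise_sd = 0.002,
                          seed = NULL) {
  if (n_points < 2L) st_value_error("n_points must be at least 2")
  with_seed(seed, {
    x <- seq(shift_range[1L], shift_range[2L], length.out = n_points)
    centers <- stats::runif(n_lines, shift_range[1L], shift_range[2L])
    gamma <- stats::runif(n_lines, 0.002, 0.02)
    amp <- stats::rexp(n_lines)
    y <- numeric(n_points)
    for (k in seq_len(n_lines))
      y <- y + amp[k] * gamma[k]^2 / ((x - centers[k])^2 + gamma[k]^2)
    y <- y / max(y)
    y <- y + stats::rnorm(n_points, sd = noise_sd)
    new_series(NULL, data.frame(x = x, y = y), kind = "trace")
  })
}

#' Synthetic IR transmittance trace
#'
#' Transmittance baseline near 1 with Gaussian absorption dips (band widths
#' 8-60 1/cm), clipped to stay positive — the signal lives in the valleys,
#' which is why IR charts bin by the per-pixel minimum.
#'
#' @param n_points Grid size.
#' @param wavenumber_range Interval in 1/cm.
#' @param n_bands Number of absorption bands.
#' @param seed RNG seed.
#' @return An `st_series` of kind `"trace"`.
#' @export
sim_ir_trace <- function(n_points = 4000L, wavenumber_range = c(400, 4000),
                         n_bands = 15L, seed = NULL) {
  if (n_points < 2L) st_value_error("n_points must be at least 2")
  with_seed(seed, {
    x <- seq(wavenumber_range[1L], wavenumber_range[2L], length.out = n_points)
    centers <- stats::runif(n_bands, wavenumber_range[1L], wavenumber_range[2L])
    width <- stats::runif(n_bands, 8, 60)
    depth <- stats::runif(n_bands, 0.1, 0.85)
    y <- rep(1, n_points)
    for (k in seq_len(n_bands))
      y <- y - depth[k] * exp(-((x - centers[k])^2) / (2 * width[k]^2))
    y <- pmax(y, 0.02) + stats::rnorm(n_points, sd = 0.003)
    new_series(NULL, data.frame(x = x, y = y), kind = "trace")
  })
}

#' Synthetic 2D NMR cross-peak point set
#'
#' Cross peaks at random (F2, F1) chemical-shift positions with exponential
#' intensities, emulating a heteronuclear correlation (HSQC-style) spectrum.
#'
#' @param n_peaks Number of cross peaks.
#' @param f2_range F2 (x) interval, ppm.
#' @param f1_range F1 (y) interval, ppm.
#' @param seed RNG seed.
#' @return An `st_series` of kind `"points2d"`.
#' @export
sim_nmr2d_points <- function(n_peaks = 40L, f2_range = c(0, 10),
                             f1_range = c(0, 160), seed = NULL) {
  with_seed(seed, {
    x <- sort(stats::runif(n_peaks, f2_range[1L], f2_range[2L]))
    y <- stats::runif(n_peaks, f1_range[1L], f1_range[2L])
    v <- stats::rexp(n_peaks)
    new_series(NULL, data.frame(x = x, y = y, value = v), kind = "points2d")
  })
}

#' Write an MDL Molfile (V2000) from atom and bond tables
#'
#' Fixed-column V2000 writer used by the fixture corpus; round-trips through
#' [parse_molfile()].
#'
#' @param title Molecule title (header line 1).
#' @param atoms Data frame with columns `element`, `x`, `y` and optionally
#'   `charge`.
#' @param bonds Data frame with columns `a1`, `a2`, `order`.
#' @return Molfile text (single string).
#' @export
write_molfile <- function(title, atoms, bonds) {
  if (is.null(atoms$charge)) atoms$charge <- 0L
  lines <- c(title, "  spectrachart", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(atoms), nrow(bonds)))
  for (i in seq_len(nrow(atoms)))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              atoms$x[i], atoms$y[i], 0, atoms$element[i]))
  for (i in seq_len(nrow(bonds)))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              bonds$a1[i], bonds$a2[i], bonds$order[i]))
  chg <- which(atoms$charge != 0L)
  if (length(chg))
    lines <- c(lines, paste0(sprintf("M  CHG%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, atoms$charge[chg]),
                                    collapse = "")))
  paste(c(lines, "M  END"), collapse = "\n")
}

#' Molfile fixture corpus
#'
#' Small hand-authored V2000 molecules plus deliberately corrupted variants
#' for parser error-path tests:
#'
#' * `methane` — single atom, no bonds.
#' * `ethanol` — heavy-atom skeleton C-C-O, two single bonds.
#' * `benzene` — hexagon with alternating single/double bonds (6 atoms,
#'   6 bonds).
#' * `uracil` — pyrimidinedione-like six-ring with two ring nitrogens and
#'   two exocyclic carbonyl oxygens (8 atoms, 8 bonds).
#' * `corrupt_truncated` — benzene with the terminator and last lines cut.
#' * `corrupt_counts` — counts line claims an extra atom.
#' * `corrupt_v3000` — counts line tagged V3000.
#'
#' @param name Fixture name (see above).
#' @return Molfile text.
#' @export
fixture_molfile <- function(name = c("ethanol", "benzene", "uracil", "methane",
                                     "corrupt_truncated", "corrupt_counts",
                                     "corrupt_v3000")) {
  name <- match.arg(name)
  hexagon <- data.frame(
    element = rep("C", 6),
    x = cos((0:5) * pi / 3), y = sin((0:5) * pi / 3))
  benzene_bonds <- data.frame(a1 = 1:6, a2 = c(2:6, 1),
                              order = c(2L, 1L, 2L, 1L, 2L, 1L))
  benzene <- write_molfile("benzene", hexagon, benzene_bonds)
  switch(name,
    methane = write_molfile("methane",
      data.frame(element = "C", x = 0, y = 0),
      data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))),
    ethanol = write_molfile("ethanol",
      data.frame(element = c("C", "C", "O"),
                 x = c(0, 1, 1.5), y = c(0, 0, 0.866)),
      data.frame(a1 = c(1L, 2L), a2 = c(2L, 3L), order = c(1L, 1L))),
    benzene = benzene,
    uracil = {
      ring <- data.frame(
        element = c("N", "C", "N", "C", "C", "C", "O", "O"),
        x = c(cos((0:5) * pi / 3), 2 * cos(pi / 3), 2 * cos(4 * pi / 3)),
        y = c(sin((0:5) * pi / 3), 2 * sin(pi / 3), 2 * sin(4 * pi / 3)))
      write_molfile("uracil-like", ring,
        data.frame(a1 = c(1:6, 2L, 5L), a2 = c(2:6, 1L, 7L, 8L),
                   order = c(1L, 1L, 1L, 2L, 1L, 1L, 2L, 2L)))
    },
    corrupt_truncated = {
      ln <- strsplit(benzene, "\n", fixed = TRUE)[[1L]]
      paste(ln[1:(length(ln) - 4L)], collapse = "\n")
    },
    corrupt_counts = {
      ln <- strsplit(benzene, "\n", fixed = TRUE)[[1L]]
      ln[4L] <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", 7L, 6L)
      paste(ln, collapse = "\n")
    },
    corrupt_v3000 = {
      ln <- strsplit(benzene, "\n", fixed = TRUE)[[1L]]
      ln[4L] <- sub("V2000", "V3000", ln[4L], fixed = TRUE)
      paste(ln, collapse = "\n")
    })
}

#' Generate fixture files on disk
#'
#' Writes seeded synthetic inputs in the formats the renderer consumes:
#' spectrum JSON, annotation JSON or molfile text. Output is byte-identical
#' for identical seeds and parameters.
#'
#' @param kind One of `"ms-peaks"`, `"nmr-trace"`, `"ir-trace"`,
#'   `"nmr2d-points"`, `"molfile"`.
#' @param dir Output directory (created if missing).
#' @param seed RNG seed.
#' @param ... Passed to the underlying generator (`n`, `n_points`,
#'   `name`, ...).
#' @return Invisibly, the path(s) written.
#' @export
generate_fixtures <- function(kind = c("ms-peaks", "nmr-trace", "ir-trace",
                                       "nmr2d-points", "molfile"),
                              dir = ".", seed = 1L, ...) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_text <- function(path, text) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(text, con, sep = "\n", useBytes = TRUE)
    path
  }
  paths <- switch(kind,
    "ms-peaks" = write_text(file.path(dir, "ms-peaks.json"),
                            serialize_series(sim_ms_peaks(seed = seed, ...))),
    "nmr-trace" = write_text(file.path(dir, "nmr-trace.json"),
                             serialize_series(sim_nmr_trace(seed = seed, ...))),
    "ir-trace" = write_text(file.path(dir, "ir-trace.json"),
                            serialize_series(sim_ir_trace(seed = seed, ...))),
    "nmr2d-points" = write_text(file.path(dir, "nmr2d-points.json"),
                                serialize_series(sim_nmr2d_points(seed = seed, ...))),
    "molfile" = {
      args <- list(...)
      nm <- if (!is.null(args$name)) args$name else "benzene"
      vapply(nm, function(n)
        write_text(file.path(dir, paste0(n, ".mol")), fixture_molfile(n)),
        character(1L))
    })
  invisible(paths)
}
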