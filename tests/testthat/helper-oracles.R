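# Independent brute-force oracles used to cross-check the implementation.
# They deliberately use different primitives (cut/split, linear scans) than
# the production code paths.

# Per-bin extremum scan: partition [lo, hi] into n_bins intervals (half-open,
# last closed) with cut(), pick the extremal-y point per non-empty bin,
# ties toward smallest x.
oracle_bin <- function(points, window, n_bins, mode) {
  lo <- window[1L]; hi <- window[2L]
  p <- points[points$x >= lo & points$x <= hi, , drop = FALSE]
  rownames(p) <- NULL
  if (nrow(p) == 0L) return(p)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  f <- cut(p$x, breaks = breaks, right = FALSE, include.lowest = TRUE,
           labels = FALSE)
  picks <- vapply(split(seq_len(nrow(p)), f), function(ii) {
    ys <- p$y[ii]
    ext <- if (mode == "max") max(ys) else min(ys)
    cand <- ii[ys == ext]
    cand[which.min(p$x[cand])]
  }, integer(1L))
  out <- p[sort(picks), , drop = FALSE]
  out <- out[order(out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random test series: uniform or clustered x positions.
random_series_points <- function(n, clustered = FALSE, x_range = c(0, 100)) {
  x <- if (clustered) {
    centers <- runif(max(1L, n %/% 20L), x_range[1L], x_range[2L])
    sort(rnorm(n, mean = sample(centers, n, replace = TRUE), sd = 0.5))
  } else {
    sort(runif(n, x_range[1L], x_range[2L]))
  }
  data.frame(x = x, y = rnorm(n))
}

# Nearest-x linear scan for annotation anchoring.
oracle_nearest <- function(xs, lookup) {
  best <- 1L
  for (j in seq_along(xs)) {
    if (abs(xs[j] - lookup) < abs(xs[best] - lookup)) best <- j
  }
  best
}

# Brute-force strict local maxima.
oracle_local_maxima <- function(y) {
  n <- length(y)
  if (n == 1L) return(1L)
  which(vapply(seq_len(n), function(i) {
    (i == 1L || y[i] > y[i - 1L]) && (i == n || y[i] > y[i + 1L])
  }, logical(1L)))
}

read_svg <- function(text_or_path) {
  if (file.exists(text_or_path)) xml2::read_xml(text_or_path)
  else xml2::read_xml(text_or_path)
}

svg_find <- function(doc, xpath) {
  # local-name() sidesteps the SVG default namespace
  xml2::xml_find_all(doc, xpath)
}

series_groups <- function(doc) {
  svg_find(doc, "//*[local-name()='g'][@class='series']")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
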