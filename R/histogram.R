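#' Pooled FRET histogram
#'
#' Pools valid frames of a set of FRET traces into a fixed-grid histogram
#' with bin width 0.03 (the bin size used for all histograms and contour
#' maps). The support extends beyond `[0, 1]` to accommodate noise-driven
#' excursions. Frames falling outside the support are dropped.
#'
#' @param fret_traces list of `fret_trace` objects.
#' @param frame_range optional integer range `c(first, last)` restricting
#'   which frames of each trace are pooled; default all valid frames.
#' @param bin_width histogram bin width.
#' @param support histogram support (lower edge, approximate upper edge; the
#'   grid is built in whole bins from the lower edge).
#' @param per_trace_normalize logical; weight each trace equally rather than
#'   each frame (off by default - pooled unnormalized counts).
#' @return A `fret_histogram`: list with `breaks`, `mids`, `counts`,
#'   `density` (integrates to 1), `n_pooled` frames and `n_traces`.
#' @export
build_histogram <- function(fret_traces, frame_range = NULL,
                            bin_width = 0.03, support = c(-0.2, 1.2),
                            per_trace_normalize = FALSE) {
  nb <- ceiling((support[2] - support[1]) / bin_width)
  breaks <- support[1] + bin_width * (0:nb)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2

  counts <- numeric(nb)
  n_pooled <- 0L
  for (ft in fret_traces) {
    E <- ft$E
    if (!is.null(frame_range)) {
      idx <- seq(max(1L, frame_range[1]), min(length(E), frame_range[2]))
      E <- E[idx]
    }
    E <- E[!is.na(E)]
    E <- E[E >= breaks[1] & E < breaks[nb + 1]]
    if (!length(E)) next
    ci <- findInterval(E, breaks, rightmost.closed = TRUE)
    tab <- tabulate(ci, nbins = nb)
    if (per_trace_normalize) tab <- tab / sum(tab)
    counts <- counts + tab
    n_pooled <- n_pooled + length(E)
  }
  density <- if (sum(counts) > 0) counts / (sum(counts) * bin_width)
             else counts
  structure(list(breaks = breaks, mids = mids, counts = counts,
                 density = density, bin_width = bin_width,
                 n_pooled = n_pooled, n_traces = length(fret_traces)),
            class = "fret_histogram")
}

#' Time-resolved FRET population contour
#'
#' 2-D population map (frame x FRET bin) over the first `duration` seconds
#' of the recordings, as used for FRET contour plots. Each cell counts the
#' traces whose valid FRET at that frame falls in that bin; a frame's row
#' sum therefore equals the number of traces still alive (valid) there.
#'
#' @param fret_traces list of `fret_trace` objects.
#' @param duration time window from trace start, in seconds (default 5 s).
#' @inheritParams build_histogram
#' @return list with `map` (matrix frames x bins), `time_s`, `mids`.
#' @export
build_contour <- function(fret_traces, duration = 5,
                          bin_width = 0.03, support = c(-0.2, 1.2)) {
  dt <- fret_traces[[1]]$dt
  n_frames <- floor(duration / dt)
  nb <- ceiling((support[2] - support[1]) / bin_width)
  breaks <- support[1] + bin_width * (0:nb)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  map <- matrix(0L, nrow = n_frames, ncol = nb)
  for (ft in fret_traces) {
    m <- min(n_frames, length(ft$E))
    for (f in seq_len(m)) {
      e <- ft$E[f]
      if (is.na(e) || e < breaks[1] || e >= breaks[nb + 1]) next
      ci <- findInterval(e, breaks, rightmost.closed = TRUE)
      map[f, ci] <- map[f, ci] + 1L
    }
  }
  list(map = map, time_s = (seq_len(n_frames) - 0.5) * dt, mids = mids)
}
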