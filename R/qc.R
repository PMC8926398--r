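#' Detect photobleaching and blinking events in an intensity trace
#'
#' Donor bleaching and donor blinks are both "dark" episodes in which the
#' summed intensity drops to background; they are distinguished by recovery:
#' a dark run that persists to the end of the trace is the donor bleach, an
#' interior dark run with recovery afterwards is a blink. Acceptor bleaching
#' leaves the summed intensity intact (the donor un-quenches) but collapses
#' the corrected FRET to ~0; it is detected as the terminal run of the
#' median-smoothed FRET below `fret_dark_threshold` within the donor-alive
#' region.
#'
#' The FRET lifetime is the number of frames preceding the first bleach event
#' of either fluorophore (the whole trace if none).
#'
#' @param trace an `intensity_trace`.
#' @param background assumed background level (a.u.).
#' @param crosstalk leakage fraction used for the internal FRET series.
#' @param fret_dark_threshold smoothed-FRET level below which the acceptor is
#'   considered bleached; must sit well below the lowest conformational
#'   FRET center (default 0.12).
#' @param smooth_window odd window for the running median (frames).
#' @param min_acceptor_run minimum terminal run length (frames) to call an
#'   acceptor bleach.
#' @return list with `donor_bleach_frame` (first dark frame, or `NA`),
#'   `acceptor_bleach_frame` (or `NA`), `blink_intervals` (two-column matrix
#'   of first/last frame), `n_blinks`, `dark_frames` (logical) and
#'   `fret_lifetime` (frames).
#' @export
detect_bleach_frames <- function(trace, background = 0, crosstalk = 0.07,
                                 fret_dark_threshold = 0.12,
                                 smooth_window = 9L,
                                 min_acceptor_run = 5L) {
  D <- trace$donor; A <- trace$acceptor
  n <- length(D)
  tot <- D + A

  # highest sustained level, robust to early bleaching (a plain quantile
  # collapses to background when most of the trace is dead)
  live_level <- if (n >= 5L) max(stats::runmed(tot, 5L)) else max(tot)
  noise_est <- stats::mad(diff(tot)) / sqrt(2)
  thr <- background + 0.3 * (live_level - background)
  dark <- tot < thr
  if (live_level - background < 6 * noise_est || live_level <= background)
    dark <- rep(FALSE, n)  # dead or flat trace: no resolvable events

  donor_bleach <- NA_integer_
  blink <- matrix(integer(0), ncol = 2)
  r <- rle(dark)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    if (ends[j] == n) donor_bleach <- starts[j]
    else blink <- rbind(blink, c(starts[j], ends[j]))
  }

  alive_end <- if (is.na(donor_bleach)) n else donor_bleach - 1L
  dark_interior <- dark & seq_len(n) <= alive_end

  acceptor_bleach <- NA_integer_
  idx <- which(seq_len(n) <= alive_end & !dark_interior)
  if (length(idx) >= max(smooth_window, min_acceptor_run)) {
    E <- (A[idx] - crosstalk * D[idx]) / (A[idx] + D[idx])
    Es <- stats::runmed(E, k = min(smooth_window,
                                   2L * (length(idx) %/% 2L) - 1L))
    below <- Es < fret_dark_threshold
    rb <- rle(below)
    if (rb$values[length(rb$values)] &&
        rb$lengths[length(rb$values)] >= min_acceptor_run) {
      start_sub <- length(below) - rb$lengths[length(rb$values)] + 1L
      acceptor_bleach <- idx[start_sub]
    }
  }

  first <- suppressWarnings(min(donor_bleach, acceptor_bleach, na.rm = TRUE))
  lifetime <- if (is.finite(first)) first - 1L else n

  list(donor_bleach_frame = donor_bleach,
       acceptor_bleach_frame = acceptor_bleach,
       blink_intervals = blink,
       n_blinks = nrow(blink),
       dark_frames = dark_interior,
       fret_lifetime = as.integer(lifetime))
}

#' Count transient donor dark events (blinks)
#'
#' @inheritParams detect_bleach_frames
#' @return integer number of interior dark runs with recovery.
#' @export
count_donor_blinks <- function(trace, background = 0) {
  detect_bleach_frames(trace, background = background)$n_blinks
}

#' Per-trace quality statistics
#'
#' Definitions (declared, since the selection thresholds are only meaningful
#' relative to a definition):
#' * `snr`: mean pre-bleach summed intensity divided by the SD of the
#'   post-donor-bleach summed intensity (background). When the donor never
#'   bleaches, the background SD is estimated from the high-frequency
#'   component, `mad(diff(total))/sqrt(2)`.
#' * `background_noise`: the same post-bleach SD, in intensity units.
#' * `correlation`: Pearson correlation of donor and acceptor over valid
#'   (pre-bleach, non-dark) frames; anticorrelation near -1 indicates true
#'   conformational FRET rather than photophysics.
#'
#' @inheritParams detect_bleach_frames
#' @return list with `snr`, `background_noise`, `correlation`,
#'   `fret_lifetime`, `n_blinks`.
#' @export
trace_statistics <- function(trace, background = 0, crosstalk = 0.07) {
  qc <- detect_bleach_frames(trace, background = background,
                             crosstalk = crosstalk)
  n <- length(trace$donor)
  tot <- trace$donor + trace$acceptor
  first <- suppressWarnings(min(qc$donor_bleach_frame,
                                qc$acceptor_bleach_frame, na.rm = TRUE))
  pre <- seq_len(n) < min(first, n + 1L) & !qc$dark_frames

  post <- if (!is.na(qc$donor_bleach_frame) &&
              qc$donor_bleach_frame + 2L <= n)
    seq(qc$donor_bleach_frame + 2L, n) else integer(0)
  bg_sd <- if (length(post) >= 10L) stats::sd(tot[post])
           else stats::mad(diff(tot)) / sqrt(2)

  corr <- if (sum(pre) >= 3L &&
              stats::sd(trace$donor[pre]) > 0 &&
              stats::sd(trace$acceptor[pre]) > 0)
    stats::cor(trace$donor[pre], trace$acceptor[pre]) else NA_real_

  snr <- if (bg_sd > 0) mean(tot[pre]) / bg_sd else Inf
  if (!any(pre)) snr <- 0

  list(snr = snr, background_noise = bg_sd, correlation = corr,
       fret_lifetime = qc$fret_lifetime, n_blinks = qc$n_blinks)
}

#' Autotrace-style trace selection criteria
#'
#' Defaults reproduce the preselection settings used for the hHv1 datasets:
#' FRET lifetime > 50 frames, donor/acceptor correlation between -1.1 and
#' 0.5, signal-to-noise ratio > 8, background noise < 70 a.u., and fewer
#' than 4 donor (Cy3) blinks. The correlation lower bound -1.1 sits below
#' the mathematical minimum of -1 and is applied as printed (effectively -1).
#'
#' @param min_fret_lifetime_frames lifetime threshold (exclusive).
#' @param correlation_range inclusive bounds on the donor/acceptor Pearson
#'   correlation.
#' @param min_snr signal-to-noise threshold (exclusive).
#' @param max_background_noise background SD threshold (exclusive, a.u.).
#' @param max_donor_blinks blink-count threshold (exclusive).
#' @return object of class `selection_criteria`.
#' @export
selection_criteria <- function(min_fret_lifetime_frames = 50,
                               correlation_range = c(-1.1, 0.5),
                               min_snr = 8,
                               max_background_noise = 70,
                               max_donor_blinks = 4) {
  stopifnot(correlation_range[1] <= correlation_range[2],
            all(is.finite(c(min_fret_lifetime_frames, correlation_range,
                            min_snr, max_background_noise,
                            max_donor_blinks))))
  structure(list(min_fret_lifetime_frames = min_fret_lifetime_frames,
                 correlation_range = correlation_range,
                 min_snr = min_snr,
                 max_background_noise = max_background_noise,
                 max_donor_blinks = max_donor_blinks),
            class = "selection_criteria")
}

#' Select analyzable traces
#'
#' A trace is accepted iff all five criteria pass. Traces flagged in their
#' metadata as overlapping molecules (`meta$overlap` - an image-level call
#' made upstream) are rejected regardless. `keep` provides the
#' manual-curation hook: when given, only trace ids in it can be accepted.
#'
#' @param traces list of `intensity_trace` objects.
#' @param criteria a [selection_criteria()].
#' @param background,crosstalk passed to [trace_statistics()].
#' @param keep optional integer vector of trace ids to retain (manual
#'   curation keep-list).
#' @return list with `accepted` (sub-list of traces) and `report`
#'   (data.frame, one row per input trace, with each criterion's value and
#'   pass flag).
#' @export
select_traces <- function(traces, criteria = selection_criteria(),
                          background = 0, crosstalk = 0.07, keep = NULL) {
  if (!length(traces)) {
    warning("no input traces")
    return(list(accepted = list(),
                report = data.frame(trace_id = integer(0))))
  }
  rows <- lapply(seq_along(traces), function(i) {
    s <- trace_statistics(traces[[i]], background = background,
                          crosstalk = crosstalk)
    overlap <- isTRUE(traces[[i]]$meta$overlap)
    data.frame(
      trace_id = i,
      fret_lifetime = s$fret_lifetime,
      correlation = s$correlation,
      snr = s$snr,
      background_noise = s$background_noise,
      n_blinks = s$n_blinks,
      overlap = overlap,
      pass_lifetime = s$fret_lifetime > criteria$min_fret_lifetime_frames,
      pass_correlation = !is.na(s$correlation) &&
        s$correlation >= criteria$correlation_range[1] &&
        s$correlation <= criteria$correlation_range[2],
      pass_snr = s$snr > criteria$min_snr,
      pass_background = s$background_noise < criteria$max_background_noise,
      pass_blinks = s$n_blinks < criteria$max_donor_blinks)
  })
  report <- do.call(rbind, rows)
  report$accepted <- report$pass_lifetime & report$pass_correlation &
    report$pass_snr & report$pass_background & report$pass_blinks &
    !report$overlap
  if (!is.null(keep)) report$accepted <- report$accepted &
    report$trace_id %in% keep
  list(accepted = traces[report$accepted], report = report)
}
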