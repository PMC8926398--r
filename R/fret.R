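#' Crosstalk-corrected apparent FRET efficiency
#'
#' Per-frame apparent FRET with donor-to-acceptor leakage subtracted from the
#' numerator only:
#' \deqn{E = (I_A - c\, I_D) / (I_A + I_D)}
#' with leakage fraction `c` (default 0.07, the value measured from
#' donor-only samples). The denominator is deliberately not
#' leakage-corrected; this is the printed convention and makes `E`
#' scale-invariant (multiplying both channels by any gamma > 0 leaves `E`
#' unchanged).
#'
#' Frames after the first photobleach event, and frames inside donor blinks
#' (both channels at background), are masked invalid via
#' [detect_bleach_frames()]. Set `mask = FALSE` to compute `E` on every frame
#' regardless.
#'
#' @param trace an `intensity_trace`.
#' @param crosstalk leakage fraction `c`.
#' @param mask logical; apply the bleach/blink validity mask.
#' @param background assumed background level (a.u.) for dark-frame detection.
#' @return A `fret_trace`: list with `E` (per frame; `NA` where invalid),
#'   `valid` (logical mask), `dt`, `meta` and `qc` (bleach/blink detection
#'   results).
#' @export
compute_fret <- function(trace, crosstalk = 0.07, mask = TRUE,
                         background = 0) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- length(trace$donor)
  if (n == 0L) stop("zero-length trace")
  D <- trace$donor; A <- trace$acceptor
  tot <- A + D
  E <- (A - crosstalk * D) / tot
  E[tot == 0] <- NA_real_

  qc <- NULL
  valid <- rep(TRUE, n)
  if (mask) {
    qc <- detect_bleach_frames(trace, background = background)
    first_bleach <- min(qc$donor_bleach_frame, qc$acceptor_bleach_frame,
                        n + 1L, na.rm = TRUE)
    valid <- seq_len(n) < first_bleach
    valid[qc$dark_frames] <- FALSE
  }
  valid[!is.finite(E)] <- FALSE
  E[!valid] <- NA_real_

  structure(list(E = E, valid = valid, dt = trace$dt, meta = trace$meta,
                 qc = qc, source = trace),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("fret_trace: %d frames, %d valid, mean E %.3f\n",
              length(x$E), sum(x$valid),
              mean(x$E[x$valid])))
  invisible(x)
}

#' Estimate the donor-to-acceptor crosstalk fraction
#'
#' From donor-only control traces, the leakage fraction is the acceptor to
#' donor intensity ratio. Robust estimate: per trace, the median of the
#' per-frame ratio `I_A / I_D` over pre-bleach, non-dark frames; then the
#' mean of the per-trace medians. Traces whose donor signal never clears the
#' noise floor carry no information and are dropped (flagged in the result).
#'
#' @param donor_only_traces list of `intensity_trace` objects from a
#'   donor-only sample.
#' @param background assumed background level (a.u.).
#' @return list with `crosstalk` (point estimate), `se` (standard error over
#'   traces), `per_trace` (per-trace medians) and `n_dropped`.
#' @export
estimate_crosstalk <- function(donor_only_traces, background = 0) {
  per_trace <- vapply(donor_only_traces, function(tr) {
    qc <- detect_bleach_frames(tr, background = background)
    n <- length(tr$donor)
    last <- min(qc$donor_bleach_frame - 1L, n, na.rm = TRUE)
    ok <- seq_len(n) <= last & !qc$dark_frames
    D <- tr$donor[ok]; A <- tr$acceptor[ok]
    keep <- D > background + 4 * stats::mad(diff(tr$donor)) / sqrt(2)
    if (!any(keep)) keep <- D > background  # noise-free fallback
    if (!any(keep)) return(NA_real_)
    stats::median(A[keep] / D[keep])
  }, numeric(1))
  dropped <- sum(is.na(per_trace))
  est <- per_trace[!is.na(per_trace)]
  if (!length(est)) stop("no usable donor-only traces")
  list(crosstalk = mean(est),
       se = if (length(est) > 1) stats::sd(est) / sqrt(length(est)) else NA_real_,
       per_trace = per_trace,
       n_dropped = dropped)
}
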