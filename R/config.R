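#' Simulation configuration for multi-state FRET dynamics
#'
#' Bundles the kinetic scheme (emission states and inter-state rate matrix)
#' with the acquisition settings used to generate synthetic smFRET traces.
#' States are characterised by an apparent-FRET mean and a conformational
#' width (the frame-to-frame jitter of the apparent FRET within a state,
#' before any channel noise is added).
#'
#' @param states data.frame with columns `mean` (apparent FRET, in `[0, 1]`)
#'   and `sigma` (per-state FRET width, >= 0), one row per state.
#' @param rate_matrix square numeric matrix of transition rates k_ij (1/s),
#'   off-diagonal entries >= 0. The diagonal is ignored on input and set to
#'   minus the row sum so the matrix is a proper generator.
#' @param frame_interval frame duration in seconds (default 0.1 s, i.e.
#'   10 frames per second).
#' @param n_frames number of frames per trace.
#' @param n_traces number of traces in the dataset.
#' @param seed integer seed; per-trace substreams are derived from it (see
#'   [simulate_traces()]).
#'
#' @return An object of class `sim_config`.
#' @seealso [photophysics()], [simulate_traces()], [benchmark_config()]
#' @export
sim_config <- function(states, rate_matrix,
                       frame_interval = 0.1,
                       n_frames = 600L,
                       n_traces = 200L,
                       seed = 1L) {
  states <- as.data.frame(states)
  if (!all(c("mean", "sigma") %in% names(states)))
    stop("`states` needs columns `mean` and `sigma`")
  k <- nrow(states)
  if (k < 1L) stop("at least one state is required")
  if (any(!is.finite(states$mean)) || any(!is.finite(states$sigma)))
    stop("state means and widths must be finite")
  if (any(states$sigma < 0)) stop("state widths must be >= 0")

  Q <- as.matrix(rate_matrix)
  if (nrow(Q) != ncol(Q)) stop("`rate_matrix` must be square")
  if (nrow(Q) != k) stop("`rate_matrix` dimension must match number of states")
  off <- Q; diag(off) <- 0
  if (any(!is.finite(off)) || any(off < 0))
    stop("off-diagonal rates must be finite and >= 0")
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)

  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("`frame_interval` must be > 0")
  if (n_frames < 1L || n_traces < 1L)
    stop("`n_frames` and `n_traces` must be positive")

  structure(list(states = states, rate_matrix = Q,
                 frame_interval = as.numeric(frame_interval),
                 n_frames = as.integer(n_frames),
                 n_traces = as.integer(n_traces),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Photophysical parameters of the donor/acceptor pair
#'
#' Controls how a state path is rendered into two-channel fluorescence:
#' total emitted intensity, additive Gaussian channel noise, donor-to-acceptor
#' spectral crosstalk (leakage), one-way photobleaching of each fluorophore,
#' and transient donor blinking (both channels dark, with recovery).
#'
#' @param total_intensity summed donor + acceptor intensity while both
#'   fluorophores are alive (arbitrary units).
#' @param channel_noise_sd SD of the additive Gaussian noise applied
#'   independently to each channel (a.u.).
#' @param crosstalk fraction of donor emission detected in the acceptor
#'   channel; must lie in `[0, 0.5)`. Default 0.07, the value measured from
#'   donor-only samples.
#' @param donor_bleach_rate,acceptor_bleach_rate one-way Poisson bleaching
#'   rates (1/s); 0 disables bleaching.
#' @param blink_rate rate (1/s) at which the emitting donor enters a dark
#'   blink; 0 disables blinking.
#' @param blink_recovery_rate rate (1/s) of recovery from a dark blink.
#' @param background_level additive baseline in both channels (a.u.).
#'
#' @return An object of class `photophysics`.
#' @export
photophysics <- function(total_intensity = 500,
                         channel_noise_sd = 25,
                         crosstalk = 0.07,
                         donor_bleach_rate = 0.01,
                         acceptor_bleach_rate = 0.01,
                         blink_rate = 0.02,
                         blink_recovery_rate = 2,
                         background_level = 0) {
  if (total_intensity <= 0) stop("`total_intensity` must be > 0")
  if (crosstalk < 0 || crosstalk >= 0.5) stop("`crosstalk` must be in [0, 0.5)")
  rates <- c(donor_bleach_rate, acceptor_bleach_rate,
             blink_rate, blink_recovery_rate)
  if (any(rates < 0)) stop("photophysical rates must be >= 0")
  if (channel_noise_sd < 0) stop("`channel_noise_sd` must be >= 0")
  structure(list(total_intensity = total_intensity,
                 channel_noise_sd = channel_noise_sd,
                 crosstalk = crosstalk,
                 donor_bleach_rate = donor_bleach_rate,
                 acceptor_bleach_rate = acceptor_bleach_rate,
                 blink_rate = blink_rate,
                 blink_recovery_rate = blink_recovery_rate,
                 background_level = background_level),
            class = "photophysics")
}

#' Fixed apparent-FRET centers per labeling-site pair
#'
#' The three-state emission centers determined by Gaussian fits to the pooled
#' FRET histograms of each labeling-site pair, used both as generator means
#' for the synthetic benchmarks and as the fixed emission centers of the
#' kinetic model.
#'
#' @param site one of `"K169C-Q194C"` or `"K125C-S224C"`.
#' @return numeric vector of three centers, low to high.
#' @export
site_centers <- function(site = c("K169C-Q194C", "K125C-S224C")) {
  site <- match.arg(site)
  switch(site,
         "K169C-Q194C" = c(0.24, 0.52, 0.78),
         "K125C-S224C" = c(0.27, 0.60, 0.90))
}

#' Standard synthetic benchmark configuration
#'
#' The reference synthetic dataset used throughout the test suite: three
#' conformational states at the fitted centers of the requested labeling-site
#' pair, FRET width 0.05 per state, all inter-state rates 0.5 1/s, 600 frames
#' at 100 ms, 200 traces. Photophysics defaults come from [photophysics()]
#' (total intensity 500 a.u., channel noise SD 25, crosstalk 0.07, mild
#' bleaching and blinking), chosen so that typical traces pass the
#' Autotrace-style selection criteria.
#'
#' @param site labeling-site pair, see [site_centers()].
#' @param n_traces,n_frames dataset size.
#' @param rate all-pairs transition rate in 1/s.
#' @param sigma per-state FRET width.
#' @param seed integer seed.
#' @return `sim_config` object.
#' @export
benchmark_config <- function(site = "K169C-Q194C",
                             n_traces = 200L, n_frames = 600L,
                             rate = 0.5, sigma = 0.05, seed = 1L) {
  mu <- site_centers(site)
  k <- length(mu)
  Q <- matrix(rate, k, k)
  sim_config(states = data.frame(mean = mu, sigma = sigma),
             rate_matrix = Q,
             frame_interval = 0.1,
             n_frames = n_frames, n_traces = n_traces, seed = seed)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("smFRET simulation config: %d state(s), %d traces x %d frames @ %g s\n",
              nrow(x$states), x$n_traces, x$n_frames, x$frame_interval))
  cat("state means:", paste(format(x$states$mean), collapse = ", "), "\n")
  invisible(x)
}
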