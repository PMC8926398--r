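#' Stationary distribution of a rate-matrix generator
#'
#' Solves pi Q = 0 with sum(pi) = 1 by least squares on the augmented linear
#' system. An all-zero generator (no transitions possible) returns the uniform
#' distribution, any of whose components is trivially stationary.
#'
#' @param Q generator matrix (rows sum to zero).
#' @return numeric stationary probability vector.
#' @export
stationary_distribution <- function(Q) {
  k <- nrow(Q)
  if (k == 1L) return(1)
  if (all(Q == 0)) return(rep(1 / k, k))
  Qs <- Q / max(abs(diag(Q)))  # stationary vector is scale-invariant
  A <- rbind(t(Qs), rep(1, k))
  b <- c(rep(0, k), 1)
  pi0 <- tryCatch(qr.solve(A, b),
                  error = function(e) stats::lsfit(A, b,
                                                   intercept = FALSE)$coef)
  if (any(!is.finite(pi0))) pi0 <- rep(1 / k, k)
  pi0[pi0 < 0] <- 0
  if (sum(pi0) == 0) pi0 <- rep(1, k)
  pi0 / sum(pi0)
}

#' Simulate one continuous-time Markov state path
#'
#' Exact event-driven simulation of the continuous-time Markov chain defined
#' by the configuration's rate matrix: exponential dwell in the current state
#' at the total exit rate, jump probabilities proportional to the outgoing
#' rates. The initial state is drawn from the stationary distribution
#' (recordings are taken at equilibrium). The continuous path is then
#' discretised to per-frame states by the state occupying each frame's
#' midpoint.
#'
#' Uses the current RNG stream; seed upstream for reproducibility.
#'
#' @param config a [sim_config()].
#' @return A `state_path`: list with `dwells` (data.frame state/entry/exit in
#'   seconds, covering `[0, duration]`) and `frame_states` (integer per-frame
#'   state index).
#' @export
simulate_state_path <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  Q <- config$rate_matrix
  k <- nrow(Q)
  duration <- config$n_frames * config$frame_interval

  pi0 <- stationary_distribution(Q)
  s <- sample.int(k, 1L, prob = pi0)

  state <- integer(0); entry <- numeric(0); exit <- numeric(0)
  t <- 0
  while (t < duration) {
    lambda <- -Q[s, s]
    dwell <- if (lambda > 0) stats::rexp(1L, lambda) else Inf
    t_exit <- min(t + dwell, duration)
    state <- c(state, s); entry <- c(entry, t); exit <- c(exit, t_exit)
    t <- t_exit
    if (t < duration) {
      p <- Q[s, ]; p[s] <- 0
      s <- sample.int(k, 1L, prob = p)
    }
  }
  dwells <- data.frame(state = state, entry = entry, exit = exit)

  mid <- (seq_len(config$n_frames) - 0.5) * config$frame_interval
  idx <- findInterval(mid, dwells$entry)
  frame_states <- dwells$state[idx]

  structure(list(dwells = dwells, frame_states = frame_states,
                 duration = duration,
                 frame_interval = config$frame_interval),
            class = "state_path")
}

#' Render a state path into a two-channel intensity trace
#'
#' Converts per-frame apparent FRET (state mean plus per-frame Gaussian
#' conformational jitter of width sigma) into donor and acceptor intensities
#' using the emission geometry
#' \deqn{I_D = T (1 - E) / (1 + c), \quad I_A = T - I_D,}
#' where `T` is the total intensity and `c` the donor-to-acceptor crosstalk.
#' This geometry is the exact inverse of the leakage-corrected efficiency
#' `E = (I_A - c I_D) / (I_A + I_D)`, so with zero noise [compute_fret()]
#' returns each frame's apparent FRET identically.
#'
#' Photophysics: acceptor bleaching (one-way, exponential time) sets the
#' apparent FRET to 0 (leakage-only emission); donor bleaching collapses both
#' channels to background; donor blinks transiently darken both channels.
#' Additive Gaussian channel noise is applied last.
#'
#' Uses the current RNG stream.
#'
#' @param path a `state_path` from [simulate_state_path()].
#' @param states data.frame of state `mean` and `sigma`.
#' @param phys a [photophysics()] object.
#' @param frame_interval frame duration (s).
#' @param meta optional named list of condition metadata (site_pair,
#'   voltage_mV, pH_intra, pH_extra, construct, ...).
#' @return An `intensity_trace`: list with `donor`, `acceptor`, `dt`, `meta`,
#'   and a `truth` list recording the simulated frame states, bleach times
#'   and blink intervals for validation.
#' @export
render_trace <- function(path, states, phys, frame_interval = path$frame_interval,
                         meta = list()) {
  stopifnot(inherits(phys, "photophysics"))
  fs <- path$frame_states
  n <- length(fs)
  dt <- frame_interval
  tmid <- (seq_len(n) - 0.5) * dt
  Tint <- phys$total_intensity
  c <- phys$crosstalk

  E <- states$mean[fs] + stats::rnorm(n, 0, states$sigma[fs])

  t_ab <- if (phys$acceptor_bleach_rate > 0)
    stats::rexp(1L, phys$acceptor_bleach_rate) else Inf
  t_db <- if (phys$donor_bleach_rate > 0)
    stats::rexp(1L, phys$donor_bleach_rate) else Inf

  # acceptor dark after its bleach: leakage-only emission, apparent FRET 0
  E[tmid > t_ab] <- 0

  D <- Tint * (1 - E) / (1 + c)
  A <- Tint - D

  # donor blinking: alternating emitting/dark renewal process until donor bleach
  blinks <- matrix(numeric(0), ncol = 2)
  if (phys$blink_rate > 0 && phys$blink_recovery_rate > 0) {
    t <- 0
    horizon <- min(t_db, n * dt)
    repeat {
      t <- t + stats::rexp(1L, phys$blink_rate)
      if (t >= horizon) break
      dark <- stats::rexp(1L, phys$blink_recovery_rate)
      blinks <- rbind(blinks, c(t, min(t + dark, horizon)))
      t <- t + dark
      if (t >= horizon) break
    }
  }
  dark_frames <- rep(FALSE, n)
  if (nrow(blinks) > 0) {
    for (b in seq_len(nrow(blinks)))
      dark_frames <- dark_frames | (tmid > blinks[b, 1] & tmid < blinks[b, 2])
  }
  D[dark_frames] <- 0; A[dark_frames] <- 0

  post_db <- tmid > t_db
  D[post_db] <- 0; A[post_db] <- 0

  D <- D + phys$background_level
  A <- A + phys$background_level
  if (phys$channel_noise_sd > 0) {
    D <- D + stats::rnorm(n, 0, phys$channel_noise_sd)
    A <- A + stats::rnorm(n, 0, phys$channel_noise_sd)
  }

  structure(list(donor = D, acceptor = A, dt = dt, meta = meta,
                 truth = list(frame_states = fs,
                              apparent_fret = E,
                              donor_bleach_time = t_db,
                              acceptor_bleach_time = t_ab,
                              blink_intervals = blinks,
                              dark_frames = dark_frames)),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("intensity_trace: %d frames @ %g s", length(x$donor), x$dt))
  if (length(x$meta)) cat(" |", paste(names(x$meta), unlist(x$meta),
                                      sep = "=", collapse = " "))
  cat("\n")
  invisible(x)
}

# Deterministic per-trace substream seeds derived from one master seed.
trace_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a synthetic smFRET dataset
#'
#' Generates `config$n_traces` independent traces. Each trace uses its own
#' RNG substream whose seed is derived deterministically from `config$seed`
#' and the trace index, so the dataset is bit-reproducible and independent of
#' evaluation order.
#'
#' @param config a [sim_config()].
#' @param phys a [photophysics()] object.
#' @param meta named list of condition metadata copied onto every trace.
#' @return list of `intensity_trace` objects.
#' @export
simulate_traces <- function(config, phys = photophysics(), meta = list()) {
  seeds <- trace_seeds(config$seed, config$n_traces)
  lapply(seq_len(config$n_traces), function(i) {
    set.seed(seeds[i])
    path <- simulate_state_path(config)
    tr <- render_trace(path, config$states, phys, meta = meta)
    tr$meta$trace_id <- i
    tr$meta$seed <- seeds[i]
    tr
  })
}

#' Simulate donor-only control traces
#'
#' Donor-only samples are how the crosstalk (leakage) fraction is measured:
#' with no acceptor present, the acceptor channel carries only
#' `crosstalk * donor` plus noise. Donor bleaching and blinking still apply.
#'
#' @param n_traces,n_frames dataset size.
#' @param phys a [photophysics()] object.
#' @param frame_interval frame duration (s).
#' @param seed integer seed.
#' @return list of `intensity_trace` objects (no acceptor fluorophore).
#' @export
simulate_donor_only <- function(n_traces, n_frames, phys = photophysics(),
                                frame_interval = 0.1, seed = 1L) {
  seeds <- trace_seeds(seed, n_traces)
  lapply(seq_len(n_traces), function(i) {
    set.seed(seeds[i])
    n <- n_frames
    tmid <- (seq_len(n) - 0.5) * frame_interval
    Tint <- phys$total_intensity
    D <- rep(Tint, n)
    A <- phys$crosstalk * D

    t_db <- if (phys$donor_bleach_rate > 0)
      stats::rexp(1L, phys$donor_bleach_rate) else Inf
    dark <- tmid > t_db
    if (phys$blink_rate > 0 && phys$blink_recovery_rate > 0) {
      t <- 0
      horizon <- min(t_db, n * frame_interval)
      repeat {
        t <- t + stats::rexp(1L, phys$blink_rate)
        if (t >= horizon) break
        off <- stats::rexp(1L, phys$blink_recovery_rate)
        dark <- dark | (tmid > t & tmid < t + off)
        t <- t + off
        if (t >= horizon) break
      }
    }
    D[dark] <- 0; A[dark] <- 0
    D <- D + phys$background_level
    A <- A + phys$background_level
    if (phys$channel_noise_sd > 0) {
      D <- D + stats::rnorm(n, 0, phys$channel_noise_sd)
      A <- A + stats::rnorm(n, 0, phys$channel_noise_sd)
    }
    structure(list(donor = D, acceptor = A, dt = frame_interval,
                   meta = list(trace_id = i, construct = "donor-only"),
                   truth = list(donor_bleach_time = t_db,
                                dark_frames = dark)),
              class = "intensity_trace")
  })
}

#' Simulate an ACMA flux-assay fluorescence time course
#'
#' Piecewise curve mimicking the plate-reader readout of the liposome proton
#' flux assay: constant initial fluorescence F0; after valinomycin addition,
#' exponential relaxation toward the valinomycin plateau (ACMA quenching as
#' liposomes acidify through active channels); after CCCP addition,
#' relaxation toward the protonophore-defined full-quench plateau.
#'
#' @param F0 initial steady-state fluorescence (a.u.).
#' @param Fval_plateau steady-state level after valinomycin.
#' @param Fcccp_plateau steady-state level after CCCP.
#' @param decay_rate relaxation rate (1/s); 0 freezes the curve at F0.
#' @param valinomycin_time,cccp_time addition times (s).
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param duration total duration (s).
#' @param dt sampling interval (s).
#' @return data.frame with columns `time_s` and `fluorescence`.
#' @export
simulate_flux_curve <- function(F0, Fval_plateau, Fcccp_plateau,
                                decay_rate = 0.01,
                                valinomycin_time = 300, cccp_time = 2700,
                                noise_sd = 0, duration = 3600, dt = 5) {
  t <- seq(0, duration, by = dt)
  f <- rep(F0, length(t))
  if (decay_rate > 0) {
    ph2 <- t >= valinomycin_time & t < cccp_time
    f[ph2] <- Fval_plateau + (F0 - Fval_plateau) *
      exp(-decay_rate * (t[ph2] - valinomycin_time))
    f_at_cccp <- Fval_plateau + (F0 - Fval_plateau) *
      exp(-decay_rate * (cccp_time - valinomycin_time))
    ph3 <- t >= cccp_time
    f[ph3] <- Fcccp_plateau + (f_at_cccp - Fcccp_plateau) *
      exp(-decay_rate * (t[ph3] - cccp_time))
  }
  if (noise_sd > 0) f <- f + stats::rnorm(length(t), 0, noise_sd)
  data.frame(time_s = t, fluorescence = f)
}
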