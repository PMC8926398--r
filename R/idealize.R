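#' Idealize a FRET trace by Viterbi decoding
#'
#' Assigns every valid frame to a model state by the most probable state
#' path under the discretised kinetic model, giving the "idealized FRET"
#' overlay (the trace takes only the model's emission means) and the dwell
#' list used for kinetic summaries. Blink gaps split a trace into contiguous
#' valid segments; each segment is decoded independently, starting from the
#' model's stationary distribution. Exact ties in the path score are broken
#' toward the lowest state index.
#'
#' @param fret_trace a `fret_trace`.
#' @param model a [kinetic_model()].
#' @return An `idealized_trace`: list with `states` (per-frame state index,
#'   `NA` where invalid), `E_ideal` (per-frame model mean), `dwells`
#'   (data.frame `state`, `start_s`, `duration_s`, `censored_left`,
#'   `censored_right`), `loglik` (score of the decoded paths), `dt`, `meta`.
#' @export
viterbi_idealize <- function(fret_trace, model) {
  E <- fret_trace$E
  n <- length(E)
  k <- length(model$means)
  P <- discretize(model)
  logP <- log(P)
  pi0 <- stationary_distribution(model$Q)
  logpi <- log(pi0)

  states <- rep(NA_integer_, n)
  loglik <- 0
  valid <- fret_trace$valid & !is.na(E)

  r <- rle(valid)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (seg in which(r$values)) {
    idx <- starts[seg]:ends[seg]
    e <- E[idx]
    m <- length(idx)
    logB <- vapply(seq_len(k), function(j)
      stats::dnorm(e, model$means[j], model$sigmas[j], log = TRUE),
      numeric(m))
    logB <- matrix(logB, nrow = m)
    delta <- matrix(-Inf, m, k)
    psi <- matrix(1L, m, k)
    delta[1, ] <- logpi + logB[1, ]
    if (m > 1) for (t in 2:m) {
      for (j in seq_len(k)) {
        cand <- delta[t - 1, ] + logP[, j]
        best <- which.max(cand)  # first index on ties -> lowest state wins
        psi[t, j] <- best
        delta[t, j] <- cand[best] + logB[t, j]
      }
    }
    path <- integer(m)
    path[m] <- which.max(delta[m, ])
    if (m > 1) for (t in (m - 1):1) path[t] <- psi[t + 1, path[t + 1]]
    states[idx] <- path
    loglik <- loglik + max(delta[m, ])
  }

  dwells <- dwell_list(states, fret_trace$dt)
  structure(list(states = states,
                 E_ideal = ifelse(is.na(states), NA_real_,
                                  model$means[states]),
                 dwells = dwells, loglik = loglik,
                 dt = fret_trace$dt, meta = fret_trace$meta,
                 model = model),
            class = "idealized_trace")
}

# dwell list from a per-frame state vector; censoring marks dwells that
# touch a segment boundary (their true duration is unobserved)
dwell_list <- function(states, dt) {
  n <- length(states)
  valid <- !is.na(states)
  out <- list()
  r <- rle(valid)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (seg in which(r$values)) {
    idx <- starts[seg]:ends[seg]
    rs <- rle(states[idx])
    de <- cumsum(rs$lengths); ds <- de - rs$lengths + 1L
    nd <- length(rs$values)
    out[[length(out) + 1L]] <- data.frame(
      state = rs$values,
      start_s = (idx[ds] - 1) * dt,
      duration_s = rs$lengths * dt,
      censored_left = seq_len(nd) == 1L,
      censored_right = seq_len(nd) == nd)
  }
  if (!length(out))
    return(data.frame(state = integer(0), start_s = numeric(0),
                      duration_s = numeric(0), censored_left = logical(0),
                      censored_right = logical(0)))
  do.call(rbind, out)
}

#' Dwell-time summaries of an idealized trace set
#'
#' Pools dwell durations per state across traces. Dwells that touch a
#' segment boundary (start of recording, bleach, blink gap) are censored and
#' excluded from the mean, which otherwise estimates `1 / sum of exit
#' rates` up to missed-event bias at the frame resolution.
#'
#' @param idealized list of `idealized_trace` objects (or a single one).
#' @param n_states number of model states (defaults to the model of the
#'   first trace).
#' @return list with `mean_dwell_s` (per state; `NA` if no complete dwell),
#'   `n_dwells` (complete dwells per state), `dwells` (pooled data.frame
#'   including censored ones).
#' @export
dwell_statistics <- function(idealized, n_states = NULL) {
  if (inherits(idealized, "idealized_trace")) idealized <- list(idealized)
  if (is.null(n_states)) n_states <- length(idealized[[1]]$model$means)
  pooled <- do.call(rbind, lapply(idealized, `[[`, "dwells"))
  complete <- pooled[!pooled$censored_left & !pooled$censored_right, ,
                     drop = FALSE]
  mean_dwell <- rep(NA_real_, n_states)
  n_dwells <- integer(n_states)
  for (s in seq_len(n_states)) {
    d <- complete$duration_s[complete$state == s]
    n_dwells[s] <- length(d)
    if (length(d)) mean_dwell[s] <- mean(d)
  }
  list(mean_dwell_s = mean_dwell, n_dwells = n_dwells, dwells = pooled)
}
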