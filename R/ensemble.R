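#' State occupancies across traces
#'
#' Per trace, the fraction of valid frames spent in each conformational
#' state; frames assigned to the `F_B` bleach/blink state are dropped and
#' the remaining fractions renormalized to sum to 1 (the sink state's
#' occupancy is negligible by design and it is excluded from kinetic
#' summaries). The ensemble value is the mean across traces with its
#' standard error, `N` being the number of traces that contribute at least
#' one valid frame.
#'
#' @param idealized list of `idealized_trace` objects.
#' @param condition optional named list of condition metadata attached to
#'   the result.
#' @return An `occupancy_stats`: list with `mean`, `se` (per conformational
#'   state), `n_traces`, `per_trace` (matrix traces x states), `condition`.
#' @export
occupancies <- function(idealized, condition = list()) {
  model <- idealized[[1]]$model
  k <- length(model$means)
  conf <- setdiff(seq_len(k), model$bleach_state)
  occ <- t(vapply(idealized, function(it) {
    st <- it$states[!is.na(it$states)]
    st <- st[st %in% conf]
    if (!length(st)) return(rep(NA_real_, length(conf)))
    tabulate(match(st, conf), nbins = length(conf)) / length(st)
  }, numeric(length(conf))))
  occ <- occ[stats::complete.cases(occ), , drop = FALSE]
  n <- nrow(occ)
  structure(list(mean = colMeans(occ),
                 se = apply(occ, 2, stats::sd) / sqrt(n),
                 n_traces = n,
                 per_trace = occ,
                 states = model$means[conf],
                 condition = condition),
            class = "occupancy_stats")
}

#' @export
print.occupancy_stats <- function(x, ...) {
  cat(sprintf("occupancies over N=%d traces:\n", x$n_traces))
  print(data.frame(state_mean = round(x$states, 3),
                   occupancy = round(x$mean, 3),
                   se = round(x$se, 4)))
  invisible(x)
}

#' Compare state occupancies between two conditions
#'
#' Unpaired two-sample Welch t-test on the per-trace occupancies of each
#' state, reported with the conventional significance stars (`*` p < 0.05,
#' `**` p < 0.01). No multiple-testing correction is applied across states
#' (per-state stars, as conventionally reported); interpret accordingly.
#' Degenerate zero-variance inputs are handled directly: equal means give
#' p = 1, different means p = 0.
#'
#' @param occA,occB `occupancy_stats` from [occupancies()] for the two
#'   conditions.
#' @return data.frame with per-state means, difference, `p_value`, `stars`.
#' @export
compare_occupancies <- function(occA, occB) {
  k <- ncol(occA$per_trace)
  stopifnot(ncol(occB$per_trace) == k)
  res <- lapply(seq_len(k), function(j) {
    a <- occA$per_trace[, j]; b <- occB$per_trace[, j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
      p <- stats::t.test(a, b, var.equal = FALSE)$p.value
    }
    data.frame(state = j, mean_A = mean(a), mean_B = mean(b),
               diff = mean(b) - mean(a), p_value = p,
               stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "")
  })
  do.call(rbind, res)
}

#' Transition density plot (TDP)
#'
#' 2-D histogram over (FRET before transition, FRET after transition) for
#' every transition in the idealized traces, using the model's emission
#' means as coordinates (so the mass concentrates in discrete blobs, one
#' per ordered state pair). Transitions into or out of the `F_B` sink are
#' excluded by default. The diagonal carries no mass by construction and
#' the total mass equals the number of idealized transitions.
#'
#' @param idealized list of `idealized_trace` objects.
#' @param bin_width histogram bin width (default 0.03).
#' @param support FRET axis range.
#' @param include_bleach logical; count transitions involving `F_B`.
#' @return list with `map` (matrix before x after), `mids`, `n_transitions`,
#'   `pair_counts` (data.frame from-state, to-state, count).
#' @export
transition_density <- function(idealized, bin_width = 0.03,
                               support = c(-0.2, 1.2),
                               include_bleach = FALSE) {
  model <- idealized[[1]]$model
  k <- length(model$means)
  conf <- if (include_bleach) seq_len(k)
          else setdiff(seq_len(k), model$bleach_state)

  from <- integer(0); to <- integer(0)
  for (it in idealized) {
    d <- it$dwells
    if (nrow(d) < 2) next
    # consecutive dwells within the same segment are transitions
    same_seg <- d$start_s[-1] - (d$start_s[-nrow(d)] +
                                 d$duration_s[-nrow(d)]) < it$dt / 2
    f <- d$state[-nrow(d)][same_seg]
    t2 <- d$state[-1][same_seg]
    keep <- f %in% conf & t2 %in% conf
    from <- c(from, f[keep]); to <- c(to, t2[keep])
  }

  nb <- ceiling((support[2] - support[1]) / bin_width)
  breaks <- support[1] + bin_width * (0:nb)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  map <- matrix(0L, nb, nb)
  if (length(from)) {
    bi <- findInterval(model$means[from], breaks, rightmost.closed = TRUE)
    bj <- findInterval(model$means[to], breaks, rightmost.closed = TRUE)
    for (t in seq_along(bi)) map[bi[t], bj[t]] <- map[bi[t], bj[t]] + 1L
  }
  pair_counts <- if (length(from))
    as.data.frame(table(from = from, to = to), stringsAsFactors = FALSE)
  else data.frame(from = integer(0), to = integer(0), Freq = integer(0))
  list(map = map, mids = mids, n_transitions = length(from),
       pair_counts = pair_counts)
}

#' Equilibrium constants from fitted rate constants
#'
#' For each transition pair, `K_eq = K_F / K_R` with `K_F` the forward and
#' `K_R` the reverse fitted rate. "Forward" is the direction given in the
#' `direction` map, conventionally toward the state enriched by activation
#' at the labeling site under study; the default maps low->medium (LM),
#' medium->high (MH) and low->high (LH) among three conformational states.
#'
#' @param model fitted [kinetic_model()].
#' @param direction named list of length-2 integer vectors
#'   `c(from, to)` in conformational-state indices (low = 1).
#' @param condition optional condition metadata attached to the result.
#' @return data.frame with `pair`, `K_F`, `K_R`, `K_eq` (and condition
#'   columns if given).
#' @export
equilibrium_constants <- function(model,
                                  direction = list(LM = c(1L, 2L),
                                                   MH = c(2L, 3L),
                                                   LH = c(1L, 3L)),
                                  condition = list()) {
  conf <- setdiff(seq_along(model$means), model$bleach_state)
  res <- lapply(names(direction), function(nm) {
    ij <- conf[direction[[nm]]]
    kf <- model$Q[ij[1], ij[2]]
    kr <- model$Q[ij[2], ij[1]]
    data.frame(pair = nm, K_F = kf, K_R = kr,
               K_eq = if (kr > 0) kf / kr else NA_real_)
  })
  out <- do.call(rbind, res)
  for (nm in names(condition)) out[[nm]] <- condition[[nm]]
  out
}
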