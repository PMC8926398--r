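#' Hidden-Markov kinetic model with Gaussian FRET emissions
#'
#' The kinetic scheme used for idealization: a small set of conformational
#' FRET states (low/medium/high for the three-state sites), optionally
#' augmented with a bleach/blink sink state `F_B` near FRET 0 that absorbs
#' dark or acceptor-dark excursions the trace selection did not remove.
#' Emission from state `i` is Gaussian with mean `means[i]` and width
#' `sigmas[i]`; dynamics are a continuous-time rate matrix discretised at
#' the frame interval.
#'
#' @param means per-state apparent-FRET emission means. With
#'   `bleach_state = TRUE` a final state with mean 0.05 and width 0.08 is
#'   appended automatically.
#' @param sigmas per-state emission widths (recycled if length 1).
#' @param rates square rate matrix (1/s); the diagonal is recomputed as the
#'   negative row sum.
#' @param frame_interval frame duration (s).
#' @param bleach_state logical; append the `F_B` bleach/blink state. Its
#'   connectivity in [mpl_fit()] is a single shared entry rate from every
#'   conformational state and a single total exit rate.
#' @return object of class `kinetic_model` with elements `means`, `sigmas`,
#'   `Q`, `dt`, `bleach_state` (index or `NA`), `n_conf`.
#' @export
kinetic_model <- function(means, sigmas = 0.05, rates = NULL,
                          frame_interval = 0.1, bleach_state = FALSE) {
  means <- as.numeric(means)
  n_conf <- length(means)
  sigmas <- rep_len(as.numeric(sigmas), n_conf)
  if (isTRUE(bleach_state)) {
    means <- c(means, 0.05)
    sigmas <- c(sigmas, 0.08)
  }
  k <- length(means)
  if (is.null(rates)) rates <- matrix(0.1, k, k)
  Q <- as.matrix(rates)
  if (nrow(Q) != k || ncol(Q) != k)
    stop("`rates` must be ", k, "x", k)
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be >= 0")
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(list(means = means, sigmas = sigmas, Q = Q,
                 dt = frame_interval,
                 bleach_state = if (isTRUE(bleach_state)) k else NA_integer_,
                 n_conf = n_conf),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("kinetic_model: %d conformational state(s)%s, dt=%g s\n",
              x$n_conf,
              if (!is.na(x$bleach_state)) " + F_B" else "", x$dt))
  cat("means:", paste(format(x$means), collapse = ", "), "\n")
  cat("rates (1/s):\n"); print(round(x$Q, 4))
  invisible(x)
}

#' Per-frame transition probability matrix
#'
#' Discretises the generator at the frame interval, `P = expm(Q dt)`. Tiny
#' negative entries from the numerical exponential are clamped and rows
#' renormalized to sum to 1.
#'
#' @param model a [kinetic_model()].
#' @return stochastic matrix of per-frame transition probabilities.
#' @export
discretize <- function(model) {
  P <- as.matrix(Matrix::expm(model$Q * model$dt))
  P[P < 0] <- 0
  P / rowSums(P)
}

# FRET traces -> NA-padded matrix (n_traces x max_frames); NA marks invalid
# or missing frames, which contribute emission probability 1 (no information)
fret_matrix <- function(fret_traces) {
  lens <- vapply(fret_traces, function(f) length(f$E), integer(1))
  M <- matrix(NA_real_, length(fret_traces), max(lens))
  for (i in seq_along(fret_traces)) {
    E <- fret_traces[[i]]$E
    E[!fret_traces[[i]]$valid] <- NA_real_
    M[i, seq_along(E)] <- E
  }
  M
}

#' Forward-algorithm log-likelihood of FRET traces under a kinetic model
#'
#' Scaled forward recursion with Gaussian emissions, vectorised across
#' traces. Invalid/missing frames contribute no emission information but the
#' chain still propagates through them. The initial distribution defaults to
#' the stationary distribution of the generator (equilibrium recordings).
#'
#' @param fret_traces list of `fret_trace` objects, or a numeric matrix of
#'   per-frame FRET values (traces x frames, `NA` = missing).
#' @param model a [kinetic_model()].
#' @param pi0 optional initial state distribution.
#' @return total log-likelihood (sum over traces).
#' @export
forward_loglik <- function(fret_traces, model, pi0 = NULL) {
  E_mat <- if (is.matrix(fret_traces)) fret_traces
           else fret_matrix(fret_traces)
  P <- discretize(model)
  if (is.null(pi0)) pi0 <- stationary_distribution(model$Q)
  forward_core(E_mat, model$means, model$sigmas, P, pi0)
}

forward_core <- function(E_mat, means, sigmas, P, pi0) {
  n <- nrow(E_mat); k <- length(means); Tn <- ncol(E_mat)
  alpha <- matrix(pi0, n, k, byrow = TRUE)
  ll <- numeric(n)
  tiny <- .Machine$double.xmin
  for (t in seq_len(Tn)) {
    if (t > 1L) alpha <- alpha %*% P
    e <- E_mat[, t]
    obs <- which(!is.na(e))
    if (length(obs)) {
      B <- matrix(1, n, k)
      for (j in seq_len(k))
        B[obs, j] <- stats::dnorm(e[obs], means[j], sigmas[j])
      alpha <- alpha * B
    }
    cs <- rowSums(alpha)
    bad <- !is.finite(cs) | cs <= 0
    if (any(bad)) {
      cs[bad] <- tiny
      alpha[bad, ] <- tiny / k
    }
    ll <- ll + log(cs)
    alpha <- alpha / cs
  }
  sum(ll)
}

# Free-parameter layout for mpl_fit: log rates of the free edges plus
# (optionally) softplus-floored emission widths for conformational states.
mpl_edges <- function(model) {
  k <- length(model$means)
  if (is.na(model$bleach_state)) {
    idx <- which(row(matrix(0, k, k)) != col(matrix(0, k, k)))
    list(type = "free", idx = idx)
  } else {
    b <- model$bleach_state
    conf <- setdiff(seq_len(k), b)
    m <- matrix(0, k, k)
    idx <- which(row(m) != col(m) & row(m) != b & col(m) != b)
    list(type = "bleach", idx = idx, b = b, conf = conf)
  }
}

build_Q <- function(model, edges, rates_free, k_b_in = NULL, k_b_out = NULL) {
  k <- length(model$means)
  Q <- matrix(0, k, k)
  Q[edges$idx] <- rates_free
  if (edges$type == "bleach") {
    Q[edges$conf, edges$b] <- k_b_in
    Q[edges$b, edges$conf] <- k_b_out / length(edges$conf)
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Fit rate constants by direct likelihood maximisation (MPL-style)
#'
#' Maximises the summed forward log-likelihood of the FRET traces over the
#' rate constants of the kinetic model, with the emission centers held fixed
#' (so datasets from different conditions share one emission model and only
#' their kinetics differ). Rates are optimised in log space, which keeps
#' them positive without explicit constraints; emission widths can be
#' co-fitted (shared across conformational states or per state) with a hard
#' floor of 0.01 to avoid degenerate spikes. When the model carries an
#' `F_B` bleach/blink state, its emission is frozen and its connectivity is
#' reduced to one shared entry rate and one total exit rate.
#'
#' @param fret_traces list of `fret_trace` objects.
#' @param model0 starting [kinetic_model()]; its means are the fixed
#'   emission centers.
#' @param fit_sigma logical; co-fit the conformational emission widths.
#' @param sigma_shared logical; one shared width for all conformational
#'   states (default) or one per state.
#' @param maxit optimizer iteration cap.
#' @return list with `model` (fitted), `loglik`, `loglik0` (at start),
#'   `convergence` (0 = converged), `counts` (function/gradient
#'   evaluations).
#' @export
mpl_fit <- function(fret_traces, model0, fit_sigma = TRUE,
                    sigma_shared = TRUE, maxit = 200L) {
  E_mat <- fret_matrix(fret_traces)
  edges <- mpl_edges(model0)
  k <- length(model0$means)
  means <- model0$means
  sig_floor <- 0.01

  r0 <- pmax(model0$Q[edges$idx], 1e-3)
  par0 <- log(r0)
  if (edges$type == "bleach") {
    kb_in0 <- pmax(mean(model0$Q[edges$conf, edges$b]), 1e-4)
    kb_out0 <- pmax(sum(model0$Q[edges$b, edges$conf]), 1e-4)
    par0 <- c(par0, log(kb_in0), log(kb_out0))
  }
  n_rate_par <- length(par0)
  conf <- if (edges$type == "bleach") edges$conf else seq_len(k)
  if (fit_sigma) {
    s0 <- if (sigma_shared) mean(model0$sigmas[conf]) else model0$sigmas[conf]
    par0 <- c(par0, log(pmax(s0 - sig_floor, 1e-4)))
  }

  unpack <- function(par) {
    rates_free <- exp(par[seq_along(edges$idx)])
    if (edges$type == "bleach") {
      kb <- exp(par[length(edges$idx) + 1:2])
      Q <- build_Q(model0, edges, rates_free, kb[1], kb[2])
    } else Q <- build_Q(model0, edges, rates_free)
    sig <- model0$sigmas
    if (fit_sigma) {
      sp <- sig_floor + exp(par[(n_rate_par + 1):length(par)])
      sig[conf] <- if (sigma_shared) sp[1] else sp
    }
    list(Q = Q, sigmas = sig)
  }

  negll <- function(par) {
    u <- unpack(par)
    P <- as.matrix(Matrix::expm(u$Q * model0$dt))
    P[P < 0] <- 0; P <- P / rowSums(P)
    pi0 <- stationary_distribution(u$Q)
    ll <- forward_core(E_mat, means, u$sigmas, P, pi0)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # rates above ~2/dt are unresolvable at the frame interval; bounding the
  # log-rates keeps unidentifiable edges (e.g. F_B exit when no dark frames
  # survive masking) from running away numerically
  rate_hi <- log(2 / model0$dt)
  lower <- c(rep(log(1e-4), n_rate_par),
             rep(log(1e-4), length(par0) - n_rate_par))
  upper <- c(rep(rate_hi, n_rate_par),
             rep(log(1), length(par0) - n_rate_par))
  ll0 <- -negll(par0)
  opt <- stats::optim(par0, negll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = 1e9))
  u <- unpack(opt$par)
  fitted <- model0
  fitted$Q <- u$Q
  fitted$sigmas <- u$sigmas
  list(model = fitted, loglik = -opt$value, loglik0 = ll0,
       convergence = opt$convergence, counts = opt$counts)
}
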