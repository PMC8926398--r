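# Gaussian mixture model of a FRET histogram, fitted by least squares on the
# binned density (the histogram is the fitted object, not the per-frame
# likelihood); SSE over bins is the model-selection objective.

mixture_density <- function(x, centers, sigmas, weights) {
  y <- numeric(length(x))
  for (j in seq_along(centers))
    y <- y + weights[j] * stats::dnorm(x, centers[j], sigmas[j])
  y
}

# quantile-style initial centers from the histogram's empirical CDF
hist_quantile_centers <- function(hist, k) {
  cdf <- cumsum(hist$counts) / sum(hist$counts)
  probs <- (2 * seq_len(k) - 1) / (2 * k)
  vapply(probs, function(p) hist$mids[which(cdf >= p)[1]], numeric(1))
}

#' Fit a sum of Gaussians to a FRET histogram
#'
#' Least-squares fit of a `k`-component Gaussian mixture to the histogram
#' density: the objective is `SSE = sum over bins (density - model)^2`.
#' Optimization is multistart L-BFGS-B: initial centers at the k-quantiles
#' of the pooled FRET values (plus jittered restarts drawn from the current
#' RNG stream), widths started at 0.05, weights uniform. The best SSE over
#' restarts is kept; components are returned sorted by center.
#'
#' @param hist a [build_histogram()] result.
#' @param k number of components (1-5 is the intended range).
#' @param fixed_centers optional numeric vector of length `k`; when given,
#'   the centers are frozen and only widths and weights are optimized.
#' @param restarts number of jittered restarts beyond the quantile start.
#' @param init optional full warm start: list with `centers`, `sigmas`,
#'   `weights` (used in addition to the quantile start).
#' @return A `mixture_fit`: list with `k`, `centers`, `sigmas`, `weights`
#'   (mixture proportions), `sse`, `converged`.
#' @export
fit_mixture <- function(hist, k, fixed_centers = NULL, restarts = 10L,
                        init = NULL) {
  stopifnot(k >= 1L)
  x <- hist$mids; y <- hist$density
  lo_mu <- hist$breaks[1]; hi_mu <- hist$breaks[length(hist$breaks)]

  fixed <- !is.null(fixed_centers)
  if (fixed && length(fixed_centers) != k)
    stop("`fixed_centers` must have length k")

  obj <- function(par) {
    if (fixed) {
      mu <- fixed_centers
      sg <- par[seq_len(k)]; w <- par[k + seq_len(k)]
    } else {
      mu <- par[seq_len(k)]
      sg <- par[k + seq_len(k)]; w <- par[2 * k + seq_len(k)]
    }
    sum((y - mixture_density(x, mu, sg, w))^2)
  }

  make_par <- function(mu, sg, w) if (fixed) c(sg, w) else c(mu, sg, w)
  lower <- make_par(rep(lo_mu, k), rep(0.005, k), rep(0, k))
  upper <- make_par(rep(hi_mu, k), rep(0.5, k), rep(10, k))

  mu0 <- if (fixed) fixed_centers else hist_quantile_centers(hist, k)
  starts <- list(make_par(mu0, rep(0.05, k), rep(1 / k, k)))
  if (!is.null(init))
    starts <- c(starts, list(make_par(init$centers, init$sigmas,
                                      init$weights)))
  for (r in seq_len(restarts)) {
    mu_r <- pmin(pmax(mu0 + stats::rnorm(k, 0, 0.05), lo_mu), hi_mu)
    sg_r <- stats::runif(k, 0.02, 0.12)
    starts <- c(starts, list(make_par(mu_r, sg_r, rep(1 / k, k))))
  }

  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("mixture fit failed from every start")
  if (best$convergence != 0) {
    # polish the winning start so the convergence flag reflects the optimum
    polish <- tryCatch(
      stats::optim(best$par, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 2000)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value) best <- polish
  }

  par <- best$par
  if (fixed) {
    mu <- fixed_centers; sg <- par[seq_len(k)]; w <- par[k + seq_len(k)]
  } else {
    mu <- par[seq_len(k)]; sg <- par[k + seq_len(k)]
    w <- par[2 * k + seq_len(k)]
  }
  ord <- order(mu)
  structure(list(k = k, centers = mu[ord], sigmas = sg[ord],
                 weights = w[ord], sse = best$value,
                 converged = best$convergence == 0),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: k=%d, SSE=%.4g%s\n", x$k, x$sse,
              if (x$converged) "" else " (not converged)"))
  print(data.frame(center = round(x$centers, 3),
                   sigma = round(x$sigmas, 3),
                   weight = round(x$weights, 3)))
  invisible(x)
}

#' Choose the number of FRET states by SSE reduction
#'
#' Fits mixtures with 1 to `kmax` components and reports, for each `k`, the
#' percent reduction in SSE relative to the one-component fit,
#' `100 (SSE_1 - SSE_k) / SSE_1`. The selected `k*` is the smallest `k`
#' whose reduction reaches `reduction_threshold` (95% by default) while the
#' further gain from `k` to `k+1` stays below `elbow_points` percentage
#' points. Two guards make the rule total: if the single-Gaussian fit
#' already explains more than 98% of the histogram's total sum of squares,
#' the data are unimodal and `k* = 1`; if no `k` reaches the reduction
#' threshold, the elbow alone decides.
#'
#' Each fit after the first is warm-started from the previous best fit plus
#' a small component at the largest positive residual, which keeps the SSE
#' sequence non-increasing in `k` (nested models from common starts).
#'
#' @param hist a [build_histogram()] result.
#' @param kmax largest component count tried.
#' @param reduction_threshold percent SSE reduction demanded of `k*`.
#' @param elbow_points maximum further gain (percentage points) tolerated
#'   beyond `k*`.
#' @param restarts per-fit restarts, see [fit_mixture()].
#' @return list with `k_star`, `table` (data.frame `k`, `sse`,
#'   `reduction_pct`), `fits` (list of `mixture_fit`), `r2_k1` (fraction of
#'   total SS explained by the 1-component fit).
#' @export
select_state_number <- function(hist, kmax = 5L, reduction_threshold = 95,
                                elbow_points = 2, restarts = 10L) {
  fits <- vector("list", kmax)
  fits[[1]] <- fit_mixture(hist, 1L, restarts = restarts)
  for (k in seq(2L, kmax)) {
    prev <- fits[[k - 1]]
    resid <- hist$density - mixture_density(hist$mids, prev$centers,
                                            prev$sigmas, prev$weights)
    warm <- list(centers = c(prev$centers, hist$mids[which.max(resid)]),
                 sigmas = c(prev$sigmas, 0.05),
                 weights = c(prev$weights, 1e-3))
    fits[[k]] <- fit_mixture(hist, k, restarts = restarts, init = warm)
  }
  sse <- vapply(fits, `[[`, numeric(1), "sse")
  reduction <- 100 * (sse[1] - sse) / sse[1]

  sst <- sum((hist$density - mean(hist$density))^2)
  r2_k1 <- 1 - sse[1] / sst

  gain_next <- c(reduction[-1] - reduction[-kmax], 0)
  if (r2_k1 > 0.98) {
    k_star <- 1L
  } else {
    ok <- reduction >= reduction_threshold & gain_next < elbow_points
    if (any(ok)) k_star <- which(ok)[1]
    else {
      elbow <- which(gain_next < elbow_points)
      k_star <- if (length(elbow)) elbow[1] else kmax
    }
  }
  list(k_star = as.integer(k_star),
       table = data.frame(k = seq_len(kmax), sse = sse,
                          reduction_pct = reduction),
       fits = fits, r2_k1 = r2_k1)
}
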