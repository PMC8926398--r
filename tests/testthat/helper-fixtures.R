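# Shared fixtures and independent oracles for the test suite.

# photophysics with a switchable subset of effects disabled
clean_phys <- function(channel_noise_sd = 0, donor_bleach_rate = 0,
                       acceptor_bleach_rate = 0, blink_rate = 0, ...) {
  photophysics(channel_noise_sd = channel_noise_sd,
               donor_bleach_rate = donor_bleach_rate,
               acceptor_bleach_rate = acceptor_bleach_rate,
               blink_rate = blink_rate, ...)
}

# small benchmark dataset (defaults scaled down from the 200 x 600 standard)
mini_benchmark <- function(site = "K169C-Q194C", n_traces = 40L,
                           n_frames = 300L, seed = 101L,
                           phys = photophysics()) {
  cfg <- benchmark_config(site, n_traces = n_traces, n_frames = n_frames,
                          seed = seed)
  simulate_traces(cfg, phys)
}

# hand-built intensity trace
make_trace <- function(donor, acceptor, dt = 0.1, meta = list()) {
  structure(list(donor = donor, acceptor = acceptor, dt = dt, meta = meta,
                 truth = NULL),
            class = "intensity_trace")
}

# independent matrix exponential via eigendecomposition (oracle; the
# implementation uses Matrix::expm)
expm_eigen <- function(Q, t) {
  ev <- eigen(Q)
  Re(ev$vectors %*% diag(exp(ev$values * t), nrow(Q)) %*% solve(ev$vectors))
}

# brute-force HMM likelihood: enumerate every state path (oracle for the
# forward recursion; only usable at toy sizes)
brute_force_lik <- function(E, means, sigmas, P, pi0) {
  k <- length(means)
  n <- length(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- pi0[s[1]] * stats::dnorm(E[1], means[s[1]], sigmas[s[1]])
    if (n > 1) for (t in 2:n)
      p <- p * P[s[t - 1], s[t]] * stats::dnorm(E[t], means[s[t]], sigmas[s[t]])
    tot <- tot + p
  }
  tot
}

# minimal occupancy_stats carrier for compare_occupancies tests
fake_occ <- function(per_trace) {
  structure(list(per_trace = per_trace, mean = colMeans(per_trace),
                 se = apply(per_trace, 2, stats::sd) / sqrt(nrow(per_trace)),
                 n_traces = nrow(per_trace)),
            class = "occupancy_stats")
}
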