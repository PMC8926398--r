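test_that("discretization matches the closed-form matrix exponential", {
  # zero rates: identity
  m0 <- kinetic_model(c(0.2, 0.8), rates = matrix(0, 2, 2))
  expect_equal(discretize(m0), diag(2), tolerance = 1e-12)

  # symmetric 2-state, k = 1/s, dt = 0.1: off-diagonal (1 - e^-0.2)/2
  m1 <- kinetic_model(c(0.2, 0.8), rates = matrix(1, 2, 2))
  P <- discretize(m1)
  off <- (1 - exp(-0.2)) / 2
  expect_equal(P, matrix(c(1 - off, off, off, 1 - off), 2, 2),
               tolerance = 1e-10)

  # rows sum to one for an arbitrary generator
  set.seed(301)
  Q <- matrix(runif(16, 0, 2), 4, 4)
  m2 <- kinetic_model(c(0.1, 0.4, 0.6, 0.9), rates = Q)
  expect_equal(rowSums(discretize(m2)), rep(1, 4), tolerance = 1e-12)
})

test_that("forward likelihood equals brute-force path enumeration", {
  means <- c(0.3, 0.7); sigmas <- c(0.06, 0.09)
  model <- kinetic_model(means, sigmas,
                         rates = matrix(c(0, 1.2, 0.7, 0), 2, 2,
                                        byrow = TRUE))
  P <- discretize(model)
  pi0 <- stationary_distribution(model$Q)
  set.seed(311)
  for (rep in 1:3) {
    E <- runif(5, 0, 1)
    lik_bf <- brute_force_lik(E, means, sigmas, P, pi0)  # all 2^5 paths
    ll <- forward_loglik(matrix(E, nrow = 1), model)
    expect_equal(ll, log(lik_bf), tolerance = 1e-10)
  }
})

test_that("rate optimization recovers generating kinetics", {
  # clean two-state data: fitted rates reproduce the empirical transition
  # frequency, and the likelihood at truth beats perturbed rates
  cfg <- sim_config(states = data.frame(mean = c(0.25, 0.75), sigma = 0.03),
                    rate_matrix = matrix(0.8, 2, 2),
                    n_frames = 2000L, n_traces = 4L, seed = 321)
  traces <- simulate_traces(cfg, clean_phys(channel_noise_sd = 5))
  frets <- lapply(traces, compute_fret)
  truth <- kinetic_model(c(0.25, 0.75), sigmas = 0.05,
                         rates = matrix(0.8, 2, 2))
  ll_true <- forward_loglik(frets, truth)
  pert <- kinetic_model(c(0.25, 0.75), sigmas = 0.05,
                        rates = matrix(c(0, 2.4, 0.2, 0), 2, 2,
                                       byrow = TRUE))
  expect_gt(ll_true, forward_loglik(frets, pert))

  m0 <- kinetic_model(c(0.25, 0.75), sigmas = 0.05,
                      rates = matrix(0.3, 2, 2))
  fit <- mpl_fit(frets, m0, fit_sigma = TRUE)
  expect_gte(fit$loglik, fit$loglik0)
  expect_lt(max(abs(fit$model$Q[1, 2] / 0.8 - 1),
                abs(fit$model$Q[2, 1] / 0.8 - 1)), 0.2)

  # constant-state traces: exit rates driven to the floor
  cfg1 <- sim_config(states = data.frame(mean = c(0.25, 0.75), sigma = 0.03),
                     rate_matrix = matrix(0, 2, 2),
                     n_frames = 500L, n_traces = 6L, seed = 322)
  frets1 <- lapply(simulate_traces(cfg1, clean_phys(channel_noise_sd = 5)),
                   compute_fret)
  fit1 <- mpl_fit(frets1, m0, fit_sigma = TRUE)
  expect_lt(max(fit1$model$Q[row(fit1$model$Q) != col(fit1$model$Q)]), 0.01)
})

test_that("three-state rates are recovered within 20% at benchmark SNR", {
  cfg <- benchmark_config(n_traces = 100L, n_frames = 400L, seed = 331)
  traces <- simulate_traces(cfg)
  frets <- lapply(select_traces(traces)$accepted, compute_fret)
  m0 <- kinetic_model(site_centers(), sigmas = 0.07,
                      rates = matrix(0.3, 3, 3))
  fit <- mpl_fit(frets, m0, fit_sigma = TRUE)
  off <- fit$model$Q[row(fit$model$Q) != col(fit$model$Q)]
  expect_lt(max(abs(off / 0.5 - 1)), 0.2)
})

test_that("the F_B sink stays rare in benchmark fits", {
  traces <- mini_benchmark(n_traces = 50L, n_frames = 400L, seed = 341)
  frets <- lapply(select_traces(traces)$accepted, compute_fret)
  m0 <- kinetic_model(site_centers(), sigmas = 0.07,
                      rates = matrix(0.3, 4, 4), bleach_state = TRUE)
  fit <- mpl_fit(frets, m0)
  b <- fit$model$bleach_state
  pi_fit <- stationary_distribution(fit$model$Q)
  expect_lt(pi_fit[b], 0.02)
  ideal <- lapply(frets, viterbi_idealize, model = fit$model)
  n_b <- sum(vapply(ideal, function(it)
    sum(it$states == b, na.rm = TRUE), numeric(1)))
  n_tot <- sum(vapply(ideal, function(it)
    sum(!is.na(it$states)), numeric(1)))
  expect_lt(n_b / n_tot, 0.02)
})

test_that("Viterbi decoding recovers clean paths and tolerates noise", {
  # noise-free, well-separated states: exact recovery of the simulated path
  cfg <- sim_config(states = data.frame(mean = c(0.2, 0.8), sigma = 0),
                    rate_matrix = matrix(0.6, 2, 2),
                    n_frames = 500L, n_traces = 1L, seed = 351)
  tr <- simulate_traces(cfg, clean_phys(channel_noise_sd = 1))[[1]]
  model <- kinetic_model(c(0.2, 0.8), sigmas = 0.03,
                         rates = matrix(0.6, 2, 2))
  it <- viterbi_idealize(compute_fret(tr), model)
  expect_equal(it$states, tr$truth$frame_states)
  expect_true(all(it$E_ideal %in% model$means))

  # benchmark SNR: frame misassignment below 5% against simulation truth
  cfgb <- benchmark_config(n_traces = 10L, n_frames = 400L, seed = 352)
  trb <- simulate_traces(cfgb)
  modelb <- kinetic_model(site_centers(), sigmas = 0.09,
                          rates = matrix(0.5, 3, 3))
  mis <- 0; tot <- 0
  for (t in trb) {
    ft <- compute_fret(t)
    it <- viterbi_idealize(ft, modelb)
    ok <- !is.na(it$states)
    mis <- mis + sum(it$states[ok] != t$truth$frame_states[ok])
    tot <- tot + sum(ok)
  }
  expect_lt(mis / tot, 0.05)
})

test_that("dwell statistics match exponential lifetimes", {
  cfg <- sim_config(states = data.frame(mean = c(0.2, 0.8), sigma = 0.02),
                    rate_matrix = matrix(1, 2, 2),
                    n_frames = 2000L, n_traces = 10L, seed = 361)
  traces <- simulate_traces(cfg, clean_phys(channel_noise_sd = 5))
  model <- kinetic_model(c(0.2, 0.8), sigmas = 0.04,
                         rates = matrix(1, 2, 2))
  ideal <- lapply(lapply(traces, compute_fret), viterbi_idealize,
                  model = model)
  dw <- dwell_statistics(ideal)
  # mean dwell ~ 1 / exit rate = 1 s, up to missed events at 0.1 s frames
  expect_lt(max(abs(dw$mean_dwell_s - 1)), 0.15)
  # durations are positive multiples of the frame interval
  expect_true(all(dw$dwells$duration_s > 0))
  n_frames_per_dwell <- dw$dwells$duration_s / 0.1
  expect_equal(n_frames_per_dwell, round(n_frames_per_dwell),
               tolerance = 1e-9)

  # single-state trace: one dwell covering the full valid region
  one <- compute_fret(make_trace(rep(100, 80), rep(100, 80)), mask = FALSE)
  m1 <- kinetic_model(0.465, sigmas = 0.05, rates = matrix(0, 1, 1))
  it1 <- viterbi_idealize(one, m1)
  expect_equal(nrow(it1$dwells), 1L)
  expect_equal(it1$dwells$duration_s, 8)
})
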