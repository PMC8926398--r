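test_that("the corrected FRET formula matches hand arithmetic", {
  tr <- make_trace(donor = c(100, 0, 100), acceptor = c(7, 200, 100))
  ft <- compute_fret(tr, crosstalk = 0.07, mask = FALSE)
  expect_equal(ft$E[1], 0)            # numerator vanishes: IA = c * ID
  expect_equal(ft$E[2], 1)            # donor-dark limit
  expect_equal(ft$E[3], 93 / 200)     # (100 - 7) / 200 = 0.465
  expect_error(compute_fret(make_trace(numeric(0), numeric(0))),
               "zero-length")
})

test_that("corrected FRET is invariant to channel rescaling", {
  set.seed(31)
  for (i in 1:10) {
    D <- runif(50, 50, 500); A <- runif(50, 50, 500)
    gamma <- runif(1, 0.1, 10)
    e1 <- compute_fret(make_trace(D, A), mask = FALSE)$E
    e2 <- compute_fret(make_trace(gamma * D, gamma * A), mask = FALSE)$E
    expect_equal(e1, e2, tolerance = 1e-12)
  }
})

test_that("crosstalk is recovered from donor-only controls", {
  # ideal leakage-only traces: exact
  ideal <- simulate_donor_only(5, 100, clean_phys(), seed = 3)
  expect_equal(estimate_crosstalk(ideal)$crosstalk, 0.07)

  # zero-leakage sample: estimate within noise of 0
  z <- simulate_donor_only(50, 300,
                           photophysics(crosstalk = 0, blink_rate = 0),
                           seed = 4)
  expect_lt(abs(estimate_crosstalk(z)$crosstalk), 0.005)

  # noisy recovery of a non-standard leakage value
  noisy <- simulate_donor_only(
    100, 600, photophysics(crosstalk = 0.12, blink_rate = 0), seed = 5)
  est <- estimate_crosstalk(noisy)
  expect_lt(abs(est$crosstalk - 0.12), 0.005)
})

test_that("bleach events are located to within two frames", {
  cfg <- benchmark_config(n_traces = 1L, n_frames = 600L, seed = 5)
  set.seed(61)
  path <- simulate_state_path(cfg)
  base <- render_trace(path, cfg$states, photophysics(
    donor_bleach_rate = 0, acceptor_bleach_rate = 0, blink_rate = 0))

  # no bleach: open-ended lifetime
  q0 <- detect_bleach_frames(base)
  expect_true(is.na(q0$donor_bleach_frame))
  expect_true(is.na(q0$acceptor_bleach_frame))
  expect_equal(q0$fret_lifetime, 600L)

  # forced acceptor bleach at frame 300: leakage-only emission afterwards
  set.seed(62)
  ab <- base
  post <- 301:600
  D0 <- 500 / 1.07
  ab$donor[post] <- D0 + rnorm(length(post), 0, 25)
  ab$acceptor[post] <- 0.07 * D0 + rnorm(length(post), 0, 25)
  qa <- detect_bleach_frames(ab)
  expect_lte(abs(qa$acceptor_bleach_frame - 301L), 2L)
  expect_lte(abs(qa$fret_lifetime - 300L), 2L)

  # forced donor bleach at frame 100: both channels to background
  set.seed(63)
  db <- base
  post <- 101:600
  db$donor[post] <- rnorm(length(post), 0, 25)
  db$acceptor[post] <- rnorm(length(post), 0, 25)
  qd <- detect_bleach_frames(db)
  expect_lte(abs(qd$donor_bleach_frame - 101L), 2L)
  expect_lte(abs(qd$fret_lifetime - 100L), 2L)
})

test_that("donor blinks are counted and gate selection", {
  cfg <- benchmark_config(n_traces = 1L, n_frames = 600L, seed = 5)
  set.seed(71)
  path <- simulate_state_path(cfg)
  base <- render_trace(path, cfg$states, photophysics(
    donor_bleach_rate = 0, acceptor_bleach_rate = 0, blink_rate = 0))
  expect_equal(count_donor_blinks(base), 0L)

  inject <- function(tr, starts, len) {
    for (s in starts) {
      idx <- s:(s + len - 1)
      tr$donor[idx] <- rnorm(len, 0, 25)
      tr$acceptor[idx] <- rnorm(len, 0, 25)
    }
    tr
  }
  set.seed(72)
  two <- inject(base, c(150, 400), 8)
  expect_equal(count_donor_blinks(two), 2L)

  set.seed(73)
  five <- inject(base, c(60, 150, 250, 350, 450), 8)
  expect_equal(count_donor_blinks(five), 5L)
  rep5 <- select_traces(list(five))$report
  expect_false(rep5$accepted[1])
  expect_false(rep5$pass_blinks[1])
})

test_that("trace statistics behave at the defined limits", {
  # noise-free anticorrelated trace: correlation exactly -1
  cfg <- sim_config(states = data.frame(mean = c(0.3, 0.7), sigma = 0),
                    rate_matrix = matrix(1, 2, 2),
                    n_frames = 200L, n_traces = 1L)
  set.seed(81)
  tr <- render_trace(simulate_state_path(cfg), cfg$states, clean_phys())
  s <- trace_statistics(tr)
  expect_equal(s$correlation, -1)

  # flat dead trace: snr ~ 0
  set.seed(82)
  dead <- make_trace(rnorm(300, 0, 25), rnorm(300, 0, 25))
  expect_lt(trace_statistics(dead)$snr, 1)
  expect_false(select_traces(list(dead))$report$accepted[1])

  # default synthetic benchmark clears the SNR threshold
  bench <- mini_benchmark(n_traces = 5L, seed = 83)
  snrs <- vapply(bench, function(t) trace_statistics(t)$snr, numeric(1))
  expect_true(all(snrs > 8))
})

test_that("selection applies all five criteria and is monotone", {
  set.seed(91)
  traces <- mini_benchmark(n_traces = 25L, n_frames = 400L, seed = 91)

  # short-lifetime trace: passes everything else, rejected on lifetime
  cfg <- benchmark_config(n_traces = 1L, n_frames = 40L, seed = 92)
  set.seed(92)
  short <- render_trace(simulate_state_path(cfg), cfg$states,
                        photophysics(donor_bleach_rate = 0,
                                     acceptor_bleach_rate = 0,
                                     blink_rate = 0))
  rep_s <- select_traces(list(short))$report
  expect_false(rep_s$pass_lifetime[1])
  expect_false(rep_s$accepted[1])

  # positively correlated channels: rejected on correlation
  set.seed(93)
  common <- 250 + cumsum(rnorm(300, 0, 10))
  pos <- make_trace(common + rnorm(300, 0, 5), common + rnorm(300, 0, 5))
  rep_p <- select_traces(list(pos))$report
  expect_gt(rep_p$correlation[1], 0.5)
  expect_false(rep_p$accepted[1])

  # report bookkeeping: one row per input, accepted is a subset
  sel <- select_traces(traces)
  expect_equal(nrow(sel$report), length(traces))
  expect_lte(length(sel$accepted), length(traces))

  # monotonicity: relaxing any single threshold never shrinks the set
  base_crit <- selection_criteria()
  relaxed <- list(
    selection_criteria(min_fret_lifetime_frames = 10),
    selection_criteria(correlation_range = c(-1.1, 0.9)),
    selection_criteria(min_snr = 2),
    selection_criteria(max_background_noise = 200),
    selection_criteria(max_donor_blinks = 10))
  n0 <- sum(select_traces(traces, base_crit)$report$accepted)
  for (cr in relaxed)
    expect_gte(sum(select_traces(traces, cr)$report$accepted), n0)

  # overlap metadata flag is honored
  ov <- traces[[which(sel$report$accepted)[1]]]
  ov$meta$overlap <- TRUE
  expect_false(select_traces(list(ov))$report$accepted[1])

  # keep-list hook restricts the accepted set
  keep2 <- select_traces(traces, keep = sel$report$trace_id[1:2])
  expect_true(all(vapply(keep2$accepted,
                         function(t) t$meta$trace_id, 1) %in%
                  sel$report$trace_id[1:2]))

  # empty input warns and returns empty
  expect_warning(out <- select_traces(list()), "no input")
  expect_length(out$accepted, 0L)
})
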