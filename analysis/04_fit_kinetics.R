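#!/usr/bin/env Rscript
# Kinetic idealization: fit the 3+1-state model (fixed per-site emission
# centers plus the F_B bleach/blink sink) by direct rate optimization,
# Viterbi-idealize the accepted traces, and summarise dwell times.

suppressPackageStartupMessages(library(smfretkin))
dir.create("results", showWarnings = FALSE)

cfg <- benchmark_config("K169C-Q194C", n_traces = 100L, n_frames = 400L,
                        seed = 20L)
frets <- lapply(select_traces(simulate_traces(cfg))$accepted, compute_fret)
message(sprintf("fitting 3+1-state model to %d traces ...", length(frets)))

m0 <- kinetic_model(site_centers("K169C-Q194C"), sigmas = 0.07,
                    rates = matrix(0.3, 4, 4), bleach_state = TRUE)
fit <- mpl_fit(frets, m0)
message(sprintf("log-likelihood %.1f (start %.1f), converged: %s",
                fit$loglik, fit$loglik0, fit$convergence == 0))
Q <- fit$model$Q
message("fitted rates (1/s), generator truth 0.5 on all pairs:")
print(round(Q[1:3, 1:3], 3))
pi_fit <- stationary_distribution(Q)
message(sprintf("F_B stationary occupancy: %.4f (rare, as intended)",
                pi_fit[4]))

ideal <- lapply(frets, viterbi_idealize, model = fit$model)
dw <- dwell_statistics(ideal)
message(sprintf("mean dwell times (s): %s  [1/exit-rate truth: 1.0]",
                paste(round(dw$mean_dwell_s[1:3], 3), collapse = ", ")))

utils::write.table(as.data.frame(Q), "results/fitted_rates_K169C_Q194C.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(state = c("F_L", "F_M", "F_H", "F_B"),
             mean_dwell_s = dw$mean_dwell_s,
             n_complete_dwells = dw$n_dwells),
  "results/dwell_times_K169C_Q194C.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)
message("tables -> results/fitted_rates_*, results/dwell_times_*")
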