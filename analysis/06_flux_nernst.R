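#!/usr/bin/env Rscript
# Liposome electrochemistry: the external K+ concentrations that clamp each
# study voltage via the Nernst equation (5 mM intraliposomal KCl,
# valinomycin), and flux-assay activities from the synthetic ACMA curves.

suppressPackageStartupMessages(library(smfretkin))
dir.create("results", showWarnings = FALSE)

voltages <- c(-200, -85, 0, 120)
nernst <- data.frame(
  voltage_mV = voltages,
  K_in_liposome_mM = 5,
  K_out_mM = required_external_K(voltages, K_in_liposome = 5))
nernst$check_mV <- nernst_voltage(5, nernst$K_out_mM)
utils::write.table(nernst, "results/nernst_table.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("Nernst-clamp table (5 mM intraliposomal K+):")
print(within(nernst, K_out_mM <- round(K_out_mM, 1)))

set.seed(25)
active <- simulate_flux_curve(1.0, 0.45, 0.15, decay_rate = 0.02,
                              noise_sd = 0.005)
wt <- simulate_flux_curve(1.0, 0.40, 0.15, decay_rate = 0.02,
                          noise_sd = 0.005)
empty <- simulate_flux_curve(1.0, 0.97, 0.15, decay_rate = 0.02,
                             noise_sd = 0.005)
A <- vapply(list(mutant = active, wt = wt, empty = empty), function(cv)
  flux_activity(curve = cv, valinomycin_time = 300, cccp_time = 2700),
  numeric(1))
rel <- relative_activity(A, A["wt"])
tab <- data.frame(sample = names(A), activity = A, relative = rel)
utils::write.table(tab, "results/flux_activities.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("flux activities:")
print(within(tab, {activity <- round(activity, 3)
                   relative <- round(relative, 3)}))

message(sprintf("reconstitution: 5 mg/ml lipid at 1:4000 wt/wt -> %.1f nM monomer",
                reconstitution_molarity()))
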