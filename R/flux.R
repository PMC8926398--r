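# Liposome electrochemistry: Nernst-clamped voltages and the ACMA proton
# flux assay. Sign convention: voltages follow the channel's physiology
# (intracellular minus extracellular). Because reconstitution leaves the
# channel's intracellular face on the extraliposomal side, the
# extraliposomal bath plays the role of the cytosol and the liposome lumen
# the extracellular space.

FARADAY <- 96485.33212    # C/mol
GAS_CONSTANT <- 8.314462618  # J/(mol K)

#' Nernst potential of a K+ gradient across a liposome membrane
#'
#' With valinomycin making the membrane K+-selective, the membrane voltage
#' is clamped at the K+ Nernst potential
#' \deqn{V = (RT/F)\,\ln([K]_{in\,liposome} / [K]_{out})}
#' reported in mV under the channel convention above (the liposome lumen is
#' the channel's extracellular side). At 25 C, RT/F = 25.693 mV. The
#' resting condition of 5 mM intraliposomal KCl against ~137 mM external
#' K+ gives about -85 mV.
#'
#' @param K_in_liposome intraliposomal K+ concentration (mM).
#' @param K_out extraliposomal K+ concentration (mM).
#' @param temperature absolute temperature (K); default 298.15 (25 C).
#' @return membrane voltage in mV.
#' @export
nernst_voltage <- function(K_in_liposome, K_out, temperature = 298.15) {
  if (any(K_in_liposome <= 0) || any(K_out <= 0))
    stop("concentrations must be > 0")
  1000 * GAS_CONSTANT * temperature / FARADAY * log(K_in_liposome / K_out)
}

#' Extraliposomal K+ needed to clamp a target voltage
#'
#' Exact inverse of [nernst_voltage()]: reconstructs the external K+
#' concentration that, against a given intraliposomal K+, clamps the
#' membrane at `target_mV`. Round-trip with [nernst_voltage()] is the
#' identity.
#'
#' @param target_mV desired membrane voltage (mV, channel convention).
#' @param K_in_liposome intraliposomal K+ (mM).
#' @param temperature absolute temperature (K).
#' @return extraliposomal K+ concentration (mM).
#' @export
required_external_K <- function(target_mV, K_in_liposome = 5,
                                temperature = 298.15) {
  if (any(K_in_liposome <= 0)) stop("concentrations must be > 0")
  K_in_liposome /
    exp(target_mV / (1000 * GAS_CONSTANT * temperature / FARADAY))
}

#' ACMA flux-assay activity
#'
#' Channel activity from the steady-state ACMA fluorescence levels,
#' \deqn{A = (F_0 - F_{val}) / (F_0 - F_{cccp})}
#' where `F0` is the initial level, `Fval` the plateau after valinomycin
#' (flux through active channels) and `Fcccp` the plateau after the
#' protonophore CCCP (maximal flux reference). `A` is invariant to any
#' affine rescaling of the fluorometer applied to all three readings.
#'
#' Either pass the three plateau values directly, or pass a full curve via
#' `curve` plus the two addition times, in which case each plateau is the
#' median over a `window`-second tail before the next event (or trace end).
#'
#' @param F0,Fval,Fcccp steady-state fluorescence readings (a.u.).
#' @param curve optional data.frame with `time_s` and `fluorescence`.
#' @param valinomycin_time,cccp_time addition times (s), required with
#'   `curve`.
#' @param window tail-median window (s) for plateau extraction.
#' @return activity `A` (dimensionless); values outside `[0, 1]` are
#'   returned as computed with a warning (inverted plateau ordering).
#' @export
flux_activity <- function(F0 = NULL, Fval = NULL, Fcccp = NULL,
                          curve = NULL, valinomycin_time = NULL,
                          cccp_time = NULL, window = 60) {
  if (!is.null(curve)) {
    stopifnot(!is.null(valinomycin_time), !is.null(cccp_time))
    tail_median <- function(t_end)
      stats::median(curve$fluorescence[curve$time_s >= t_end - window &
                                       curve$time_s < t_end])
    F0 <- tail_median(valinomycin_time)
    Fval <- tail_median(cccp_time)
    Fcccp <- tail_median(max(curve$time_s) + 1e-9)
  }
  if (F0 == Fcccp) return(0)  # no dynamic range: no measurable flux
  A <- (F0 - Fval) / (F0 - Fcccp)
  if (A < 0 || A > 1)
    warning("plateau ordering F0 >= Fval >= Fcccp violated (A = ",
            signif(A, 3), ")")
  A
}

#' Activity relative to wild type
#'
#' Flux activities are normalized against the wild-type proteoliposomes
#' included in every assay batch; with several WT replicates per batch the
#' batch mean is the denominator.
#'
#' @param A_sample activity (or vector of activities) of the sample.
#' @param A_wt activity (or vector, averaged) of the batch's WT control.
#' @return relative activity.
#' @export
relative_activity <- function(A_sample, A_wt) {
  wt <- mean(A_wt)
  if (wt <= 0) stop("non-positive WT reference activity")
  A_sample / wt
}

#' Protein molar concentration in a liposome reconstitution
#'
#' Worked-example arithmetic for the reconstitution conditions: at a lipid
#' concentration of 5 mg/ml and a protein:lipid ratio of 1:4000 (wt/wt),
#' the protein mass concentration is 1.25 ug/ml; for a His-tagged monomer
#' of ~33 kDa this is ~38 nM - roughly 100x below the channel's
#' dimerisation Kd, so reconstituted channels are overwhelmingly monomeric.
#'
#' @param lipid_mg_per_ml lipid concentration (mg/ml).
#' @param protein_to_lipid protein:lipid mass ratio (wt/wt).
#' @param monomer_kda protein monomer mass (kDa).
#' @return molar protein concentration in nM.
#' @export
reconstitution_molarity <- function(lipid_mg_per_ml = 5,
                                    protein_to_lipid = 1 / 4000,
                                    monomer_kda = 33) {
  g_per_l <- lipid_mg_per_ml * protein_to_lipid  # mg/ml == g/L
  g_per_l / (monomer_kda * 1000) * 1e9
}
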