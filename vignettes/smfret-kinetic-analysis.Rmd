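---
title: "Kinetic analysis of single-molecule FRET trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic analysis of single-molecule FRET trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The human voltage-gated proton channel hHv1 opens when its S4 helix — the
voltage sensor — moves outward across the membrane. smFRET imaging of
liposome-reconstituted channels, with donor/acceptor dyes attached at pairs
of engineered cysteines (K169C-Q194C or K125C-S224C), reads this motion out
as a fluctuating FRET efficiency at 100 ms frames while the liposome voltage
is clamped by a K⁺ gradient plus valinomycin. `smfretkin` implements the
complete trajectory-analysis pipeline for such experiments — and, because
the pipeline must be testable without the original recordings, a generative
simulator that produces data with exactly the statistical structure the
analysis assumes.

## The generative model

A trace is a continuous-time Markov chain over a small set of conformational
states, each carrying an apparent-FRET mean $\mu_i$ and width $\sigma_i$.
Paths are simulated by exact event sampling (exponential dwells at the total
exit rate, jump probabilities $k_{ij}/\sum_j k_{ij}$), started from the
stationary distribution $\pi Q = 0$ because the recordings are taken at
equilibrium, and discretised by the state occupying each frame midpoint.
Sampling a CTMC at a fixed interval yields a Markov chain with transition
matrix $e^{Q\Delta t}$ exactly, so the downstream hidden-Markov model is the
correct likelihood for the simulated data and parameter-recovery tests are
well posed.

Per frame, the apparent FRET $E$ (state mean plus Gaussian conformational
jitter) is rendered into two channels as

$$I_D = T\,\frac{1-E}{1+c}, \qquad I_A = T - I_D,$$

with total intensity $T$ and donor→acceptor crosstalk $c$. This geometry is
chosen deliberately: it is the exact algebraic inverse of the
leakage-corrected efficiency

$$E = \frac{I_A - c\,I_D}{I_A + I_D},$$

the formula applied to the real recordings (with $c = 0.07$ as measured
from donor-only samples), so the noise-free render/compute round trip is an
identity at machine precision. Note the denominator is *not*
leakage-corrected; the printed convention is kept as-is, and it makes $E$
invariant to rescaling both channels.

Photophysics is layered on top: one-way exponential photobleaching of each
fluorophore (acceptor bleach → leakage-only emission, apparent FRET 0;
donor bleach → both channels at background), transient donor blinks
(alternating renewal process, both channels dark with recovery), additive
Gaussian channel noise. Out of scope by design: camera gain/excess noise,
acceptor direct excitation, and triplet photophysics beyond the two-rate
blink model — so passing tests certify the trajectory-level analysis, not
robustness to detector pathologies real movies may contain.

### Benchmark defaults

The study-defined constants (state centers 0.24/0.52/0.78 and 0.27/0.6/0.9,
crosstalk 0.07, 100 ms frames, 0.03 histogram bins, the five selection
thresholds) are fixed by the study design. The purely generative knobs have
no measured counterpart, so they are declared once as what a practitioner
would call a realistic single-molecule movie and not revisited: total
intensity 500 a.u. with channel noise SD 25 (SNR ≈ 14 under the declared
SNR definition, comfortably above the >8 cut), conformational width
σ = 0.05, all inter-state rates 0.5 s⁻¹ (dwells of ~1 s, an order of
magnitude above the frame time), bleach rates 0.01 s⁻¹ per fluorophore
(half-life ~1 min, matching typical recording half-lives), blink rate
0.02 s⁻¹ with 2 s⁻¹ recovery (roughly one short blink per minute, far
below the <4 blink cut).

## Trace QC

`detect_bleach_frames()` classifies dark episodes by recovery: a dark run
persisting to the trace end is the donor bleach; an interior run with
recovery is a blink. Acceptor bleaching leaves total intensity intact but
collapses corrected FRET to ~0, so it is found as the terminal run of
median-smoothed FRET below 0.12 — a threshold that must (and does) sit well
below the lowest conformational center of either site. The "live" intensity
level is the maximum of a 5-frame running median, which stays correct even
when a trace bleaches early and most frames are background.

The study's selection thresholds (lifetime > 50 frames, correlation in
[−1.1, 0.5], SNR > 8, background noise < 70, blinks < 4) reference
quantities whose definitions live inside the original acquisition software;
this package therefore declares its own: SNR is mean pre-bleach total
intensity over the SD of post-bleach total intensity, background noise is
that same SD, correlation is Pearson's over valid frames. The thresholds
are only meaningful relative to these definitions, and the synthetic
benchmarks are constructed to pass them. The −1.1 correlation lower bound
is below the mathematical minimum and is applied as printed (effectively
−1).

## State discovery

Histograms use 0.03 bins over [−0.2, 1.21] (whole bins from the lower
edge; the support exceeds [0, 1] because channel noise pushes apparent
FRET outside it). The mixture fit minimises the SSE between the binned
density and a sum of Gaussians — the histogram, not the per-frame
likelihood, is the fitted object, matching how the centers were originally
determined. Optimization is multistart L-BFGS-B (centers initialised at
histogram quantiles, 10 jittered restarts, best SSE kept, ties broken by
lowest SSE then lowest k).

State-number selection reports the percent SSE reduction
$100(SSE_1 - SSE_k)/SSE_1$ and picks the smallest $k$ reaching 95% whose
further gain to $k+1$ is below 2 percentage points. Two guards make this
rule total. First, each fit is warm-started from the previous one plus a
small component at the largest residual, keeping $SSE_k$ non-increasing.
Second, when the one-component fit already explains >98% of the
histogram's total sum of squares the data are unimodal and $k^\ast = 1$ —
necessary because the reduction statistic is relative to $SSE_1$, and for
unimodal data $SSE_1$ is pure sampling noise that extra components can
"reduce" by large relative amounts while fitting nothing.

## Kinetic idealization

The kinetic model is the 3+1-state scheme: three conformational states
F_L/F_M/F_H with fixed emission centers (per labeling site) plus a
bleach/blink sink F_B near FRET 0 for the dark excursions selection did not
remove. Model cardinality is a parameter — the K125C-K169C site pair, for
example, is analysed with a 2+1-state model.

Rates are fitted by direct likelihood maximisation: the exact forward
log-likelihood of the discretised chain ($P = e^{Q\Delta t}$, Gaussian
emissions) summed over traces, optimised over log-rates with L-BFGS-B and
numerical gradients. Emission centers stay frozen so different conditions
share one emission model; widths can be co-fitted, floored at 0.01, and
shared across conformational states by default (a per-state flag exists;
whether widths should be refit per condition is genuinely open, so it is
exposed rather than decided). Choices worth recording:

* **F_B connectivity.** No topology is published for the sink, and its
  occupancy is negligible, so it gets the least-informative symmetric
  wiring: one shared entry rate from every conformational state, one total
  exit rate split equally. Its emission is frozen at mean 0.05, σ 0.08.
  The test suite verifies fitted F_B stationary occupancy stays below 2%
  on benchmarks, so sensitivity to this wiring is low.
* **Rate bounds.** Log-rates are bounded above at $2/\Delta t$: faster
  rates are unresolvable at the frame interval, and without the bound
  unidentifiable edges (the F_B exit rate, when masking leaves no dark
  frames) diverge numerically.
* **Missing frames.** Invalid frames (post-bleach, blink gaps) contribute
  emission probability 1 while the chain still propagates — algebraically
  identical to truncating the product at the last valid frame, but it
  keeps the recursion vectorised across traces.
* **Initial distribution** is the stationary distribution of the fitted
  generator, again because recordings are at equilibrium.

Viterbi decoding runs per contiguous valid segment (blink gaps split
segments), ties break toward the lowest state index, and the dwell list
marks boundary dwells as censored; censored dwells are excluded from mean
dwell times, which otherwise estimate $1/\sum_{j \ne i} k_{ij}$ up to
missed-event bias at 100 ms. No dead-time correction is attempted (a
stated non-goal): at benchmark rates of 0.5 s⁻¹ the bias is small, but
users fitting rates within an order of magnitude of $1/\Delta t$ should
not trust the dwell means.

## Ensemble statistics

Occupancies are per-trace fractions of valid frames, F_B frames dropped
and the remainder renormalized (the sink is ignored in kinetic summaries);
ensemble values are means ± SE over traces, with N the trace count — SE is
taken over traces rather than imaging batches so that N matches the
reported trace numbers. Condition comparisons use Welch's unpaired t-test
per state ("unpaired t-test" leaves the variance assumption open; unequal
variances is the safer default), with no multiple-testing correction
across states — mirroring per-state stars, and flagged here so nobody
mistakes the stars for family-wise control. Transition-density plots place
each idealized transition at the (departing mean, arriving mean)
coordinate on the 0.03 grid; total mass equals the transition count and
the diagonal is empty by construction. Equilibrium constants are
$K_{eq} = K_F/K_R$ from the fitted rates, with the forward direction
configurable per site pair (activation enriches opposite ends of the FRET
scale at the two sites).

## Electrochemistry

Liposome voltages are Nernst potentials
$V = (RT/F)\ln([K^+]_{in}/[K^+]_{out})$, reported in the channel's
physiological convention (intracellular minus extracellular); since
reconstitution leaves the channel's intracellular face on the
extraliposomal side, the bath is the "cytosol". Assay temperature is not
stated; 25 °C ($RT/F = 25.693$ mV) is the default and a parameter. The
inverse operation reconstructs the external K⁺ for each printed voltage
from the 5 mM intraliposomal KCl (e.g. ~137 mM for −85 mV). Flux-assay
activity is $A = (F_0 - F_{val})/(F_0 - F_{cccp})$ with plateaus taken as
tail medians before each addition, and batch normalization against WT.
`reconstitution_molarity()` documents the monomer-concentration
arithmetic (5 mg/ml lipid, 1:4000 wt/wt, ~33 kDa tagged monomer → ~38 nM);
the monomer mass is this package's default, consistent with the His-tagged
channel construct, not a printed constant.

## Problem sizes and determinism

The reference benchmark is 200 traces × 600 frames per site — ample for
the headline checks (fitted centers land within ±0.005 of the generator
means; the acceptance tolerance is ±0.02). Parameter-recovery tests run on
scaled-down sets (40–100 traces × 300–400 frames, ~10 seeds) sized so the
Monte-Carlo spread stays well inside the asserted bounds; rate recovery at
100 × 400 keeps every edge within ±20% of truth with margin. All
randomness flows from one master seed: per-trace (and per-condition)
substream seeds are drawn from it once, so datasets are bit-reproducible
and independent of evaluation order.

## Worked example

```{r}
library(smfretkin)

cfg <- benchmark_config("K169C-Q194C", n_traces = 200, seed = 20)
traces <- simulate_traces(cfg)
sel <- select_traces(traces)
frets <- lapply(sel$accepted, compute_fret)

h <- build_histogram(frets)
ssn <- select_state_number(h)
ssn$fits[[ssn$k_star]]          # three components at ~0.24 / 0.52 / 0.78

m0 <- kinetic_model(site_centers("K169C-Q194C"), sigmas = 0.07,
                    rates = matrix(0.3, 4, 4), bleach_state = TRUE)
fit <- mpl_fit(frets, m0)
ideal <- lapply(frets, viterbi_idealize, model = fit$model)
occupancies(ideal)
equilibrium_constants(fit$model)
```

The numbered scripts under `analysis/` run this workflow end to end —
simulation, selection, state discovery, kinetics, voltage-series ensemble
statistics, and the electrochemistry tables — writing their outputs under
`results/`.

## Known limitations

* The simulator's noise model is Gaussian and stationary; EMCCD gain
  fluctuations, baseline drift and spectral bleed-through beyond constant
  crosstalk are absent, so QC thresholds validated here may need retuning
  on real recordings.
* SNR/background-noise definitions are this package's own; selections on
  real data preselected by other software will differ at the margins.
* No missed-event correction: rates approaching the frame rate are biased
  toward zero.
* The SSE-reduction rule inherits the histogram's binning; with very few
  pooled frames the 95% criterion becomes noisy (the test suite pools
  ≥10⁴ frames).
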