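# smfretkin

Kinetic analysis of single-molecule FRET (smFRET) trajectories, built for
studies of membrane-protein conformational dynamics — specifically the
workflow used to resolve voltage- and pH-dependent motions of the hHv1
proton channel's S4 voltage sensor in liposomes, where donor/acceptor dyes
on engineered cysteine pairs (K169C-Q194C, K125C-S224C) report S4 position
as an apparent FRET efficiency sampled at 100 ms while the membrane voltage
is clamped by a K⁺ gradient plus valinomycin.

It is aimed at single-molecule biophysicists who need the full trajectory
pipeline — and a matching generative simulator, so every stage is testable
without the original recordings.

## What it computes

Per frame, apparent FRET with donor→acceptor leakage correction
(crosstalk c = 0.07, measured from donor-only samples):

    E = (I_A − c·I_D) / (I_A + I_D)

Traces pass Autotrace-style selection (FRET lifetime > 50 frames,
donor/acceptor correlation in [−1.1, 0.5], SNR > 8, background noise < 70,
donor blinks < 4). Valid frames pool into 0.03-bin histograms; Gaussian
mixtures with k = 1…5 components are fitted by least squares on the binned
density, and the state number is chosen where the SSE reduction
100·(SSE₁ − SSE_k)/SSE₁ exceeds 95%. Kinetics use a 3+1-state hidden-Markov
model (F_L/F_M/F_H at fixed per-site centers plus a bleach/blink sink F_B):
rate constants k_ij of the generator Q are optimized directly against the
exact forward likelihood of the discretized chain P = exp(QΔt), traces are
idealized by Viterbi decoding, and the ensemble is summarised by state
occupancies (mean ± SE over N traces, Welch t-tests across conditions),
transition-density plots, and equilibrium constants K_eq = K_F/K_R per
transition pair. Liposome voltages follow the Nernst relation
V = (RT/F)·ln([K⁺]_in/[K⁺]_out), and ACMA flux-assay activity is
A = (F₀ − F_val)/(F₀ − F_cccp), normalized batch-wise against WT.

The simulator generates continuous-time Markov state paths (exact event
sampling, stationary initial state), renders them into two channels with
the inverse of the FRET formula above plus crosstalk, Gaussian channel
noise, photobleaching of either fluorophore and donor blinking — so the
noise-free simulate→analyze round trip is exact by construction, and
parameter-recovery tests are well posed.

## Worked example

```r
library(smfretkin)

cfg    <- benchmark_config("K169C-Q194C", n_traces = 200, seed = 20)
traces <- simulate_traces(cfg)                 # 3 states, rates 0.5/s
frets  <- lapply(select_traces(traces)$accepted, compute_fret)

h   <- build_histogram(frets)                  # 0.03-bin pooled histogram
set.seed(23)
ssn <- select_state_number(h)
ssn$fits[[ssn$k_star]]
#> mixture_fit: k=3, SSE=0.03043
#>   center sigma weight
#> 1  0.241 0.065  0.347
#> 2  0.520 0.062  0.311
#> 3  0.778 0.067  0.337

m0  <- kinetic_model(site_centers("K169C-Q194C"), sigmas = 0.07,
                     rates = matrix(0.3, 4, 4), bleach_state = TRUE)
fit <- mpl_fit(frets, m0)                      # direct rate optimization
ideal <- lapply(frets, viterbi_idealize, model = fit$model)
occupancies(ideal)
#> occupancies over N=178 traces:
#>   state_mean occupancy     se
#> 1       0.24     0.345 0.0087
#> 2       0.52     0.314 0.0079
#> 3       0.78     0.341 0.0090
equilibrium_constants(fit$model)
#>   pair       K_F       K_R      K_eq
#> 1   LM 0.4605705 0.5085164 0.9057142
#> 2   MH 0.5159704 0.4872502 1.0589434
#> 3   LH 0.5012930 0.5137469 0.9757587
```

The fitted mixture lands on the generating centers (0.24/0.52/0.78) within
a few thousandths; SSE reduction at three states is 99.8%, well past the
95% selection criterion. Occupancies are near-uniform and every K_eq is
near 1, as they must be for a generator with symmetric 0.5 s⁻¹ rates; the
voltage-series driver (`analysis/05_ensemble_stats.R`) shows K_eq(LH)
moving from ~1 to ~4 when only the low↔high rate pair is shifted, while
K_eq(LM) and K_eq(MH) stay flat.

## Analysis workflow

Numbered drivers under `analysis/` run the study end to end, each writing
tables under `results/`:

1. `01_simulate.R` — benchmark datasets, donor-only controls, flux curves
2. `02_select_traces.R` — per-trace QC report against the five criteria
3. `03_discover_states.R` — histograms, mixture fits, SSE state selection
4. `04_fit_kinetics.R` — 3+1-state rate fits, idealization, dwell times
5. `05_ensemble_stats.R` — occupancies, t-tests, TDPs, K_eq across voltages
6. `06_flux_nernst.R` — Nernst-clamp table and flux-assay activities

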