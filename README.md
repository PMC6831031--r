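# mcmorient

Quantitative inference of how a hexameric replicative helicase (MCM family)
sits on fork DNA and which face leads during translocation and unwinding.

Ring-shaped MCM helicases encircle one strand of a replication fork and
translocate 3′→5′, but on a model fork the hexamer can load on either
single-stranded arm in either of two orientations: N-terminal face toward
the duplex junction (**N@duplex**) or C-terminal face toward it
(**C@duplex**). Whether unwinding proceeds **N-first** or **C-first** is a
population-level inference problem, assembled from three independent
assays. `mcmorient` implements the full quantitative chain for each assay,
plus a mechanistic synthetic-data generator with known ground truth so
every stage has a parameter-recovery test surface. It is written for
biochemists and biophysicists analysing gel densitometry, anisotropy
titrations and stopped-flow records; everything takes and returns tidy
data frames.

## The models

* **Footprint orientation fractions.** Site-specific cleavage probes
  conjugated near one face of the hexamer cut the labelled strand close to
  the bound face. After subtracting a protein-free control lane, cleavage
  intensity summed over a junction-proximal region (S_N) and a distal
  region (S_C) of the single-stranded window gives the orientation
  fraction

  F_N = S_N / (S_N + S_C),  F_C = 1 − F_N,

  compared between replicates by a two-tailed equal-variance t-test.

* **Single-turnover unwinding.** With ATP plus excess trap DNA each
  helicase acts once, so the fraction unwound

  F(t) = [r(t) − r(0)] / [r(b) − r(0)],  r = Is / (Is + Id)

  (normalized between the zero-time lane and a boiled control) rises as
  F(t) = A_f (1 − e^(−kt)), and the amplitude A_f is the fraction of
  complexes bound in the productive configuration. The amplitude's
  standard error propagates the uncertainty of the shared normalization
  anchors.

* **Cooperative binding.** Anisotropy titrations are fitted to the Hill
  isotherm Y = A_max·[MCM]^n / (K_d^n + [MCM]^n).

* **Presteady-state FRET.** Stopped-flow traces on a split time base are
  fitted (weighted, jointly across segments) to
  v(t) = Σ a_i e^(−k_i t) + C with 1–3 exponentials chosen by AICc with
  phase-resolution gating; a phase with a_i < 0 is a signal increase. With
  a streptavidin roadblock on the translocating strand, a slow FRET rise
  occurs only when the dye-labelled face leads.

* **Direction verdict.** The orientation fraction and the unwinding
  amplitude estimate the same population, compared by
  z = |F_or − F_unwound| / √(SE₁² + SE₂²) (consistent if z < 1.96). A
  direction is declared only when the footprint–unwinding correspondence
  and the blocked-substrate FRET sign pattern concur; anything else is
  `indeterminate`.

## Worked example

```r
library(mcmorient)

sub   <- substrate_preset("fork_equal")       # 20-bp duplex, 30/30-nt arms
rmap  <- default_region_map(sub)              # bases 20-35 / 36-50
lanes <- simulate_cleavage_profiles(sub, rmap,
                                    population_preset("fork_equal_wt"),
                                    n_replicates = 5, noise_cv = 0.10,
                                    seed = 1)
footprint_analysis(lanes, rmap)
#> <footprint_result>  n = 5 replicates
#>   F_N = 0.233 +/- 0.004   F_C = 0.767 +/- 0.004
#>   t = -102.224, p = 9.367e-14  ***  ->  C_at_duplex_preferred

tc  <- simulate_unwinding_timecourse(0.26, "N_first", k = 0.07,
                                     noise_sd = 0.02, seed = 2)
fit <- fit_single_exponential(fraction_unwound(tc))
tidy(fit)
#> # A tibble: 2 × 3
#>   term      estimate std.error
#> 1 amplitude   0.261    0.0107
#> 2 k_per_min   0.0770   0.00670

run_polarity_study("N_first", seed = 1)$verdict
#> <direction_verdict> N_first
#>   - footprint~unwinding [fork_equal,fork_3long]: F_N consistent & F_C not
#>     on >=1 substrate -> N_first
#>   - blocked-substrate slow phase: N-label rise TRUE, C-label rise FALSE
#>     -> N_first
```

Read as: on the equal-arm fork only ~23% of hexamers sit N-face-to-duplex,
and the single-turnover amplitude (0.26) matches that minority fraction —
the N@duplex subpopulation is the productive one. Combined with the FRET
sign pattern the verdict is N-first, 3′→5′ translocation.

Each fitted object also has `glance()` and `autoplot()` methods;
`plot_profiles()` draws lane profiles with the orientation regions shaded.

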