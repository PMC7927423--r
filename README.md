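# nirsconn

Inter-regional functional connectivity analysis for continuous-wave
fNIRS recordings acquired during block-design motor tasks — built for
researchers studying how cortical coupling (for example between
prefrontal and motor regions during surgical skill training) differs
across groups.

The package implements the complete chain:

1. **Preprocessing** — channel pruning by intensity level (80–140 dB),
   optical density, PCA motion correction, modified Beer–Lambert
   inversion (PPF 6.4 at 690 nm / 5.8 at 830 nm), and a
   short-separation GLM with a consecutive Gaussian temporal basis
   that removes superficial systemic physiology while retaining the
   task structure, yielding one HbO series per cortical region (LPFC,
   CPFC, RPFC, LMM1, SMA).
2. **Connectivity** — analytic Morlet continuous wavelet transform
   (ω₀ = 6) with cone-of-influence masking; per frequency, with time
   averages ⟨·⟩ over jointly COI-valid samples,

   WCO(f) = |⟨w₁w₂\*⟩|² / (⟨|w₁|²⟩·⟨|w₂|²⟩)

   WPCO(f) = √(⟨cos Δφ⟩² + ⟨sin Δφ⟩²), Δφ = arg w₁ − arg w₂

   band-averaged over the physiological bands I–V, with the
   neurovascular band IV (0.02–0.05 Hz) as the default endpoint, for
   all ten unordered region pairs.
3. **Statistics** — Shapiro–Wilk and Levene checks, one-way MANOVA
   with Wilks' Λ = det(E)/det(E+H) and Rao's F, per-pair partial η²,
   Bonferroni correction, exact two-tailed Mann–Whitney U, and
   noncentral-t power analysis.
4. **Synthetic cohorts** — a seeded generator (hemodynamic signal
   model + optical forward model) that plants known band-IV coupling
   κ between region pairs, so recovery of planted effects validates
   every stage end to end.

## Worked example

Generate a trained-versus-control cohort (9 vs 5 subjects, planted
CPFC-SMA coupling κ = 0.9 vs 0.3, 600 s sessions at 10 Hz), run it
through preprocessing, coherence, and the statistics layer:

```r
library(nirsconn)
library(dplyr)

res <- run_pipeline(default_config(master_seed = 1))
res
#> <run_result> 14 subjects, 140 pair rows
#> -- WPCO --
#> <nirs_manova> Wilks' Lambda = 0.0138, F(10, 3) = 21.461, p = 0.01413 (n = 14, 2 groups)
#> <mw_test> U = 45, two-tailed p = 0.000999 (exact; n = 9 vs 5)
#> -- WCO --
#> <nirs_manova> Wilks' Lambda = 0.0140, F(10, 3) = 21.104, p = 0.01448 (n = 14, 2 groups)
#> <mw_test> U = 45, two-tailed p = 0.000999 (exact; n = 9 vs 5)

res$connectivity |>
  filter(pair == "CPFC-SMA") |>
  group_by(group) |>
  summarise(mean_wpco = mean(wpco), sd_wpco = sd(wpco))
#> # A tibble: 2 × 3
#>   group   mean_wpco sd_wpco
#>   <chr>       <dbl>   <dbl>
#> 1 control     0.337  0.115
#> 2 trained     0.786  0.0694

tidy(res$stats$wpco$manova) |> arrange(desc(eta_squared)) |> head(3)
#> # A tibble: 3 × 4
#>   dv        ss_between ss_within eta_squared
#>   <chr>          <dbl>     <dbl>       <dbl>
#> 1 CPFC-SMA      0.647     0.0914       0.876
#> 2 SMA-LMM1      0.0229    0.0928       0.198
#> 3 CPFC-RPFC     0.0273    0.112        0.196
```

Reading the output: the trained group's band-IV CPFC-SMA phase
coherence (0.79 ± 0.07) sits far above the control group's
(0.34 ± 0.12); the exact Mann–Whitney U = 45 is complete separation of
the two groups (the smallest attainable two-sided p at 9 vs 5,
2/2002 ≈ 0.000999); and the pair with the planted coupling difference
carries by far the largest effect size — the pipeline recovers what
the generator planted. Each fitted object also has `tidy()`/`glance()`
methods, and `autoplot()` works on region series, coherence profiles,
and time–frequency maps; `plot_connectivity()` draws the per-pair
group comparison.

Lower-level functions are ordinary data-frame-in/tibble-out verbs
(`build_paradigm()`, `simulate_region_hbo()`, `forward_optics()`,
`preprocess_recording()`, `morlet_cwt()`, `coherence_profile()`,
`pairwise_connectivity()`, `manova_wilks()`, ...) and chain with the
pipe; see the methods vignette (`vignettes/nirsconn-methods.Rmd`) for
the model details and design rationale.

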