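# isoturn

Stable-isotope trophic ecology asks a deceptively simple question — *what is
this animal actually eating?* — and answers it with two methods that often
disagree: gut-content analysis (a snapshot of recent meals, biased toward
indigestible items like mussel shell) and stable-isotope mixing models (an
integrated view over weeks, but only as accurate as the trophic
discrimination factors fed into them). isoturn implements the full analysis
chain for resolving that disagreement with a controlled feeding trial, built
around the invasive round goby (*Neogobius melanostomus*) and its dreissenid
(zebra/quagga mussel) prey:

* **Lipid normalization** of δ¹³C from the C:N ratio
  (`normalized δ¹³C = δ¹³C − 3.32 + 0.99 × C:N`), applied to all food items
  and to fish muscle only when C:N > 3.5.
* **Joint discrimination/turnover estimation.** After a diet switch, tissue
  follows `δ_t = δ_e + (δ₀ − δ_e) e^(−τt)` with equilibrium
  `δ_e = δ_prey + Δ`. One discrimination factor Δ (‰) and one turnover rate
  τ (day⁻¹) are fitted jointly across all diet groups per isotope by
  damped Gauss–Newton (Levenberg–Marquardt) with the analytic Jacobian;
  half-life = ln 2/τ.
* **Bayesian two-source mixing model** (standard SIMMR-style normal
  likelihood: mean `Σ p_k(μ_k + c_k)`, variance
  `Σ p_k²(σ_k² + σ_c,k²) + σ_res²`; Dirichlet(1,1) prior, Uniform(0, 20 ‰)
  residual SDs) via random-walk Metropolis, with Gelman–Rubin diagnostics
  and posterior-predictive checks, run per consumer size class under
  standard vs experimentally determined enrichment factors.
* **Gut-content summaries**: percent frequency of occurrence
  (`FOO = 100 × fish containing taxon / fish with identifiable content`)
  within four 25-mm size bins.
* **Seeded synthetic-data generators** reproducing the study design (a
  64-fish, four-diet, 63-day trial; 45 wild consumers in three size classes;
  226 gut samples), so every stage runs and is tested without raw data.

Everything is data-frame-first and pipe-friendly: tibbles in, tibbles out,
with `tidy()`, `glance()` and `autoplot()` methods on fitted objects.

## Worked example

```r
library(isoturn)
library(dplyr)

# 1. Simulate the feeding trial at its study-design defaults and fit both isotopes
trial <- gen_feeding_trial(trial_design(seed = 1))
fits  <- fit_both_isotopes(trial)
bind_rows(lapply(fits, glance))
#>   isotope   disc se_disc    tau  se_tau  rmse n_obs half_life_days converged
#> 1 C13     -0.632   0.268 0.0289 0.00360 1.36     64           24.0 TRUE
#> 2 N15      3.77    0.234 0.0184 0.00131 0.556    64           37.6 TRUE
```

The true generator values (Δ = −0.41 / 4.04 ‰, τ = 0.0229 / 0.0192 day⁻¹)
sit within roughly one standard error of each estimate; the carbon
discrimination is clearly below the standard literature value of 0.4 ‰ and
the nitrogen one above 3.4 ‰, and the half-lives (ln 2/τ ≈ 24 and 38 days
here) are in the fast range expected for small, fast-growing fish.

```r
# 2. Wild consumers: compare enrichment scenarios across size classes
wild <- gen_wild_consumers(wild_design(seed = 2))
cmp  <- compare_tef_scenarios(wild, mixing_sources(), settings = mcmc_settings(seed = 3))
filter(cmp$summary, source == "dreissenid")
#>   size_class scenario     source     max_rhat n_consumers median lower upper
#> 1 <=70mm     standard     dreissenid     1.00          20  0.725 0.462 0.905
#> 2 <=70mm     experimental dreissenid     1.00          20  0.592 0.432 0.757
#> 3 71-100mm   standard     dreissenid     1.00          14  0.749 0.299 0.966
#> 4 71-100mm   experimental dreissenid     1.00          14  0.513 0.291 0.736
#> 5 >100mm     standard     dreissenid     1.00          11  0.768 0.530 0.955
#> 6 >100mm     experimental dreissenid     1.00          11  0.744 0.569 0.949
```

Each row is the posterior median and 95% credible interval for the
dreissenid (pelagic-pathway) diet share in one size class under one
discrimination scenario; all R-hat < 1.1, so the four chains mixed.

```r
# 3. Gut contents: occurrence by size bin
guts <- gen_gut_contents(seed = 4)
summarize_guts(guts)
#>   n_total n_empty pct_empty n_unidentifiable_only pct_unidentifiable_only n_identifiable
#> 1     226      22        10                    13                       6            191
filter(foo_by_bin(guts), is_top, size_bin %in% c("17-42mm", "95-120mm"))
#>   size_bin taxon       n_identifiable n_with   foo  rank is_top
#> 1 17-42mm  chironomid              46     36  78.3     1 TRUE
#> 2 17-42mm  cladoceran              46     35  76.1     2 TRUE
#> 3 17-42mm  amphipod                46      6  13.0     3 TRUE
#> 4 95-120mm dreissenid              55     51  92.7     1 TRUE
#> 5 95-120mm chironomid              55     20  36.4     2 TRUE
#> 6 95-120mm trichoptera             55      8  14.5     3 TRUE
```

The smallest fish feed mostly on cladocerans and chironomids while the
largest are dreissenid specialists — the ontogenetic diet shift the mixing
model probes from the isotope side. `run_demo_pipeline(seed = 1)` chains all
three stages (deriving the experimental enrichment scenario from the fitted
trial) into one reproducible report.

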