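# sleepsynth

Physiologically constrained hierarchical copula synthesis of sleep and
heart-rate-variability (HRV) parameters, with fidelity metrics, HRV profile
archetypes, template-based report generation, and a profile-aided top-k
mixture-of-experts routing harness.

## The problem

Cohorts pairing overnight sleep architecture with HRV summaries are small,
hard to share, and expensive to collect, which starves downstream modelling
(personalized sleep reports, question answering, event detection) of
training data. `sleepsynth` generates synthetic cohorts of the seven
standard parameters —

| column | meaning | unit |
|---|---|---|
| `total_sleep_h` | total sleep duration | h |
| `deep_sleep_h` | deep (slow-wave) sleep duration | h |
| `light_sleep_h` | light sleep duration | h |
| `sdnn_ms` | SDNN, overall HRV | ms |
| `rmssd_ms` | RMSSD, parasympathetic marker | ms |
| `lf_hf` | LF/HF spectral power ratio | – |
| `pnn50_pct` | PNN50 | % |

— that are simultaneously *statistically faithful* to a reference cohort and
*physiologically admissible* under a hard constraint system.

## The model

Each parameter is mapped to a latent standard-normal scale by a
constraint-preserving transform `T` (log-normalization for durations and
ms-scale HRV, a standardized logit of the min–max rescaled value for the
bounded LF/HF and PNN50). Dependence is modelled hierarchically on the
copula scale in two physiological subsystems:

* **sleep architecture** (total, deep, light) — an exchangeable **Gumbel**
  copula, τ-parameterized, capturing upper-tail co-movement of long sleep;
* **autonomic regulation** (SDNN, RMSSD, LF/HF, PNN50) — an exchangeable
  **Clayton** copula, capturing joint collapse of HRV in the lower tail.

Families are chosen per subsystem from empirical upper/lower tail-dependence
coefficients (Gaussian fallback), and Archimedean parameters are estimated by
Kendall-tau inversion: `θ_gumbel = 1/(1−τ)`, `θ_clayton = 2τ/(1−τ)`. A
bivariate Gaussian **linking copula** couples the subsystems through a
physiologically motivated conditional pair — the deep-sleep ratio
(deep/total) and RMSSD — fitted on normal scores of ranks. Sampling is

```
U ~ V(C_Sub1, C_Sub2)      # hierarchical copula, frailty constructions
Z = Φ⁻¹(U)                 # latent normal scale
X = T⁻¹(Z)                 # physiological scale
```

followed by hard constraint enforcement (rejection with a deterministic
projection fallback) against the knowledge base:
deep + light ≤ total; total ∈ [3, 12] h; deep/total ∈ [0.1, 0.35];
SDNN ∈ [15, 220] ms; RMSSD ∈ [10, 180] ms; PNN50 ∈ [0, 70] %;
LF/HF ∈ [0.1, 7]; with clinical thresholds SDNN < 30 ms (severe autonomic
dysfunction) and LF/HF > 4 (sympathetic dominance). Clinically significant
regions (short sleep, low SDNN, high deep ratio, elevated LF/HF) can be
oversampled by importance weights.

Around the generator the package provides:

* **fidelity/diversity metrics** — per-variable histogram KL divergence,
  two-sample Kolmogorov–Smirnov tests, and a Gaussian-kernel HSIC
  V-statistic with permutation p-values;
* **endpoint scoring** — sensitivity/specificity with Clopper–Pearson 95%
  intervals for autonomic dysfunction (SDNN < 30 and/or RMSSD < 20 ms) and
  sympathetic dominance (LF/HF > 4);
* **profile archetypes** — k-means clustering of the 4-dim HRV profile
  `[sSDNN, sRMSSD, sPNN50, sLF/HF]` into three descriptive archetypes with
  silhouette/Calinski–Harabasz/bootstrap-Jaccard/noise-stability validation;
* **PA-CoT chains and reports** — deterministic assembly of cluster-preamble
  + question-type templates, template-based report rendering, and a
  lexicon/regex parser that inverts it;
* **profile-aided MoE routing** — a top-k temperature-softmax gate over N
  experts taking both the hidden state and an encoded profile
  (`g = W_gate h + W_profile p_enc + b`), with the four-term loss
  `L = L_CE + λ_a·L_aux + λ_f·L_freq + λ_p·L_profile`
  (defaults λ_a = 0.1, λ_f = 0.15, λ_p = 0.05), exercised end to end on a
  toy routed-regression harness.

## Worked example

```r
library(sleepsynth)
library(dplyr)

ref   <- generate_fixture(fixture_spec(n = 1000), seed = 42)  # offline reference cohort
model <- synth_fit(ref)                                       # transforms + copulas + link
glance(model)
#>   n_reference n_dropped family_sub1 family_sub2 tau_sub1 tau_sub2 link_rho
#> 1        1000         0 gumbel      clayton        0.513    0.418    0.325

synth <- synthesize(model, 5000, seed = 7)
nrow(check_records(synth))    # 0 — every record physiologically admissible

set.seed(7)
fid <- evaluate_fidelity(ref, synth)
glance(fid)
#>   ks_median_p ks_min_p kl_mean     hsic hsic_p hsic_mode n_real n_synth
#> 1       0.879    0.531  0.0287 0.000355  0.468 dataset     1000    5000
```

The fixture was generated with Gumbel θ = 2 (τ = 0.5) in the sleep
subsystem, Clayton θ = 1.5 (τ = 0.43) in the autonomic subsystem and link
ρ = 0.3; the fitted taus (0.513, 0.418) and link (0.325) recover them. The
median KS p-value of 0.879 says no variable's synthetic marginal is
distinguishable from the reference at conventional levels; mean per-variable
KL of 0.029 and an HSIC of 3.6e-4 (permutation p = 0.47) indicate closely
matched distributions with no spurious cross-cohort coupling.

```r
label_events(synth) |>
  summarise(autonomic = mean(autonomic_dysfunction),
            sympathetic = mean(sympathetic_dominance))
#>   autonomic sympathetic
#> 1    0.0946      0.0658

render_report(synth[1, ])
#> == Sleep parameters ==
#> - Total sleep duration: 9.40 h
#> ...
#> == Sleep state ==
#> No evidence of autonomic dysfunction.
#> No evidence of sympathetic dominance.
#> ...
```

A command-line interface over the same functions ships in
`inst/cli/sleepsynth.R` with subcommands `fixture`, `synthesize`,
`evaluate`, `cluster`, `chain`, `route-demo` and `label-events`, each
writing a JSON run manifest (seed, config hash, version).

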