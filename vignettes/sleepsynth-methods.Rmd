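---
title: "Methods: constrained copula synthesis of sleep/HRV cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained copula synthesis of sleep/HRV cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepsynth)
```

This vignette documents the statistical model, the design decisions behind
it, the numerical choices, and what the package's tests do and do not
establish.

## The constraint knowledge base

Synthesis operates under a closed system of physiological plausibility
rules: box bounds per parameter (total sleep in [3, 12] h, SDNN in
[15, 220] ms, RMSSD in [10, 180] ms, PNN50 in [0, 70] %, LF/HF in
[0.1, 7]), the deep-sleep ratio band deep/total in [0.1, 0.35], and the
stage-sum rule deep + light ≤ total. All intervals are closed; the sum rule
carries zero slack, with the remaining time interpreted as unmodelled stages
(REM, wake after sleep onset). Box bounds for deep ([0.3, 4.2] h) and light
([0, 12] h) sleep are implied by the total-sleep box and the ratio band, so
the box system is internally consistent: a ratio repair can never push deep
sleep out of its own box.

Two threshold sets are deliberately kept distinct. The knowledge base's
clinical rule "SDNN < 30 ms ⇒ severe autonomic dysfunction" is a
single-parameter marker and is exposed as `severe_autonomic_dysfunction`.
The *endpoint* used for report scoring is the composite
"SDNN < 30 ms and/or RMSSD < 20 ms", exposed as `autonomic_dysfunction`;
sensitivity/specificity are computed against this endpoint. RMSSD < 20 ms is
not a synthesis constraint — records with RMSSD in [10, 20) ms are valid and
clinically interesting. Comparators are strict, so boundary values are
negative.

## Marginal transforms

Each parameter is mapped to a latent standard-normal axis and back:

* **log-normal** (`z = (log x − μ̂)/σ̂`) for the three durations and the two
  millisecond-scale HRV metrics, whose empirical distributions are
  right-skewed and strictly positive;
* **bounded logit** (logit of the min–max rescaled value, then
  standardized) for LF/HF and PNN50, whose physiological ranges are hard
  two-sided bounds of modest width.

The assignment is a documented default, overridable per parameter via the
`transforms` argument, since either transform is defensible for several
parameters. Values at or outside the bounds are shrunk inward by
ε = 1e−6 of the interval width before the log/logit so latents stay finite;
the clip count is recorded on the fitted model. The inverse transform clamps
into the box, so `from_latent()` output is always admissible per parameter.
Fitting requires n ≥ 10 and positive variance; constant columns raise a
degenerate-column error rather than silently producing NaNs.

## Dependence model

Dependence is modelled on the copula scale (pseudo-observations = average
ranks divided by n + 1, keeping values strictly inside the unit interval) in
two physiological subsystems: sleep architecture (total, deep, light) and
autonomic regulation (SDNN, RMSSD, LF/HF, PNN50).

**Family selection.** For each subsystem the mean pairwise empirical tail
coefficients λ̂_U = P(v > 1−q | u > 1−q) and λ̂_L at q = 0.05 are compared:
an upper-tail excess beyond a margin δ selects Gumbel, a lower-tail excess
selects Clayton, otherwise the Gaussian family is the fallback. δ defaults
to 0.1 — large enough that independent data (both coefficients ≈ q) never
triggers an Archimedean family, small enough that θ = 3 samples at n = 2000
are classified correctly in ≥ 90% of runs (verified in the test suite). δ
and q are configuration entries because no principled universal value
exists.

**Within-subsystem copulas are exchangeable.** Each subsystem gets a single
multivariate Archimedean copula (d = 3 and d = 4) with one θ from the mean
pairwise tau-b, rather than a pair-copula construction: the subsystems are
conceived as single physiological regimes with one named family each, and
an exchangeable model is the minimal structure consistent with that. The
cost is that heterogeneous within-subsystem pairwise dependence is averaged;
the dependence-preservation test bounds the resulting distortion (max
absolute pairwise tau error < 0.1 on synthetic-vs-reference cohorts).

**Estimation** is Kendall-tau inversion — Gumbel θ = 1/(1−τ̄), Clayton
θ = 2τ̄/(1−τ̄) — which is closed-form, unbiased in τ, and independent of the
likelihood. Non-positive τ̄ collapses Gumbel to θ = 1 (exactly the
independence copula) and makes Clayton fall back to independence with a
warning, since its parameter space excludes τ ≤ 0. The Gaussian family uses
the normal-scores correlation matrix of the ranks, repaired to the nearest
positive-definite correlation matrix when necessary.

**Sampling** uses exact frailty constructions: positive-stable frailty
(Chambers–Mallows–Stuck) for Gumbel, gamma frailty for Clayton, Cholesky
for Gaussian. These produce exact uniform margins and the closed-form
tau, both property-tested.

**The cross-subsystem link** runs through one conditional pair:
RMSSD conditioned on the deep-sleep ratio. At fit time the ratio's normal
score is regressed on the three sleep-architecture normal scores (the ratio
is a deterministic function of deep and total, so this regression is nearly
exact), and a bivariate Gaussian linking copula correlation ρ is estimated
between the ratio score and the RMSSD score. At sampling time the ratio
score is reconstructed from the sampled sleep-architecture latents plus the
stored residual noise, and the RMSSD coordinate is shifted through the
Gaussian conditional `z' = ρ z_r + sqrt(1−ρ²) z`. The shift preserves the
uniform margin exactly and attenuates RMSSD's within-subsystem dependence
only by the factor sqrt(1−ρ²) (≈ 0.95 at the realistic ρ ≈ 0.3), which the
±0.05 tau-reproduction test absorbs. A degenerate ratio column drops the
link with a warning. Additional linking pairs are out of scope for v1; the
two-level structure with one link is the simplest faithful reading of a
vine across two named subsystems.

## Synthesis and constraint enforcement

Generation is: sample correlated uniforms from the hierarchy, map through
the inverse normal CDF, invert the marginal transforms, then enforce the
constraint system. Two mechanisms are provided because published synthetic
cohorts with "100% constraint satisfaction" can be produced either way:

* **rejection** (default): invalid candidates are discarded under a budget
  of 50 attempts per accepted record. Under the default generator the
  violation rate is below 1%, so rejection is cheap and leaves the sampled
  distribution untouched (it is exact conditioning on admissibility);
* **projection**: a deterministic repair used as last resort when the
  budget is exhausted, or as the primary mode on request. Box violations
  clip to the bounds; a stage-sum violation rescales deep and light
  proportionally; a ratio violation moves deep sleep to the nearest ratio
  bound and transfers the difference to light sleep (floored at zero). The
  order — box, sum, ratio — is chosen so each later repair preserves the
  earlier invariants, making the projection idempotent. One-ulp
  floating-point overshoots at the ratio and sum boundaries are nudged
  strictly inside by a relative 1e−12, so repaired records pass the exact
  checker. The projected fraction is reported in the run manifest; the
  dependence-preservation guarantees are stated for projected fractions
  below 5%.

**Clinically weighted regions.** The strategy may name regions (predicate
expressions with weights ≥ 1); four presets ship — short sleep
(total < 6 h), low SDNN (< 50 ms), high deep ratio (> 0.30), elevated LF/HF
(> 3) — at weight 2.0, a package default since no numeric weights are
prescribed anywhere. Weighting is realized by stratified resampling from a
4× candidate pool: a stratum with unweighted share p and weight w receives
share w·p / Σ(w·p), i.e. weight-proportional oversampling capped by pool
feasibility, rather than by deriving region-conditional copulas. This keeps
the mechanism transparent, exactly seeded, and independent of the fitted
model.

All sampling, resampling and tie-breaking run off a single integer seed;
identical (model, n, seed) gives byte-identical CSV output.

## Evaluation metrics

* **KL divergence** is estimated per variable on 50 shared equal-width bins
  spanning the pooled range, with ε = 1e−8 added to both histograms before
  renormalization; the direction is fixed to KL(real ‖ synth). Because
  divergence conventions differ across reports (some summaries score
  "higher is better"), the similarity transform exp(−KL) is reported
  alongside the raw value without asserting either convention.
* **Two-sample KS** uses the classical test; aggregation over the seven
  variables reports the median and minimum p-value. Its type-I rate is
  verified to sit in [0.03, 0.07] at α = 0.05 over 1000 null runs.
* **HSIC** is the Gaussian-kernel biased V-statistic
  trace(K H L H)/n², bandwidths by the median heuristic, p-values from
  ≥ 200 permutations. Usage as a "diversity" score is ambiguous, so two
  modes exist: `dataset` (real table vs synthetic table after
  rank-standardization — low values mean no spurious cross-cohort
  coupling) and `within` (mean pairwise HSIC across the synthetic columns —
  low values mean less redundant internal coupling). Kernel matrices are
  O(n²), so inputs beyond `max_n` rows (default 500) are subsampled
  deterministically.
* **Endpoint performance** reports per-endpoint confusion counts,
  sensitivity and specificity with exact Clopper–Pearson 95% intervals
  (chosen because interval methods are rarely stated alongside published
  CIs, and Clopper–Pearson is conservative and assumption-free). Endpoints
  with no positive (or negative) references yield NA with a flag.

## Profile archetypes

The HRV profile is the ordered quadruple [sSDNN, sRMSSD, sPNN50, sLF/HF].
Clustering is k-means (k = 3, 10 restarts, seeded) on z-scored columns —
z-scoring because the four components have incommensurate units, k-means
because no algorithm is prescribed and the archetypes are descriptive.
Archetype labels attach to clusters by their standardized centroids: the
highest s_rmssd + s_pnn50 centroid is "high variability / low stress"; the
lowest s_sdnn + s_pnn50 among the rest is "low variability / high stress";
the remainder is "moderate". Applying the high-variability rule first makes
the mapping well-defined and invariant to k-means label permutations. The
descriptive marker "variable LF/HF > 3" sometimes attached to the moderate
archetype is not used as an assignment rule. Whether clustering should run
on raw or standardized profiles is genuinely open; standardized was chosen
and fixed.

Validation reports the silhouette score, the Calinski–Harabasz index, mean
bootstrap Jaccard stability (100 resamples of 80% subsets, refit, greedy
best-overlap label matching — a single Jaccard number requires *some*
matching rule, and greedy best-overlap is the simplest that is exact for
separated clusters), and the fraction of points reassigned after adding
Gaussian noise with relative sd 10% per column.

## Chains, reports and parsing

Chain assembly is deterministic text concatenation. Report generation uses
the fixed generation template alone. QA tasks prepend the cluster preamble
of the user's profile to exactly one question-type template (S1:
interpretation of own parameters, S2: recommendation request, S3: general
mechanism), selected by keyword rules; a question matching no rule falls to
a default path with a low-confidence flag. Selecting *one* template rather
than concatenating all three follows the inference-path reading of the
chain definition — a router picks a path, it does not stack them.

Templates and preambles ship as editable plain-text resources. The report
renderer and the parser share one lexicon, authored together so that
parse(render(record)) reproduces the event labels exactly — this round trip
is the package's verifiable stand-in for parsing generated free text, which
is necessarily best-effort (negation handling covers the package's own
phrasings: "no evidence of", "no signs of", "without", "absence of").

## Profile-aided routing

The router computes gate logits `g = W_gateᵀ h + W_profileᵀ enc(p) + b`
with a seeded affine 4 → d_profile_enc encoder (the encoder architecture is
otherwise unspecified, so affine is the minimal choice; default
d_profile_enc = 128, N = 6 experts, k = 3, τ = 0.5). Probabilities are a
temperature-scaled softmax; the top-k mask keeps the k largest (exact ties
to the lowest index); sparse weights are probabilities ∘ mask, deliberately
*not* renormalized, following the weight definition literally — a
renormalization flag exists for comparison.

The four-term loss is L_CE + λ_a L_aux + λ_f L_freq + λ_p L_profile with
defaults λ_a = 0.1, λ_f = 0.15, λ_p = 0.05. L_profile is the negative log
activation probability of the profile-designated expert (clamped at 1e−12);
the designated expert comes from a configurable path→expert map, since
three chain paths must map onto six experts somehow and no mapping is
prescribed. L_aux is the squared deviation of token shares F and
probability shares P from 1/N. L_freq is the literal squared deviation of
selection counts from T/N; because top-k makes ΣA = kT, the literal form
has a nonzero floor for k > 1, and a normalize-by-T² mode is provided — the
normalization is genuinely ambiguous, so both are exposed and the
normalized form is what the toy trainer logs.

In the toy trainer the task loss is the MSE of a routed linear-expert
regression (cluster-specific unit-norm linear maps generate the targets, so
the task sits on the O(1) scale the loss coefficients assume). Gradients
flow through the softmax with the top-k mask treated as constant (the usual
straight-through convention); the F-term of L_aux and the whole of L_freq
are computed from integer counts and are therefore monitored rather than
differentiated — the differentiable P-term does the balancing, as in
standard sparse-MoE practice. Analytic gradients of L_profile and the
P-term of L_aux are verified against numerical differentiation to 1e−5.

## The fixture generator

Because no external cohort is required, tests run against an offline
reference generator with fully known ground truth: log-normal/logit-normal
marginals emulating a healthy adult cohort (≈7.2 h total sleep, ≈21%
deep-sleep ratio, SDNN ≈ 50 ms, RMSSD ≈ 35 ms, LF/HF ≈ 2, PNN50 ≈ 20%),
Gumbel θ = 2 within sleep architecture, Clayton θ = 1.5 within autonomic
regulation, and link ρ = 0.3. The marginal scales were chosen once so the
implied records satisfy the constraint system with probability > 0.99
before enforcement (measured violation rate ≈ 0.2%). An optional archetype
mixture shifts the autonomic latents per record (±3.5 latent units by
default) to produce three separated profile blobs for clustering tests;
the shift must be large on the latent scale because the bounded logit
transforms compress extremes near the physiological bounds.

What the fixture does *not* emulate: measurement error and device
artifacts, repeated measures within subjects, age/sex covariate structure,
non-exchangeable within-subsystem dependence, and real-world marginal
shapes beyond the two parametric families. Passing tests therefore
establish internal correctness (parameter recovery, constraint enforcement,
metric calibration) — not that the generator reproduces any particular
real population.

## Problem sizes and numerical choices

The test and acceptance runs use: 5,000 records for constraint
satisfaction; n = 10,000 at the subsystem dimension (d = 3) for θ recovery
(the mean pairwise tau over three pairs roughly halves the estimator sd
relative to a single pair, matching how the model actually fits); 100
datasets of n = 2000 per family for selection accuracy; 50 seeded runs of
n = 500 for KS self-consistency; 1000 null runs for KS calibration; 600
profiles for clustering; 1000 records for the report round trip; and 10
paired seeds of a 400-sample, d_in = 12, 150-epoch toy training run for the
loss-effect checks. These sizes keep every stage well-estimated while the
whole suite completes in a few minutes.

Numerical guards worth knowing: pseudo-observations use (n+1) scaling;
copula uniforms are clamped to [1e−12, 1−1e−12] before the normal quantile;
boundary shrinkage ε = 1e−6 of the interval width in the transforms;
projection nudges of relative 1e−12 at exact constraint boundaries;
probability clamping at 1e−12 in the profile loss; and exact ties in top-k
selection and cluster assignment resolve to the lowest index.

## Limitations

The generator is cross-sectional and exchangeable within subsystems; it
does not model longitudinal dynamics, covariates, or more than one
cross-subsystem link. KL estimates are histogram-based and carry the usual
binning bias (visible as ≈ +0.05 at the Gaussian-shift oracle). The report
parser is exact only for the package's own templates. The routing harness
is a desk-scale surrogate: it demonstrates that the loss terms shape
routing as intended, not that they improve any language model.
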