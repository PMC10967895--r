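---
title: "Methods: proteome-wide MR for target discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide MR for target discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistical machinery, the
choices made where the design was genuinely open, and what the test suite
does and does not establish. It states no empirical result that the tests or
the acceptance script do not themselves compute.

## The model

A plasma protein is treated as an exposure instrumented by its cis-pQTLs;
a disease (here, an osteoarthritis-like binary trait) is the outcome. Under
the instrumental-variable assumptions (relevance, independence, exclusion),
the Wald ratio `β_out/β_exp` at a valid instrument estimates the causal
log-odds of disease per SD of protein level, and the IVW estimator pools
ratios across instruments with weights `1/se_i²`. Cis instruments are used
because variants near the encoding gene are less likely to act on the
outcome through other pathways; the remaining threats — heterogeneity,
directional pleiotropy, reverse causation, and confounding by LD — are each
addressed by a dedicated diagnostic (Cochran's Q, the MR-Egger intercept,
Steiger filtering, and colocalization/HEIDI respectively).

## Instrument selection

Filters are applied in a fixed, logged order: significance (`p < 5e-8`),
MHC exclusion (chr6, 29–33 Mb, closed interval — excluded for its extreme
LD), cis window, MAF, F-statistic, LD clumping, then palindrome removal and
harmonization. Each dropped variant records the *first* filter that removed
it, so the funnel is auditable and byte-reproducible.

Open choices, resolved as follows:

- **Cis-window anchor.** The 1000 kb window is anchored on the gene *body*
  (`[start − 1e6, end + 1e6]`, 1-based inclusive), not the TSS; with
  summary-level inputs the gene body is the anchor a user can always supply.
- **F-statistic.** The `(β/se)²` approximation is used because per-SNP
  variance explained and exact per-variant sample sizes are not always
  published; this matches common two-sample MR practice. Threshold is
  strict (`F > 10`).
- **Palindromic variants** (A/T, C/G) are always dropped — no
  allele-frequency rescue — because strand cannot be resolved from summary
  data alone and the cost of a few lost instruments is small in a
  proteome-wide screen.
- **Clumping ties** on p-value break lexicographically by variant id, for
  determinism.
- **MAF** filters on `min(eaf, 1 − eaf)`, default 0 for the pQTL stage and
  0.01 for the eQTL stage.

## Estimators and diagnostics

- **Wald ratio SE** is first-order (`se_out/|β_exp|`), ignoring exposure
  uncertainty; the second-order correction is available via
  `wald_ratio(second_order = TRUE)`. First-order is the default of standard
  two-sample MR ratio methods and is conservative only when instruments are
  strong, which the F filter enforces.
- **Random effects.** The paper-style rule "fixed unless heterogeneity"
  needs a threshold; Q's p ≤ 0.05 triggers *multiplicative* random effects
  (SE inflated by `sqrt(max(1, Q/(k−1)))`, floored at the fixed-effect SE).
  Multiplicative rather than additive keeps the point estimate unchanged.
- **Egger intercept** regresses outcome on exposure effects with weights
  `1/se_out²` after orienting all exposure effects non-negative; p is
  two-sided t with `k − 2` df. On perfectly noise-free input the t-ratio is
  0/0; the implementation returns p = 1 when the fitted intercept is
  numerically zero (no residual scatter, no evidence of pleiotropy) and
  p = 0 otherwise.
- **Steiger** uses the per-SNP approximation `r² = z²/(z² + n − 2)` summed
  over instruments, for binary and quantitative traits alike (observed
  scale). This is a documented limitation: for very imbalanced case-control
  outcomes the observed-scale r² understates the liability-scale value, but
  the *comparison* between exposure and outcome — which is all the
  direction test uses — is robust in the regimes the tests exercise.
- **FDR family**: BH is computed per outcome dataset across all proteins
  tested against that outcome, matching per-outcome reporting; `suggestive`
  means nominally significant but not after correction.

## Colocalization

Per-SNP Wakefield log-ABFs (`0.5·log(1−r) + 0.5·z²·r`, `r = W/(V+W)`) are
combined entirely in log space. H3's sum over ordered pairs of distinct
SNPs is evaluated as `log-diff-exp(S1+S2, S12)` with a non-negativity
clamp; a 200-SNP region with z ≈ 40 overflows linear space, which is why
the brute-force linear oracle in the tests is restricted to ≤ 4 SNPs. The
effect-size prior SDs are not stated by the study this pipeline emulates;
the framework defaults (0.15 for quantitative traits, 0.20 log-odds for
case-control) are used and exposed (`sd1`, `sd2`). Priors default to
`p1 = p2 = 1e-4`, `p12 = 1e-5`; `PPH4 ≥ 0.8` (boundary inclusive) calls
colocalization.

## SMR and HEIDI

SMR tests mediation through expression at the top cis-eQTL. HEIDI
eligibility thresholds (eQTL `p < 1.57e-3`, LD `r²` to the top SNP in
`[0.05, 0.9]`, at most the 20 strongest eQTL SNPs, at least 3) follow the
published SMR tool's defaults, since the emulated study configures that
tool without restating them. The statistic sums squared standardized
differences of `b_xy` against the top SNP; its null distribution is a
weighted sum of χ²₁ with weights from the eigenvalues of the correlation
matrix of those differences (delta-method covariance, `cov(β_i, β_j) ≈
r_ij·se_i·se_j` within each trait, traits independent). The tail
probability uses Imhof's inversion integral, evaluated per oscillation
period with a truncation bound from integration by parts (single-weight and
equal-weight cases short-circuit to exact χ² tails; numerically zero
statistics return p = 1). Accuracy is ~1e-8 against exact references; a
seeded Monte-Carlo fallback (default 1e6 draws) guards pathological
weights. HEIDI is known to be slightly conservative under pleiotropy; the
tests tolerate a null rejection rate up to 0.10 at α = 0.05.

## Tier classification

Absent evidence scores as a failed criterion — a protein with no SMR row
cannot pass expression-level validation. An odds ratio exactly 1 fails the
direction criterion (directionality is a prerequisite, and OR = 1 has no
direction). Proteins without usable blood eQTLs are classified on pQTL
colocalization alone (tier 2 if `PPH4 ≥ 0.8`, else tier 4). The packaged
twelve-protein example encodes HEIDI outcomes as indicator stand-ins (0.5
pass / 0.01 fail) because only pass/fail outcomes are available for those
proteins, and leaves the knee-specific SMR fields of CRYZ absent (no
knee-specific SMR evidence exists for it), which yields tier 4 for that
row.

## The synthetic-data generator

Summary statistics are simulated directly at the summary level: joint
causal z-scores `u` project to marginal expectations `R·u` through the LD
matrix, and observed z-scores are multivariate normal around them with
covariance `R` — exactly the sampling model two-sample MR and ABF
colocalization assume. Per-SNP sampling variance is `1/(2·eaf·(1−eaf)·n)`,
divided by `case_fraction·(1−case_fraction)` for binary outcomes (log-odds
scale), which emulates imbalanced biobank phenotypes without fitting a
mixed model. Defaults are the emulated study's stated world: exposure panel
n = 35,559; outcome GWAS n = 403,124 with case fraction ≈ 0.062; eQTL panel
n = 31,684; cis signals with expected causal z ≈ 12 (clearly genome-wide
significant). Scenario-specific regions share, separate (`distinct_causal`,
for linkage), reverse, or remove the exposure–outcome dependency; the
`truth` record enables parameter-recovery and empirical-FDR studies.
`make_study` writes 120-SNP regions by default — large enough for LD
structure to matter, small enough for a 20-protein bundle to run in
seconds.

What the generator does *not* emulate — hence what a green test does not
establish: realistic human LD maps (AR(1)/block models only), allele-
frequency-dependent effect-size architecture, sample overlap between
exposure and outcome panels, population stratification, and liability-scale
subtleties of binary traits. Conclusions from the simulation suites are
about the estimators under their own assumptions, not about robustness to
those violations.

## Numerical choices and degenerate inputs

- All five-hypothesis posteriors are asserted to sum to 1 within 1e-9 on
  every call; H3 cancellation clamps at zero with a warning.
- `β_exp = 0` (Wald), `β_eqtl = 0` (SMR) raise degenerate-instrument
  errors; empty instrument sets yield a `no_instruments` status row, not an
  exception, so a proteome-wide run survives individual failures.
- Steiger clamps instrument r² at `1 − 1e-12` with a warning if it reaches
  1 numerically; equal r² gives direction FALSE with p = 1.
- Determinism: every stochastic component takes an explicit seed; rerunning
  a study on identical inputs produces byte-identical outputs (tested).

## Known limitations

Single-causal-variant colocalization only (no SuSiE-style conditioning);
no multi-SNP SMR; no liability-scale Steiger; LD is an input, never
computed from genotypes; PheWAS "corrected p" uses BH across the outcome
family per protein (Bonferroni available via `correction = "bonferroni"`),
a choice the emulated design leaves unspecified.
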