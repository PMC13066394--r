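---
title: "Methods: bidirectional two-sample Mendelian randomization with bimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bidirectional two-sample Mendelian randomization with bimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimr)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect
$\theta$ of an exposure on an outcome using genetic variants as
instrumental variables, with per-variant association estimates taken from
two non-overlapping GWAS. For instrument $j$ the observed summary
statistics are modelled as

$$\hat\gamma_j \sim N(\gamma_j,\ \sigma_{Xj}^2), \qquad
  \hat\Gamma_j \sim N(\theta\,\gamma_j + \alpha_j,\ \sigma_{Yj}^2),$$

where $\gamma_j$ is the true variant-exposure effect and $\alpha_j$ a
pleiotropic effect on the outcome that bypasses the exposure. Valid
instruments have $\alpha_j = 0$; the estimator battery and the robustness
corrections differ in what they assume about the $\alpha_j$.

* **IVW** regresses $\hat\Gamma_j$ on $\hat\gamma_j$ through the origin
  with weights $1/\sigma_{Yj}^2$, equivalently
  $\hat\theta = \sum w_j\hat\gamma_j\hat\Gamma_j / \sum w_j\hat\gamma_j^2$.
  It is efficient when all $\alpha_j = 0$.
* **MR-Egger** adds an intercept after orienting all $\gamma_j \ge 0$; the
  intercept estimates the mean directional pleiotropy and its t-test
  ($J-2$ df) is the step-2 pleiotropy gate. Validity rests on the InSIDE
  assumption (pleiotropy independent of instrument strength).
* **Weighted median** orders the per-variant ratios
  $\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$ and takes the weighted
  median with the half-weight convention
  $S_j = \sum_{k\le j} w_k - w_j/2$ (normalized), linearly interpolated at
  0.5; consistent while valid instruments hold over half the weight. Its
  SE comes from a seeded parametric bootstrap.
* **Cochran's Q** on the ratios and the **leave-one-variant-out** IVW
  scan ($p_{\max}$) diagnose heterogeneity and single-variant drivers.
* **MR-PRESSO** simulates the null distribution of the weighted residual
  sum of squares around leave-one-out IVW predictions to detect outlier
  instruments, re-estimates after removal, and reports an advisory
  distortion p-value. Outliers are only declared when the global test is
  itself significant: with a finite simulation count the smallest
  achievable per-variant p is 0, and ungated flagging would fix the
  clean-data family-wise false-flag rate near $J/n_{\mathrm{sim}}$
  regardless of the data.
* **Steiger filtering** removes variants explaining more variance in the
  outcome than in the exposure, $r^2 = z^2/(z^2+n)$ per side (an
  EAF-based $2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2$ variant is available
  by option); these are likely reverse-causal.
* The **correlated-pleiotropy model** (`mr_horse`) places a horseshoe
  prior on the $\alpha_j$ (local half-Cauchy scales $\lambda_j$, global
  half-Cauchy scale $\tau$) and lets each $\alpha_j$ correlate with the
  true effect $g_j$ through $\rho_j \sim U(-1,1)$, relaxing InSIDE.
  Sampling is a custom Metropolis-within-Gibbs: $\theta$, $g_j$,
  $\alpha_j$ and the hierarchical mean are conjugate normal updates;
  $\lambda_j$, $\tau$, $\sigma_g$ move on the log scale and $\rho_j$ by a
  reflected random walk. Chains are seeded independently, the first half
  is discarded, and convergence is gated on split-$\hat R \le 1.1$ (a
  result above the gate is returned flagged `unconverged`, never silently
  accepted).

## The decision procedure

Every directed exposure-outcome test is classified into one of six tiers,
in this order:

1. fewer than `min_iv` instruments (default 30, sensitivity value 5)
   → *InsufficientIVs*;
2. optionally, failing the sample-size rule (effective
   $n \ge 100{,}000$ or cases $\ge 10{,}000$; continuous traits on total
   $n$) → *InsufficientSampleSize* — by default this rule is a reporting
   partition, not an exclusion;
3. Egger intercept $p < 0.05$ → *HorizontalPleiotropy*;
4. Benjamini–Hochberg FDR-adjusted IVW $p \ge 0.01$ → *NoAssociation*
   (the BH family is exactly the set of pairs that passed step 1 within
   one direction; pooling both directions is possible but off by
   default);
5. if Cochran's Q has $p < 0.05$, both the weighted-median and Egger
   slopes must share the IVW sign, else *Weak* (requiring both is the
   stricter reading of "the sensitivity tests agree"; an either-suffices
   variant is a config flag);
6. leave-one-out $p_{\max} < 0.05$ is required for *Association*, else
   *Weak*. The leave-one-out gate applies on both the homogeneous and the
   heterogeneous path — a single-variant-driven signal is not an
   association even without detectable heterogeneity.

Association-tier tests then run the step-7 battery (MR-PRESSO, Steiger,
correlated-pleiotropy model); `robust = TRUE` when the outlier-corrected
and direction-filtered IVW estimates stay below `robust_alpha` (0.01)
with the original sign and the posterior interval excludes zero.

Instrument construction before step 1: genome-wide-significant exposure
variants ($p < 5\times10^{-8}$, strict), greedy clumping (ascending p,
10,000 kb window, retained pairs $r^2 < 0.001$), extraction from the
outcome GWAS with proxy substitution ($r^2 > 0.8$, strict; the proxy's
own outcome effect is used, aligned by EAF concordance), then allele
harmonization. Palindromic variants are kept only when both EAFs sit on
the same side of 0.5 outside the ambiguity zone
$[0.42, 0.58]$, otherwise dropped — whether the original analysis
dropped or inferred palindromes is unstated, so the limit is exposed in
the configuration. Instrument strength is summarized by
$F = \beta^2/\mathrm{SE}^2$; $F < 10$ warns of weak-instrument bias.

## Tunable parameters

All thresholds live in `mr_config()` (YAML-loadable via
`read_mr_config()`). Values stated by the protocol: `p_gw = 5e-8`,
`clump_window_kb = 10000`, `clump_r2 = 0.001`, `proxy_r2 = 0.8`,
`min_iv = 30`, `egger_alpha = het_alpha = loo_alpha = 0.05`,
`fdr_alpha = 0.01`, `ci_level = 0.99`, `neff_min = 1e5`,
`ncases_min = 1e4`. Conventions adopted where the protocol is silent:
multiplicative random-effects IVW (SE inflated by $\max(1, s)$ with $s$
the weighted residual SD; fixed-effect by option), normal reference for
IVW and weighted-median p-values, t reference for both Egger
coefficients, palindrome EAF limit 0.42, `wm_boot = 1000`,
`presso_nsim = 1000`, `horse_chains = 4`, `horse_iter = 10000`. The 99%
normal quantile is computed, not hard-coded (2.5758).

## What the synthetic generator emulates

`simulate_pair()` draws EAFs from $U(0.05, 0.95)$, sets per-allele SEs by
the standardized-trait approximation
$1/\sqrt{2\,\mathrm{EAF}(1-\mathrm{EAF})\,n}$ (binary traits reuse it
with the effective sample size), scales true effects so a configurable
fraction (default 0.9) of expected exposure z-scores reach genome-wide
significance, winsorizes expected z at `z_max` (default 40, about the
strongest instruments seen in very large GWAS), and adds pleiotropy by
regime: *balanced* (zero-mean), *directional* (mean `alpha_mean` relative
to the exposure-increasing allele — sign-coupled to $g_j$, because a
fixed-allele-frame shift cancels under Egger orientation and is
undetectable by construction), *correlated*
($\alpha_j = \rho g_j + \varepsilon$, violating InSIDE). Reverse-causal
variants are structural: the primary effect sits on the outcome and the
exposure sees `theta_rev` times it, still large enough to enter the
instrument set, so Steiger detection is a genuine test. Allele records
exercise harmonization (swapped labels, strand flips, palindromes at
configurable rates), and LD is block-diagonal with fixed within-block
$r^2$. Default sample sizes are 500,000 per side — a large but ordinary
biobank-scale GWAS.

Not emulated: LD-induced correlation between the *effect estimates* of
variants sharing a block (LD affects selection only), sample overlap
between the two GWAS, allele-frequency mismatch between populations,
winner's curse in instrument selection, and binary-trait liability-scale
subtleties. A green end-to-end test therefore establishes that the
pipeline implements the stated decision procedure on data satisfying its
assumptions, not that the procedure is robust to those real-data
complications.

Notable generator-design consequences, found by structural analysis
rather than tuning:

* Instruments selected at $p < 5\times10^{-8}$ necessarily carry
  $F = z^2 > 29$, so a weak-instrument (mean $F < 10$) scenario can only
  arise when instruments come from a relaxed threshold; the
  `weak_instrument` fixture is analyzed at `p_gw = 0.05`.
* In a bidirectional-causal pair, each trait's instruments acquire
  induced effects $\theta z$ on the other trait; with large $\theta$ and
  strong instruments they cross the selection threshold and contaminate
  the reverse instrument set, honestly tripping the pleiotropy gate. The
  "causal in both directions" fixture therefore uses moderate effects
  (0.3 and 0.2) with z capped at 7, keeping cross-induced z more than
  3.5 SD below the threshold.
* IVW carries regression-dilution bias of order $\theta/\bar F$ from
  measurement error in $\hat\gamma$. At field-realistic strength
  ($\bar F \approx 40$–$1700$) this exceeds a 2-Monte-Carlo-SE bias
  margin over 500 replicates, so the parameter-recovery study simulates
  very strong instruments (z winsorized at 200) to isolate estimator
  correctness from that known attenuation.

## Numerical choices and degenerate inputs

Weighted regressions are evaluated in closed form (normal equations), and
`stats::lm` serves as an independent oracle in the tests, never as the
implementation. Variants with $\hat\gamma_j = 0$ (possible in synthetic
data after harmonization) are excluded from ratio-based methods with a
log message. P-values are clamped to the smallest positive double so
reported values stay in $(0, 1]$. Estimator preconditions are enforced
(IVW $\ge 2$, Egger/median/leave-one-out $\ge 3$, MR-PRESSO $\ge 4$,
posterior model $\ge 10$ instruments); a failing pair is recorded and
never aborts its family. Clumping breaks p-value ties by (chromosome,
position, id); proxy ties break by higher $r^2$, then smaller position,
then lexical id. Simulation p-values in MR-PRESSO are plain tail
fractions; the result records `n_sim` and the seed. All randomness flows
through per-call isolated RNG streams (`with_seed`), so calls are
reproducible and never perturb the caller's RNG state.

## Known limitations

Single-variant instruments cannot be tested (no estimator precondition is
met below 2, and the tier procedure needs at least `min_iv`). Only
biallelic SNVs enter palindrome/strand logic; indels harmonize by exact
or swapped labels only. Unit metadata is carried as free text with no
harmonization. The correlated-pleiotropy sampler is a pragmatic MCMC, not
a match for any external reference implementation; its output should be
read through the reported $\hat R$ and effective sample size. FDR is
Benjamini–Hochberg only ("q value" is reported identically to the
adjusted p); a Storey estimator is not implemented.
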