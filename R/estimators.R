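# Core MR estimators and diagnostics on a harmonized instrument set.
#
# Notation: gamma_j / sigma_x = variant-exposure effect and SE,
# Gamma_j / sigma_y = variant-outcome effect and SE. All estimators are
# invariant to variant order and to joint sign flips of (gamma_j, Gamma_j).

#' Evaluate an expression under an isolated, seeded RNG stream
#'
#' Saves the caller's RNG state, seeds, evaluates, restores. Every
#' stochastic operation in the package routes its randomness through this
#' helper so results are reproducible per call.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.pclamp <- function(p) pmin(pmax(p, .Machine$double.xmin), 1)

#' Construct an MR estimate record
#'
#' @param method Estimator label.
#' @param beta,se Causal-effect estimate and standard error.
#' @param n_variants Number of instruments used.
#' @param ci_level Two-sided confidence level (default 0.99).
#' @param df If finite, p-value and CI use a t reference with `df` degrees
#'   of freedom; otherwise the normal reference.
#' @param binary_outcome Populate odds-ratio fields `exp(beta)` etc.?
#' @return A list of class `mr_estimate` with `beta`, `se`, `ci_low`,
#'   `ci_high`, `pvalue`, `or_`, `or_low`, `or_high`, `n_variants`.
#' @export
mr_estimate <- function(method, beta, se, n_variants, ci_level = 0.99,
                        df = Inf, binary_outcome = TRUE) {
  if (is.finite(df)) {
    q <- stats::qt(1 - (1 - ci_level) / 2, df = df)
    pvalue <- if (se > 0) 2 * stats::pt(-abs(beta / se), df = df) else
      as.numeric(beta == 0)
  } else {
    q <- stats::qnorm(1 - (1 - ci_level) / 2)
    pvalue <- if (se > 0) 2 * stats::pnorm(-abs(beta / se)) else
      as.numeric(beta == 0)
  }
  ci_low <- beta - q * se
  ci_high <- beta + q * se
  out <- list(
    method = method, beta = beta, se = se,
    ci_low = ci_low, ci_high = ci_high,
    pvalue = .pclamp(pvalue), ci_level = ci_level,
    n_variants = as.integer(n_variants),
    or_ = NA_real_, or_low = NA_real_, or_high = NA_real_
  )
  if (binary_outcome) {
    out$or_ <- exp(beta); out$or_low <- exp(ci_low); out$or_high <- exp(ci_high)
  }
  structure(out, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (SE %.4f), %g%% CI [%.4f, %.4f], p = %.3g",
              x$method, x$beta, x$se, 100 * x$ci_level,
              x$ci_low, x$ci_high, x$pvalue))
  if (is.finite(x$or_)) {
    cat(sprintf("; OR = %.3f [%.3f, %.3f]", x$or_, x$or_low, x$or_high))
  }
  cat("\n")
  invisible(x)
}

#' Odds ratio with confidence bounds from a log-odds estimate
#'
#' `OR = exp(beta)` with bounds `exp(beta -/+ z * se)`, `z` the two-sided
#' normal quantile at `ci_level` (2.5758 at 99%).
#'
#' @param beta,se Log-odds estimate and standard error (`se >= 0`).
#' @param ci_level Confidence level, default 0.99.
#' @return List with `or_`, `or_low`, `or_high`.
#' @export
to_or <- function(beta, se, ci_level = 0.99) {
  stopifnot(se >= 0)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  list(or_ = exp(beta), or_low = exp(beta - z * se),
       or_high = exp(beta + z * se))
}

#' Per-variant ratio (Wald) estimates
#'
#' `theta_j = Gamma_j / gamma_j` with first-order delta-method SE
#' `sigma_Yj / |gamma_j|`. Variants with `gamma_j = 0` (possible after
#' harmonization of synthetic data) are excluded with a message.
#'
#' @param iv An [instrument_set].
#' @return `data.frame` with `variant_id`, `theta`, `se`, `weight`
#'   (`1/se^2`).
#' @export
ratio_estimates <- function(iv) {
  v <- iv$variants
  zero <- v$gamma == 0
  if (any(zero)) {
    message("ratio_estimates: excluded ", sum(zero),
            " variant(s) with gamma = 0")
    v <- v[!zero, , drop = FALSE]
  }
  theta <- v$Gamma / v$gamma
  se <- v$sigma_y / abs(v$gamma)
  data.frame(variant_id = v$variant_id, theta = theta, se = se,
             weight = 1 / se^2, stringsAsFactors = FALSE)
}

# Closed-form IVW on raw gamma/Gamma vectors; shared by mr_ivw, leave-one-out
# and MR-PRESSO. Returns beta, fixed-effect SE and the residual SD used for
# multiplicative random-effects inflation.
.ivw_fit <- function(gamma, Gamma, sigma_y) {
  w <- 1 / sigma_y^2
  swg2 <- sum(w * gamma^2)
  beta <- sum(w * gamma * Gamma) / swg2
  se_fixed <- sqrt(1 / swg2)
  J <- length(gamma)
  resid_sd <- if (J > 1) sqrt(sum(w * (Gamma - beta * gamma)^2) / (J - 1)) else NA_real_
  list(beta = beta, se_fixed = se_fixed, resid_sd = resid_sd, J = J)
}

#' Inverse-variance weighted estimator
#'
#' Weighted regression of the outcome effects on the exposure effects
#' through the origin with weights `1/sigma_Yj^2`; equal to the classical
#' inverse-variance weighted combination of per-variant ratio estimates,
#' `sum(w_j gamma_j Gamma_j) / sum(w_j gamma_j^2)`. Under the default
#' multiplicative random-effects model the fixed-effect SE is inflated by
#' `max(1, residual SD)`; the p-value uses the normal reference.
#'
#' @param iv An [instrument_set] with at least 2 variants.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @param ci_level Confidence level, default 0.99.
#' @param binary_outcome Populate odds-ratio fields?
#' @return An [mr_estimate] with method `"IVW"`.
#' @export
mr_ivw <- function(iv, model = c("multiplicative_random", "fixed"),
                   ci_level = 0.99, binary_outcome = TRUE) {
  model <- match.arg(model)
  v <- iv$variants[iv$variants$gamma != 0, , drop = FALSE]
  if (nrow(v) < 2) {
    stop("mr_ivw: at least 2 instruments required", call. = FALSE)
  }
  fit <- .ivw_fit(v$gamma, v$Gamma, v$sigma_y)
  se <- if (model == "multiplicative_random") {
    fit$se_fixed * max(1, fit$resid_sd)
  } else {
    fit$se_fixed
  }
  mr_estimate("IVW", fit$beta, se, fit$J, ci_level,
              binary_outcome = binary_outcome)
}

#' MR-Egger regression
#'
#' Weighted regression `Gamma_j = alpha + theta * gamma_j` with weights
#' `1/sigma_Yj^2`, after orienting every variant so `gamma_j >= 0` (joint
#' negation of `gamma_j` and `Gamma_j` where needed, which leaves all
#' estimators unchanged). A non-zero intercept `alpha` indicates
#' directional horizontal pleiotropy; the slope is the Egger causal
#' estimate. Both coefficients use a t reference with `J - 2` degrees of
#' freedom; the intercept test is conventionally read at p < 0.05.
#'
#' @param iv An [instrument_set] with at least 3 variants.
#' @param ci_level Confidence level, default 0.99.
#' @param binary_outcome Populate odds-ratio fields on the slope?
#' @return List with `slope` and `intercept`, both [mr_estimate]s.
#' @export
mr_egger <- function(iv, ci_level = 0.99, binary_outcome = TRUE) {
  v <- iv$variants[iv$variants$gamma != 0, , drop = FALSE]
  J <- nrow(v)
  if (J < 3) {
    stop("mr_egger: at least 3 instruments required", call. = FALSE)
  }
  flip <- sign(v$gamma)
  x <- v$gamma * flip
  y <- v$Gamma * flip
  w <- 1 / v$sigma_y^2

  # Closed-form weighted least squares with intercept.
  W <- sum(w); Sx <- sum(w * x); Sy <- sum(w * y)
  Sxx <- sum(w * x^2); Sxy <- sum(w * x * y)
  denom <- W * Sxx - Sx^2
  slope <- (W * Sxy - Sx * Sy) / denom
  intercept <- (Sxx * Sy - Sx * Sxy) / denom
  resid <- y - intercept - slope * x
  s2 <- sum(w * resid^2) / (J - 2)
  se_slope <- sqrt(s2 * W / denom)
  se_int <- sqrt(s2 * Sxx / denom)

  list(
    slope = mr_estimate("Egger-slope", slope, se_slope, J, ci_level,
                        df = J - 2, binary_outcome = binary_outcome),
    intercept = mr_estimate("Egger-intercept", intercept, se_int, J,
                            ci_level, df = J - 2, binary_outcome = FALSE)
  )
}

# Weighted median of point estimates with the half-weight convention
# S_j = cumsum(w_j) - w_j/2 (normalized), linearly interpolated at 0.5.
.weighted_median <- function(theta, weight) {
  o <- order(theta)
  b <- theta[o]
  w <- weight[o] / sum(weight)
  S <- cumsum(w) - w / 2
  if (S[1] >= 0.5) return(b[1])
  below <- max(which(S < 0.5))
  if (below == length(b)) return(b[length(b)])
  b[below] + (b[below + 1] - b[below]) * (0.5 - S[below]) /
    (S[below + 1] - S[below])
}

#' Weighted-median estimator
#'
#' Consistent when valid instruments carry more than half of the total
#' inverse-variance weight. Ratio estimates are ordered and the estimate is
#' the interpolated theta where the cumulative standardized weight (with
#' the half-weight convention) crosses 0.5. The SE comes from a seeded
#' parametric bootstrap resampling `gamma_j` and `Gamma_j` from normal
#' distributions with their reported SEs.
#'
#' @param iv An [instrument_set] with at least 3 variants.
#' @param n_boot Bootstrap replicates, default 1000.
#' @param seed RNG seed for the bootstrap (isolated per call).
#' @param ci_level Confidence level, default 0.99.
#' @param binary_outcome Populate odds-ratio fields?
#' @return An [mr_estimate] with method `"WeightedMedian"`.
#' @export
mr_weighted_median <- function(iv, n_boot = 1000, seed = 1,
                               ci_level = 0.99, binary_outcome = TRUE) {
  v <- iv$variants[iv$variants$gamma != 0, , drop = FALSE]
  J <- nrow(v)
  if (J < 3) {
    stop("mr_weighted_median: at least 3 instruments required", call. = FALSE)
  }
  theta <- v$Gamma / v$gamma
  weight <- v$gamma^2 / v$sigma_y^2
  beta <- .weighted_median(theta, weight)

  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      g <- stats::rnorm(J, v$gamma, v$sigma_x)
      G <- stats::rnorm(J, v$Gamma, v$sigma_y)
      ok <- g != 0
      .weighted_median(G[ok] / g[ok], g[ok]^2 / v$sigma_y[ok]^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_estimate("WeightedMedian", beta, se, J, ci_level,
              binary_outcome = binary_outcome)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum((theta_j - beta_IVW)^2 / se_j^2)` over per-variant ratio
#' estimates, referred to the upper tail of a chi-square with `J - 1`
#' degrees of freedom. Large Q indicates variant heterogeneity of the
#' causal-effect estimates.
#'
#' @param iv An [instrument_set] with at least 2 variants.
#' @param ivw_beta The IVW point estimate; computed internally if missing.
#' @return List of class `heterogeneity_result` with `q_stat`, `df`,
#'   `pvalue`.
#' @export
cochran_q <- function(iv, ivw_beta = NULL) {
  r <- ratio_estimates(iv)
  if (nrow(r) < 2) {
    stop("cochran_q: at least 2 instruments required", call. = FALSE)
  }
  if (is.null(ivw_beta)) {
    v <- iv$variants[iv$variants$gamma != 0, , drop = FALSE]
    ivw_beta <- .ivw_fit(v$gamma, v$Gamma, v$sigma_y)$beta
  }
  q <- sum((r$theta - ivw_beta)^2 / r$se^2)
  df <- nrow(r) - 1
  structure(
    list(q_stat = q, df = df,
         pvalue = stats::pchisq(q, df = df, lower.tail = FALSE)),
    class = "heterogeneity_result"
  )
}

#' Leave-one-variant-out IVW analysis
#'
#' Refits the IVW estimator on every size `J - 1` subset. `p_max`, the
#' largest subset p-value, answers whether the pooled signal survives the
#' removal of any single variant (read at p_max < 0.05).
#'
#' @param iv An [instrument_set] with at least 3 variants.
#' @param model,ci_level Passed to [mr_ivw].
#' @return List of class `loo_result` with `per_variant` (`data.frame`:
#'   `left_out_id`, `beta`, `se`, `pvalue`) and `p_max`.
#' @export
leave_one_out <- function(iv, model = "multiplicative_random",
                          ci_level = 0.99) {
  v <- iv$variants[iv$variants$gamma != 0, , drop = FALSE]
  J <- nrow(v)
  if (J < 3) {
    stop("leave_one_out: at least 3 instruments required", call. = FALSE)
  }
  rows <- lapply(seq_len(J), function(j) {
    sub <- instrument_set(v[-j, , drop = FALSE],
                          exposure_name = iv$exposure_name,
                          outcome_name = iv$outcome_name)
    est <- mr_ivw(sub, model = model, ci_level = ci_level,
                  binary_outcome = FALSE)
    data.frame(left_out_id = v$variant_id[j], beta = est$beta, se = est$se,
               pvalue = est$pvalue, stringsAsFactors = FALSE)
  })
  per_variant <- do.call(rbind, rows)
  structure(
    list(per_variant = per_variant, p_max = max(per_variant$pvalue)),
    class = "loo_result"
  )
}
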