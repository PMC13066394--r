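# FDR adjustment and the tiered evidence classification.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment with monotonicity enforcement, returned in input
#' order. A thin validating wrapper over [stats::p.adjust].
#'
#' @param pvalues Numeric vector with all values in (0, 1].
#' @return Adjusted values ("q values") in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("bh_fdr: p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Evidence tiers
#'
#' @return Character vector of the six tier labels.
#' @export
mr_tiers <- function() {
  c("Association", "Weak", "HorizontalPleiotropy", "NoAssociation",
    "InsufficientIVs", "InsufficientSampleSize")
}

#' Classify one directed test into an evidence tier
#'
#' The multi-step decision procedure applied to every directed
#' exposure-outcome test, in order:
#'
#' 1. fewer than `min_iv` instruments -> `"InsufficientIVs"`;
#' 2. (only when `apply_sample_size_filter` is set) failing the
#'    sample-size rule -> `"InsufficientSampleSize"`;
#' 3. Egger intercept p < `egger_alpha` -> `"HorizontalPleiotropy"`
#'    (directional pleiotropy disqualifies the test regardless of the IVW
#'    result);
#' 4. FDR-adjusted IVW p >= `fdr_alpha` -> `"NoAssociation"`;
#' 5. with heterogeneity p < `het_alpha`, both the weighted-median and
#'    Egger slopes must share the IVW sign, else `"Weak"`;
#' 6. the leave-one-variant-out p_max must be < `loo_alpha` for
#'    `"Association"`, else `"Weak"`.
#'
#' A diagnostic that is missing but needed at the step actually reached
#' raises an incomplete-evaluation error; diagnostics past the deciding
#' step are never required.
#'
#' @param n_variable Number of instruments.
#' @param egger_intercept_p Egger intercept p-value.
#' @param fdr_q FDR-adjusted IVW p-value.
#' @param het_p Cochran's Q p-value.
#' @param ivw_sign,wm_sign,egger_sign Signs of the IVW, weighted-median and
#'   Egger slope estimates (only consulted when heterogeneity is present).
#' @param loo_p_max Maximum leave-one-out p-value.
#' @param passes_sample_size Logical; consulted only when
#'   `config$apply_sample_size_filter` is `TRUE`.
#' @param config Threshold list, see [mr_config()].
#' @return One of [mr_tiers()].
#' @export
classify_tier <- function(n_variable, egger_intercept_p = NULL, fdr_q = NULL,
                          het_p = NULL, ivw_sign = NULL, wm_sign = NULL,
                          egger_sign = NULL, loo_p_max = NULL,
                          passes_sample_size = TRUE, config = mr_config()) {
  need <- function(x, what) {
    if (is.null(x) || length(x) == 0 || is.na(x)) {
      stop("classify_tier: incomplete evaluation - missing ", what,
           call. = FALSE)
    }
    x
  }
  if (need(n_variable, "n_variable") < config$min_iv) {
    return("InsufficientIVs")
  }
  if (isTRUE(config$apply_sample_size_filter) && !isTRUE(passes_sample_size)) {
    return("InsufficientSampleSize")
  }
  if (need(egger_intercept_p, "egger_intercept_p") < config$egger_alpha) {
    return("HorizontalPleiotropy")
  }
  if (need(fdr_q, "fdr_q") >= config$fdr_alpha) {
    return("NoAssociation")
  }
  if (need(het_p, "heterogeneity p") < config$het_alpha) {
    ivw_sign <- need(ivw_sign, "ivw_sign")
    agree <- if (isTRUE(config$require_both_sensitivity)) {
      need(wm_sign, "wm_sign") == ivw_sign &&
        need(egger_sign, "egger_sign") == ivw_sign
    } else {
      need(wm_sign, "wm_sign") == ivw_sign ||
        need(egger_sign, "egger_sign") == ivw_sign
    }
    if (!agree) return("Weak")
  }
  if (need(loo_p_max, "loo_p_max") < config$loo_alpha) "Association" else "Weak"
}
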