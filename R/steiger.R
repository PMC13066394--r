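# Steiger directionality filtering: remove instruments that explain more
# variance in the outcome than in the exposure (likely reverse-causal).

#' Steiger directionality filter
#'
#' Per instrument, the variance explained on each side is approximated from
#' the test statistic and sample size as `r2 = z^2 / (z^2 + n)` with
#' `z = beta/se` — no allele frequency needed. A variant points in the
#' assumed causal direction (`direction_ok`) when `r2_exposure >
#' r2_outcome`; `steiger_p` records the two-sided p-value of Steiger's
#' z-test comparing the two (Fisher-transformed) correlations. The filtered
#' estimate is the IVW fit on direction-consistent variants, identical to
#' the plain IVW when nothing is removed. When EAF and effect size are
#' preferred, `r2_method = "eaf"` uses `2 * eaf * (1 - eaf) * beta^2` on
#' the observed scale (exposure side only where EAF is carried).
#'
#' @param iv An [instrument_set].
#' @param exposure,outcome The source `gwas_summary` objects (for
#'   per-variant or trait-level sample sizes).
#' @param alpha Significance level recorded with the result, default 0.05.
#' @param r2_method `"z2"` (default) or `"eaf"`.
#' @param ci_level Confidence level for the filtered estimate.
#' @return List of class `steiger_result`: `per_variant` (`data.frame`
#'   with `variant_id`, `r2_exposure`, `r2_outcome`, `direction_ok`,
#'   `steiger_p`), `filtered_estimate` (or `NULL`), `insufficient` flag.
#' @export
steiger_filter <- function(iv, exposure, outcome, alpha = 0.05,
                           r2_method = c("z2", "eaf"), ci_level = 0.99) {
  r2_method <- match.arg(r2_method)
  v <- iv$variants[iv$variants$gamma != 0, , drop = FALSE]
  if (nrow(v) == 0) stop("steiger_filter: empty instrument set", call. = FALSE)

  trait_n <- function(gw, label) {
    n <- gw$variants$n[match(v$variant_id, gw$variants$variant_id)]
    fallback <- if (isTRUE(gw$is_binary)) gw$effective_n else gw$n_total
    n[is.na(n)] <- fallback
    if (any(is.na(n))) {
      stop("steiger_filter: sample size unavailable for trait '",
           label, "'", call. = FALSE)
    }
    n
  }
  n_x <- trait_n(exposure, exposure$trait_name)
  n_y <- trait_n(outcome, outcome$trait_name)

  z_x <- v$gamma / v$sigma_x
  z_y <- v$Gamma / v$sigma_y
  if (r2_method == "z2") {
    r2_x <- z_x^2 / (z_x^2 + n_x)
    r2_y <- z_y^2 / (z_y^2 + n_y)
  } else {
    if (any(is.na(v$eaf))) {
      stop("steiger_filter: r2_method = 'eaf' requires EAF on every variant",
           call. = FALSE)
    }
    maf_var <- 2 * v$eaf * (1 - v$eaf)
    r2_x <- pmin(maf_var * v$gamma^2, 0.999)
    r2_y <- pmin(maf_var * v$Gamma^2, 0.999)
  }
  direction_ok <- r2_x > r2_y

  # Steiger's z-test on Fisher-transformed correlations.
  fz_x <- atanh(sqrt(r2_x))
  fz_y <- atanh(sqrt(r2_y))
  z_stat <- (fz_x - fz_y) / sqrt(1 / (n_x - 3) + 1 / (n_y - 3))
  steiger_p <- 2 * stats::pnorm(-abs(z_stat))

  per_variant <- data.frame(
    variant_id = v$variant_id,
    r2_exposure = r2_x, r2_outcome = r2_y,
    direction_ok = direction_ok, steiger_p = steiger_p,
    stringsAsFactors = FALSE
  )

  insufficient <- sum(direction_ok) < 2
  filtered <- NULL
  if (!insufficient) {
    keep <- instrument_set(v[direction_ok, , drop = FALSE],
                           exposure_name = iv$exposure_name,
                           outcome_name = iv$outcome_name)
    filtered <- mr_ivw(keep, ci_level = ci_level)
  }
  structure(
    list(per_variant = per_variant, filtered_estimate = filtered,
         insufficient = insufficient, alpha = alpha),
    class = "steiger_result"
  )
}
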