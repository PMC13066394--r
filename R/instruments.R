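# Instrument selection, LD clumping, proxy substitution and allele
# harmonization for one directed exposure -> outcome test.

.complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

.is_palindromic <- function(ea, oa) {
  nchar(ea) == 1 & nchar(oa) == 1 & .complement_allele(ea) == oa
}

#' Instrument strength F-statistic
#'
#' `F = beta^2 / SE^2` for a variant's association with the exposure. An
#' instrument with F below 10 is conventionally flagged as weak.
#'
#' @param beta,se Effect size and standard error on the exposure; `se > 0`.
#' @return The F-statistic (vectorized).
#' @examples
#' f_statistic(0.1, 0.02) # 25
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("f_statistic: se must be positive", call. = FALSE)
  }
  beta^2 / se^2
}

#' Select genome-wide-significant exposure variants
#'
#' Retains exactly the variants with `pvalue < p_threshold` (strict
#' inequality), preserving input order.
#'
#' @param exposure A `gwas_summary`.
#' @param p_threshold Significance threshold, default `5e-8`.
#' @return `data.frame` of retained variant rows (possibly empty).
#' @export
select_significant <- function(exposure, p_threshold = 5e-8) {
  stopifnot(inherits(exposure, "gwas_summary"))
  v <- exposure$variants
  v[v$pvalue < p_threshold, , drop = FALSE]
}

#' Greedy LD clumping
#'
#' PLINK-style greedy selection: candidates are visited in ascending p-value
#' order (ties broken by chromosome, position, id) and accepted unless they
#' lie within `window_kb` of an already-accepted variant on the same
#' chromosome with `r2 >= r2_cutoff`. Output is sorted by (chrom, pos).
#'
#' @param candidates `data.frame` of variant rows with `chrom`, `pos`,
#'   `pvalue`, `variant_id`.
#' @param ld An [ld_provider].
#' @param window_kb Clumping window in kilobases (default 10000).
#' @param r2_cutoff Variants with `r2 >=` this value against an accepted
#'   variant are removed (default 0.001, i.e. retained pairs satisfy
#'   `r2 < 0.001`).
#' @return `data.frame` of index variants sorted by (chrom, pos).
#' @export
clump <- function(candidates, ld, window_kb = 10000, r2_cutoff = 0.001) {
  if (nrow(candidates) == 0) return(candidates)
  if (any(is.na(candidates$chrom)) || any(is.na(candidates$pos))) {
    stop("clump: candidates must carry chrom and pos", call. = FALSE)
  }
  ord <- order(candidates$pvalue, candidates$chrom, candidates$pos,
               candidates$variant_id)
  cand <- candidates[ord, , drop = FALSE]
  accepted <- integer(0)
  for (i in seq_len(nrow(cand))) {
    keep <- TRUE
    if (length(accepted) > 0) {
      acc <- cand[accepted, , drop = FALSE]
      near <- acc$chrom == cand$chrom[i] &
        abs(acc$pos - cand$pos[i]) <= window_kb * 1000
      if (any(near)) {
        r2 <- ld$r2(cand$variant_id[i], acc$variant_id[near])
        if (any(r2 >= r2_cutoff)) keep <- FALSE
      }
    }
    if (keep) accepted <- c(accepted, i)
  }
  out <- cand[accepted, , drop = FALSE]
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Find an LD proxy in the outcome GWAS
#'
#' Searches outcome variants on the same chromosome within the clumping
#' window for the highest-r2 proxy with `r2 > proxy_r2` (strict). Ties break
#' by smaller position, then lexically smaller id.
#'
#' @param missing Single-row `data.frame`: the index variant absent from the
#'   outcome.
#' @param outcome A `gwas_summary`.
#' @param ld An [ld_provider].
#' @param proxy_r2 Minimum (exclusive) r2, default 0.8.
#' @param window_kb Search window in kilobases, default 10000.
#' @return The proxy variant row, or `NULL` if none qualifies.
#' @export
find_proxy <- function(missing, outcome, ld, proxy_r2 = 0.8,
                       window_kb = 10000) {
  stopifnot(inherits(outcome, "gwas_summary"))
  ov <- outcome$variants
  cand <- ov[!is.na(ov$chrom) & !is.na(ov$pos) &
               ov$chrom == missing$chrom &
               abs(ov$pos - missing$pos) <= window_kb * 1000 &
               ov$variant_id != missing$variant_id, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  r2 <- ld$r2(missing$variant_id, cand$variant_id)
  cand <- cand[r2 > proxy_r2, , drop = FALSE]
  r2 <- r2[r2 > proxy_r2]
  if (nrow(cand) == 0) return(NULL)
  best <- order(-r2, cand$pos, cand$variant_id)[1]
  cand[best, , drop = FALSE]
}

#' Construct an instrument set
#'
#' @param variants `data.frame` of harmonized pairs with columns
#'   `variant_id`, `effect_allele`, `other_allele`, `gamma`, `sigma_x`,
#'   `Gamma`, `sigma_y`, `eaf`, `f_stat`.
#' @param exclusions `data.frame` with `variant_id`, `reason`.
#' @param exposure_name,outcome_name Trait labels.
#' @return An object of class `instrument_set`.
#' @export
instrument_set <- function(variants, exclusions = NULL,
                           exposure_name = "exposure",
                           outcome_name = "outcome") {
  if (is.null(exclusions)) {
    exclusions <- data.frame(variant_id = character(0),
                             reason = character(0),
                             stringsAsFactors = FALSE)
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (nrow(variants) > 0) {
    stopifnot(all(variants$sigma_x > 0), all(variants$sigma_y > 0))
  }
  rownames(variants) <- NULL
  structure(
    list(
      exposure_name = exposure_name,
      outcome_name  = outcome_name,
      variants      = variants,
      n_variable    = nrow(variants),
      mean_f        = if (nrow(variants) > 0) mean(variants$f_stat) else NA_real_,
      exclusions    = exclusions
    ),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set: ", x$exposure_name, " -> ", x$outcome_name, "\n",
      sep = "")
  cat("  n_variable = ", x$n_variable,
      "; mean F = ", format(round(x$mean_f, 1)),
      "; ", nrow(x$exclusions), " exclusion(s)\n", sep = "")
  invisible(x)
}

#' Harmonize exposure and outcome effects to shared alleles
#'
#' For each variant id present in both collections the outcome record is
#' re-expressed relative to the exposure's effect allele:
#' identical alleles pass through; swapped alleles negate the outcome beta
#' and complement its EAF; strand-complemented (and swapped-complemented)
#' records are recoded first; palindromic pairs (A/T, C/G) are kept only
#' when both EAFs lie on the same side of 0.5 and both fall outside the
#' ambiguity zone `[palindrome_eaf_limit, 1 - palindrome_eaf_limit]`,
#' otherwise they are dropped with reason `"palindromic-ambiguous"`.
#' Incompatible allele pairs are dropped with reason
#' `"incompatible-alleles"`. Indel alleles (length > 1) never enter the
#' palindromic or strand-complement logic. Drops are logged, never raised.
#'
#' @param exposure_variants,outcome_variants Variant `data.frame`s as held
#'   by [gwas_summary] objects.
#' @param palindrome_eaf_limit Lower edge of the EAF ambiguity zone
#'   (default 0.42).
#' @param exposure_name,outcome_name Trait labels for the result.
#' @return An [instrument_set]; `gamma`/`sigma_x` come from the exposure,
#'   `Gamma`/`sigma_y` from the (re-oriented) outcome, `f_stat` from the
#'   exposure association.
#' @export
harmonize <- function(exposure_variants, outcome_variants,
                      palindrome_eaf_limit = 0.42,
                      exposure_name = "exposure", outcome_name = "outcome") {
  ex <- as.data.frame(exposure_variants, stringsAsFactors = FALSE)
  ou <- as.data.frame(outcome_variants, stringsAsFactors = FALSE)
  shared <- intersect(ex$variant_id, ou$variant_id)
  ex <- ex[match(shared, ex$variant_id), , drop = FALSE]
  ou <- ou[match(shared, ou$variant_id), , drop = FALSE]

  keep <- logical(length(shared))
  reason <- character(length(shared))
  Gamma <- numeric(length(shared))
  eaf_out <- rep(NA_real_, length(shared))

  for (i in seq_along(shared)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    b_y <- ou$beta[i]; f_y <- ou$eaf[i]
    is_indel <- nchar(ea_x) > 1 || nchar(oa_x) > 1 ||
      nchar(ea_y) > 1 || nchar(oa_y) > 1
    pal <- !is_indel && .is_palindromic(ea_x, oa_x)

    aligned <- FALSE
    if (ea_y == ea_x && oa_y == oa_x) {
      aligned <- TRUE
    } else if (ea_y == oa_x && oa_y == ea_x) {
      b_y <- -b_y
      if (!is.na(f_y)) f_y <- 1 - f_y
      aligned <- TRUE
    } else if (!is_indel) {
      cea <- .complement_allele(ea_y); coa <- .complement_allele(oa_y)
      if (cea == ea_x && coa == oa_x) {
        aligned <- TRUE
      } else if (cea == oa_x && coa == ea_x) {
        b_y <- -b_y
        if (!is.na(f_y)) f_y <- 1 - f_y
        aligned <- TRUE
      }
    }
    if (!aligned) {
      reason[i] <- "incompatible-alleles"
      next
    }
    if (pal) {
      f_x <- ex$eaf[i]
      lo <- palindrome_eaf_limit; hi <- 1 - palindrome_eaf_limit
      unambiguous <- !is.na(f_x) && !is.na(f_y) &&
        (f_x < lo || f_x > hi) && (f_y < lo || f_y > hi) &&
        sign(f_x - 0.5) == sign(f_y - 0.5)
      if (!unambiguous) {
        reason[i] <- "palindromic-ambiguous"
        next
      }
    }
    keep[i] <- TRUE
    Gamma[i] <- b_y
    eaf_out[i] <- f_y
  }

  harmonized <- data.frame(
    variant_id    = shared[keep],
    chrom         = ex$chrom[keep],
    pos           = ex$pos[keep],
    effect_allele = ex$effect_allele[keep],
    other_allele  = ex$other_allele[keep],
    gamma         = ex$beta[keep],
    sigma_x       = ex$se[keep],
    Gamma         = Gamma[keep],
    sigma_y       = ou$se[keep],
    eaf           = ex$eaf[keep],
    f_stat        = f_statistic(ex$beta[keep], ex$se[keep]),
    stringsAsFactors = FALSE
  )
  exclusions <- data.frame(
    variant_id = shared[!keep],
    reason     = reason[!keep],
    stringsAsFactors = FALSE
  )
  instrument_set(harmonized, exclusions, exposure_name, outcome_name)
}

#' Build the harmonized instrument set for one directed test
#'
#' Composes the selection stages preceding the estimator battery:
#' genome-wide-significant exposure variants, greedy LD clumping, extraction
#' of the same variants (or qualifying proxies) from the outcome GWAS, and
#' allele harmonization. Per-variant and mean F-statistics are attached; a
#' complete exclusion log records every variant removed and why. Weak
#' instruments (F < 10) trigger a warning but are retained.
#'
#' @param exposure,outcome `gwas_summary` objects.
#' @param ld An [ld_provider].
#' @param config Threshold list, see [mr_config()]; keys used: `p_gw`,
#'   `clump_window_kb`, `clump_r2`, `proxy_r2`, `palindrome_eaf_limit`.
#' @return An [instrument_set].
#' @export
build_instrument_set <- function(exposure, outcome, ld, config = mr_config()) {
  stopifnot(inherits(exposure, "gwas_summary"),
            inherits(outcome, "gwas_summary"))
  sig <- select_significant(exposure, config$p_gw)
  if (nrow(sig) == 0) {
    return(instrument_set(
      data.frame(variant_id = character(0), effect_allele = character(0),
                 other_allele = character(0), gamma = numeric(0),
                 sigma_x = numeric(0), Gamma = numeric(0),
                 sigma_y = numeric(0), eaf = numeric(0), f_stat = numeric(0)),
      exposure_name = exposure$trait_name, outcome_name = outcome$trait_name
    ))
  }
  idx <- clump(sig, ld, config$clump_window_kb, config$clump_r2)

  ov <- outcome$variants
  excl <- data.frame(variant_id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  direct <- idx$variant_id %in% ov$variant_id
  exp_rows <- idx[direct, , drop = FALSE]
  out_rows <- ov[match(exp_rows$variant_id, ov$variant_id), , drop = FALSE]

  # Proxy substitution: the index variant's exposure effect is paired with
  # the proxy's own outcome effect, oriented by EAF concordance.
  proxy_exp <- list(); proxy_out <- list()
  for (i in which(!direct)) {
    pr <- find_proxy(idx[i, , drop = FALSE], outcome, ld,
                     config$proxy_r2, config$clump_window_kb)
    if (is.null(pr)) {
      excl <- rbind(excl, data.frame(variant_id = idx$variant_id[i],
                                     reason = "missing-in-outcome"))
      next
    }
    f_x <- idx$eaf[i]; f_y <- pr$eaf
    lo <- config$palindrome_eaf_limit; hi <- 1 - lo
    if (is.na(f_x) || is.na(f_y) ||
        !(f_x < lo || f_x > hi) || !(f_y < lo || f_y > hi)) {
      excl <- rbind(excl, data.frame(variant_id = idx$variant_id[i],
                                     reason = "proxy-eaf-ambiguous"))
      next
    }
    flip <- sign(f_x - 0.5) != sign(f_y - 0.5)
    pr$beta <- if (flip) -pr$beta else pr$beta
    pr$eaf <- if (flip) 1 - pr$eaf else pr$eaf
    # Present the proxy under the index variant's id and alleles so
    # harmonization treats the pair as already aligned.
    pr$variant_id <- idx$variant_id[i]
    pr$effect_allele <- idx$effect_allele[i]
    pr$other_allele <- idx$other_allele[i]
    proxy_exp[[length(proxy_exp) + 1]] <- idx[i, , drop = FALSE]
    proxy_out[[length(proxy_out) + 1]] <- pr
  }
  if (length(proxy_exp) > 0) {
    exp_rows <- rbind(exp_rows, do.call(rbind, proxy_exp))
    out_rows <- rbind(out_rows, do.call(rbind, proxy_out))
  }

  iv <- harmonize(exp_rows, out_rows, config$palindrome_eaf_limit,
                  exposure$trait_name, outcome$trait_name)
  iv$exclusions <- rbind(iv$exclusions, excl)
  if (iv$n_variable > 0) {
    ord <- order(iv$variants$chrom, iv$variants$pos)
    iv$variants <- iv$variants[ord, , drop = FALSE]
    rownames(iv$variants) <- NULL
  }
  n_weak <- sum(iv$variants$f_stat < 10)
  if (n_weak > 0) {
    warning("build_instrument_set: ", n_weak,
            " instrument(s) with F-statistic < 10 (weak-instrument bias)",
            call. = FALSE)
  }
  iv
}
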