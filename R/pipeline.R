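# Orchestration of the multi-step decision procedure over families of
# directed exposure -> outcome tests.

#' Analysis configuration
#'
#' All thresholds and simulation settings of the pipeline in one list.
#' Defaults follow the published protocol where it states a value
#' (genome-wide significance 5e-8; 10,000 kb clumping window with r2 <
#' 0.001; proxies at r2 > 0.8; minimum 30 instruments, relaxable to 5;
#' Egger intercept, heterogeneity and leave-one-out alpha 0.05; FDR alpha
#' 0.01; 99% confidence intervals; effective sample size >= 100,000 or >=
#' 10,000 cases) and common two-sample MR practice where it does not
#' (multiplicative random-effects IVW, palindrome EAF ambiguity limit
#' 0.42, simulation and MCMC sizes).
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `mr_config`.
#' @export
mr_config <- function(...) {
  cfg <- list(
    # instrument selection
    p_gw = 5e-8, clump_window_kb = 10000, clump_r2 = 0.001,
    proxy_r2 = 0.8, palindrome_eaf_limit = 0.42,
    # decision thresholds
    min_iv = 30, fdr_alpha = 0.01, egger_alpha = 0.05, het_alpha = 0.05,
    loo_alpha = 0.05, require_both_sensitivity = TRUE,
    # sample-size reporting rule
    neff_min = 100000, ncases_min = 10000, apply_sample_size_filter = FALSE,
    # estimators
    ci_level = 0.99, ivw_model = "multiplicative_random", wm_boot = 1000,
    # step-7 battery
    presso_nsim = 1000, presso_alpha = 0.05,
    horse_chains = 4, horse_iter = 10000, robust_alpha = 0.01,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop("mr_config: unknown option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(utils::modifyList(cfg, overrides), class = "mr_config")
}

#' Read a configuration from a YAML file
#'
#' Keys absent from the file keep their [mr_config()] defaults.
#'
#' @param path YAML file path.
#' @return An `mr_config` list.
#' @export
read_mr_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(mr_config, vals)
}

#' Partition GWAS summaries by the sample-size rule
#'
#' A binary-trait summary passes when its effective sample size is at least
#' `neff_min` or its case count at least `ncases_min` (a disjunction);
#' continuous traits pass on total sample size alone.
#'
#' @param summaries List of `gwas_summary` objects.
#' @param neff_min,ncases_min Rule thresholds (defaults 100,000 and
#'   10,000).
#' @return List with `pass` and `fail` sublists and a logical `passes`
#'   vector in input order.
#' @export
sample_size_filter <- function(summaries, neff_min = 100000,
                               ncases_min = 10000) {
  if (inherits(summaries, "gwas_summary")) summaries <- list(summaries)
  passes <- vapply(summaries, function(gw) {
    if (isTRUE(gw$is_binary)) {
      (!is.na(gw$effective_n) && gw$effective_n >= neff_min) ||
        (!is.na(gw$n_cases) && gw$n_cases >= ncases_min)
    } else {
      !is.na(gw$n_total) && gw$n_total >= neff_min
    }
  }, logical(1))
  list(pass = summaries[passes], fail = summaries[!passes], passes = passes)
}

.passes_sample_size <- function(exposure, outcome, config) {
  all(sample_size_filter(list(exposure, outcome),
                         config$neff_min, config$ncases_min)$passes)
}

# Evaluate the estimator battery (steps 2-6 diagnostics) for one pair that
# already passed the instrument-count restriction.
.evaluate_pair <- function(iv, exposure, outcome, config) {
  binary <- isTRUE(outcome$is_binary)
  ivw <- mr_ivw(iv, model = config$ivw_model, ci_level = config$ci_level,
                binary_outcome = binary)
  egger <- mr_egger(iv, ci_level = config$ci_level, binary_outcome = binary)
  wm <- mr_weighted_median(iv, n_boot = config$wm_boot,
                           seed = config$seed + 101L,
                           ci_level = config$ci_level,
                           binary_outcome = binary)
  het <- cochran_q(iv, ivw$beta)
  loo <- leave_one_out(iv, model = config$ivw_model,
                       ci_level = config$ci_level)
  list(ivw = ivw, egger_slope = egger$slope, egger_intercept = egger$intercept,
       wm = wm, heterogeneity = het, loo = loo)
}

# Step-7 battery: outlier removal, directionality filtering, correlated
# pleiotropy correction. Returns the three results plus the robust flag.
.step7_battery <- function(iv, exposure, outcome, ivw, config) {
  presso <- tryCatch(
    mr_presso(iv, n_sim = config$presso_nsim,
              outlier_alpha = config$presso_alpha,
              seed = config$seed + 211L, ci_level = config$ci_level),
    error = function(e) NULL
  )
  steiger <- tryCatch(
    steiger_filter(iv, exposure, outcome, ci_level = config$ci_level),
    error = function(e) NULL
  )
  horse <- tryCatch(
    mr_horse(iv, n_chains = config$horse_chains, n_iter = config$horse_iter,
             ci_level = config$ci_level, seed = config$seed + 307L),
    error = function(e) NULL
  )
  sgn <- sign(ivw$beta)
  ok_est <- function(est) {
    !is.null(est) && est$pvalue < config$robust_alpha && sign(est$beta) == sgn
  }
  robust <- ok_est(presso$corrected_estimate) &&
    !is.null(steiger) && !steiger$insufficient &&
    ok_est(steiger$filtered_estimate) &&
    !is.null(horse) && !isTRUE(horse$unconverged) &&
    (horse$theta_ci_low > 0 || horse$theta_ci_high < 0)
  list(presso = presso, steiger = steiger, horse = horse, robust = robust)
}

.new_evaluation <- function(exposure, outcome, iv) {
  structure(
    list(
      exposure_name = exposure$trait_name,
      outcome_name = outcome$trait_name,
      n_variable = iv$n_variable,
      mean_f = iv$mean_f,
      ivw = NULL, fdr_q = NULL, egger_slope = NULL, egger_intercept = NULL,
      egger_intercept_p = NULL, wm = NULL, heterogeneity = NULL, loo = NULL,
      presso = NULL, steiger = NULL, horse = NULL,
      tier = NA_character_, robust = NA,
      instruments = iv
    ),
    class = "test_evaluation"
  )
}

#' @export
print.test_evaluation <- function(x, ...) {
  cat("MR test: ", x$exposure_name, " -> ", x$outcome_name, "\n", sep = "")
  cat("  n_variable = ", x$n_variable,
      "; mean F = ", format(round(x$mean_f, 1)), "\n", sep = "")
  if (!is.null(x$ivw)) {
    cat("  IVW beta = ", format(round(x$ivw$beta, 4)),
        " (p = ", format(x$ivw$pvalue, digits = 3),
        ", q = ", format(x$fdr_q, digits = 3), ")\n", sep = "")
  }
  cat("  tier: ", x$tier,
      if (!is.na(x$robust)) paste0(" (robust: ", x$robust, ")"), "\n",
      sep = "")
  invisible(x)
}

#' Run one direction of tests: a single exposure against many outcomes
#'
#' Builds the harmonized instrument set for every exposure-outcome pair,
#' runs the estimator battery on pairs with at least `min_iv` instruments,
#' applies Benjamini-Hochberg FDR across exactly that family of IVW
#' p-values, classifies every pair into an evidence tier, and runs the
#' step-7 battery (MR-PRESSO, Steiger filtering, correlated-pleiotropy
#' correction) on Association-tier pairs only, setting the `robust` flag
#' when the corrected and filtered estimates stay significant with the IVW
#' sign and the Bayesian posterior interval excludes zero. A failure in one
#' pair is recorded and never aborts the family.
#'
#' @param exposure A `gwas_summary`.
#' @param outcomes List of `gwas_summary` objects (or a single one).
#' @param ld An [ld_provider].
#' @param config An [mr_config()].
#' @return List of class `family_result`: `direction`, `evaluations`,
#'   `proportions` (see [summarize_proportions]).
#' @export
run_direction <- function(exposure, outcomes, ld, config = mr_config()) {
  if (inherits(outcomes, "gwas_summary")) outcomes <- list(outcomes)
  stopifnot(length(outcomes) >= 1)

  evals <- lapply(outcomes, function(outcome) {
    iv <- tryCatch(
      suppressWarnings(build_instrument_set(exposure, outcome, ld, config)),
      error = function(e) NULL
    )
    if (is.null(iv)) {
      iv <- instrument_set(
        data.frame(variant_id = character(0), gamma = numeric(0),
                   sigma_x = numeric(0), Gamma = numeric(0),
                   sigma_y = numeric(0), eaf = numeric(0),
                   f_stat = numeric(0)),
        exposure_name = exposure$trait_name,
        outcome_name = outcome$trait_name
      )
    }
    ev <- .new_evaluation(exposure, outcome, iv)
    ev$passes_sample_size <- .passes_sample_size(exposure, outcome, config)
    ev
  })

  in_family <- vapply(evals, function(ev) ev$n_variable >= config$min_iv,
                      logical(1))

  # Estimator battery for pairs passing the instrument-count restriction.
  for (i in which(in_family)) {
    ests <- tryCatch(
      .evaluate_pair(evals[[i]]$instruments, exposure, outcomes[[i]], config),
      error = function(e) e
    )
    if (inherits(ests, "error")) {
      in_family[i] <- FALSE
      evals[[i]]$error <- conditionMessage(ests)
      next
    }
    evals[[i]][names(ests)] <- ests
    evals[[i]]$egger_intercept_p <- ests$egger_intercept$pvalue
  }

  # BH-FDR across the family of IVW p-values (pairs passing step 1 only).
  fam_idx <- which(in_family)
  if (length(fam_idx) > 0) {
    qs <- bh_fdr(vapply(fam_idx, function(i) evals[[i]]$ivw$pvalue,
                        numeric(1)))
    for (k in seq_along(fam_idx)) evals[[fam_idx[k]]]$fdr_q <- qs[k]
  }

  for (i in seq_along(evals)) {
    ev <- evals[[i]]
    evals[[i]]$tier <- if (!(i %in% fam_idx)) {
      # either too few instruments, or the estimator battery failed
      if (ev$n_variable < config$min_iv) "InsufficientIVs" else NA_character_
    } else {
      classify_tier(
        n_variable = ev$n_variable,
        egger_intercept_p = ev$egger_intercept_p,
        fdr_q = ev$fdr_q,
        het_p = ev$heterogeneity$pvalue,
        ivw_sign = sign(ev$ivw$beta),
        wm_sign = sign(ev$wm$beta),
        egger_sign = sign(ev$egger_slope$beta),
        loo_p_max = ev$loo$p_max,
        passes_sample_size = ev$passes_sample_size,
        config = config
      )
    }
  }

  # Step-7 battery on Association-tier pairs only.
  for (i in seq_along(evals)) {
    if (identical(evals[[i]]$tier, "Association")) {
      s7 <- .step7_battery(evals[[i]]$instruments, exposure, outcomes[[i]],
                           evals[[i]]$ivw, config)
      evals[[i]][c("presso", "steiger", "horse", "robust")] <- s7
    }
  }

  structure(
    list(
      direction = paste0(exposure$trait_name, " -> outcomes"),
      exposure_name = exposure$trait_name,
      evaluations = evals,
      proportions = summarize_proportions(evals)
    ),
    class = "family_result"
  )
}

#' @export
print.family_result <- function(x, ...) {
  cat("MR family: ", x$direction, " (", length(x$evaluations),
      " tests)\n", sep = "")
  tiers <- vapply(x$evaluations, function(e) e$tier, character(1))
  print(table(factor(tiers, levels = mr_tiers())))
  p <- x$proportions
  if (!is.na(p$fraction)) {
    cat(sprintf("  putative: %d/%d (%.1f%%); robust: %d\n",
                p$n_putative, p$n_tested, 100 * p$fraction, p$n_robust))
  } else {
    cat("  no testable pairs\n")
  }
  invisible(x)
}

#' Run a bidirectional pair of tests
#'
#' Runs both directed tests with direction-specific instrument selection
#' (instruments for A -> B are genome-wide-significant variants of A, and
#' vice versa). Results do not depend on call order.
#'
#' @param trait_a,trait_b `gwas_summary` objects.
#' @param ld An [ld_provider].
#' @param config An [mr_config()].
#' @return List with `a_to_b` and `b_to_a` `test_evaluation`s.
#' @export
run_bidirectional <- function(trait_a, trait_b, ld, config = mr_config()) {
  fwd <- run_direction(trait_a, list(trait_b), ld, config)
  rev <- run_direction(trait_b, list(trait_a), ld, config)
  list(a_to_b = fwd$evaluations[[1]], b_to_a = rev$evaluations[[1]])
}

#' Summarize tier proportions over a family of evaluations
#'
#' Denominators exclude the `InsufficientIVs` and
#' `InsufficientSampleSize` tiers. "Putative" counts pairs whose IVW test
#' reached the FDR threshold without directional pleiotropy (tiers
#' `Association` and `Weak`); "robust" counts Association-tier pairs whose
#' step-7 battery confirmed the effect. With zero testable pairs the
#' fraction is `NA` (an explicit undefined marker), never 0/0.
#'
#' @param family A `family_result` or a list of `test_evaluation`s.
#' @return List with `n_total`, `n_tested`, `n_putative`, `n_association`,
#'   `n_robust`, `fraction` (putative / tested).
#' @export
summarize_proportions <- function(family) {
  evals <- if (inherits(family, "family_result")) family$evaluations else family
  tiers <- vapply(evals, function(e) e$tier, character(1))
  robust <- vapply(evals, function(e) isTRUE(e$robust), logical(1))
  tested <- !is.na(tiers) &
    !(tiers %in% c("InsufficientIVs", "InsufficientSampleSize"))
  n_tested <- sum(tested)
  n_putative <- sum(tiers %in% c("Association", "Weak"))
  list(
    n_total = length(evals),
    n_tested = n_tested,
    n_putative = n_putative,
    n_association = sum(tiers == "Association"),
    n_robust = sum(tiers == "Association" & robust),
    fraction = if (n_tested > 0) n_putative / n_tested else NA_real_
  )
}
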