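# Synthetic two-sample GWAS summary statistics with known causal ground
# truth: every pipeline stage is testable without external downloads.
#
# The generator works on a standardized-trait scale: per-allele SEs follow
# the usual 1/sqrt(2 * EAF * (1 - EAF) * n) approximation, so instrument
# strength is controlled directly by the sample sizes and the significant
# fraction. Binary traits reuse the formula with the effective sample size.

.z_gw <- function(p_threshold = 5e-8) stats::qnorm(1 - p_threshold / 2)

#' Generating parameters of a synthetic exposure-outcome pair
#'
#' @param theta True causal effect of the exposure on the outcome.
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`,
#'   `"correlated"`.
#' @param alpha_mean,alpha_sd Mean and SD of the pleiotropic effects on
#'   affected variants (mean is forced to 0 under `"balanced"`).
#' @param prop_invalid Fraction of variants carrying pleiotropy.
#' @param rho_corr Correlation coefficient linking pleiotropy to the true
#'   variant-exposure effect under `"correlated"` (InSIDE violation).
#' @param n_reverse Count of structurally reverse-causal variants (primary
#'   effect on the outcome; the induced exposure effect is `theta_rev`
#'   times it, still genome-wide significant so the variant genuinely
#'   enters the instrument set).
#' @param theta_rev Reverse effect used for those variants.
#' @param n_variants Number of forward variants.
#' @param n_exp,n_out Exposure and outcome GWAS sample sizes.
#' @param frac_sig Target fraction of variants whose expected exposure
#'   z-score reaches genome-wide significance (default 0.9).
#' @param z_max Winsorization cap on expected exposure z-scores (default
#'   40, about the strongest single instruments seen in large GWAS).
#' @param palindromic_rate,strand_flip_rate Rates at which variants get
#'   palindromic allele pairs, and at which outcome records are reported on
#'   the complementary strand.
#' @param ld_block_size Variants per LD block (1 = independent sentinel
#'   variants); `ld_r2` is the fixed within-block r-squared.
#' @param ld_r2 Within-block r-squared (default 0.9).
#' @param seed RNG seed; generation is a pure function of this record.
#' @return List of class `simulation_truth`.
#' @export
simulation_truth <- function(theta = 0, pleiotropy_mode = c("none", "balanced",
                                                            "directional",
                                                            "correlated"),
                             alpha_mean = 0, alpha_sd = 0.05,
                             prop_invalid = 0, rho_corr = 0.7,
                             n_reverse = 0, theta_rev = 0.3,
                             n_variants = 50, n_exp = 500000, n_out = 500000,
                             frac_sig = 0.9, z_max = 40,
                             palindromic_rate = 0.1, strand_flip_rate = 0.1,
                             ld_block_size = 1, ld_r2 = 0.9, seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(prop_invalid >= 0, prop_invalid <= 1,
            n_reverse <= n_variants, n_variants >= 1,
            frac_sig > 0, frac_sig <= 1, theta_rev != 0)
  if (pleiotropy_mode == "balanced") alpha_mean <- 0
  structure(
    list(theta = theta, pleiotropy_mode = pleiotropy_mode,
         alpha_mean = alpha_mean, alpha_sd = alpha_sd,
         prop_invalid = prop_invalid, rho_corr = rho_corr,
         n_reverse = as.integer(n_reverse), theta_rev = theta_rev,
         n_variants = as.integer(n_variants),
         n_exp = n_exp, n_out = n_out, frac_sig = frac_sig, z_max = z_max,
         palindromic_rate = palindromic_rate,
         strand_flip_rate = strand_flip_rate,
         ld_block_size = as.integer(ld_block_size), ld_r2 = ld_r2,
         seed = as.integer(seed)),
    class = "simulation_truth"
  )
}

# Scale raw normal draws so frac_sig of expected z-scores reach the
# genome-wide threshold, then winsorize at z_max.
.scale_effects <- function(g_raw, se, frac_sig, z_max, p_threshold = 5e-8) {
  z_raw <- abs(g_raw) / se
  q <- stats::quantile(z_raw, 1 - frac_sig, names = FALSE)
  if (q <= 0) stop("simulate_pair: cannot reach target significant fraction",
                   call. = FALSE)
  z_exp <- pmin(.z_gw(p_threshold) / q * z_raw, z_max)
  sign(g_raw) * z_exp * se
}

#' Simulate a two-sample exposure-outcome GWAS pair
#'
#' Draws allele frequencies, true variant-exposure effects (scaled so a
#' target fraction is genome-wide significant at the exposure sample
#' size), pleiotropic effects per the configured regime, structural
#' reverse-causal variants, observed effects with per-allele sampling
#' noise, palindromic and strand-flipped allele labels, and a
#' block-diagonal LD structure. Observed p-values are exactly the
#' two-sided normal p of beta/SE.
#'
#' @param truth A [simulation_truth].
#' @return List with `exposure` and `outcome` (`gwas_summary`), `ld`
#'   ([ld_provider]), and `truth` (the input record augmented with
#'   per-variant ground truth: `variant_id`, `g_true`, `alpha`,
#'   `is_invalid`, `is_reverse`, `outlier_ids`).
#' @export
simulate_pair <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  with_seed(truth$seed, .simulate_pair_impl(truth))
}

.simulate_pair_impl <- function(truth, id_prefix = "rs", chrom_offset = 0L) {
  J <- truth$n_variants
  n_rev <- truth$n_reverse
  eaf <- stats::runif(J, 0.05, 0.95)
  se_x <- 1 / sqrt(2 * eaf * (1 - eaf) * truth$n_exp)
  se_y <- 1 / sqrt(2 * eaf * (1 - eaf) * truth$n_out)

  g <- .scale_effects(stats::rnorm(J), se_x, truth$frac_sig, truth$z_max)

  is_invalid <- rep(FALSE, J)
  alpha <- numeric(J)
  n_inv <- round(truth$prop_invalid * J)
  if (truth$pleiotropy_mode != "none" && n_inv > 0) {
    inv <- sample.int(J, n_inv)
    is_invalid[inv] <- TRUE
    # "directional" means directional relative to the exposure-increasing
    # allele (the orientation Egger regression works in), hence the
    # sign(g) coupling.
    alpha[inv] <- switch(
      truth$pleiotropy_mode,
      balanced    = stats::rnorm(n_inv, 0, truth$alpha_sd),
      directional = sign(g[inv]) *
        stats::rnorm(n_inv, truth$alpha_mean, truth$alpha_sd),
      correlated  = truth$rho_corr * g[inv] +
        stats::rnorm(n_inv, 0, truth$alpha_sd)
    )
  }

  # Forward variants: outcome effect theta * g + alpha. Reverse-causal
  # variants: primary effect b on the outcome, induced exposure effect
  # theta_rev * b -- generated structurally, with the induced effect still
  # significant so the variant genuinely enters the instrument set.
  true_x <- g
  true_y <- truth$theta * g + alpha
  is_reverse <- rep(FALSE, J)
  if (n_rev > 0) {
    rev_idx <- seq_len(J) > J - n_rev   # deterministic tail positions
    is_reverse[rev_idx] <- TRUE
    b <- g[rev_idx] / truth$theta_rev
    true_y[rev_idx] <- b
    true_x[rev_idx] <- truth$theta_rev * b  # = g, already significant
    alpha[rev_idx] <- 0
  }

  beta_x <- true_x + stats::rnorm(J, 0, se_x)
  beta_y <- true_y + stats::rnorm(J, 0, se_y)
  # clamp away from exact 0 (underflow for the strongest instruments)
  p_x <- .pclamp(2 * stats::pnorm(-abs(beta_x / se_x)))
  p_y <- .pclamp(2 * stats::pnorm(-abs(beta_y / se_y)))

  # Allele labels: palindromic pairs at the configured rate; outcome rows
  # reported swapped and/or strand-complemented to exercise harmonization.
  pal <- stats::runif(J) < truth$palindromic_rate
  ea <- oa <- character(J)
  pick <- function(n, choices) choices[sample.int(length(choices), n,
                                                  replace = TRUE)]
  npal <- sum(!pal)
  if (npal > 0) {
    base <- pick(npal, c("AG", "AC", "TG", "TC"))
    ea[!pal] <- substr(base, 1, 1)
    oa[!pal] <- substr(base, 2, 2)
  }
  if (any(pal)) {
    base <- pick(sum(pal), c("AT", "CG"))
    ea[pal] <- substr(base, 1, 1)
    oa[pal] <- substr(base, 2, 2)
  }

  # Genomic layout: block-diagonal LD; blocks spaced far beyond the
  # clumping window and wrapped over 22 chromosomes.
  block <- (seq_len(J) - 1) %/% truth$ld_block_size
  chrom <- as.character(((block + chrom_offset) %% 22) + 1)
  pos <- 1e6 + ((block + chrom_offset) %/% 22) * 2e7 +
    ((seq_len(J) - 1) %% truth$ld_block_size) * 1000

  ids <- paste0(id_prefix, seq_len(J))
  ld <- ld_provider(blocks = stats::setNames(paste(chrom, block), ids),
                    within_r2 = truth$ld_r2,
                    chrom = stats::setNames(chrom, ids))

  exp_variants <- data.frame(
    variant_id = ids, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta_x, se = se_x, pvalue = p_x, n = truth$n_exp,
    stringsAsFactors = FALSE
  )

  swap <- stats::runif(J) < 0.5
  flip <- stats::runif(J) < truth$strand_flip_rate
  ea_y <- ifelse(swap, oa, ea)
  oa_y <- ifelse(swap, ea, oa)
  ea_y <- ifelse(flip, .complement_allele(ea_y), ea_y)
  oa_y <- ifelse(flip, .complement_allele(oa_y), oa_y)
  out_variants <- data.frame(
    variant_id = ids, chrom = chrom, pos = pos,
    effect_allele = ea_y, other_allele = oa_y,
    eaf = ifelse(swap, 1 - eaf, eaf),
    beta = ifelse(swap, -beta_y, beta_y), se = se_y, pvalue = p_y,
    n = truth$n_out,
    stringsAsFactors = FALSE
  )

  half <- function(n) c(ceiling(n / 2), floor(n / 2))
  exposure <- suppressWarnings(gwas_summary(
    exp_variants, trait_name = "synthetic_exposure", is_binary = TRUE,
    n_cases = half(truth$n_exp)[1], n_controls = half(truth$n_exp)[2]
  ))
  outcome <- suppressWarnings(gwas_summary(
    out_variants, trait_name = "synthetic_outcome", is_binary = TRUE,
    n_cases = half(truth$n_out)[1], n_controls = half(truth$n_out)[2]
  ))

  truth$variant_id <- ids
  truth$g_true <- g
  truth$alpha <- alpha
  truth$is_invalid <- is_invalid
  truth$is_reverse <- is_reverse
  truth$outlier_ids <- character(0)
  list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
}

#' Plant a pleiotropic outlier in a simulated pair
#'
#' Adds `displacement` to one variant's observed outcome effect (and
#' recomputes its p-value); the truth record gains the variant id in
#' `outlier_ids`. A displacement of 0 leaves the pair unchanged.
#'
#' @param pair Output of [simulate_pair].
#' @param variant_index Index of the variant to displace.
#' @param displacement Additive shift on the outcome beta, in trait units
#'   (typically quoted as a multiple of that variant's outcome SE).
#' @return The modified pair.
#' @export
plant_outlier <- function(pair, variant_index, displacement) {
  v <- pair$outcome$variants
  if (variant_index < 1 || variant_index > nrow(v)) {
    stop("plant_outlier: variant_index out of range", call. = FALSE)
  }
  if (displacement == 0) return(pair)
  # The outcome row may be stored swapped relative to the exposure allele;
  # displace on the stored orientation consistently with its sign.
  id <- pair$truth$variant_id[variant_index]
  row <- match(id, v$variant_id)
  same_orientation <- v$effect_allele[row] %in%
    c(pair$exposure$variants$effect_allele[variant_index],
      .complement_allele(pair$exposure$variants$effect_allele[variant_index]))
  shift <- if (same_orientation) displacement else -displacement
  v$beta[row] <- v$beta[row] + shift
  v$pvalue[row] <- 2 * stats::pnorm(-abs(v$beta[row] / v$se[row]))
  pair$outcome$variants <- v
  pair$truth$outlier_ids <- union(pair$truth$outlier_ids, id)
  pair
}

#' Simulate a bidirectional trait pair
#'
#' Builds two traits A and B where a set of A-primary variants carries a
#' causal effect `theta_ab` onto B and a disjoint set of B-primary
#' variants carries `theta_ba` onto A, merged into two complete GWAS
#' summaries sharing one LD provider. Setting either theta to 0 gives a
#' one-directional (or null) pair.
#'
#' @param truth_ab [simulation_truth] for the A -> B component (its
#'   variants are A's instruments).
#' @param truth_ba [simulation_truth] for the B -> A component.
#' @return List with `trait_a`, `trait_b` (`gwas_summary`), `ld`, and both
#'   truth records.
#' @export
simulate_bidirectional_pair <- function(truth_ab, truth_ba) {
  pa <- with_seed(truth_ab$seed,
                  .simulate_pair_impl(truth_ab, id_prefix = "rsA"))
  n_blocks_a <- ceiling(truth_ab$n_variants / truth_ab$ld_block_size)
  pb <- with_seed(truth_ba$seed,
                  .simulate_pair_impl(truth_ba, id_prefix = "rsB",
                                      chrom_offset = n_blocks_a))
  merge_gwas <- function(primary, secondary, name) {
    gw <- primary
    gw$trait_name <- name
    gw$variants <- rbind(primary$variants, secondary$variants)
    rownames(gw$variants) <- NULL
    gw
  }
  trait_a <- merge_gwas(pa$exposure, pb$outcome, "trait_a")
  trait_b <- merge_gwas(pb$exposure, pa$outcome, "trait_b")

  ids <- c(pa$truth$variant_id, pb$truth$variant_id)
  chrom <- stats::setNames(c(pa$exposure$variants$chrom,
                             pb$exposure$variants$chrom), ids)
  blk_a <- (seq_len(truth_ab$n_variants) - 1) %/% truth_ab$ld_block_size
  blk_b <- (seq_len(truth_ba$n_variants) - 1) %/% truth_ba$ld_block_size +
    n_blocks_a
  blocks <- stats::setNames(c(blk_a, blk_b), ids)
  ld <- ld_provider(blocks = blocks,
                    within_r2 = max(truth_ab$ld_r2, truth_ba$ld_r2),
                    chrom = chrom)
  list(trait_a = trait_a, trait_b = trait_b, ld = ld,
       truth_ab = pa$truth, truth_ba = pb$truth)
}

#' Simulate a harmonized instrument set directly
#'
#' Fast ratio-level generator for estimator studies: skips alleles, LD and
#' selection and returns an [instrument_set] whose observed effects follow
#' the same model as [simulate_pair]. All variants are genome-wide
#' significant by construction.
#'
#' @param J Number of instruments.
#' @inheritParams simulation_truth
#' @param seed RNG seed (isolated per call).
#' @return An [instrument_set] with a `truth` attribute carrying `g_true`,
#'   `alpha`, `is_invalid`.
#' @export
simulate_instruments <- function(J = 50, theta = 0,
                                 pleiotropy_mode = c("none", "balanced",
                                                     "directional",
                                                     "correlated"),
                                 alpha_mean = 0, alpha_sd = 0.05,
                                 prop_invalid = 0, rho_corr = 0.7,
                                 n_exp = 500000, n_out = 500000,
                                 frac_sig = 1, z_max = 40, seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  with_seed(seed, {
    eaf <- stats::runif(J, 0.05, 0.95)
    se_x <- 1 / sqrt(2 * eaf * (1 - eaf) * n_exp)
    se_y <- 1 / sqrt(2 * eaf * (1 - eaf) * n_out)
    g <- .scale_effects(stats::rnorm(J), se_x, frac_sig, z_max)
    alpha <- numeric(J)
    is_invalid <- rep(FALSE, J)
    n_inv <- round(prop_invalid * J)
    if (pleiotropy_mode != "none" && n_inv > 0) {
      inv <- sample.int(J, n_inv)
      is_invalid[inv] <- TRUE
      alpha[inv] <- switch(
        pleiotropy_mode,
        balanced    = stats::rnorm(n_inv, 0, alpha_sd),
        directional = sign(g[inv]) *
          stats::rnorm(n_inv, alpha_mean, alpha_sd),
        correlated  = rho_corr * g[inv] + stats::rnorm(n_inv, 0, alpha_sd)
      )
    }
    gamma <- g + stats::rnorm(J, 0, se_x)
    Gamma <- theta * g + alpha + stats::rnorm(J, 0, se_y)
    iv <- instrument_set(data.frame(
      variant_id = paste0("rs", seq_len(J)),
      chrom = "1", pos = seq_len(J) * 1e6,
      effect_allele = "A", other_allele = "G",
      gamma = gamma, sigma_x = se_x, Gamma = Gamma, sigma_y = se_y,
      eaf = eaf, f_stat = f_statistic(gamma, se_x),
      stringsAsFactors = FALSE
    ))
    attr(iv, "truth") <- list(theta = theta, g_true = g, alpha = alpha,
                              is_invalid = is_invalid)
    iv
  })
}

#' Canonical fixture scenarios
#'
#' Deterministic generation (pure function of `seed`) of the scenarios the
#' pipeline must discriminate: `null`, `causal`, `bidirectional` (causal
#' in both directions), `directional_pleiotropy`, `correlated_pleiotropy`,
#' `reverse_causal`, `insufficient_iv` (29 instruments, one below the
#' default minimum) and `weak_instrument` (mean F below 10).
#'
#' @param seed Base RNG seed.
#' @param n_variants Forward variant count for the standard scenarios
#'   (default 50).
#' @param n_exp,n_out GWAS sample sizes (default 500,000 each).
#' @return Named list; each element is a [simulate_pair] result except
#'   `bidirectional`, a [simulate_bidirectional_pair] result.
#' @export
fixture_suite <- function(seed = 1, n_variants = 50, n_exp = 500000,
                          n_out = 500000) {
  base <- function(i, ...) {
    args <- utils::modifyList(
      list(n_variants = n_variants, n_exp = n_exp, n_out = n_out,
           seed = seed + i),
      list(...)
    )
    do.call(simulation_truth, args)
  }
  list(
    null = simulate_pair(base(1, theta = 0)),
    causal = simulate_pair(base(2, theta = 0.5)),
    # Moderate effects with z capped at 7 keep each trait's instruments out
    # of the other's selection (cross-induced z stays > 3.5 SD below the
    # genome-wide threshold), which is what "disjoint instrument sets,
    # causal both ways" means as a scenario.
    bidirectional = simulate_bidirectional_pair(
      base(3, theta = 0.3, z_max = 7),
      base(4, theta = 0.2, z_max = 7)
    ),
    directional_pleiotropy = simulate_pair(
      base(5, theta = 0, pleiotropy_mode = "directional", alpha_mean = 0.1,
           alpha_sd = 0.02, prop_invalid = 1)
    ),
    correlated_pleiotropy = simulate_pair(
      base(6, theta = 0.3, pleiotropy_mode = "correlated", rho_corr = 0.7,
           alpha_sd = 0.02, prop_invalid = 0.4)
    ),
    reverse_causal = simulate_pair(base(7, theta = 0.5, n_reverse = 10)),
    insufficient_iv = simulate_pair(base(8, theta = 0.5, n_variants = 29)),
    # Instruments selected at p < 5e-8 necessarily carry F > 29, so a
    # weak-instrument set can only arise under a relaxed selection
    # threshold (instruments taken from prior literature, say). Analyze
    # this scenario with p_gw = 0.05.
    weak_instrument = simulate_pair(
      base(9, theta = 0.5, frac_sig = 1, z_max = 2.5)
    )
  )
}

#' Write a simulated pair to disk in the standard table dialect
#'
#' Emits exposure and outcome tables readable by [read_gwas_table], the LD
#' matrix, and a JSON truth record.
#'
#' @param pair Output of [simulate_pair].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulated_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  exp_path <- file.path(dir, "exposure.tsv")
  out_path <- file.path(dir, "outcome.tsv")
  ld_path <- file.path(dir, "ld.tsv")
  truth_path <- file.path(dir, "truth.json")
  write_gwas_table(pair$exposure, exp_path)
  write_gwas_table(pair$outcome, out_path)
  write_ld_matrix(pair$ld, pair$truth$variant_id, ld_path)
  jsonlite::write_json(unclass(pair$truth), truth_path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(list(exposure = exp_path, outcome = out_path, ld = ld_path,
                 truth = truth_path))
}
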