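# The synthetic-data generator: determinism, internal consistency, and the
# structural features each pipeline stage relies on.

test_that("generation is a pure function of the truth record", {
  tr <- simulation_truth(theta = 0.4, n_variants = 30, seed = 7,
                         pleiotropy_mode = "directional", alpha_mean = 0.05,
                         prop_invalid = 0.3, n_reverse = 3)
  a <- suppressMessages(simulate_pair(tr))
  b <- suppressMessages(simulate_pair(tr))
  expect_identical(a$exposure$variants, b$exposure$variants)
  expect_identical(a$outcome$variants, b$outcome$variants)
  expect_identical(a$truth$g_true, b$truth$g_true)

  # and the global RNG stream is untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(suppressMessages(simulate_pair(tr)))
  expect_identical(rnorm(1), before)
})

test_that("generated p-values match the two-sided normal formula", {
  pair <- suppressMessages(simulate_pair(simulation_truth(
    theta = 0.2, n_variants = 60, seed = 13, z_max = 20
  )))
  for (gw in list(pair$exposure, pair$outcome)) {
    v <- gw$variants
    expect_equal(v$pvalue, 2 * pnorm(-abs(v$beta / v$se)), tolerance = 1e-12)
  }
})

test_that("the significant fraction hits its target within tolerance", {
  J <- 400
  pair <- suppressMessages(simulate_pair(simulation_truth(
    n_variants = J, frac_sig = 0.7, seed = 17,
    palindromic_rate = 0, z_max = 40
  )))
  frac <- mean(pair$exposure$variants$pvalue < 5e-8)
  # binomial-ish tolerance around the target (expected z exactly at the
  # threshold for the marginal variant adds noise beyond binomial)
  expect_lt(abs(frac - 0.7), 4 * sqrt(0.7 * 0.3 / J) + 0.02)
})

test_that("SEs follow the per-allele approximation", {
  pair <- suppressMessages(simulate_pair(simulation_truth(
    n_variants = 20, n_exp = 250000, n_out = 80000, seed = 19
  )))
  ve <- pair$exposure$variants
  expect_equal(ve$se, 1 / sqrt(2 * ve$eaf * (1 - ve$eaf) * 250000))
  vo <- pair$outcome$variants
  # 2 * eaf * (1 - eaf) is invariant to allele swaps
  expect_equal(vo$se, 1 / sqrt(2 * vo$eaf * (1 - vo$eaf) * 80000))
})

test_that("reverse-causal variants are structural, not labels", {
  pair <- suppressMessages(simulate_pair(simulation_truth(
    theta = 0.5, n_variants = 30, n_reverse = 6, theta_rev = 0.3, seed = 23,
    frac_sig = 1, palindromic_rate = 0, strand_flip_rate = 0
  )))
  tr <- pair$truth
  rev <- tr$is_reverse
  ve <- pair$exposure$variants
  # reverse variants carry a genuinely significant expected exposure signal
  expect_true(all(abs(tr$g_true[rev]) / ve$se[rev] >= qnorm(1 - 2.5e-8) - 1e-6))
  # and their outcome/exposure z ratio (1/theta_rev) exceeds every forward
  # variant's (theta)
  iv <- suppressWarnings(build_instrument_set(pair$exposure, pair$outcome,
                                              pair$ld, mr_config()))
  vv <- iv$variants
  ratio <- abs(vv$Gamma / vv$sigma_y) / abs(vv$gamma / vv$sigma_x)
  is_rev <- vv$variant_id %in% tr$variant_id[rev]
  expect_gt(min(ratio[is_rev]), max(ratio[!is_rev]))
})

test_that("block LD structure feeds the provider and clumping", {
  pair <- suppressMessages(simulate_pair(simulation_truth(
    n_variants = 12, ld_block_size = 3, ld_r2 = 0.9, seed = 29,
    frac_sig = 1, palindromic_rate = 0
  )))
  ids <- pair$truth$variant_id
  expect_equal(pair$ld$r2(ids[1], ids[2]), 0.9)   # same block
  expect_equal(pair$ld$r2(ids[1], ids[4]), 0)     # different block
  expect_equal(pair$ld$r2(ids[5], ids[5]), 1)
  sig <- select_significant(pair$exposure)
  clumped <- clump(sig, pair$ld)
  # at most one variant survives per block
  blocks <- (match(clumped$variant_id, ids) - 1) %/% 3
  expect_equal(anyDuplicated(blocks), 0)
})

test_that("plant_outlier displaces exactly one variant and is invertible", {
  base <- suppressMessages(simulate_pair(simulation_truth(
    theta = 0.3, n_variants = 20, seed = 37
  )))
  same <- plant_outlier(base, 4, 0)
  expect_identical(same$outcome$variants, base$outcome$variants)

  shifted <- plant_outlier(base, 4, 0.05)
  d <- abs(shifted$outcome$variants$beta - base$outcome$variants$beta)
  expect_equal(sum(d > 0), 1)
  expect_equal(shifted$truth$outlier_ids, base$truth$variant_id[4])
  expect_error(plant_outlier(base, 99, 1), "out of range")

  # the displacement lands on the harmonized scale with its stated sign
  cfg <- mr_config()
  iv0 <- suppressWarnings(build_instrument_set(base$exposure, base$outcome,
                                               base$ld, cfg))
  iv1 <- suppressWarnings(build_instrument_set(shifted$exposure,
                                               shifted$outcome,
                                               shifted$ld, cfg))
  id <- base$truth$variant_id[4]
  if (id %in% iv0$variants$variant_id) {
    g0 <- iv0$variants$Gamma[iv0$variants$variant_id == id]
    g1 <- iv1$variants$Gamma[iv1$variants$variant_id == id]
    expect_equal(g1 - g0, 0.05, tolerance = 1e-12)
  }
})

test_that("the fixture suite is deterministic and spans its scenarios", {
  fx1 <- suppressMessages(fixture_suite(seed = 5, n_variants = 20))
  fx2 <- suppressMessages(fixture_suite(seed = 5, n_variants = 20))
  expect_identical(fx1$causal$exposure$variants,
                   fx2$causal$exposure$variants)
  expect_identical(fx1$bidirectional$trait_a$variants,
                   fx2$bidirectional$trait_a$variants)
  expect_named(fx1, c("null", "causal", "bidirectional",
                      "directional_pleiotropy", "correlated_pleiotropy",
                      "reverse_causal", "insufficient_iv",
                      "weak_instrument"))
  expect_lt(fx1$insufficient_iv$truth$n_variants, 30)
})

test_that("simulated pairs round-trip through the I/O layer", {
  pair <- suppressMessages(simulate_pair(simulation_truth(
    theta = 0.2, n_variants = 15, seed = 43
  )))
  dir <- withr::local_tempdir()
  paths <- write_simulated_pair(pair, dir)
  exp_back <- read_gwas_table(paths$exposure,
                              trait_meta = list(trait_name = "e",
                                                n_cases = 250000,
                                                n_controls = 250000))
  expect_equal(exp_back$variants$beta, pair$exposure$variants$beta,
               tolerance = 1e-12)
  ld_back <- read_ld_matrix(paths$ld)
  ids <- pair$truth$variant_id
  expect_equal(ld_back$r2(ids[1], ids[2]), pair$ld$r2(ids[1], ids[2]))
  truth_back <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth_back$theta, 0.2)
})
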