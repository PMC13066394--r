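# Estimator battery: oracles, invariances and hand-computable cases.

test_that("ratio estimates match element-wise recomputation", {
  iv <- make_iv(gamma = c(0.2, -0.2), Gamma = c(0.1, -0.1),
                sigma_x = 0.01, sigma_y = c(0.02, 0.02))
  r <- ratio_estimates(iv)
  expect_equal(r$theta, c(0.5, 0.5))
  expect_equal(r$se, c(0.1, 0.1))

  iv2 <- simulate_instruments(J = 30, theta = 0.4, seed = 7)
  r2 <- ratio_estimates(iv2)
  v <- iv2$variants
  expect_equal(r2$theta, v$Gamma / v$gamma)
  expect_equal(r2$se, v$sigma_y / abs(v$gamma))

  # gamma = 0 variants are excluded with a message
  iv3 <- make_iv(gamma = c(0.2, 0, 0.3), Gamma = c(0.1, 0.5, 0.15),
                 sigma_x = 0.01, sigma_y = 0.02)
  expect_message(r3 <- ratio_estimates(iv3), "gamma = 0")
  expect_equal(nrow(r3), 2)
})

test_that("IVW reproduces perfect-slope and replication cases", {
  g <- c(0.1, 0.2, 0.3)
  iv <- make_iv(g, 0.5 * g, sigma_x = 0.01, sigma_y = c(0.02, 0.05, 0.01))
  est <- mr_ivw(iv)
  expect_equal(est$beta, 0.5)
  expect_equal(cochran_q(iv, est$beta)$q_stat, 0)
  expect_equal(cochran_q(iv, est$beta)$pvalue, 1)

  # duplicating a variant halves the fixed-model variance
  one <- make_iv(c(0.2, 0.21), c(0.1, 0.105), 0.01, 0.02)
  two <- make_iv(rep(c(0.2, 0.21), 2), rep(c(0.1, 0.105), 2), 0.01, 0.02)
  e1 <- mr_ivw(one, model = "fixed")
  e2 <- mr_ivw(two, model = "fixed")
  expect_equal(e2$beta, e1$beta)
  expect_equal(e2$se, e1$se / sqrt(2), tolerance = 1e-12)

  expect_error(mr_ivw(make_iv(0.1, 0.05, 0.01, 0.02)), "at least 2")
})

test_that("IVW and Egger match weighted-regression oracles", {
  for (seed in 1:10) {
    iv <- simulate_instruments(J = sample(3:60, 1), theta = 0.3,
                               pleiotropy_mode = "balanced",
                               prop_invalid = 0.3, alpha_sd = 0.03,
                               seed = seed)
    for (model in c("fixed", "multiplicative_random")) {
      est <- mr_ivw(iv, model = model)
      ora <- oracle_ivw(iv, model)
      expect_equal(est$beta, ora$beta, tolerance = 1e-10)
      expect_equal(est$se, ora$se, tolerance = 1e-10)
    }
    eg <- mr_egger(iv)
    oe <- oracle_egger(iv)
    expect_equal(eg$slope$beta, oe$slope, tolerance = 1e-10)
    expect_equal(eg$slope$se, oe$slope_se, tolerance = 1e-10)
    expect_equal(eg$intercept$beta, oe$intercept, tolerance = 1e-10)
    expect_equal(eg$intercept$se, oe$intercept_se, tolerance = 1e-10)
    expect_equal(eg$intercept$pvalue, oe$intercept_p, tolerance = 1e-10)
  }
})

test_that("Egger recovers exact fits and planted intercepts", {
  g <- seq(0.05, 0.3, length.out = 6)
  iv <- make_iv(g, 0.5 * g, 0.01, 0.02)
  eg <- mr_egger(iv)
  expect_equal(eg$intercept$beta, 0, tolerance = 1e-12)
  expect_equal(eg$slope$beta, 0.5, tolerance = 1e-12)

  iv_shift <- make_iv(g, 0.2 + 0.5 * g, 0.01, 0.02)
  eg2 <- mr_egger(iv_shift)
  expect_equal(eg2$intercept$beta, 0.2, tolerance = 1e-12)
  expect_equal(eg2$slope$beta, 0.5, tolerance = 1e-12)

  expect_error(mr_egger(make_iv(c(0.1, 0.2), c(0.05, 0.1), 0.01, 0.02)),
               "at least 3")
})

test_that("estimators are invariant to order and joint sign flips", {
  iv <- simulate_instruments(J = 25, theta = -0.2, seed = 11)
  v <- iv$variants
  flip <- rep(c(1, -1), length.out = 25)
  v2 <- v
  v2$gamma <- v$gamma * flip
  v2$Gamma <- v$Gamma * flip
  v2 <- v2[sample.int(25), ]
  iv2 <- instrument_set(v2)
  expect_equal(mr_ivw(iv2)$beta, mr_ivw(iv)$beta, tolerance = 1e-12)
  expect_equal(mr_ivw(iv2)$se, mr_ivw(iv)$se, tolerance = 1e-12)
  expect_equal(mr_egger(iv2)$slope$beta, mr_egger(iv)$slope$beta,
               tolerance = 1e-12)
  expect_equal(mr_egger(iv2)$intercept$beta, mr_egger(iv)$intercept$beta,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(iv2, n_boot = 10, seed = 1)$beta,
               mr_weighted_median(iv, n_boot = 10, seed = 1)$beta,
               tolerance = 1e-12)
  expect_equal(cochran_q(iv2)$q_stat, cochran_q(iv)$q_stat,
               tolerance = 1e-12)
})

test_that("weighted median handles plain-median and dominant-weight cases", {
  # three equal-weight variants: plain median
  iv <- make_iv(gamma = c(1, 1, 1), Gamma = c(0.4, 0.5, 0.9),
                sigma_x = 0.01, sigma_y = 1)
  expect_equal(mr_weighted_median(iv, n_boot = 10, seed = 1)$beta, 0.5)

  # a variant holding well over half the weight dominates the estimate
  iv2 <- make_iv(gamma = c(1, 1, 1), Gamma = c(0.1, 0.7, 1.5),
                 sigma_x = 0.01, sigma_y = c(1, 0.05, 1))
  wm <- mr_weighted_median(iv2, n_boot = 10, seed = 1)$beta
  expect_equal(wm, 0.7, tolerance = 0.02)
  expect_error(mr_weighted_median(make_iv(c(1, 1), c(1, 1), 0.1, 0.1)),
               "at least 3")
})

test_that("weighted median resists 40% grossly invalid instruments", {
  iv <- simulate_instruments(J = 50, theta = 0.3, n_exp = 1e6, n_out = 1e6,
                             seed = 21)
  v <- iv$variants
  bad <- seq_len(50) %% 5 < 2                    # 40%, spread over strengths
  v$Gamma[bad] <- v$Gamma[bad] + 2 * v$gamma[bad]  # ratios shifted by +2
  ivb <- instrument_set(v)
  wm <- mr_weighted_median(ivb, n_boot = 50, seed = 22)
  naive_mean <- mean(v$Gamma / v$gamma)
  expect_lt(abs(wm$beta - 0.3), 0.05)
  expect_gt(abs(naive_mean - 0.3), 0.5)
})

test_that("Cochran's Q matches hand arithmetic", {
  # theta = {0, 1}, se = {1, 1}, ivw at 0.5 -> Q = 0.5
  iv <- make_iv(gamma = c(1, 1), Gamma = c(0, 1), sigma_x = 0.01,
                sigma_y = 1)
  q <- cochran_q(iv, ivw_beta = 0.5)
  expect_equal(q$q_stat, 0.5)
  expect_equal(q$df, 1)
  expect_equal(q$pvalue, pchisq(0.5, 1, lower.tail = FALSE))
})

test_that("leave-one-out spans all variants and finds single drivers", {
  iv <- simulate_instruments(J = 20, theta = 0.5, seed = 31)
  loo <- leave_one_out(iv)
  expect_equal(nrow(loo$per_variant), 20)
  expect_equal(loo$p_max, max(loo$per_variant$pvalue))
  expect_lt(loo$p_max, 0.05)
  expect_equal(sort(loo$per_variant$left_out_id),
               sort(iv$variants$variant_id))

  # signal carried by a single variant: dropping it loses significance
  g <- rep(0.1, 10)
  G <- c(rep(0, 9), 0.5)
  iv1 <- make_iv(g, G, sigma_x = 0.001, sigma_y = 0.05)
  loo1 <- leave_one_out(iv1)
  expect_gt(loo1$p_max, 0.05)
})

test_that("odds-ratio transform uses the configured normal quantile", {
  expect_equal(to_or(0, 0.1)$or_, 1)
  degenerate <- to_or(log(2), 0)
  expect_equal(degenerate$or_, 2)
  expect_equal(degenerate$or_low, 2)
  z <- qnorm(0.995)
  expect_equal(round(z, 4), 2.5758)
  got <- to_or(0.5, 0.1, ci_level = 0.99)
  expect_equal(got$or_low, exp(0.5 - z * 0.1))
  expect_equal(got$or_high, exp(0.5 + z * 0.1))
})
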