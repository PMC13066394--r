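# Bayesian MR with horseshoe-shrinkage pleiotropy allowing correlated
# pleiotropy (the MR-Horse family of models), sampled by a custom
# Metropolis-within-Gibbs MCMC.
#
# Model, for each instrument j:
#   Gamma_hat_j ~ N(theta * g_j + alpha_j, sigma_Yj^2)
#   gamma_hat_j ~ N(g_j, sigma_Xj^2)
#   alpha_j ~ N(0, (tau * lambda_j)^2)            horseshoe pleiotropy
#   g_j | alpha_j ~ N(m + rho_j * sigma_g * alpha_j / (tau * lambda_j),
#                     sigma_g^2 * (1 - rho_j^2))  correlated pleiotropy
#   lambda_j, tau, sigma_g ~ half-Cauchy(0, 1); rho_j ~ U(-1, 1)
#   m ~ N(0, 1); theta ~ N(0, 10^2)
#
# The per-variant correlation rho_j between the pleiotropic effect and the
# true variant-exposure effect relaxes the InSIDE assumption, which is what
# distinguishes this correction from Egger regression.

.half_cauchy_lp <- function(x) -log1p(x^2)

# log joint density of (alpha_j, g_j) given scales; vectorized over j.
.alpha_g_lp <- function(alpha, g, s, rho, m, sigma_g) {
  mu_g <- m + rho * sigma_g * alpha / s
  v_g <- sigma_g^2 * (1 - rho^2)
  -log(s) - alpha^2 / (2 * s^2) -
    0.5 * log(v_g) - (g - mu_g)^2 / (2 * v_g)
}

.run_horse_chain <- function(gh, Gh, sX, sY, n_iter, theta_init, seed) {
  J <- length(gh)
  wY <- 1 / sY^2
  theta_prior_var <- 100

  set.seed(seed)
  theta <- theta_init + stats::rnorm(1, 0, 0.1)
  g <- gh
  alpha <- (Gh - theta * g) * 0.5
  lambda <- rep(1, J)
  tau <- 0.1
  rho <- rep(0, J)
  m <- mean(g)
  sigma_g <- max(stats::sd(g), 1e-3)

  keep <- n_iter - floor(n_iter / 2)
  theta_draws <- numeric(keep)
  k <- 0L

  for (it in seq_len(n_iter)) {
    # --- theta | rest (Gibbs, conjugate normal)
    prec <- 1 / theta_prior_var + sum(g^2 * wY)
    mu <- sum(g * (Gh - alpha) * wY) / prec
    theta <- stats::rnorm(1, mu, sqrt(1 / prec))

    s <- tau * lambda
    v_g <- sigma_g^2 * (1 - rho^2)

    # --- g_j | rest (Gibbs)
    mu_g0 <- m + rho * sigma_g * alpha / s
    prec_g <- theta^2 * wY + 1 / sX^2 + 1 / v_g
    part_g <- theta * (Gh - alpha) * wY + gh / sX^2 + mu_g0 / v_g
    g <- stats::rnorm(J, part_g / prec_g, sqrt(1 / prec_g))

    # --- alpha_j | rest (Gibbs; conditional prior alpha | g)
    v_a <- s^2 * (1 - rho^2)
    mu_a0 <- rho * (s / sigma_g) * (g - m)
    prec_a <- wY + 1 / v_a
    part_a <- (Gh - theta * g) * wY + mu_a0 / v_a
    alpha <- stats::rnorm(J, part_a / prec_a, sqrt(1 / prec_a))

    # --- lambda_j (Metropolis on log scale, vectorized)
    lam_prop <- lambda * exp(stats::rnorm(J, 0, 0.8))
    lp_cur <- .alpha_g_lp(alpha, g, tau * lambda, rho, m, sigma_g) +
      .half_cauchy_lp(lambda) + log(lambda)
    lp_prop <- .alpha_g_lp(alpha, g, tau * lam_prop, rho, m, sigma_g) +
      .half_cauchy_lp(lam_prop) + log(lam_prop)
    acc <- log(stats::runif(J)) < lp_prop - lp_cur
    lambda[acc] <- lam_prop[acc]

    # --- tau (Metropolis on log scale)
    tau_prop <- tau * exp(stats::rnorm(1, 0, 0.4))
    lp_cur <- sum(.alpha_g_lp(alpha, g, tau * lambda, rho, m, sigma_g)) +
      .half_cauchy_lp(tau) + log(tau)
    lp_prop <- sum(.alpha_g_lp(alpha, g, tau_prop * lambda, rho, m, sigma_g)) +
      .half_cauchy_lp(tau_prop) + log(tau_prop)
    if (log(stats::runif(1)) < lp_prop - lp_cur) tau <- tau_prop

    # --- rho_j (Metropolis random walk in (-1, 1), vectorized)
    rho_prop <- rho + stats::rnorm(J, 0, 0.3)
    ok <- abs(rho_prop) < 0.995
    s <- tau * lambda
    lp_cur <- .alpha_g_lp(alpha, g, s, rho, m, sigma_g)
    lp_prop <- .alpha_g_lp(alpha, g, s, pmin(pmax(rho_prop, -0.995), 0.995),
                           m, sigma_g)
    acc <- ok & (log(stats::runif(J)) < lp_prop - lp_cur)
    rho[acc] <- rho_prop[acc]

    # --- m | rest (Gibbs; prior N(0, 1))
    v_g <- sigma_g^2 * (1 - rho^2)
    c_j <- rho * sigma_g * alpha / s
    prec_m <- 1 + sum(1 / v_g)
    part_m <- sum((g - c_j) / v_g)
    m <- stats::rnorm(1, part_m / prec_m, sqrt(1 / prec_m))

    # --- sigma_g (Metropolis on log scale)
    sg_prop <- sigma_g * exp(stats::rnorm(1, 0, 0.3))
    lp_cur <- sum(.alpha_g_lp(alpha, g, s, rho, m, sigma_g)) +
      .half_cauchy_lp(sigma_g) + log(sigma_g)
    lp_prop <- sum(.alpha_g_lp(alpha, g, s, rho, m, sg_prop)) +
      .half_cauchy_lp(sg_prop) + log(sg_prop)
    if (log(stats::runif(1)) < lp_prop - lp_cur) sigma_g <- sg_prop

    if (it > n_iter - keep) {
      k <- k + 1L
      theta_draws[k] <- theta
    }
  }
  theta_draws
}

# Split R-hat (Gelman-Rubin) over a list of equally long chains.
.split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(ch) {
    n <- length(ch) %/% 2
    list(ch[seq_len(n)], ch[(n + 1):(2 * n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  B <- n * stats::var(means)
  W <- mean(vars)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bayesian MR with correlated horseshoe pleiotropy
#'
#' Fits the hierarchical model described in the package vignette: each
#' instrument's pleiotropic effect receives horseshoe shrinkage (local
#' half-Cauchy scales under a global half-Cauchy scale) and is allowed a
#' per-variant correlation with the true variant-exposure effect, so the
#' causal effect `theta` remains identifiable when pleiotropy is correlated
#' with instrument strength (an InSIDE violation that biases IVW and
#' Egger). Sampling is Metropolis-within-Gibbs over multiple seeded chains;
#' the second half of each chain is retained.
#'
#' @param iv An [instrument_set] with at least 10 variants.
#' @param n_chains Number of MCMC chains, default 4.
#' @param n_iter Iterations per chain (half discarded as burn-in), default
#'   10000.
#' @param ci_level Central posterior interval level, default 0.99.
#' @param seed Base RNG seed; chain c uses `seed + c` (isolated per call).
#' @return List of class `horse_result`: `theta_posterior_mean`,
#'   `theta_posterior_sd`, `theta_ci_low`, `theta_ci_high`, `rhat`,
#'   `ess`, `unconverged` flag (rhat > 1.1, also warned), `n_chains`,
#'   `n_iter`, `seed`.
#' @export
mr_horse <- function(iv, n_chains = 4, n_iter = 10000, ci_level = 0.99,
                     seed = 1) {
  v <- iv$variants[iv$variants$gamma != 0, , drop = FALSE]
  J <- nrow(v)
  if (J < 10) {
    stop("mr_horse: at least 10 instruments required", call. = FALSE)
  }
  theta_init <- .ivw_fit(v$gamma, v$Gamma, v$sigma_y)$beta
  chains <- with_seed(seed, {
    lapply(seq_len(n_chains), function(ch) {
      .run_horse_chain(v$gamma, v$Gamma, v$sigma_x, v$sigma_y,
                       n_iter, theta_init, seed + ch)
    })
  })
  draws <- unlist(chains)
  rhat <- if (n_chains > 1 || length(chains[[1]]) >= 4) {
    .split_rhat(chains)
  } else {
    NA_real_
  }
  # Crude effective sample size from lag-1 autocorrelation of pooled chains.
  ac1 <- mean(vapply(chains, function(ch) {
    stats::cor(ch[-length(ch)], ch[-1])
  }, numeric(1)))
  ess <- length(draws) * max(1e-3, (1 - ac1) / (1 + ac1))

  a <- (1 - ci_level) / 2
  qs <- stats::quantile(draws, c(a, 1 - a), names = FALSE)
  unconverged <- is.finite(rhat) && rhat > 1.1
  if (unconverged) {
    warning("mr_horse: chains unconverged (split R-hat = ",
            round(rhat, 3), " > 1.1)", call. = FALSE)
  }
  structure(
    list(
      theta_posterior_mean = mean(draws),
      theta_posterior_sd = stats::sd(draws),
      theta_ci_low = qs[1], theta_ci_high = qs[2],
      ci_level = ci_level, rhat = rhat, ess = ess,
      unconverged = unconverged,
      n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
      seed = as.integer(seed)
    ),
    class = "horse_result"
  )
}
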