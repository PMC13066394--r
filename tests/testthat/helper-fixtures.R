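# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data files.

# A tiny hand-built variant table with clean rows.
make_variant_table <- function() {
  data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    chrom = c("1", "1", "2"),
    pos = c(1e6, 2e6, 5e5),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    eaf = c(0.3, 0.6, 0.2),
    beta = c(0.10, -0.05, 0.08),
    se = c(0.01, 0.012, 0.015),
    pvalue = 2 * pnorm(-abs(c(0.10, -0.05, 0.08) / c(0.01, 0.012, 0.015))),
    n = 100000,
    stringsAsFactors = FALSE
  )
}

make_gwas <- function(variants = make_variant_table(), name = "trait",
                      n_cases = 50000, n_controls = 50000, ...) {
  suppressWarnings(suppressMessages(
    gwas_summary(variants, trait_name = name, n_cases = n_cases,
                 n_controls = n_controls, ...)
  ))
}

# Build an instrument set directly from vectors (exposure-allele frame).
make_iv <- function(gamma, Gamma, sigma_x, sigma_y,
                    ids = paste0("rs", seq_along(gamma))) {
  instrument_set(data.frame(
    variant_id = ids, chrom = "1", pos = seq_along(gamma) * 1e6,
    effect_allele = "A", other_allele = "G",
    gamma = gamma, sigma_x = sigma_x, Gamma = Gamma, sigma_y = sigma_y,
    eaf = 0.3, f_stat = (gamma / sigma_x)^2,
    stringsAsFactors = FALSE
  ))
}

# Independent weighted-least-squares oracles via stats::lm.
oracle_ivw <- function(iv, model = "multiplicative_random") {
  v <- iv$variants
  w <- 1 / v$sigma_y^2
  fit <- lm(Gamma ~ 0 + gamma, data = v, weights = w)
  s <- summary(fit)$sigma
  se_lm <- summary(fit)$coefficients[1, 2]
  se <- if (model == "fixed") se_lm / s else se_lm / s * max(1, s)
  list(beta = unname(coef(fit)[1]), se = se)
}

oracle_egger <- function(iv) {
  v <- iv$variants
  flip <- sign(v$gamma)
  d <- data.frame(x = v$gamma * flip, y = v$Gamma * flip)
  fit <- lm(y ~ x, data = d, weights = 1 / v$sigma_y^2)
  co <- summary(fit)$coefficients
  list(intercept = co[1, 1], intercept_se = co[1, 2],
       intercept_p = co[1, 4],
       slope = co[2, 1], slope_se = co[2, 2], slope_p = co[2, 4])
}

# Step-by-step Benjamini-Hochberg oracle.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (i in seq(m, 1)) {
    running_min <- min(running_min, p[o[i]] * m / i)
    adj[o[i]] <- running_min
  }
  adj
}
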