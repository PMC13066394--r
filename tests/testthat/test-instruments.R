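# Instrument selection, clumping, proxies and harmonization.

test_that("genome-wide selection uses a strict threshold", {
  tab <- make_variant_table()
  tab$pvalue <- c(1e-9, 1e-7, 5e-8)
  gw <- make_gwas(tab)
  sel <- select_significant(gw)
  expect_equal(sel$variant_id, "rs1")           # 1e-7 out, 5e-8 boundary out
  tab$pvalue <- rep(0.5, 3)
  expect_equal(nrow(select_significant(make_gwas(tab))), 0)
})

test_that("F-statistic is beta^2/se^2 with weak instruments below 10", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(0, 1), 0)
  expect_equal(f_statistic(-0.3, 0.1), 9)
  expect_lt(f_statistic(-0.3, 0.1), 10)
  expect_error(f_statistic(0.1, 0), "positive")
})

test_that("clumping keeps the most significant variant per LD region", {
  cand <- data.frame(
    variant_id = c("a", "b"), chrom = "1", pos = c(1e6, 1e6 + 1000),
    pvalue = c(1e-10, 1e-9), stringsAsFactors = FALSE
  )
  ld <- ld_provider(r2_matrix = matrix(c(1, 0.5, 0.5, 1), 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b"))))
  expect_equal(clump(cand, ld)$variant_id, "a")

  # cross-chromosome pairs are independent whatever the matrix says
  cand$chrom <- c("1", "2")
  expect_equal(nrow(clump(cand, ld)), 2)

  # all pairwise r2 below cutoff: everything is retained
  cand3 <- data.frame(
    variant_id = c("a", "b", "c"), chrom = "1",
    pos = c(1e6, 2e6, 3e6), pvalue = c(1e-8, 1e-9, 1e-10),
    stringsAsFactors = FALSE
  )
  m <- diag(3) * 0.9995 + 0.0005
  dimnames(m) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(nrow(clump(cand3, ld_provider(r2_matrix = m))), 3)

  expect_error(clump(data.frame(variant_id = "a", chrom = NA, pos = 1,
                                pvalue = 0.5), ld),
               "chrom")
})

test_that("clumping matches an independent greedy oracle on random inputs", {
  greedy_oracle <- function(cand, m, window_kb, r2_cutoff) {
    ord <- order(cand$pvalue, cand$chrom, cand$pos, cand$variant_id)
    kept <- character(0)
    for (id in cand$variant_id[ord]) {
      row <- cand[cand$variant_id == id, ]
      ok <- TRUE
      for (k in kept) {
        krow <- cand[cand$variant_id == k, ]
        if (krow$chrom == row$chrom &&
            abs(krow$pos - row$pos) <= window_kb * 1000 &&
            m[id, k] >= r2_cutoff) ok <- FALSE
      }
      if (ok) kept <- c(kept, id)
    }
    sort(kept)
  }
  for (seed in 1:20) {
    cand <- with_seed(seed, {
      n <- 8
      data.frame(
        variant_id = paste0("v", 1:n),
        chrom = as.character(sample(1:2, n, replace = TRUE)),
        pos = sample(1e6:2e7, n),
        pvalue = runif(n, 1e-12, 1e-6),
        stringsAsFactors = FALSE
      )
    })
    m <- with_seed(seed + 100, {
      a <- matrix(runif(64, 0, 0.01), 8, 8)
      a[upper.tri(a)][1:10] <- runif(10, 0, 1)   # some high-LD pairs
      a <- (a + t(a)) / 2
      diag(a) <- 1
      dimnames(a) <- list(cand$variant_id, cand$variant_id)
      a
    })
    ld <- ld_provider(r2_matrix = m)
    got <- clump(cand, ld, window_kb = 10000, r2_cutoff = 0.001)
    expect_equal(sort(got$variant_id),
                 greedy_oracle(cand, m, 10000, 0.001))
    # retained pairs on a chromosome within the window are independent
    if (nrow(got) > 1) {
      for (i in 1:(nrow(got) - 1)) for (j in (i + 1):nrow(got)) {
        if (got$chrom[i] == got$chrom[j] &&
            abs(got$pos[i] - got$pos[j]) <= 1e7) {
          expect_lt(ld$r2(got$variant_id[i], got$variant_id[j]), 0.001)
        }
      }
    }
  }
})

test_that("proxy search honors the strict r2 > 0.8 rule and argmax", {
  out_tab <- data.frame(
    variant_id = c("p1", "p2"), chrom = "1", pos = c(1.1e6, 1.2e6),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = 0.05, se = 0.01, pvalue = 0.1, n = 1e5,
    stringsAsFactors = FALSE
  )
  outcome <- make_gwas(out_tab)
  missing <- data.frame(variant_id = "idx", chrom = "1", pos = 1e6,
                        eaf = 0.3, stringsAsFactors = FALSE)
  mk_ld <- function(r1, r2) {
    ids <- c("idx", "p1", "p2")
    m <- diag(3)
    dimnames(m) <- list(ids, ids)
    m["idx", "p1"] <- m["p1", "idx"] <- r1
    m["idx", "p2"] <- m["p2", "idx"] <- r2
    ld_provider(r2_matrix = m)
  }
  expect_equal(find_proxy(missing, outcome, mk_ld(0.9, 0))$variant_id, "p1")
  expect_null(find_proxy(missing, outcome, mk_ld(0.8, 0.8)))   # boundary
  expect_equal(find_proxy(missing, outcome, mk_ld(0.85, 0.95))$variant_id,
               "p2")
})

test_that("harmonization handles every allele configuration", {
  ex <- data.frame(
    variant_id = paste0("v", 1:5), chrom = "1", pos = 1:5 * 1e6,
    effect_allele = "A", other_allele = "G", eaf = 0.1,
    beta = 0.10, se = 0.02, pvalue = 1e-9, n = 1e5,
    stringsAsFactors = FALSE
  )
  ou <- ex
  ou$beta <- 0.2
  ou$se <- 0.03
  # v1 identical; v2 swapped; v3 strand complement; v4 complement+swap;
  # v5 incompatible
  ou$effect_allele <- c("A", "G", "T", "C", "A")
  ou$other_allele <-  c("G", "A", "C", "T", "T")
  ou$eaf <- c(0.1, 0.9, 0.1, 0.9, 0.1)
  iv <- harmonize(ex, ou)
  expect_equal(iv$n_variable, 4)
  expect_equal(iv$variants$gamma, rep(0.10, 4))
  expect_equal(iv$variants$Gamma, c(0.2, -0.2, 0.2, -0.2))
  expect_equal(iv$variants$eaf, rep(0.1, 4))
  expect_equal(iv$exclusions$variant_id, "v5")
  expect_equal(iv$exclusions$reason, "incompatible-alleles")
})

test_that("swap negation example: exposure A/G 0.10 vs outcome G/A -0.10", {
  ex <- make_variant_table()[1, ]   # A/G, beta 0.10
  ou <- ex
  ou$effect_allele <- "G"; ou$other_allele <- "A"
  ou$beta <- -0.10; ou$eaf <- 1 - ex$eaf
  iv <- harmonize(ex, ou)
  expect_equal(iv$variants$gamma, 0.10)
  expect_equal(iv$variants$Gamma, 0.10)
})

test_that("palindromic variants resolve by EAF or drop as ambiguous", {
  ex <- data.frame(
    variant_id = paste0("v", 1:4), chrom = "1", pos = 1:4 * 1e6,
    effect_allele = c("A", "A", "A", "C"),
    other_allele = c("T", "T", "T", "G"),
    eaf = c(0.1, 0.50, 0.1, 0.2),
    beta = 0.1, se = 0.02, pvalue = 1e-9, n = 1e5,
    stringsAsFactors = FALSE
  )
  ou <- ex
  ou$beta <- 0.2
  ou$eaf <- c(0.1, 0.50, 0.9, 0.2)  # v3: opposite side of 0.5 -> drop
  iv <- harmonize(ex, ou)
  expect_equal(iv$variants$variant_id, c("v1", "v4"))
  expect_equal(iv$variants$Gamma, c(0.2, 0.2))
  expect_setequal(iv$exclusions$variant_id, c("v2", "v3"))
  expect_true(all(iv$exclusions$reason == "palindromic-ambiguous"))
})

test_that("harmonization is involutive and sign-consistent", {
  fx <- suppressMessages(simulate_pair(simulation_truth(
    theta = 0.3, n_variants = 30, seed = 42
  )))
  ex <- fx$exposure$variants
  ou <- fx$outcome$variants
  iv1 <- harmonize(ex, ou)

  # re-harmonizing the already-harmonized outcome changes nothing
  ou2 <- data.frame(
    variant_id = iv1$variants$variant_id, chrom = iv1$variants$chrom,
    pos = iv1$variants$pos,
    effect_allele = iv1$variants$effect_allele,
    other_allele = iv1$variants$other_allele,
    eaf = iv1$variants$eaf, beta = iv1$variants$Gamma,
    se = iv1$variants$sigma_y, pvalue = 0.5, n = 1e5,
    stringsAsFactors = FALSE
  )
  iv2 <- harmonize(ex, ou2)
  expect_equal(iv2$variants$gamma, iv1$variants$gamma)
  expect_equal(iv2$variants$Gamma, iv1$variants$Gamma)

  # flipping every outcome label and beta leaves harmonized pairs unchanged
  ou_flip <- ou
  ou_flip$effect_allele <- ou$other_allele
  ou_flip$other_allele <- ou$effect_allele
  ou_flip$beta <- -ou$beta
  ou_flip$eaf <- 1 - ou$eaf
  iv3 <- harmonize(ex, ou_flip)
  expect_equal(iv3$variants$gamma, iv1$variants$gamma)
  expect_equal(iv3$variants$Gamma, iv1$variants$Gamma)
})

test_that("build_instrument_set composes selection and logs exclusions", {
  n <- 50
  ex_tab <- data.frame(
    variant_id = paste0("v", 1:n), chrom = as.character(rep(1:10, 5)),
    pos = rep(seq(1e6, 2e8, length.out = 5), each = 10),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = 0.10, se = 0.01, pvalue = 2 * pnorm(-10), n = 1e5,
    stringsAsFactors = FALSE
  )
  ou_tab <- ex_tab
  ou_tab$beta <- 0.05
  exposure <- make_gwas(ex_tab, "exp")
  outcome <- make_gwas(ou_tab, "out")
  ld <- ld_provider(blocks = setNames(1:n, ex_tab$variant_id),
                    within_r2 = 0)
  iv <- build_instrument_set(exposure, outcome, ld)
  expect_equal(iv$n_variable, 50)
  expect_equal(iv$mean_f, mean(iv$variants$f_stat))
  expect_equal(iv$mean_f, 100)

  # 5 variants absent from the outcome, no proxies -> logged exclusions
  outcome5 <- make_gwas(ou_tab[-(1:5), ], "out")
  iv5 <- build_instrument_set(exposure, outcome5, ld)
  expect_equal(iv5$n_variable, 45)
  expect_equal(sum(iv5$exclusions$reason == "missing-in-outcome"), 5)

  # no significant exposure variants -> empty set
  ex_ns <- ex_tab
  ex_ns$beta <- 0.001
  ex_ns$pvalue <- 0.5
  iv0 <- build_instrument_set(make_gwas(ex_ns, "exp"), outcome, ld)
  expect_equal(iv0$n_variable, 0)
})

test_that("proxy substitution transfers the proxy's outcome effect", {
  ex_tab <- data.frame(
    variant_id = c("idx", paste0("f", 1:3)), chrom = "1",
    pos = c(1e6, 5e7, 9e7, 1.3e8),
    effect_allele = "A", other_allele = "G", eaf = 0.2,
    beta = 0.1, se = 0.01, pvalue = 2 * pnorm(-10), n = 1e5,
    stringsAsFactors = FALSE
  )
  ou_tab <- ex_tab
  ou_tab$variant_id[1] <- "prx"
  ou_tab$pos[1] <- 1.1e6
  ou_tab$beta <- 0.05
  ou_tab$eaf[1] <- 0.8   # proxy reported for the other allele
  ids <- c("idx", "prx", paste0("f", 1:3))
  m <- diag(5)
  m[1, 2] <- m[2, 1] <- 0.95
  dimnames(m) <- list(ids, ids)
  ld <- ld_provider(r2_matrix = m)
  iv <- build_instrument_set(make_gwas(ex_tab, "e"), make_gwas(ou_tab, "o"),
                             ld)
  expect_equal(iv$n_variable, 4)
  prx_row <- iv$variants[iv$variants$variant_id == "idx", ]
  expect_equal(prx_row$Gamma, -0.05)  # EAF-discordant: flipped
})
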