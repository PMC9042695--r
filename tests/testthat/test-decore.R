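test_that("TMM factors are 1 for identical or depth-scaled libraries", {
  a <- c(100L, 250L, 30L, 800L, 40L, 5L)
  m <- cbind(s1 = a, s2 = a)
  rownames(m) <- sprintf("g%d", 1:6)
  expect_equal(unname(tmm_factors(m)), c(1, 1))
  m2 <- cbind(s1 = a, s2 = 2L * a)
  expect_equal(unname(tmm_factors(m2)), c(1, 1))
})

test_that("TMM matches a step-by-step hand computation on the toy", {
  m <- toy_counts()
  ref <- 1
  expect_equal(unname(tmm_factors(m, reference = ref)),
               unname(oracle_tmm_factors(m, ref)), tolerance = 1e-12)
})

test_that("TMM agrees with edgeR on random matrices", {
  skip_if_not_installed("edgeR")
  set.seed(101)
  for (i in 1:3) {
    m <- matrix(rnbinom(400 * 5, mu = 80, size = 5), ncol = 5,
                dimnames = list(sprintf("g%d", 1:400), sprintf("s%d", 1:5)))
    m[seq_len(20 * i), 2] <- m[seq_len(20 * i), 2] * 8L
    expect_equal(unname(tmm_factors(m)),
                 edgeR::calcNormFactors(edgeR::DGEList(m))$samples$norm.factors,
                 tolerance = 1e-10)
  }
})

test_that("TMM factors have geometric mean 1 and flag all-zero samples", {
  set.seed(7)
  m <- matrix(rnbinom(300 * 4, mu = 50, size = 2), ncol = 4,
              dimnames = list(sprintf("g%d", 1:300), sprintf("s%d", 1:4)))
  f <- tmm_factors(m)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
  m[, 2] <- 0L
  expect_error(tmm_factors(m), "s2")
})

test_that("exact test is 1 for symmetric splits and reduces to binomial at phi = 0", {
  expect_equal(nb_exact_test(c(5, 5), c(5, 5), c(1e5, 1e5), c(1e5, 1e5),
                             0.1), 1)
  # Poisson limit: equals the two-sided exact binomial test of the split
  p0 <- nb_exact_test(14, 3, 1e5, 1e5, 0)
  expect_equal(p0, binom.test(14, 17, p = 0.5)$p.value, tolerance = 1e-12)
  p_uneq <- nb_exact_test(c(14, 2), 3, c(1e5, 1e5), 1e5, 0)
  expect_equal(p_uneq, binom.test(16, 19, p = 2 / 3)$p.value,
               tolerance = 1e-12)
})

test_that("exact test matches full conditional enumeration for totals <= 200", {
  cases <- expand.grid(ya = c(0, 2, 18, 50, 97), yb = c(2, 20, 100),
                       phi = c(0, 0.05, 0.1, 0.5), n_a = c(2, 4),
                       n_b = c(4))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    got <- nb_exact_test(rep(cs$ya / cs$n_a, cs$n_a),
                         rep(cs$yb / cs$n_b, cs$n_b),
                         rep(1e6, cs$n_a), rep(1e6, cs$n_b), cs$phi)
    want <- oracle_nb_split_p(round(cs$ya), round(cs$yb), cs$n_a, cs$n_b,
                              cs$phi)
    expect_equal(got, want, tolerance = 1e-10,
                 label = paste("case", i, "p"))
  }
  # the spec's 18 vs 2 split with equal group sizes
  expect_equal(nb_exact_test(18, 2, 1, 1, 0.1),
               oracle_nb_split_p(18, 2, 1, 1, 0.1), tolerance = 1e-10)
})

test_that("exact test agrees with edgeR small-p exact test", {
  skip_if_not_installed("edgeR")
  set.seed(5)
  for (i in 1:20) {
    y1 <- rnbinom(3, mu = 40, size = 10)
    y2 <- rnbinom(3, mu = 120, size = 10)
    pe <- edgeR::exactTestBySmallP(matrix(y1, 1), matrix(y2, 1),
                                   dispersion = 0.1)
    pm <- nb_exact_test(y1, y2, rep(1e5, 3), rep(1e5, 3), 0.1)
    expect_equal(pm, as.numeric(pe), tolerance = 1e-10)
  }
})

test_that("exact test rejects invalid dispersion and empty groups", {
  expect_error(nb_exact_test(1, 1, 1, 1, -0.1), "dispersion")
  expect_error(nb_exact_test(numeric(0), 1, numeric(0), 1, 0.1), "group")
})

test_that("dispersion estimation recovers Poisson and NB truth", {
  set.seed(31)
  d <- toy_design(n_donors = 4)
  mu <- 2^runif(2000, 4, 9)
  pois <- sapply(seq_len(nrow(d)), function(j) rpois(2000, mu))
  dimnames(pois) <- list(sprintf("g%d", 1:2000), d$sample)
  storage.mode(pois) <- "integer"
  expect_lt(estimate_dispersion(pois, d), 0.05)
  nb <- sapply(seq_len(nrow(d)), function(j)
    rnbinom(2000, mu = mu, size = 1 / 0.2))
  dimnames(nb) <- dimnames(pois)
  storage.mode(nb) <- "integer"
  expect_equal(estimate_dispersion(nb, d), 0.2, tolerance = 0.5)
  expect_lt(abs(estimate_dispersion(nb, d) - 0.2), 0.1)
})

test_that("dispersion is zero for constant groups and errors without replicates", {
  d <- toy_design(n_donors = 2)
  m <- matrix(rep(c(10L, 20L, 40L), each = 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), d$sample))
  expect_equal(estimate_dispersion(m, d), 0)
  d1 <- toy_design(n_donors = 1)
  m1 <- m[, d1$sample, drop = FALSE]
  expect_error(estimate_dispersion(m1, d1), "replicates")
})

test_that("signed fold change follows the negative-reciprocal convention", {
  expect_equal(signed_fc(1), 2)
  expect_equal(signed_fc(-1), -2)
  expect_equal(signed_fc(0), 1)
  # a log2FC of -7.1175 displays as roughly a -139-fold change
  expect_equal(signed_fc(-7.1175), -138.856, tolerance = 1e-4)
})

test_that("run_contrast reports no change for identical groups and finds planted effects", {
  set.seed(77)
  d <- toy_design(n_donors = 4)
  n <- 1100  # mostly null so normalization has a stable majority
  mu <- 2^runif(n, 5, 9)
  lfc <- c(rep(0, 1000), rep(2, 100))  # 100 genes planted at log2FC 2
  counts <- sapply(seq_len(nrow(d)), function(j) {
    m <- if (d$treatment[j] == "IFNL3") mu * 2^lfc else mu
    rnbinom(n, mu = m, size = 1 / 0.05)
  })
  dimnames(counts) <- list(sprintf("g%d", seq_len(n)), d$sample)
  storage.mode(counts) <- "integer"
  res <- run_contrast(counts, d, "M1", "IFNL3", "NT", dispersion = 0.05)
  expect_gte(mean(res$is_deg[1001:1100]), 0.95)
  # null genes stay near FC 1 on average
  expect_lt(mean(abs(res$signed_fc[1:1000])), 1.5)
  expect_error(run_contrast(counts, d, "M7", "IFNL3", "NT"), "cell type")
  expect_error(run_contrast(counts, d, "M1", "IFNL9", "NT"), "treatment")
})

test_that("DEG rule excludes the exact threshold and is monotone in thresholds", {
  res <- data.frame(gene = sprintf("g%d", 1:6),
                    signed_fc = c(1.5, -1.6, 2.0, 4.0, -1.2, 10),
                    p_value = c(0.01, 0.01, 0.20, 0.04, 0.001, 1))
  expect_setequal(call_degs(res), c("g2", "g4"))
  expect_false("g1" %in% call_degs(res))  # exactly 1.5-fold is not a DEG
  for (fc in c(1.1, 1.5, 2, 5)) {
    for (p in c(0.001, 0.05, 0.5)) {
      expect_lte(length(call_degs(res, fc, p)),
                 length(call_degs(res, 1.1, 0.5)))
    }
  }
  expect_length(call_degs(transform(res, p_value = 1)), 0)
})

test_that("BH adjustment matches the hand step-up and validates input", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  # step-up by hand: p_(i) * n / i, then running minimum from the top
  hand <- rev(cummin(rev(p * 4 / 1:4)))
  expect_equal(bh_adjust(p), hand)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 0)), "p-values")
  expect_error(bh_adjust(c(0.5, 1.2)), "p-values")
})

test_that("run_triplet shares gene order and orients lambda4 as numerator", {
  set.seed(9)
  cfg <- sim_config(n_genes = 150, seed = 9)
  sim <- simulate_counts(cfg)
  tr <- run_triplet(sim$counts, sim$design, "M1")
  expect_identical(tr$l3$gene, tr$l4$gene)
  expect_identical(tr$l3$gene, tr$l4vl3$gene)
  # a strong lambda4-only responder must have positive FC in l4 and l4vl3
  up <- sim$truth$gene[sim$truth$cell_type == "M1" &
                         sim$truth$archetype == "l4_up"]
  if (length(up) > 0) {
    i <- match(up, tr$l4$gene)
    expect_true(all(tr$l4$signed_fc[i] > 1))
    expect_true(all(tr$l4vl3$signed_fc[i] > 1))
  }
})
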