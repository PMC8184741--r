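test_that("LD generator respects the block design across rho values", {
  # independence case
  g0 <- simulate_ld_genotypes(2000, 10, rho = 0, seed = 3)$genotypes
  r0 <- abs(cor(g0))
  expect_lt(mean(r0[upper.tri(r0)]), 0.1)

  # near-perfect LD: every pair clears the purity threshold
  g99 <- simulate_ld_genotypes(2000, 4, rho = 0.99, seed = 3)$genotypes
  r99 <- abs(cor(g99))
  expect_true(all(r99[upper.tri(r99)] > 0.5))

  # blocks are independent of each other
  g <- simulate_ld_genotypes(2000, c(3, 3), rho = 0.9, seed = 3)$genotypes
  r <- abs(cor(g))
  expect_lt(mean(r[1:3, 4:6]), 0.1)

  # within-block mean |r| increases with rho
  means <- vapply(c(0, 0.5, 0.9), function(rho) {
    gg <- simulate_ld_genotypes(1000, rep(10, 2), rho, seed = 5)$genotypes
    rr <- abs(cor(gg))
    w <- c(rr[1:10, 1:10][upper.tri(diag(10))],
           rr[11:20, 11:20][upper.tri(diag(10))])
    mean(w)
  }, numeric(1))
  expect_true(all(diff(means) > 0))

  expect_error(simulate_ld_genotypes(100, 5, rho = 1), "rho")
  expect_error(simulate_ld_genotypes(100, 5, rho = -0.1), "rho")
  expect_error(simulate_ld_genotypes(1, 5, rho = 0.5), "n must be")
})

test_that("fixed seeds reproduce byte-identical genotypes", {
  a <- simulate_ld_genotypes(200, rep(5, 2), 0.5, seed = 11)
  b <- simulate_ld_genotypes(200, rep(5, 2), 0.5, seed = 11)
  c <- simulate_ld_genotypes(200, rep(5, 2), 0.5, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$genotypes, c$genotypes))
  expect_true(all(apply(a$genotypes, 2, var) > 0))
})

test_that("expression model recovers a fixed effect by OLS", {
  err <- vapply(1:20, function(s) {
    locus <- simulate_ld_genotypes(500, rep(10, 2), 0.3, seed = s)
    locus <- simulate_expression(locus, 1, noise_sd = 1, seed = s + 100,
                                 causal_index = 7, effects = 0.5)
    x <- scale(locus$genotypes[, 7])
    unname(coef(lm(locus$expression ~ x))[2]) - 0.5
  }, numeric(1))
  expect_true(all(abs(err) < 0.15))
})

test_that("a dominant causal variant has the top marginal correlation in its block", {
  hits <- vapply(1:10, function(s) {
    locus <- simulate_ld_genotypes(800, rep(10, 2), 0.5, seed = s)
    locus <- simulate_expression(locus, 1, beta_sd = 0, noise_sd = 0.2,
                                 seed = s + 50, causal_index = 4,
                                 effects = 2)
    r <- abs(cor(locus$genotypes[, 1:10], locus$expression))
    which.max(r) == 4
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("null expression yields no pure credible set in most seeds", {
  n_pure <- vapply(1:10, function(s) {
    locus <- simulate_ld_genotypes(300, rep(10, 3), 0, seed = s)
    locus <- simulate_expression(locus, 0, noise_sd = 1, seed = s + 100)
    fit <- ibss_fit(locus$genotypes, locus$expression, L = 3)
    sum(vapply(fit$sets, `[[`, logical(1), "pure"))
  }, numeric(1))
  expect_gte(sum(n_pure == 0), 9)
})

test_that("feature generator produces the advertised structure", {
  truth <- c(rep(TRUE, 1000), rep(FALSE, 99000))
  f <- simulate_features(truth, enrich_binary = 10, seed = 9)

  # binary enrichment in causal pairs near the requested 10-fold
  enr <- mean(f$baseline_peak_1[truth]) / mean(f$baseline_peak_1)
  expect_gte(enr, 8)
  expect_lte(enr, 12)

  # causal pairs sit nearer the TSS
  expect_lt(median(abs(f$tss_distance[truth])),
            median(abs(f$tss_distance[!truth])))

  # an uninformative score carries no signal
  f0 <- simulate_features(truth, score_informativeness = 0, seed = 10)
  auc <- score_eval(f0$dl_score_1, truth)$auroc
  expect_gte(auc, 0.45)
  expect_lte(auc, 0.55)

  expect_error(simulate_features(truth, enrich_binary = 0.5), "enrich")
  expect_error(simulate_features(truth, score_informativeness = -1),
               "informativeness")
})

test_that("catalog truth rate matches the requested rate within binomial CI", {
  cat0 <- simulate_catalog(n_genes = 10, m_per_gene = 100, block_size = 10,
                           rho = 0.5, n_individuals = 50, causal_frac = 0.1,
                           beta_sd = 0.3, finemap = FALSE, seed = 21)
  n <- length(cat0$truth)
  ci <- qbinom(c(0.025, 0.975), n, 0.1) / n
  expect_gte(mean(cat0$truth), ci[1])
  expect_lte(mean(cat0$truth), ci[2])
  expect_gt(mean(cat0$truth), 0)
  expect_lt(mean(cat0$truth), 1)
  expect_identical(nrow(cat0$features), nrow(cat0$pairs))
})

test_that("block-mode causality places one causal variant per chosen block", {
  cat0 <- simulate_catalog(n_genes = 6, m_per_gene = 50, block_size = 10,
                           rho = 0.5, n_individuals = 50, causal_frac = 0.2,
                           causal_mode = "block", finemap = FALSE, seed = 4)
  for (locus in cat0$loci) {
    expect_length(locus$causal_index_set, 1L)  # 0.2 * 5 blocks = 1
  }
})

test_that("catalog writes a complete plain-text representation", {
  dir <- tempfile()
  small <- simulate_catalog(n_genes = 2, m_per_gene = 10, block_size = 5,
                            rho = 0.5, n_individuals = 30,
                            causal_frac = 0.1, finemap = FALSE, seed = 2)
  files <- write_catalog(small, dir)
  expect_true(all(file.exists(files)))
  back <- read_tsv(files[["pairs"]])
  expect_identical(nrow(back), nrow(small$pairs))
  # BED round-trip: 0-based half-open intervals recover 1-based positions
  bedf <- files[grep("\\.bed$", files)][1]
  bed <- read_bed(bedf)
  if (nrow(bed)) expect_true(all(bed$end - bed$start == 1L))
})
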