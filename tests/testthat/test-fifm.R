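test_that("PIPs combine single effects by the product rule", {
  a1 <- matrix(c(0.5, 0.5, 0), 1, 3)
  expect_equal(as.numeric(compute_pip(a1)), c(0.5, 0.5, 0))  # L=1 identity
  a2 <- rbind(c(0.5, 0.5, 0), c(0.5, 0, 0.5))
  expect_equal(as.numeric(compute_pip(a2)), c(0.75, 0.5, 0.5))
  expect_equal(as.numeric(compute_pip(a2, only_effects = 2)),
               c(0.5, 0, 0.5))
})

test_that("credible sets take the smallest covering prefix with id tie-break", {
  expect_identical(credible_set_95(c(v1 = 1, v2 = 0, v3 = 0))$members, "v1")
  cs <- credible_set_95(c(v1 = 0.5, v2 = 0.3, v3 = 0.15, v4 = 0.05))
  expect_identical(cs$members, c("v1", "v2", "v3"))
  expect_equal(cs$mass, 0.95)
  # four variants in perfect LD at alpha 0.25 each: all four are members
  cs4 <- credible_set_95(rep(0.25, 4),
                         variant_ids = c("a", "b", "c", "d"))
  expect_identical(sort(cs4$members), c("a", "b", "c", "d"))
  # equal alphas resolve ties by ascending variant id
  cs_tie <- credible_set_95(c(b = 0.5, a = 0.5), coverage = 0.5)
  expect_identical(cs_tie$members, "a")
  expect_error(credible_set_95(c(0.5, 0.5), coverage = 0), "coverage")
})

test_that("purity is the minimum pairwise |correlation|", {
  corr <- matrix(c(1, 0.4, 0.4, 1), 2, 2,
                 dimnames = list(c("v1", "v2"), c("v1", "v2")))
  expect_identical(purity("v1", corr), list(min_abs_corr = 1, pure = TRUE))
  p <- purity(c("v1", "v2"), corr)
  expect_equal(p$min_abs_corr, 0.4)
  expect_false(p$pure)
  perfect <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  p4 <- purity(letters[1:4], perfect)
  expect_true(p4$pure)
  expect_equal(p4$min_abs_corr, 1)
  expect_error(purity(c("v1", "vX"), corr), "vX")
})

test_that("reweighting reproduces the published worked example", {
  fx <- cited4_fixture()
  rw <- reweight_alpha(fx$alpha, fx$ems, pure = TRUE)
  a <- as.numeric(rw$alpha)
  expect_equal(round(a[1], 3), 0.956)
  expect_equal(a, c(0.956, 0.0338, 0.0055, 0.0048), tolerance = 0.02)
  expect_equal(sum(a), 1, tolerance = 1e-12)
})

test_that("reweighting follows the prior-weighting equation", {
  rw <- reweight_alpha(matrix(c(0.6, 0.4), 1), c(1, 3), pure = TRUE)
  expect_equal(as.numeric(rw$alpha), c(1 / 3, 2 / 3), tolerance = 1e-12)
  # equal weights are an identity
  a <- matrix(c(0.2, 0.3, 0.5), 1)
  expect_equal(reweight_alpha(a, c(2, 2, 2), pure = TRUE)$alpha, a,
               tolerance = 1e-15)
  # impure rows pass through untouched
  expect_identical(reweight_alpha(a, c(1, 5, 9), pure = FALSE)$alpha, a)
  # all-zero weighted mass: unchanged and flagged degenerate
  z <- matrix(c(1, 0, 0), 1)
  rz <- reweight_alpha(z, c(0, 1, 1), pure = TRUE)
  expect_identical(rz$alpha, z)
  expect_true(rz$degenerate)
  expect_error(reweight_alpha(a, c(-1, 1, 1), pure = TRUE), "nonnegative")
})

test_that("reweighting invariants hold over random rows", {
  set.seed(77)
  n_rows <- 1000
  m <- 8
  for (i in seq_len(n_rows)) {
    a <- matrix(rexp(m), 1)
    a <- a / sum(a)
    w <- rexp(m)
    rw <- reweight_alpha(a, w, pure = TRUE)$alpha
    # rows renormalize exactly
    expect_equal(sum(rw), 1, tolerance = 1e-10)
    # the argmax-weight variant never loses posterior mass
    j <- which.max(w)
    expect_gte(rw[j], a[j] - 1e-12)
    # scale invariance of the weights
    rw2 <- reweight_alpha(a, w * 17.3, pure = TRUE)$alpha
    expect_equal(rw, rw2, tolerance = 1e-12)
    # reweighting then uniform reweighting is a no-op
    rw3 <- reweight_alpha(rw, rep(1, m), pure = TRUE)$alpha
    expect_equal(rw3, rw, tolerance = 1e-12)
  }
})

test_that("IBSS with one effect matches the closed-form single-effect Bayes oracle", {
  for (s in 1:5) {
    set.seed(s)
    n <- 80 + 10 * s
    m <- 6
    X <- matrix(rnorm(n * m), n, m)
    y <- 0.5 * scale(X[, (s %% m) + 1])[, 1] + rnorm(n)
    V <- 0.2 * var(y)
    s2 <- var(y)
    fit <- ibss_fit(X, y, L = 1, prior_variance = V, residual_variance = s2,
                    estimate_residual = FALSE)
    # oracle: exhaustive single-causal Bayes factors from OLS summary stats
    Xs <- scale(X)
    yc <- y - mean(y)
    d <- colSums(Xs^2)
    bhat <- as.numeric(crossprod(Xs, yc)) / d
    shat2 <- s2 / d
    lbf <- 0.5 * log(shat2 / (shat2 + V)) +
      0.5 * bhat^2 / shat2 * V / (V + shat2)
    alpha <- exp(lbf - max(lbf))
    alpha <- alpha / sum(alpha)
    expect_lt(max(abs(fit$alpha[1, ] - alpha)), 1e-6)
  }
})

test_that("a strong causal variant attains high PIP in nearly all seeds", {
  hits <- vapply(1:20, function(s) {
    locus <- simulate_ld_genotypes(500, rep(10, 2), 0.3, seed = s)
    locus <- simulate_expression(locus, 1, beta_sd = 0, noise_sd = 0.5,
                                 seed = s + 200, causal_index = 5,
                                 effects = 1.5)
    fit <- ibss_fit(locus$genotypes, locus$expression, L = 3)
    fit$pip[5] > 0.95
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("IBSS rejects degenerate inputs and flags non-convergence", {
  X <- matrix(rnorm(200), 20, 10)
  expect_error(ibss_fit(X, rep(1, 20)), "constant phenotype")
  Xc <- X
  Xc[, 3] <- 2
  expect_error(ibss_fit(Xc, rnorm(20)), "constant genotype")
  expect_error(ibss_fit(X[1:5, ], rnorm(5)), "at least 10")
  fit <- ibss_fit(X, rnorm(20), L = 2, max_iter = 1)
  expect_false(fit$converged)
})

test_that("functionally informed PIPs reduce to the uniform fit under equal weights", {
  locus <- simulate_ld_genotypes(300, rep(10, 2), 0.8, seed = 41)
  locus <- simulate_expression(locus, 1, beta_sd = 0, noise_sd = 1,
                               seed = 42, causal_index = 3, effects = 0.8)
  res <- functionally_informed_pips(locus$genotypes, locus$expression,
                                    rep(1, 20), L = 3)
  expect_equal(res$pip$pip_ems, res$pip$pip_unif, tolerance = 1e-12)

  # named weights: unscored variants get the 5th-percentile default
  w <- stats::setNames(seq(0.001, 0.019, length.out = 19),
                       sprintf("v%d", 1:19))
  res2 <- functionally_informed_pips(locus$genotypes, locus$expression, w,
                                     L = 3)
  expect_equal(unname(res2$weights["v20"]),
               as.numeric(quantile(w, 0.05)), tolerance = 1e-12)

  # ratio adjustment caps the dynamic range and labels the prior
  w3 <- stats::setNames(c(rep(1e-6, 19), 1), sprintf("v%d", 1:20))
  res3 <- functionally_informed_pips(locus$genotypes, locus$expression, w3,
                                     L = 3, max_prior_ratio = 100)
  expect_identical(res3$prior_kind, "ems-ratio-adjusted")
  expect_lte(max(res3$weights) / min(res3$weights), 100 + 1e-9)
})
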