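test_that("label construction requires concordance of both methods", {
  pairs <- data.frame(pip_a = c(0.95, 0.95, 5e-5, 0.5),
                      pip_b = c(0.92, 0.50, 1e-6, 0.5))
  lab <- construct_labels(pairs)
  expect_identical(lab$label,
                   c("positive", "unlabeled", "negative", "unlabeled"))
  expect_error(construct_labels(data.frame(pip_a = 1.2, pip_b = 0.5)),
               "outside")
  expect_error(construct_labels(pairs, pos_threshold = 0.1,
                                neg_threshold = 0.5), "below")
})

test_that("calibration implements the prevalence-rescaled positive fraction", {
  # two clean score bins: low bin f = 0.2, high bin f = 0.8, pi_t = 0.5
  raw <- c(runif(100, 0.05, 0.15), runif(100, 0.85, 0.95))
  labels <- c(rep(c("positive", "negative"), c(20, 80)),
              rep(c("positive", "negative"), c(80, 20)))
  cal <- calibrate_to_ems(raw, labels, base_rate = 0.001, n_bins = 2,
                          min_bin = 10)
  f <- 0.8; pi <- 0.001; pi_t <- 0.5
  expected <- (f * pi / pi_t) / (f * pi / pi_t + (1 - f) * (1 - pi) / (1 - pi_t))
  expect_equal(tail(cal$ems_value, 1), expected, tolerance = 1e-10)
  expect_equal(expected, 0.003988, tolerance = 1e-3)

  # pi_t equal to pi: no rescaling, ems equals the positive fraction
  cal2 <- calibrate_to_ems(raw, labels, base_rate = 0.5, n_bins = 2,
                           min_bin = 10)
  expect_equal(cal2$ems_value, cal2$pos_fraction, tolerance = 1e-12)

  # a bin with no positives scores exactly zero
  raw3 <- c(runif(50, 0, 0.2), runif(50, 0.8, 1))
  lab3 <- c(rep("negative", 50), rep("positive", 50))
  cal3 <- calibrate_to_ems(raw3, lab3, base_rate = 0.01, n_bins = 2,
                           min_bin = 10)
  expect_identical(cal3$ems_value[1], 0)

  expect_error(calibrate_to_ems(numeric(0), character(0), 0.5), "empty")
  expect_error(calibrate_to_ems(raw, labels, base_rate = 0), "base_rate")
})

test_that("calibrated EMS is monotone in the raw score", {
  set.seed(31)
  raw <- runif(2000)
  labels <- ifelse(runif(2000) < 0.2 + 0.5 * raw, "positive", "negative")
  cal <- calibrate_to_ems(raw, labels, base_rate = 0.05, n_bins = 20,
                          min_bin = 50)
  expect_true(all(diff(cal$ems_value) >= -1e-12))
  expect_true(all(cal$ems_value >= 0 & cal$ems_value <= 1))
})

test_that("prior-ratio adjustment floors the weights and is idempotent", {
  w <- c(1e-6, 5e-4, 2e-2)
  adj <- adjust_prior_ratio(w)
  expect_equal(adj, c(2e-4, 5e-4, 2e-2), tolerance = 1e-12)
  expect_equal(max(adj) / min(adj), 100, tolerance = 1e-12)
  expect_identical(adjust_prior_ratio(adj), adj)          # idempotent
  expect_identical(adjust_prior_ratio(c(1, 2, 3)), c(1, 2, 3))  # within ratio
  expect_identical(adjust_prior_ratio(rep(0.5, 4)), rep(0.5, 4))
  expect_error(adjust_prior_ratio(c(0, 1)), "positive")
  expect_error(adjust_prior_ratio(c(1, 2), max_ratio = 1), "max_ratio")
})

test_that("feature selection surfaces the informative score", {
  truth <- rep(c(TRUE, FALSE), c(300, 2700))
  top3 <- vapply(1:5, function(s) {
    f <- simulate_features(truth, score_informativeness = 3,
                           tss_decay_bp = 1e5, seed = s)
    # drop the dominant distance feature so the score must compete only
    # with noise-level columns
    f2 <- f[, -1]
    labels <- ifelse(truth, "positive", "negative")
    sel <- select_features(f2, labels, k = 3, seed = s)
    "dl_score_1" %in% sel || "dl_score_2" %in% sel || "dl_score_3" %in% sel
  }, logical(1))
  expect_true(all(top3))
  expect_error(select_features(data.frame(a = 1:4),
                               c("positive", "negative", "positive",
                                 "negative"), k = 0), "k must be")
})

test_that("hyperparameter search is seeded and budget-aware", {
  truth <- rep(c(TRUE, FALSE), c(100, 400))
  f <- simulate_features(truth, score_informativeness = 2, seed = 3)
  labels <- ifelse(truth, "positive", "negative")
  clf1 <- tune_and_train(f, labels, search_budget = 1, seed = 5)
  expect_length(clf1$trace, 0)              # budget 1: default configuration
  clf2 <- tune_and_train(f, labels, search_budget = 4, seed = 5)
  clf3 <- tune_and_train(f, labels, search_budget = 4, seed = 5)
  expect_identical(clf2$best_params, clf3$best_params)
  expect_error(tune_and_train(f, rep("positive", 500)), "both classes")
})

test_that("scoring is deterministic, column-checked, and supports fixed TSS", {
  pairs <- shared_catalog$pairs
  feats <- shared_catalog$features
  model <- train_ems(pairs, feats, holdout_chrom = "chr2",
                     search_budget = 1, num_trees = 150, n_bins = 10,
                     min_bin = 10, seed = 13)
  held <- which(pairs$chrom == "chr2")
  s1 <- score_pairs(model, feats[held])
  s2 <- score_pairs(model, feats[held])
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))

  # identical feature rows get identical EMS
  twice <- feats[rep(held[1], 2)]
  expect_identical(score_pairs(model, twice)[1], score_pairs(model, twice)[2])

  # fixing the TSS distance makes the output invariant to the true distance
  f_fixed <- data.table::copy(feats[held])
  s_fix1 <- score_pairs(model, f_fixed, fixed_tss_bp = 200)
  f_fixed$tss_distance <- f_fixed$tss_distance * 10 + 12345
  s_fix2 <- score_pairs(model, f_fixed, fixed_tss_bp = 200)
  expect_identical(s_fix1, s_fix2)

  broken <- feats[held][, setdiff(names(feats), "dl_score_1"), with = FALSE]
  expect_error(score_pairs(model, broken), "dl_score_1")
})

test_that("feature importances report conserved category shares", {
  pairs <- shared_catalog$pairs
  feats <- shared_catalog$features
  model <- train_ems(pairs, feats, holdout_chrom = "chr3",
                     search_budget = 1, num_trees = 150, n_bins = 10,
                     min_bin = 10, seed = 17)
  rep <- feature_importance_report(model)
  expect_equal(sum(rep$per_feature), 1, tolerance = 1e-12)
  expect_equal(sum(rep$per_category), 1, tolerance = 1e-12)
  expect_true(all(rep$per_feature >= 0))
  expect_true(all(names(rep$per_category) %in%
                    c("distance", "baseline-binary", "histone-binary",
                      "continuous-scores")))
  expect_error(feature_importance_report(list()), "trained")
})

test_that("model persistence round-trips through a directory", {
  model <- train_ems(shared_catalog$pairs, shared_catalog$features,
                     holdout_chrom = "chr1", search_budget = 1,
                     num_trees = 100, n_bins = 10, min_bin = 10, seed = 19)
  dir <- tempfile()
  save_ems_model(model, dir)
  expect_true(file.exists(file.path(dir, "calibration.tsv")))
  expect_true(file.exists(file.path(dir, "metadata.json")))
  back <- load_ems_model(dir)
  held <- which(shared_catalog$pairs$chrom == "chr1")
  expect_identical(score_pairs(back, shared_catalog$features[held]),
                   score_pairs(model, shared_catalog$features[held]))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_identical(meta$holdout_chrom, "chr1")
})
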