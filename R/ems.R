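# The expression modifier score: a binary classifier of putative causal
# eQTL status (positive = concordantly fine-mapped with PIP > 0.9 by both
# methods, negative = PIP < 1e-4 by both), trained on functional features,
# whose output is calibrated into an estimated probability by binned
# positive fractions with a prior-odds rescaling from training prevalence to
# genome-wide prevalence.

#' Construct training labels from two fine-mapping posteriors
#'
#' A pair is positive iff both PIPs exceed `pos_threshold`, negative iff both
#' fall below `neg_threshold`, and unlabeled otherwise (excluded from
#' training).
#'
#' @param pairs Table with `pip_a` and `pip_b` columns in `[0, 1]`.
#' @param pos_threshold Positive PIP threshold (default 0.9).
#' @param neg_threshold Negative PIP threshold (default 1e-4).
#' @param require_both Require both methods to agree (default TRUE); when
#'   FALSE only `pip_a` is consulted.
#' @return The table with a `label` column in
#'   `{"positive","negative","unlabeled"}`.
#' @export
construct_labels <- function(pairs, pos_threshold = 0.9,
                             neg_threshold = 1e-4, require_both = TRUE) {
  pairs <- data.table::as.data.table(pairs)
  if (neg_threshold >= pos_threshold)
    stop_invalid("neg_threshold must be below pos_threshold")
  a <- pairs$pip_a
  b <- if (require_both) pairs$pip_b else pairs$pip_a
  if (is.null(a) || is.null(b)) stop_invalid("pip_a/pip_b columns required")
  if (any(c(a, b) < 0 | c(a, b) > 1, na.rm = TRUE))
    stop_invalid("PIP values outside [0, 1]")
  lab <- rep("unlabeled", nrow(pairs))
  lab[pmin(a, b) > pos_threshold] <- "positive"
  lab[pmax(a, b) < neg_threshold] <- "negative"
  pairs[, label := lab]
  pairs[]
}

rf_frame <- function(features, labels = NULL) {
  df <- as.data.frame(features)
  if (!is.null(labels)) df$.label <- factor(labels, c("negative", "positive"))
  df
}

#' Select the most predictive features
#'
#' Ranks features by mean decrease of impurity from a preliminary
#' random-forest fit and returns the top `k` names (ties broken
#' lexicographically). Deterministic given the seed.
#'
#' @param features Feature matrix (labeled training rows only).
#' @param labels Character labels, `"positive"`/`"negative"`.
#' @param k Number of features to keep (default 152).
#' @param num_trees Trees in the preliminary forest.
#' @param seed Integer seed.
#' @return Ordered character vector of feature names (most important first).
#' @export
select_features <- function(features, labels, k = 152, num_trees = 200,
                            seed = 1) {
  if (k <= 0) stop_invalid("k must be positive")
  k <- min(k, ncol(features))
  fit <- ranger::ranger(
    dependent.variable.name = ".label",
    data = rf_frame(features, labels),
    num.trees = num_trees, importance = "impurity",
    probability = TRUE, seed = seed, num.threads = 1
  )
  imp <- fit$variable.importance
  ord <- order(-imp, names(imp))
  names(imp)[ord][seq_len(k)]
}

#' Tune and train the random-forest classifier
#'
#' Random search over `mtry` and `min.node.size` followed by a small local
#' grid refinement around the best draw, selecting the configuration with the
#' highest AUROC on an internal validation split. `search_budget = 1` fits
#' the default configuration without searching.
#'
#' @param features Feature matrix (labeled rows).
#' @param labels `"positive"`/`"negative"` labels; both classes required.
#' @param search_budget Number of random-search draws (>= 1).
#' @param num_trees Trees per forest.
#' @param valid_frac Fraction of rows held out for tuning validation.
#' @param seed Integer seed.
#' @return List of class `ems_classifier`: `forest` (ranger probability
#'   forest refit on all rows with the chosen configuration),
#'   `best_params`, `trace` (search log), `valid_auroc`.
#' @export
tune_and_train <- function(features, labels, search_budget = 10,
                           num_trees = 300, valid_frac = 0.25, seed = 1) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop_invalid("both classes required")
  p <- ncol(features)
  df <- rf_frame(features, labels)
  default <- list(mtry = max(1L, floor(sqrt(p))), min_node = 10L)
  trace <- list()
  best <- default
  best_auc <- NA_real_
  if (search_budget > 1 && min(table(labels)) >= 2) {
    # stratified validation split: both splits keep both classes
    idx <- with_seed(derive_seed(seed, 1L), {
      unlist(lapply(c("positive", "negative"), function(cl) {
        rows <- which(labels == cl)
        take <- min(length(rows) - 1L,
                    max(1L, round(valid_frac * length(rows))))
        sample(rows, take)
      }))
    })
    eval_cfg <- function(cfg, s) {
      fit <- ranger::ranger(dependent.variable.name = ".label",
                            data = df[-idx, , drop = FALSE],
                            num.trees = num_trees, mtry = cfg$mtry,
                            min.node.size = cfg$min_node,
                            probability = TRUE, seed = s, num.threads = 1)
      pr <- predict(fit, df[idx, , drop = FALSE])$predictions[, "positive"]
      as.numeric(pROC::auc(pROC::roc(labels[idx], pr, levels =
                                       c("negative", "positive"),
                                     direction = "<", quiet = TRUE)))
    }
    cand <- with_seed(derive_seed(seed, 2L), {
      lapply(seq_len(search_budget), function(i)
        list(mtry = sample.int(p, 1L),
             min_node = sample(c(1L, 5L, 10L, 20L, 50L), 1L)))
    })
    best_auc <- -Inf
    for (i in seq_along(cand)) {
      auc <- eval_cfg(cand[[i]], derive_seed(seed, 10L + i))
      trace[[length(trace) + 1L]] <- c(cand[[i]], auc = auc, stage = "random")
      if (auc > best_auc) { best_auc <- auc; best <- cand[[i]] }
    }
    # local grid refinement around the best random draw
    grid <- unique(lapply(c(-1L, 1L), function(dm)
      list(mtry = min(p, max(1L, best$mtry + dm)),
           min_node = best$min_node)))
    for (i in seq_along(grid)) {
      auc <- eval_cfg(grid[[i]], derive_seed(seed, 50L + i))
      trace[[length(trace) + 1L]] <- c(grid[[i]], auc = auc, stage = "grid")
      if (auc > best_auc) { best_auc <- auc; best <- grid[[i]] }
    }
  }
  forest <- ranger::ranger(dependent.variable.name = ".label", data = df,
                           num.trees = num_trees, mtry = best$mtry,
                           min.node.size = best$min_node,
                           importance = "impurity", probability = TRUE,
                           seed = derive_seed(seed, 99L), num.threads = 1)
  structure(list(forest = forest, best_params = best, trace = trace,
                 valid_auroc = best_auc, num_trees = num_trees, seed = seed),
            class = "ems_classifier")
}

raw_scores <- function(classifier, features) {
  stopifnot(inherits(classifier, "ems_classifier"))
  predict(classifier$forest, rf_frame(features),
          num.threads = 1)$predictions[, "positive"]
}

# Weighted pool-adjacent-violators: smallest monotone (non-decreasing)
# adjustment of per-bin values under bin-count weights.
pava <- function(values, weights) {
  v <- as.numeric(values); w <- as.numeric(weights)
  i <- 1L
  while (i < length(v)) {
    if (v[i] > v[i + 1L] + 1e-15) {
      pooled <- (v[i] * w[i] + v[i + 1L] * w[i + 1L]) / (w[i] + w[i + 1L])
      v[i] <- pooled; w[i] <- w[i] + w[i + 1L]
      v <- v[-(i + 1L)]; w <- w[-(i + 1L)]
      i <- max(1L, i - 1L)
    } else i <- i + 1L
  }
  list(values = v, weights = w)
}

#' Calibrate raw classifier scores into EMS probabilities
#'
#' Raw scores on held-out labeled pairs are cut into `n_bins` quantile bins
#' (adjacent bins with fewer than `min_bin` labeled pairs are merged). For
#' each bin the positive fraction `f` is computed and rescaled from the
#' training prevalence `pi_t` to the genome-wide base rate `pi` by prior
#' odds:
#' `ems = (f * pi / pi_t) / (f * pi / pi_t + (1 - f) * (1 - pi) / (1 - pi_t))`,
#' then made non-decreasing in raw score by pooling adjacent violators.
#' With `rescale = FALSE` the bin positive fraction is used directly
#' (`ems = f`).
#'
#' @param raw Raw classifier scores of held-out labeled pairs.
#' @param labels Their labels (`"positive"`/`"negative"`).
#' @param base_rate Genome-wide positive prevalence `pi` in `(0, 1)`.
#' @param n_bins Number of quantile bins (default 20).
#' @param min_bin Minimum labeled pairs per bin before merging (default 50).
#' @param rescale Apply the prevalence rescaling (default TRUE).
#' @return Object of class `ems_calibration`: `bin_edges` (raw-score cut
#'   points incl. 0 and 1), `n`, `pos_fraction`, `ems_value` (monotone),
#'   `base_rate`, `train_rate`, `rescale`.
#' @export
calibrate_to_ems <- function(raw, labels, base_rate, n_bins = 20,
                             min_bin = 50, rescale = TRUE) {
  if (!length(raw)) stop_invalid("empty held-out set")
  if (base_rate <= 0 || base_rate >= 1)
    stop_invalid("base_rate must lie strictly in (0, 1)")
  pos <- as.character(labels) == "positive"
  pi_t <- mean(pos)
  if (rescale && (pi_t <= 0 || pi_t >= 1))
    stop_invalid("held-out labels contain a single class; cannot rescale")
  # quantiles of the distinct raw scores: heavy ties at one value (typical
  # when most pairs score ~0) must not swallow the whole score range
  edges <- unique(quantile(unique(raw),
                           probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(edges) < 2) edges <- c(0, 1)   # constant scores: one bin
  edges[1] <- 0; edges[length(edges)] <- 1
  bin <- findInterval(raw, edges, rightmost.closed = TRUE, all.inside = TRUE)
  nb <- length(edges) - 1L
  cnt <- tabulate(bin, nb)
  npos <- vapply(seq_len(nb), function(b) sum(pos[bin == b]), numeric(1))
  # merge small bins into their left neighbor (leftmost merges right)
  keep_edge <- rep(TRUE, length(edges))
  repeat {
    small <- which(cnt < min_bin)
    if (!length(small) || length(cnt) == 1L) break
    b <- small[1]
    tgt <- if (b == 1L) 2L else b - 1L
    cnt[tgt] <- cnt[tgt] + cnt[b]; npos[tgt] <- npos[tgt] + npos[b]
    cnt <- cnt[-b]; npos <- npos[-b]
    edges <- edges[-(b + if (b == 1L) 1L else 0L)]
  }
  f <- npos / cnt
  ems <- if (rescale) {
    num <- f * base_rate / pi_t
    den <- num + (1 - f) * (1 - base_rate) / (1 - pi_t)
    ifelse(f == 0, 0, num / den)
  } else f
  # monotone adjustment: pool adjacent violators weighted by bin size
  pooled <- pava(ems, cnt)
  # expand pooled values back to per-bin values
  mono <- numeric(length(ems))
  j <- 1L; acc <- 0
  for (i in seq_along(ems)) {
    acc <- acc + cnt[i]
    mono[i] <- pooled$values[j]
    if (acc >= sum(pooled$weights[seq_len(j)])) j <- min(j + 1L,
                                                         length(pooled$values))
  }
  structure(list(bin_edges = edges, n = cnt, pos_fraction = f,
                 ems_value = pmin(pmax(mono, 0), 1),
                 base_rate = base_rate, train_rate = pi_t,
                 rescale = rescale),
            class = "ems_calibration")
}

apply_calibration <- function(calibration, raw) {
  bin <- findInterval(raw, calibration$bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  calibration$ems_value[bin]
}

#' Cap the dynamic range of prior weights
#'
#' Weights below `max(weights) / max_ratio` are raised to that floor, so the
#' maximum prior never exceeds `max_ratio` times the minimum. A floor (not a
#' ceiling) preserves the top of the prior. Idempotent.
#'
#' @param weights Positive weights.
#' @param max_ratio Maximum allowed max/min ratio (default 100).
#' @return Adjusted weights, same length and order.
#' @export
adjust_prior_ratio <- function(weights, max_ratio = 100) {
  w <- as.numeric(weights)
  if (any(!is.finite(w)) || any(w <= 0))
    stop_invalid("weights must be positive and finite")
  if (max_ratio <= 1) stop_invalid("max_ratio must exceed 1")
  pmax(w, max(w) / max_ratio)
}

#' Train an EMS model with leave-one-chromosome-out provenance
#'
#' End-to-end training: hold out one chromosome, construct labels on the
#' remaining pairs, balance classes (all positives plus an equal-size seeded
#' random negative sample), select features, tune and fit the forest, and
#' calibrate on an internal labeled holdout not used for fitting. The
#' returned model only ever scores pairs outside its training chromosomes.
#'
#' @param pairs Pair table with `chrom`, `pip_a`, `pip_b`.
#' @param features Feature matrix aligned to `pairs` (with `feature_class`
#'   attribute when available).
#' @param holdout_chrom Chromosome excluded from training.
#' @param k_features Number of features to select (default all, capped
#'   at 152).
#' @param base_rate Genome-wide positive prevalence; default
#'   `#positives / #pairs` over the full input.
#' @param search_budget Hyperparameter search draws.
#' @param calib_frac Fraction of labeled training rows reserved for
#'   calibration.
#' @param n_bins,min_bin,rescale Calibration options ([calibrate_to_ems()]).
#' @param pos_threshold,neg_threshold Label thresholds ([construct_labels()]).
#' @param num_trees Trees per forest.
#' @param seed Integer seed.
#' @return Object of class `ems_model`: `classifier`, `selected_features`,
#'   `calibration`, `holdout_chrom`, `feature_importances` (normalized MDI),
#'   `feature_class`, `seed`.
#' @export
train_ems <- function(pairs, features, holdout_chrom, k_features = 152,
                      base_rate = NULL, search_budget = 5, calib_frac = 0.3,
                      n_bins = 20, min_bin = 50, rescale = TRUE,
                      pos_threshold = 0.9, neg_threshold = 1e-4,
                      num_trees = 300, seed = 1) {
  pairs <- data.table::as.data.table(pairs)
  fc <- attr(features, "feature_class")
  labeled_all <- construct_labels(pairs, pos_threshold, neg_threshold)
  if (is.null(base_rate))
    base_rate <- max(mean(labeled_all$label == "positive"), 1e-6)
  split <- loco_split(cbind(labeled_all, .row = seq_len(nrow(pairs))),
                      holdout_chrom)
  tr <- split$train[label != "unlabeled"]
  if (nrow(tr) == 0 || length(unique(tr$label)) < 2)
    stop_invalid("training partition lacks labeled pairs of both classes")
  # internal calibration holdout, stratified so both classes are present;
  # with very few labeled pairs of one class, calibrate in-sample instead
  pos_all <- which(tr$label == "positive")
  neg_all <- which(tr$label == "negative")
  if (length(pos_all) < 4 || length(neg_all) < 4) {
    cal_idx <- seq_len(nrow(tr))
    fit_rows <- seq_len(nrow(tr))
  } else {
    cal_idx <- with_seed(derive_seed(seed, 3L), {
      c(sample(pos_all, max(1L, round(calib_frac * length(pos_all)))),
        sample(neg_all, max(1L, round(calib_frac * length(neg_all)))))
    })
    fit_rows <- setdiff(seq_len(nrow(tr)), cal_idx)
  }
  fit_tr <- tr[fit_rows]
  # class balance: all positives + equal-size random negative sample
  pos_i <- which(fit_tr$label == "positive")
  neg_i <- which(fit_tr$label == "negative")
  if (!length(pos_i) || !length(neg_i))
    stop_invalid("balanced training sample needs both classes")
  neg_take <- with_seed(derive_seed(seed, 4L),
                        sample(neg_i, min(length(neg_i), length(pos_i))))
  bal <- sort(c(pos_i, neg_take))
  Xfit <- features[fit_tr$.row[bal], , drop = FALSE]
  yfit <- fit_tr$label[bal]
  sel <- select_features(Xfit, yfit, k = min(k_features, ncol(features)),
                         seed = derive_seed(seed, 5L))
  clf <- tune_and_train(Xfit[, sel, with = FALSE], yfit,
                        search_budget = search_budget,
                        num_trees = num_trees, seed = derive_seed(seed, 6L))
  cal_tr <- tr[cal_idx]
  raw_cal <- raw_scores(clf, features[cal_tr$.row, sel, with = FALSE])
  calibration <- calibrate_to_ems(raw_cal, cal_tr$label, base_rate,
                                  n_bins = n_bins, min_bin = min_bin,
                                  rescale = rescale)
  imp <- clf$forest$variable.importance
  imp <- imp / sum(imp)
  structure(list(classifier = clf, selected_features = sel,
                 calibration = calibration, holdout_chrom = holdout_chrom,
                 feature_importances = imp,
                 feature_class = fc[sel], base_rate = base_rate,
                 seed = seed),
            class = "ems_model")
}

#' @export
print.ems_model <- function(x, ...) {
  cat(sprintf("ems_model: %d features, holdout = %s\n",
              length(x$selected_features), x$holdout_chrom))
  cat(sprintf("  base rate pi = %.4g, training prevalence pi_t = %.4g\n",
              x$calibration$base_rate, x$calibration$train_rate))
  invisible(x)
}

#' Score variant-gene pairs with a trained EMS model
#'
#' Maps raw forest probabilities through the calibration table. With
#' `fixed_tss_bp` set, the TSS-distance feature is overridden to that
#' constant before scoring (episomal-assay mode, where the native genomic
#' distance is meaningless).
#'
#' @param model An `ems_model`.
#' @param features Feature matrix containing all selected features.
#' @param fixed_tss_bp Optional constant TSS distance in bp.
#' @param distance_feature Name of the distance column (default
#'   `"tss_distance"`).
#' @return Numeric EMS per row of `features`.
#' @export
score_pairs <- function(model, features, fixed_tss_bp = NULL,
                        distance_feature = "tss_distance") {
  stopifnot(inherits(model, "ems_model"))
  missing <- setdiff(model$selected_features, names(features))
  if (length(missing))
    stop_invalid("missing feature column(s): %s",
                 paste(missing, collapse = ", "))
  X <- data.table::as.data.table(features)[, model$selected_features,
                                           with = FALSE]
  if (!is.null(fixed_tss_bp) && distance_feature %in% names(X))
    X[[distance_feature]] <- rep(as.numeric(fixed_tss_bp), nrow(X))
  apply_calibration(model$calibration, raw_scores(model$classifier, X))
}

#' Feature-importance report by category
#'
#' Normalized mean-decrease-of-impurity importances per feature and summed
#' per category. Default categories come from the model's feature classes,
#' with binary features split into `baseline-binary` / `histone-binary` by
#' name prefix (`histone*` vs other binary features) and continuous scores
#' reported as `continuous-scores`.
#'
#' @param model A trained `ems_model`.
#' @param categories Optional named character vector feature -> category,
#'   overriding the default mapping.
#' @return List with `per_feature` (named, sums to 1) and `per_category`
#'   (named, sums to 1).
#' @export
feature_importance_report <- function(model, categories = NULL) {
  if (!inherits(model, "ems_model") || is.null(model$feature_importances))
    stop_invalid("trained ems_model required")
  imp <- model$feature_importances
  imp <- imp / sum(imp)
  if (is.null(categories)) {
    fc <- model$feature_class
    if (is.null(fc)) fc <- stats::setNames(rep("continuous", length(imp)),
                                           names(imp))
    categories <- vapply(names(imp), function(nm) {
      cls <- fc[[nm]]
      if (is.null(cls) || is.na(cls)) cls <- "continuous"
      switch(cls,
             distance = "distance",
             binary = if (grepl("^histone", nm)) "histone-binary"
                      else "baseline-binary",
             "continuous-scores")
    }, character(1))
  }
  per_cat <- tapply(imp, categories[names(imp)], sum)
  list(per_feature = imp, per_category = per_cat / sum(per_cat))
}

#' Persist an EMS model to a directory
#'
#' Writes the calibration table (TSV), metadata (JSON: seed, holdout,
#' selected features, base rate) and the classifier object (RDS).
#'
#' @param model An `ems_model`.
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
save_ems_model <- function(model, dir) {
  stopifnot(inherits(model, "ems_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cal <- model$calibration
  write_tsv(data.table::data.table(
    bin_lower = head(cal$bin_edges, -1), bin_upper = tail(cal$bin_edges, -1),
    n = cal$n, pos_fraction = cal$pos_fraction, ems_value = cal$ems_value
  ), file.path(dir, "calibration.tsv"))
  jsonlite::write_json(list(
    seed = model$seed, holdout_chrom = model$holdout_chrom,
    selected_features = model$selected_features,
    base_rate = cal$base_rate, train_rate = cal$train_rate,
    rescale = cal$rescale
  ), file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' Load a persisted EMS model
#'
#' @param dir Directory written by [save_ems_model()].
#' @return The `ems_model`.
#' @export
load_ems_model <- function(dir) {
  f <- file.path(dir, "model.rds")
  if (!file.exists(f)) stop_invalid("no model.rds under %s", dir)
  readRDS(f)
}
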