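# Sum-of-single-effects fine-mapping and functionally informed reweighting.
#
# The phenotype model is y = X b + e with b = sum_{l=1}^{L} b_l and each b_l
# having exactly one nonzero entry. The fitter is iterative Bayesian stepwise
# selection (IBSS): each sweep refits every single effect against the
# residual of the others, yielding per-effect posterior probability vectors
# alpha_l over variants. Reweighting multiplies a pure effect's alpha_l by
# per-variant prior weights (EMS) and renormalizes.

#' Fit a sum-of-single-effects regression by IBSS
#'
#' Columns of `X` are standardized and `y` centered internally. Each single
#' effect is refit in turn against the residual of all other effects; the
#' per-effect prior variance is chosen by marginal likelihood on a fixed grid
#' (fractions of `var(y)`), and the residual variance is re-estimated after
#' every sweep unless `estimate_residual = FALSE`. Convergence is declared
#' when the evidence lower bound changes by less than `tol`.
#'
#' @param X Genotype dosage matrix, n individuals x m variants.
#' @param y Phenotype vector, length n.
#' @param L Number of single effects.
#' @param coverage Credible-set coverage (default 0.95).
#' @param prior_variance Fixed prior effect variance; `NULL` (default)
#'   estimates it per effect on `prior_grid`.
#' @param prior_grid Grid of prior variances as fractions of `var(y)`.
#' @param residual_variance Starting residual variance (default `var(y)`).
#' @param estimate_residual Re-estimate the residual variance each sweep.
#' @param tol ELBO convergence tolerance.
#' @param max_iter Maximum number of sweeps; hitting it flags
#'   `converged = FALSE` rather than raising an error.
#' @param variant_ids Variant names (default `colnames(X)` or `v1..vm`).
#' @param seed Unused by the deterministic fitter; accepted for interface
#'   uniformity.
#' @return Object of class `ibss_fit`: `alpha` (L x m, rows sum to 1), `mu`
#'   and `mu2` (posterior first/second moments), `pip`, `sets` (credible sets
#'   with purity, see [credible_set_95()] / [purity()]), `sigma2`, `elbo`
#'   trace, `niter`, `converged`, `corr` (sample variant correlation matrix),
#'   `variant_ids`.
#' @export
ibss_fit <- function(X, y, L = 10, coverage = 0.95, prior_variance = NULL,
                     prior_grid = c(0, 1e-4, 1e-3, 0.005, 0.01, 0.05, 0.1,
                                    0.2, 0.4, 0.8, 1),
                     residual_variance = NULL, estimate_residual = TRUE,
                     tol = 1e-6, max_iter = 200, variant_ids = NULL,
                     seed = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); m <- ncol(X)
  if (n < 10) stop_invalid("need at least 10 individuals, got %d", n)
  if (length(y) != n) stop_invalid("length(y) != nrow(X)")
  if (sd(y) == 0) stop_invalid("constant phenotype")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) stop_invalid("constant genotype column(s): %s",
                                  paste(which(sds == 0), collapse = ","))
  if (is.null(variant_ids)) {
    variant_ids <- colnames(X)
    if (is.null(variant_ids)) variant_ids <- sprintf("v%d", seq_len(m))
  }
  L <- min(L, m)

  Xs <- scale(X)
  yc <- y - mean(y)
  d <- rep(n - 1, m)                       # colSums(Xs^2) after standardizing
  vy <- var(y)
  sigma2 <- if (is.null(residual_variance)) vy else
    as.numeric(residual_variance)
  Vgrid <- if (is.null(prior_variance)) vy * prior_grid else
    as.numeric(prior_variance)

  alpha <- matrix(1 / m, L, m)
  mu1 <- matrix(0, L, m)
  mu2 <- matrix(0, L, m)
  V_l <- rep(Vgrid[1], L)
  Xb_l <- matrix(0, n, L)                  # per-effect fitted values
  Xb <- rowSums(Xb_l)
  elbo <- -Inf
  elbo_trace <- numeric(0)
  converged <- FALSE

  ser_lbf <- function(Xty, s2, V) {
    if (V == 0) return(rep(0, m))  # null effect: flat evidence
    0.5 * log(s2 / (s2 + V)) + 0.5 * (Xty / d)^2 / s2 * V / (V + s2)
  }

  for (it in seq_len(max_iter)) {
    kl <- numeric(L)
    for (l in seq_len(L)) {
      r <- yc - Xb + Xb_l[, l]
      Xty <- as.numeric(crossprod(Xs, r))
      s2 <- sigma2 / d
      if (is.null(prior_variance)) {
        # per-effect prior variance by marginal likelihood on the grid
        best <- -Inf
        for (V in Vgrid) {
          lbf <- ser_lbf(Xty, s2, V)
          mx <- max(lbf)
          tot <- mx + log(mean(exp(lbf - mx)))
          if (tot > best) { best <- tot; V_l[l] <- V }
        }
      }
      V <- V_l[l]
      lbf <- ser_lbf(Xty, s2, V)
      mx <- max(lbf)
      w <- exp(lbf - mx)
      alpha[l, ] <- w / sum(w)
      lbf_model <- mx + log(mean(w))
      pv <- if (V == 0) rep(0, m) else 1 / (1 / V + d / sigma2)
      m1 <- pv * Xty / sigma2
      mu1[l, ] <- m1
      mu2[l, ] <- pv + m1^2
      b_bar <- alpha[l, ] * m1
      b2_bar <- alpha[l, ] * mu2[l, ]
      Xb_l[, l] <- as.numeric(Xs %*% b_bar)
      Xb <- rowSums(Xb_l)
      # KL(q_l || prior) = -log BF + E_q[residual terms], per single effect
      kl[l] <- -lbf_model +
        (2 * sum(r * Xb_l[, l]) - sum(d * b2_bar)) / (2 * sigma2)
    }
    erss <- sum((yc - Xb)^2) - sum(Xb_l^2) +
      sum(d * colSums(alpha * mu2))
    new_elbo <- -n / 2 * log(2 * pi * sigma2) - erss / (2 * sigma2) - sum(kl)
    elbo_trace <- c(elbo_trace, new_elbo)
    if (estimate_residual) sigma2 <- max(erss / n, 1e-12)
    if (abs(new_elbo - elbo) < tol) { converged <- TRUE; elbo <- new_elbo; break }
    elbo <- new_elbo
  }

  dimnames(alpha) <- list(NULL, variant_ids)
  corr <- cor(Xs)
  dimnames(corr) <- list(variant_ids, variant_ids)
  # effects whose prior variance shrank to zero carry no signal: they are
  # excluded from PIPs and form no credible set
  active <- V_l > 0
  sets <- lapply(which(active), function(l) {
    cs <- credible_set_95(alpha[l, ], coverage = coverage,
                          variant_ids = variant_ids)
    pur <- purity(cs$members, corr)
    list(effect_index = l, members = cs$members,
         coverage = coverage, mass = cs$mass,
         min_abs_corr = pur$min_abs_corr, pure = pur$pure)
  })
  pure <- rep(FALSE, L)
  for (s in sets) pure[s$effect_index] <- s$pure
  pip <- if (any(active)) compute_pip(alpha, only_effects = which(active))
         else stats::setNames(rep(0, m), variant_ids)

  structure(list(
    alpha = alpha, mu = mu1, mu2 = mu2,
    pip = pip, active = active, pure = pure,
    sets = sets, sigma2 = sigma2, prior_variance = V_l,
    elbo = elbo_trace, niter = length(elbo_trace), converged = converged,
    corr = corr, variant_ids = variant_ids, coverage = coverage
  ), class = "ibss_fit")
}

#' @export
print.ibss_fit <- function(x, ...) {
  cat(sprintf("ibss_fit: %d effects x %d variants, %d iterations (%s)\n",
              nrow(x$alpha), ncol(x$alpha), x$niter,
              if (x$converged) "converged" else "NOT converged"))
  pure <- vapply(x$sets, `[[`, logical(1), "pure")
  cat(sprintf("  pure %d%% credible sets: %d of %d\n",
              round(100 * x$coverage), sum(pure), length(pure)))
  invisible(x)
}

#' Posterior inclusion probabilities from single-effect posteriors
#'
#' `PIP(v) = 1 - prod_l (1 - alpha_l(v))` over the retained effects.
#'
#' @param alphas An `ibss_fit` or an L x m matrix with rows summing to 1.
#' @param only_effects Optional subset of effect indices to retain.
#' @return Named numeric vector of PIPs in `[0, 1]`.
#' @export
compute_pip <- function(alphas, only_effects = NULL) {
  A <- if (inherits(alphas, "ibss_fit")) alphas$alpha else as.matrix(alphas)
  if (!is.null(only_effects)) A <- A[only_effects, , drop = FALSE]
  pip <- 1 - apply(1 - A, 2, prod)
  pmin(pmax(pip, 0), 1)
}

#' 95% credible set of one single effect
#'
#' The smallest set of variants, taken in order of descending posterior
#' probability (ties broken by ascending variant id), whose cumulative mass
#' reaches `coverage`.
#'
#' @param alpha_row Probability vector over variants.
#' @param coverage Coverage in `(0, 1]`.
#' @param variant_ids Variant names (default names of `alpha_row` or `v1..`).
#' @return List with `members` (variant ids in inclusion order) and `mass`
#'   (their cumulative posterior mass).
#' @export
credible_set_95 <- function(alpha_row, coverage = 0.95, variant_ids = NULL) {
  if (coverage <= 0 || coverage > 1)
    stop_invalid("coverage must lie in (0, 1], got %s", format(coverage))
  a <- as.numeric(alpha_row)
  if (is.null(variant_ids)) {
    variant_ids <- names(alpha_row)
    if (is.null(variant_ids)) variant_ids <- sprintf("v%d", seq_along(a))
  }
  ord <- order(-a, variant_ids)
  cum <- cumsum(a[ord])
  k <- which(cum >= coverage - 1e-12)[1]
  if (is.na(k)) k <- length(a)
  list(members = variant_ids[ord[seq_len(k)]], mass = cum[k])
}

#' Purity of a credible set
#'
#' Minimum absolute pairwise correlation among member variants; a set is pure
#' iff this minimum is at least 0.5. Singletons are pure with purity 1.
#'
#' @param members Variant ids in the set.
#' @param corr Variant correlation matrix with dimnames covering `members`.
#' @param threshold Purity threshold (default 0.5).
#' @return List with `min_abs_corr` and logical `pure`.
#' @export
purity <- function(members, corr, threshold = 0.5) {
  if (length(members) == 1L) return(list(min_abs_corr = 1, pure = TRUE))
  missing <- setdiff(members, rownames(corr))
  if (length(missing))
    stop_invalid("variants absent from correlation source: %s",
                 paste(missing, collapse = ", "))
  sub <- abs(corr[members, members])
  mac <- min(sub[upper.tri(sub)])
  list(min_abs_corr = mac, pure = mac >= threshold)
}

#' Reweight single-effect posteriors by per-variant prior weights
#'
#' For each effect whose credible set is pure, the posterior vector is
#' multiplied elementwise by the weights and renormalized to sum to 1:
#' `alpha_hat_l(v) = w_v alpha_l(v) / sum_u w_u alpha_l(u)`. Effects with an
#' impure credible set are returned untouched. A pure row whose weighted mass
#' is zero is left unchanged and flagged degenerate.
#'
#' @param alphas An `ibss_fit` or L x m matrix.
#' @param weights Nonnegative per-variant weights (EMS), length m; names are
#'   matched to variant ids when present.
#' @param pure Logical per-effect purity flags; defaults to the fit's own
#'   credible-set purity when `alphas` is an `ibss_fit`.
#' @return List with `alpha` (reweighted matrix) and `degenerate` (logical
#'   per effect).
#' @export
reweight_alpha <- function(alphas, weights, pure = NULL) {
  A <- if (inherits(alphas, "ibss_fit")) alphas$alpha else as.matrix(alphas)
  if (is.null(pure)) {
    if (!inherits(alphas, "ibss_fit"))
      stop_invalid("pure flags required when alphas is a plain matrix")
    pure <- alphas$pure
  }
  w <- as.numeric(weights)
  if (!is.null(names(weights)) && !is.null(colnames(A)))
    w <- as.numeric(weights[colnames(A)])
  if (length(w) != ncol(A)) stop_invalid("weights length != number of variants")
  if (anyNA(w) || any(w < 0)) stop_invalid("weights must be nonnegative")
  if (length(pure) != nrow(A)) stop_invalid("pure flags length != L")
  degenerate <- logical(nrow(A))
  out <- A
  for (l in which(pure)) {
    wa <- w * A[l, ]
    tot <- sum(wa)
    if (tot <= 0) { degenerate[l] <- TRUE; next }
    out[l, ] <- wa / tot
  }
  list(alpha = out, degenerate = degenerate)
}

#' Functionally informed fine-mapping with EMS weights
#'
#' Runs [ibss_fit()] once under the uniform prior, reweights the pure
#' effects' posteriors by the supplied EMS weights ([reweight_alpha()]), and
#' reports both posteriors side by side. Credible sets under the EMS prior
#' are recomputed from the reweighted posteriors; reweighting eligibility is
#' decided by the uniform-prior purity.
#'
#' @param genotypes n x m dosage matrix.
#' @param phenotype Length-n phenotype.
#' @param ems_weights Per-variant EMS, named by variant id or aligned to the
#'   genotype columns. Variants without a score receive `default_weight`.
#' @param L Number of single effects.
#' @param coverage Credible-set coverage.
#' @param default_weight Weight for unscored variants; default is the 5th
#'   percentile of the supplied weights.
#' @param max_prior_ratio Optional cap: weights are floored so that
#'   `max(w)/min(w) <= max_prior_ratio` (see [adjust_prior_ratio()]);
#'   `NULL` (default) leaves weights as given.
#' @param ... Further arguments to [ibss_fit()].
#' @return Object of class `fifm_result`: `fit` (the uniform-prior
#'   `ibss_fit`), `pip` (`data.table` with `variant_id`, `pip_unif`,
#'   `pip_ems`), `alpha_ems`, `cs_unif`, `cs_ems`, `weights`, `prior_kind`.
#' @export
functionally_informed_pips <- function(genotypes, phenotype, ems_weights,
                                       L = 10, coverage = 0.95,
                                       default_weight = NULL,
                                       max_prior_ratio = NULL, ...) {
  fit <- ibss_fit(genotypes, phenotype, L = L, coverage = coverage, ...)
  ids <- fit$variant_ids
  if (!is.null(names(ems_weights))) {
    w <- ems_weights[ids]
    if (is.null(default_weight))
      default_weight <- as.numeric(quantile(ems_weights, 0.05, na.rm = TRUE))
    w[is.na(w)] <- default_weight
    names(w) <- ids
  } else {
    if (length(ems_weights) != length(ids))
      stop_invalid("unnamed ems_weights must align with genotype columns")
    w <- as.numeric(ems_weights)
  }
  prior_kind <- "ems"
  if (!is.null(max_prior_ratio)) {
    w <- adjust_prior_ratio(w, max_ratio = max_prior_ratio)
    prior_kind <- "ems-ratio-adjusted"
  }
  rw <- reweight_alpha(fit, w)
  cs_ems <- lapply(which(fit$active), function(l) {
    cs <- credible_set_95(rw$alpha[l, ], coverage = coverage,
                          variant_ids = ids)
    pur <- purity(cs$members, fit$corr)
    list(effect_index = l, members = cs$members, coverage = coverage,
         mass = cs$mass, min_abs_corr = pur$min_abs_corr, pure = pur$pure)
  })
  pip_ems <- if (any(fit$active)) {
    as.numeric(compute_pip(rw$alpha, only_effects = which(fit$active)))
  } else rep(0, length(ids))
  pip <- data.table::data.table(
    variant_id = ids,
    pip_unif = as.numeric(fit$pip),
    pip_ems = pip_ems
  )
  structure(list(fit = fit, pip = pip, alpha_ems = rw$alpha,
                 degenerate = rw$degenerate, cs_unif = fit$sets,
                 cs_ems = cs_ems, weights = stats::setNames(w, ids),
                 prior_kind = prior_kind),
            class = "fifm_result")
}

#' @export
print.fifm_result <- function(x, ...) {
  cat(sprintf("fifm_result: %d variants, prior = %s\n",
              nrow(x$pip), x$prior_kind))
  cat(sprintf("  PIP > 0.9: uniform %d, EMS %d\n",
              sum(x$pip$pip_unif > 0.9), sum(x$pip$pip_ems > 0.9)))
  invisible(x)
}
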