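# Synthetic data with the statistical structure the method assumes:
# LD-blocked genotypes, causal effects near the TSS, binary annotations
# enriched in causal pairs, continuous scores correlated with causal status,
# expression from causal genotypes plus noise, and a complex trait sharing
# causal variants with a subset of genes.

#' Simulate LD-blocked genotype dosages
#'
#' Draws hard-call dosages (0/1/2) for `n` individuals at `sum(block_sizes)`
#' variants via a Gaussian copula: two latent haplotypes per individual share a
#' per-block factor with loading `sqrt(rho)`, and each latent value is
#' thresholded at the variant's allele-frequency quantile (Hardy-Weinberg).
#' Variants in different blocks are independent; within a block the latent
#' correlation is `rho` (the dosage correlation is slightly attenuated by
#' thresholding).
#'
#' @param n Number of individuals (>= 2).
#' @param block_sizes Integer vector of LD-block sizes; the locus has
#'   `sum(block_sizes)` variants.
#' @param rho Within-block latent correlation, in `[0, 1)`.
#' @param maf_range Minor-allele-frequency interval in `(0, 0.5]` from which
#'   per-variant MAFs are drawn uniformly.
#' @param seed Integer seed.
#' @return An object of class `synthetic_locus`: a list with `genotypes`
#'   (n x m matrix), `maf`, and `ld_structure` (block sizes and rho).
#'   `expression`, `causal_index_set` and `effect_sizes` are filled by
#'   [simulate_expression()].
#' @export
simulate_ld_genotypes <- function(n, block_sizes, rho,
                                  maf_range = c(0.05, 0.5), seed = 1) {
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
    stop_invalid("rho must lie in [0, 1), got %s", format(rho))
  if (n < 2) stop_invalid("n must be >= 2, got %d", n)
  if (any(block_sizes < 1)) stop_invalid("block sizes must be positive")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop_invalid("maf_range must be an interval in (0, 0.5]")
  m <- sum(block_sizes)
  with_seed(seed, {
    # one MAF per block: variants in strong LD share allele frequencies,
    # and equal thresholds keep the dosage correlation close to rho
    block_id <- rep(seq_along(block_sizes), block_sizes)
    maf <- runif(length(block_sizes), maf_range[1], maf_range[2])[block_id]
    G <- matrix(0L, n, m)
    for (b in seq_along(block_sizes)) {
      idx <- which(block_id == b)
      k <- length(idx)
      for (hap in 1:2) {
        common <- rnorm(n)
        Z <- sqrt(rho) * matrix(common, n, k) +
          sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
        thr <- qnorm(maf[idx])
        G[, idx] <- G[, idx] + (Z < matrix(thr, n, k, byrow = TRUE))
      }
    }
    # rare monomorphic columns get an independent redraw so every column has
    # finite, nonzero variance
    for (tries in 1:50) {
      mono <- which(apply(G, 2, var) == 0)
      if (!length(mono)) break
      for (j in mono) {
        G[, j] <- rbinom(n, 1L, maf[j]) + rbinom(n, 1L, maf[j])
      }
    }
    structure(list(
      genotypes = G,
      maf = maf,
      expression = NULL,
      causal_index_set = integer(0),
      effect_sizes = numeric(0),
      ld_structure = list(block_sizes = as.integer(block_sizes), rho = rho)
    ), class = "synthetic_locus")
  })
}

#' Fill a synthetic locus with expression
#'
#' Expression is `standardized genotypes \%*\% b + Gaussian noise` where `b`
#' has `n_causal` nonzero entries (chosen uniformly unless `causal_index` is
#' given), each drawn from `Normal(0, beta_sd^2)` unless `effects` is given.
#'
#' @param locus A `synthetic_locus` from [simulate_ld_genotypes()].
#' @param n_causal Number of causal variants (`0` gives pure noise).
#' @param beta_sd Standard deviation of causal effect sizes (per standardized
#'   genotype column).
#' @param noise_sd Residual standard deviation (> 0).
#' @param seed Integer seed.
#' @param causal_index Optional explicit causal indices (overrides `n_causal`).
#' @param effects Optional explicit effect sizes aligned to `causal_index`.
#' @return The locus with `expression`, `causal_index_set` and `effect_sizes`
#'   filled.
#' @export
simulate_expression <- function(locus, n_causal, beta_sd = 0.5, noise_sd = 1,
                                seed = 1, causal_index = NULL, effects = NULL) {
  stopifnot(inherits(locus, "synthetic_locus"))
  if (noise_sd <= 0) stop_invalid("noise_sd must be > 0")
  m <- ncol(locus$genotypes)
  n <- nrow(locus$genotypes)
  if (!is.null(causal_index)) n_causal <- length(causal_index)
  if (n_causal > m) stop_invalid("n_causal (%d) exceeds m (%d)", n_causal, m)
  with_seed(seed, {
    idx <- if (is.null(causal_index)) sort(sample.int(m, n_causal)) else
      sort(as.integer(causal_index))
    b <- if (is.null(effects)) rnorm(length(idx), 0, beta_sd) else
      as.numeric(effects)
    Xs <- scale(locus$genotypes)
    y <- rnorm(n, 0, noise_sd)
    if (length(idx)) y <- y + as.numeric(Xs[, idx, drop = FALSE] %*% b)
    locus$expression <- as.numeric(y)
    locus$causal_index_set <- idx
    locus$effect_sizes <- b
    locus
  })
}

#' Simulate a feature matrix for variant-gene pairs
#'
#' Emulates the qualitative structure of real functional annotations: causal
#' pairs sit nearer the TSS (two-sided exponential with scale `tss_decay_bp`;
#' non-causal pairs uniform over the +/-1 Mb cis window), binary peak
#' annotations fire `enrich_binary`-fold more often in causal pairs, and
#' continuous scores equal the standardized causal indicator times
#' `score_informativeness` plus standard normal noise.
#'
#' @param truth Logical causal flag per pair.
#' @param tss_decay_bp Exponential scale (bp) of causal TSS distances.
#' @param enrich_binary Fold enrichment (>= 1) of binary features in causal
#'   pairs.
#' @param score_informativeness Signal size (>= 0) of continuous scores.
#' @param n_binary,n_continuous Number of binary / continuous feature columns.
#' @param binary_base_rate Firing rate of binary features in non-causal pairs.
#' @param cis_halfwidth Half-width (bp) of the cis window.
#' @param seed Integer seed.
#' @return A `data.table` with columns `tss_distance`, binary features (named
#'   `baseline_*` / `histone_*`) and continuous features (`dl_score_*`), with a
#'   `feature_class` attribute naming each column's class
#'   (distance/binary/continuous).
#' @export
simulate_features <- function(truth, tss_decay_bp = 10000, enrich_binary = 10,
                              score_informativeness = 1, n_binary = 4,
                              n_continuous = 3, binary_base_rate = 0.02,
                              cis_halfwidth = 1e6, seed = 1) {
  if (enrich_binary < 1) stop_invalid("enrich_binary must be >= 1")
  if (score_informativeness < 0)
    stop_invalid("score_informativeness must be >= 0")
  truth <- as.logical(truth)
  n <- length(truth)
  with_seed(seed, {
    d <- numeric(n)
    nc <- sum(truth)
    d[truth] <- round(rexp(nc, 1 / tss_decay_bp) * sample(c(-1, 1), nc, TRUE))
    d[truth] <- pmax(pmin(d[truth], cis_halfwidth), -cis_halfwidth)
    d[!truth] <- round(runif(n - nc, -cis_halfwidth, cis_halfwidth))
    out <- data.table::data.table(tss_distance = d)
    p1 <- min(1, enrich_binary * binary_base_rate)
    bnames <- c(
      sprintf("baseline_peak_%d", seq_len(ceiling(n_binary / 2))),
      sprintf("histone_peak_%d", seq_len(floor(n_binary / 2)))
    )[seq_len(n_binary)]
    for (nm in bnames) {
      out[[nm]] <- rbinom(n, 1L, ifelse(truth, p1, binary_base_rate))
    }
    z <- if (nc > 0 && nc < n) as.numeric(scale(truth)) else rep(0, n)
    snames <- sprintf("dl_score_%d", seq_len(n_continuous))
    for (nm in snames) {
      out[[nm]] <- z * score_informativeness + rnorm(n)
    }
    data.table::setattr(out, "feature_class", stats::setNames(
      c("distance", rep("binary", n_binary), rep("continuous", n_continuous)),
      c("tss_distance", bnames, snames)
    ))
    out[]
  })
}

#' Simulate a full variant-gene catalog
#'
#' Builds `n_genes` independent cis loci (LD-blocked genotypes, expression with
#' causal variants at rate `causal_frac`), the corresponding variant-gene pair
#' table and feature matrix, and optionally a complex trait whose causal
#' variants are shared with a subset of genes. When `finemap = TRUE`
#' (default), each locus is fine-mapped with [ibss_fit()] under the uniform
#' prior to fill `pip_a`/`pip_b` (the bundled fitter stands in for both
#' fine-mapping methods) and, for trait genes, per-variant trait PIPs.
#'
#' @param n_genes Number of genes.
#' @param m_per_gene Variants per gene.
#' @param block_size LD block size (must divide `m_per_gene`).
#' @param rho Within-block correlation.
#' @param n_individuals Cohort size.
#' @param causal_frac Causal fraction: with `causal_mode = "variant"` the
#'   per-variant probability of being causal; with `causal_mode = "block"`
#'   the fraction of LD blocks carrying one causal variant (rounded, at
#'   least one block per gene).
#' @param causal_mode `"variant"` (Bernoulli per variant) or `"block"`
#'   (a fixed fraction of blocks, one causal variant each, mirroring the
#'   small number of independent signals at real eQTL loci).
#' @param beta_sd,noise_sd Effect / noise scales (see [simulate_expression()]).
#' @param maf_range MAF interval.
#' @param n_chrom Chromosomes genes are distributed over (round-robin).
#' @param tissue Tissue label for the pairs.
#' @param trait_share_frac Fraction of genes whose causal variants also affect
#'   the simulated trait (0 disables the trait).
#' @param finemap Run the bundled fine-mapper to fill PIP columns.
#' @param L Number of single effects per locus when fine-mapping.
#' @param feature_args List of overrides passed to [simulate_features()].
#' @param seed Integer seed; all stage seeds derive from it.
#' @return Object of class `synthetic_catalog`: list with `pairs`, `features`,
#'   `truth`, `loci`, `trait_pips` (or NULL), and the generation parameters.
#' @export
simulate_catalog <- function(n_genes = 20, m_per_gene = 50, block_size = 10,
                             rho = 0.9, n_individuals = 400,
                             causal_frac = 0.1, causal_mode = c("variant",
                                                                "block"),
                             beta_sd = 0.3, noise_sd = 1,
                             maf_range = c(0.05, 0.5), n_chrom = 3,
                             tissue = "Whole_Blood", trait_share_frac = 0,
                             finemap = TRUE, L = 10,
                             feature_args = list(), seed = 1) {
  if (m_per_gene %% block_size != 0)
    stop_invalid("block_size must divide m_per_gene")
  if (causal_frac <= 0 || causal_frac >= 1)
    stop_invalid("causal_frac must lie strictly in (0, 1)")
  causal_mode <- match.arg(causal_mode)
  n_blocks <- m_per_gene / block_size
  loci <- vector("list", n_genes)
  truth <- logical(0)
  pair_list <- vector("list", n_genes)
  gene_ids <- sprintf("GENE%03d", seq_len(n_genes))
  chroms <- sprintf("chr%d", ((seq_len(n_genes) - 1L) %% n_chrom) + 1L)
  tss <- 1e6 + (seq_len(n_genes) - 1L) %/% n_chrom * 3e6

  for (g in seq_len(n_genes)) {
    sg <- derive_seed(seed, 100L + g)
    locus <- simulate_ld_genotypes(n_individuals,
                                   rep(block_size, n_blocks), rho,
                                   maf_range, seed = sg)
    causal <- with_seed(derive_seed(seed, 200L + g), {
      if (causal_mode == "variant") which(runif(m_per_gene) < causal_frac)
      else {
        blocks <- sample.int(n_blocks, max(1L, round(causal_frac * n_blocks)))
        sort(vapply(blocks, function(b)
          as.integer((b - 1L) * block_size) + sample.int(block_size, 1L),
          integer(1)))
      }
    })
    if (!length(causal))
      causal <- with_seed(derive_seed(seed, 300L + g),
                          sample.int(m_per_gene, 1L))
    locus <- simulate_expression(locus, length(causal), beta_sd, noise_sd,
                                 seed = derive_seed(seed, 400L + g),
                                 causal_index = causal)
    loci[[g]] <- locus
    truth <- c(truth, seq_len(m_per_gene) %in% causal)
  }

  fargs <- utils::modifyList(list(truth = truth,
                                  seed = derive_seed(seed, 500L)),
                             feature_args)
  features <- do.call(simulate_features, fargs)

  k <- 0L
  for (g in seq_len(n_genes)) {
    d <- features$tss_distance[k + seq_len(m_per_gene)]
    pos <- tss[g] + as.integer(d)
    pair_list[[g]] <- data.table::data.table(
      chrom = chroms[g], pos = pos,
      ref = "A", alt = "G",
      variant_id = variant_key(chroms[g], pos, "A", "G"),
      gene_id = gene_ids[g], tissue = tissue,
      tss_distance = as.integer(d),
      truth = truth[k + seq_len(m_per_gene)]
    )
    k <- k + m_per_gene
  }
  pairs <- data.table::rbindlist(pair_list)

  # keep variant ids unique within a gene (collisions possible at low density)
  pairs[, variant_id := ifelse(duplicated(variant_id),
                               paste0(variant_id, "_", seq_len(.N)),
                               variant_id), by = gene_id]

  trait_pips <- NULL
  trait_genes <- character(0)
  if (trait_share_frac > 0) {
    n_share <- max(1L, round(trait_share_frac * n_genes))
    share <- with_seed(derive_seed(seed, 600L),
                       sort(sample.int(n_genes, n_share)))
    trait_genes <- gene_ids[share]
    y_trait <- with_seed(derive_seed(seed, 601L),
                         rnorm(n_individuals, 0, noise_sd))
    for (g in share) {
      locus <- loci[[g]]
      b <- with_seed(derive_seed(seed, 602L + g),
                     rnorm(length(locus$causal_index_set), 0, beta_sd))
      Xs <- scale(locus$genotypes)
      y_trait <- y_trait +
        as.numeric(Xs[, locus$causal_index_set, drop = FALSE] %*% b)
    }
  }

  if (finemap) {
    pips <- numeric(nrow(pairs))
    tpips <- numeric(nrow(pairs))
    k <- 0L
    for (g in seq_len(n_genes)) {
      locus <- loci[[g]]
      ids <- pairs$variant_id[k + seq_len(m_per_gene)]
      fit <- ibss_fit(locus$genotypes, locus$expression, L = L,
                      seed = derive_seed(seed, 700L + g))
      pips[k + seq_len(m_per_gene)] <- fit$pip
      if (trait_share_frac > 0 && gene_ids[g] %in% trait_genes) {
        tfit <- ibss_fit(locus$genotypes, y_trait, L = L,
                         seed = derive_seed(seed, 800L + g))
        tpips[k + seq_len(m_per_gene)] <- tfit$pip
      }
      k <- k + m_per_gene
    }
    pairs[, pip_a := pips]
    pairs[, pip_b := pips]
    if (trait_share_frac > 0) {
      trait_pips <- data.table::data.table(variant_id = pairs$variant_id,
                                           gene_id = pairs$gene_id,
                                           trait_pip = tpips)
    }
  }

  structure(list(
    pairs = pairs, features = features, truth = truth, loci = loci,
    gene_ids = gene_ids, trait_pips = trait_pips, trait_genes = trait_genes,
    params = list(n_genes = n_genes, m_per_gene = m_per_gene,
                  block_size = block_size, rho = rho,
                  n_individuals = n_individuals, causal_frac = causal_frac,
                  beta_sd = beta_sd, noise_sd = noise_sd, seed = seed)
  ), class = "synthetic_catalog")
}

#' Simulate a TF-by-tissue TPM matrix
#'
#' A fraction of transcription factors are tissue-specific: one tissue's
#' expression is inflated `fold`-fold over a low baseline; the rest are flat.
#'
#' @param n_tf Number of transcription factors.
#' @param tissues Character vector of tissue names (>= 3).
#' @param specific_frac Fraction of TFs made tissue-specific.
#' @param base_tpm Baseline TPM level.
#' @param fold Fold inflation in the specific tissue.
#' @param seed Integer seed.
#' @return Numeric matrix (TF x tissue) with dimnames.
#' @export
simulate_tpm <- function(n_tf = 20, tissues = sprintf("tissue_%d", 1:10),
                         specific_frac = 0.5, base_tpm = 2, fold = 50,
                         seed = 1) {
  if (length(tissues) < 3) stop_invalid("need >= 3 tissues")
  with_seed(seed, {
    tpm <- matrix(base_tpm * exp(rnorm(n_tf * length(tissues), 0, 0.2)),
                  n_tf, length(tissues),
                  dimnames = list(sprintf("TF%03d", seq_len(n_tf)), tissues))
    spec <- sample.int(n_tf, round(specific_frac * n_tf))
    for (i in spec) {
      tpm[i, sample.int(length(tissues), 1L)] <- base_tpm * fold
    }
    tpm
  })
}

#' Write a synthetic catalog to disk
#'
#' Emits the pair table, feature matrix, per-gene genotype/expression TSVs and
#' a BED file (0-based half-open) per binary annotation.
#'
#' @param catalog A `synthetic_catalog`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_catalog <- function(catalog, dir) {
  stopifnot(inherits(catalog, "synthetic_catalog"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    pairs = file.path(dir, "pairs.tsv"),
    features = file.path(dir, "features.tsv")
  )
  write_tsv(catalog$pairs, files[["pairs"]])
  write_tsv(catalog$features, files[["features"]])
  fc <- attr(catalog$features, "feature_class")
  for (nm in names(fc)[fc == "binary"]) {
    hit <- catalog$features[[nm]] == 1L
    bed <- data.table::data.table(
      chrom = catalog$pairs$chrom[hit],
      start = catalog$pairs$pos[hit] - 1L,  # 1-based -> 0-based half-open
      end = catalog$pairs$pos[hit]
    )
    f <- file.path(dir, paste0(nm, ".bed"))
    data.table::fwrite(bed, f, sep = "\t", col.names = FALSE)
    files[nm] <- f
  }
  for (g in seq_along(catalog$loci)) {
    locus <- catalog$loci[[g]]
    gid <- catalog$gene_ids[g]
    gf <- file.path(dir, sprintf("genotypes_%s.tsv", gid))
    ids <- catalog$pairs$variant_id[catalog$pairs$gene_id == gid]
    G <- data.table::as.data.table(locus$genotypes)
    data.table::setnames(G, ids)
    write_tsv(G, gf)
    ef <- file.path(dir, sprintf("expression_%s.tsv", gid))
    write_tsv(data.table::data.table(expression = locus$expression), ef)
    files[paste0("genotypes_", gid)] <- gf
    files[paste0("expression_", gid)] <- ef
  }
  invisible(files)
}
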