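# Shared fixtures, built in code once per test run.

# A small catalog exercising every downstream stage (labels, training,
# scoring, coloc) at test scale.
shared_catalog <- simulate_catalog(
  n_genes = 12, m_per_gene = 40, block_size = 10, rho = 0.9,
  n_individuals = 300, causal_frac = 0.05, beta_sd = 0.4, noise_sd = 1,
  n_chrom = 3, trait_share_frac = 0.25, L = 5,
  feature_args = list(score_informativeness = 2), seed = 7
)

# One full recovery-benchmark replicate: simulate loci, fine-map under the
# uniform prior, train EMS leave-one-chromosome-out on PIP-derived labels,
# reweight, and tally recovery / FDR / pure credible-set sizes.
run_recovery_benchmark <- function(seed, n_genes = 300, m_per_gene = 200,
                                   block_size = 10, rho = 0.9,
                                   n_individuals = 400, causal_frac = 0.1,
                                   L = 10) {
  cat0 <- simulate_catalog(
    n_genes = n_genes, m_per_gene = m_per_gene, block_size = block_size,
    rho = rho, n_individuals = n_individuals, causal_frac = causal_frac,
    causal_mode = "block", beta_sd = 0.3, noise_sd = 1, n_chrom = 3,
    finemap = FALSE, feature_args = list(score_informativeness = 2),
    seed = seed
  )
  fits <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    locus <- cat0$loci[[g]]
    ids <- cat0$pairs$variant_id[cat0$pairs$gene_id == cat0$gene_ids[g]]
    G <- locus$genotypes
    colnames(G) <- ids
    fits[[g]] <- ibss_fit(G, locus$expression, L = L)
  }
  pip_unif <- unlist(lapply(fits, function(f) as.numeric(f$pip)))
  cat0$pairs[, pip_a := pip_unif]
  cat0$pairs[, pip_b := pip_unif]
  ems <- rep(NA_real_, nrow(cat0$pairs))
  for (ch in unique(cat0$pairs$chrom)) {
    model <- train_ems(cat0$pairs, cat0$features, holdout_chrom = ch,
                       search_budget = 2, num_trees = 200, n_bins = 20,
                       min_bin = 30, seed = seed)
    rows <- which(cat0$pairs$chrom == ch)
    ems[rows] <- score_pairs(model, cat0$features[rows])
  }
  pip_ems <- numeric(0)
  cs_unif_sizes <- integer(0)
  cs_ems_sizes <- integer(0)
  for (g in seq_len(n_genes)) {
    f <- fits[[g]]
    w <- ems[cat0$pairs$gene_id == cat0$gene_ids[g]]
    rw <- reweight_alpha(f, stats::setNames(w, f$variant_ids))
    pe <- if (any(f$active)) {
      as.numeric(compute_pip(rw$alpha, only_effects = which(f$active)))
    } else rep(0, m_per_gene)
    pip_ems <- c(pip_ems, pe)
    for (s in f$sets) {
      if (!s$pure) next
      cs_unif_sizes <- c(cs_unif_sizes, length(s$members))
      cs <- credible_set_95(rw$alpha[s$effect_index, ],
                            variant_ids = f$variant_ids)
      cs_ems_sizes <- c(cs_ems_sizes, length(cs$members))
    }
  }
  truth <- cat0$truth
  list(
    n_causal_unif = sum(pip_unif > 0.9 & truth),
    n_causal_ems = sum(pip_ems > 0.9 & truth),
    n_calls_ems = sum(pip_ems > 0.9),
    fdr_ems = sum(pip_ems > 0.9 & !truth) / max(1L, sum(pip_ems > 0.9)),
    median_cs_unif = median(cs_unif_sizes),
    median_cs_ems = median(cs_ems_sizes)
  )
}
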