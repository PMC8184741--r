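# Tissue-specific putative causal eQTLs (high posterior in exactly one
# tissue) and the tissue-matched transcription-factor feature enrichment
# test.

#' Classify a variant-gene pair as tissue-specific
#'
#' Assigned to tissue T iff its PIP exceeds `hi` in T and is below `lo` (or
#' missing) in every other tissue. At most one tissue can qualify.
#'
#' @param pips Named numeric vector of PIPs per tissue; `NA` = variant
#'   missing in that tissue (treated as low).
#' @param hi High-PIP threshold (default 0.9).
#' @param lo Low-PIP threshold for all other tissues (default 0.1).
#' @return The specific tissue name, or `NA_character_` if none.
#' @export
classify_tissue_specific <- function(pips, hi = 0.9, lo = 0.1) {
  if (length(pips) < 2) stop_invalid("need PIPs for at least 2 tissues")
  if (is.null(names(pips))) names(pips) <- sprintf("tissue_%d",
                                                   seq_along(pips))
  ok <- vapply(seq_along(pips), function(i) {
    !is.na(pips[i]) && pips[i] > hi &&
      all(is.na(pips[-i]) | pips[-i] < lo)
  }, logical(1))
  if (sum(ok) == 1L) names(pips)[ok] else NA_character_
}

#' Classify all pairs in a tissue-PIP profile table
#'
#' @param profile Table with `variant_id`, `gene_id`, `tissue`, `pip`.
#' @param hi,lo Thresholds (see [classify_tissue_specific()]).
#' @return `data.table` with `variant_id`, `gene_id`, `specific_tissue`
#'   (`NA` when none).
#' @export
classify_tissue_specific_all <- function(profile, hi = 0.9, lo = 0.1) {
  prof <- data.table::as.data.table(profile)
  prof[, .(specific_tissue = {
    v <- stats::setNames(pip, tissue)
    if (length(v) < 2) NA_character_
    else classify_tissue_specific(v, hi, lo)
  }), by = .(variant_id, gene_id)]
}

#' Tissue specificity of a transcription factor from TPM
#'
#' The TF is specific for the tissue with the unique maximum TPM if that
#' maximum exceeds the across-tissue mean by more than two (sample) standard
#' deviations. Control tissues are those with TPM below a tenth of the
#' specific tissue's; a call without any control tissue is dropped.
#'
#' @param tpm_row Named numeric vector of TPM per tissue (>= 3 tissues,
#'   nonnegative).
#' @return List of class `tf_tissue_call`: `specific_tissue` (or `NA`),
#'   `control_tissues` (character, possibly empty), `reason` when no call.
#' @export
tf_tissue_specificity <- function(tpm_row) {
  if (length(tpm_row) < 3) stop_invalid("need >= 3 tissues")
  if (any(tpm_row < 0)) stop_invalid("negative TPM")
  if (is.null(names(tpm_row))) names(tpm_row) <- sprintf("tissue_%d",
                                                         seq_along(tpm_row))
  mx <- max(tpm_row)
  top <- which(tpm_row == mx)
  none <- function(reason) structure(
    list(specific_tissue = NA_character_, control_tissues = character(0),
         reason = reason), class = "tf_tissue_call")
  if (length(top) > 1L) return(none("maximum not unique"))
  # the mean/sd include the candidate tissue itself
  if (!(mx > mean(tpm_row) + 2 * sd(tpm_row)))
    return(none("maximum within 2 sd of the mean"))
  controls <- names(tpm_row)[tpm_row < mx / 10]
  if (!length(controls)) return(none("no control tissues"))
  structure(list(specific_tissue = names(tpm_row)[top],
                 control_tissues = controls, reason = NA_character_),
            class = "tf_tissue_call")
}

#' Tissue-matched enrichment test for one TF feature
#'
#' Welch two-sample two-sided t test comparing the feature's average score in
#' tissue-specific putative causal eQTLs of the TF's specific tissue against
#' those of its control tissues, with Bonferroni significance at
#' `0.05 / n_features`.
#'
#' @param specific_scores Feature scores of eQTLs specific to the matched
#'   tissue (>= 2).
#' @param control_scores Feature scores of eQTLs specific to control tissues
#'   (>= 2).
#' @param n_features Number of features tested (Bonferroni divisor,
#'   default 42).
#' @param alpha Familywise level before correction (default 0.05).
#' @return List with `mean_difference` (specific - control), `t_statistic`,
#'   `p_value`, `significant`, `alpha_corrected`.
#' @export
tf_enrichment_test <- function(specific_scores, control_scores,
                               n_features = 42, alpha = 0.05) {
  if (length(specific_scores) < 2 || length(control_scores) < 2)
    stop_invalid("need >= 2 eQTLs per group")
  md <- mean(specific_scores) - mean(control_scores)
  if (sd(specific_scores) == 0 && sd(control_scores) == 0) {
    return(list(mean_difference = md, t_statistic = NA_real_,
                p_value = NA_real_, significant = FALSE,
                alpha_corrected = alpha / n_features))
  }
  tt <- stats::t.test(specific_scores, control_scores,
                      alternative = "two.sided", var.equal = FALSE)
  list(mean_difference = md,
       t_statistic = unname(tt$statistic),
       p_value = tt$p.value,
       significant = tt$p.value < alpha / n_features,
       alpha_corrected = alpha / n_features)
}

#' Filter tissue-specific eQTL pairs by proximity
#'
#' Pairs of tissue-specific putative causal eQTLs on the same gene in two
#' different tissues, lying within `max_distance` bp of each other. A plain
#' filter; no statistics attached.
#'
#' @param calls Table with `variant_id`, `gene_id`, `specific_tissue`, `pos`.
#' @param max_distance Maximum distance in bp (default 1e4).
#' @return `data.table` with one row per qualifying pair.
#' @export
tissue_specific_pairs <- function(calls, max_distance = 1e4) {
  x <- data.table::as.data.table(calls)[!is.na(specific_tissue)]
  out <- list()
  for (g in unique(x$gene_id)) {
    sub <- x[gene_id == g]
    if (nrow(sub) < 2) next
    cmb <- utils::combn(nrow(sub), 2)
    for (j in seq_len(ncol(cmb))) {
      i1 <- cmb[1, j]; i2 <- cmb[2, j]
      if (sub$specific_tissue[i1] != sub$specific_tissue[i2] &&
          abs(sub$pos[i1] - sub$pos[i2]) <= max_distance) {
        out[[length(out) + 1L]] <- data.table::data.table(
          gene_id = g,
          variant_1 = sub$variant_id[i1], tissue_1 = sub$specific_tissue[i1],
          variant_2 = sub$variant_id[i2], tissue_2 = sub$specific_tissue[i2],
          distance = abs(sub$pos[i1] - sub$pos[i2]))
      }
    }
  }
  if (!length(out)) return(data.table::data.table(
    gene_id = character(0), variant_1 = character(0), tissue_1 = character(0),
    variant_2 = character(0), tissue_2 = character(0), distance = numeric(0)))
  data.table::rbindlist(out)
}
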