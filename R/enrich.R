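# Evaluation machinery: enrichment of a variant set in a score bin with a
# binomial standard error, percentile binning, downsampling that preserves
# the set of interest, and AUROC/AUPRC score evaluation.

#' Enrichment of a set within a bin
#'
#' `P(in set | in bin) / P(in set)`, i.e.
#' `(n_set_in_bin / n_bin) / (n_set / n_total)`. The standard error is the
#' binomial standard error of the numerator proportion divided by the
#' denominator (the denominator is treated as fixed, appropriate when the
#' total is large).
#'
#' @param set_flags Logical vector: membership in the set of interest.
#' @param bin_flags Logical vector: membership in the score bin.
#' @return List of class `enrichment_result`: counts (`n_total`, `n_set`,
#'   `n_bin`, `n_set_in_bin`), `enrichment`, `se`.
#' @export
enrichment <- function(set_flags, bin_flags) {
  set_flags <- as.logical(set_flags); bin_flags <- as.logical(bin_flags)
  stopifnot(length(set_flags) == length(bin_flags))
  n_total <- length(set_flags)
  n_set <- sum(set_flags)
  n_bin <- sum(bin_flags)
  if (n_bin == 0) stop_invalid("empty bin: enrichment undefined")
  if (n_set == 0) stop_invalid("empty set: enrichment undefined")
  n_set_in_bin <- sum(set_flags & bin_flags)
  p_num <- n_set_in_bin / n_bin
  p_den <- n_set / n_total
  structure(list(n_total = n_total, n_set = n_set, n_bin = n_bin,
                 n_set_in_bin = n_set_in_bin,
                 enrichment = p_num / p_den,
                 se = sqrt(p_num * (1 - p_num) / n_bin) / p_den),
            class = "enrichment_result")
}

#' Percentile-bin assignment of scores
#'
#' Cuts scores into right-closed bins at the given percentile edges of their
#' own distribution; tied scores always share a bin.
#'
#' @param scores Numeric scores.
#' @param edges Percentile cut points, strictly increasing in `(0, 100)`.
#'   The default is deciles with a finer 99th-percentile top bin.
#' @return Integer bin index per score (1 = lowest bin).
#' @export
percentile_bins <- function(scores, edges = c(seq(10, 90, 10), 99)) {
  if (any(diff(edges) <= 0) || any(edges <= 0) || any(edges >= 100))
    stop_invalid("edges must be strictly increasing within (0, 100)")
  if (length(unique(scores)) == 1L)
    stop_invalid("constant scores cannot form more than one bin")
  cuts <- unique(quantile(scores, edges / 100, names = FALSE))
  # right-closed: score <= cut stays in the lower bin
  findInterval(scores, cuts, left.open = TRUE) + 1L
}

#' Downsample keeping the whole set of interest
#'
#' All set rows are kept; non-set rows are sampled without replacement so the
#' output has exactly `target_total` rows. Deterministic per seed.
#'
#' @param rows A data.frame (or vector of row indices to subset from).
#' @param set_flags Logical set membership per row.
#' @param target_total Output size (default 100000).
#' @param seed Integer seed.
#' @return The subsampled rows, set rows first, in original order within each
#'   group.
#' @export
downsample_keep_set <- function(rows, set_flags, target_total = 100000,
                                seed = 1) {
  set_flags <- as.logical(set_flags)
  n_set <- sum(set_flags)
  if (target_total < n_set)
    stop_invalid("target_total (%d) below set size (%d)",
                 target_total, n_set)
  n <- length(set_flags)
  if (n <= target_total) keep <- seq_len(n)
  else {
    non <- which(!set_flags)
    fill <- with_seed(seed, sort(sample(non, target_total - n_set)))
    keep <- sort(c(which(set_flags), fill))
  }
  if (is.data.frame(rows)) rows[keep, , drop = FALSE] else rows[keep]
}

auprc_step <- function(scores, labels) {
  # average precision: sum of precision * delta-recall over descending-score
  # thresholds (ties processed together)
  pos <- as.logical(labels)
  ord <- order(-scores)
  s <- scores[ord]; p <- pos[ord]
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / sum(pos)
  precision <- tp / (tp + fp)
  sum(precision * diff(c(0, recall)))
}

#' Evaluate a score against binary labels
#'
#' AUROC (threshold-sweep, via pROC), AUPRC (average precision), and a
#' percentile-bin enrichment table of the positive set.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) positive flags; both classes required.
#' @param edges Percentile edges for the enrichment table
#'   ([percentile_bins()]).
#' @return List with `auroc`, `auprc`, and `enrichment_table` (a
#'   `data.table` with one row per bin).
#' @export
score_eval <- function(scores, labels, edges = c(seq(10, 90, 10), 99)) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2)
    stop_invalid("both classes required for score evaluation")
  auroc <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
  auprc <- auprc_step(scores, labels)
  bins <- percentile_bins(scores, edges)
  tab <- data.table::rbindlist(lapply(sort(unique(bins)), function(b) {
    e <- enrichment(labels, bins == b)
    data.table::data.table(bin = b, n_bin = e$n_bin,
                           n_set_in_bin = e$n_set_in_bin,
                           enrichment = e$enrichment, se = e$se)
  }))
  list(auroc = auroc, auprc = auprc, enrichment_table = tab)
}
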