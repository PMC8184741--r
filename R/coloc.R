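# Colocalization of eQTL and complex-trait fine-mapping posteriors: CLPP is
# the maximum over tissues and credible-set variants of the product of the
# eQTL PIP and the trait PIP; a gene is prioritized when its CLPP exceeds
# 0.1 and is the strict maximum in its region.

#' Colocalization posterior probability for one gene
#'
#' `CLPP = max over (tissue, variant in the credible set) of
#' eqtl_pip * trait_pip`. Ties on the product are broken by ascending
#' variant id, then tissue.
#'
#' @param eqtl_pips Table with `variant_id`, `tissue`, `pip` (or a named
#'   numeric vector for a single tissue).
#' @param trait_pips Named numeric vector of trait PIPs by variant id (or a
#'   table with `variant_id`, `trait_pip`).
#' @param credible_variants Variant ids of the (unresolved) credible set to
#'   maximize over; default all variants shared by the two inputs.
#' @return List of class `coloc_record`: `clpp`, `argmax_variant`,
#'   `argmax_tissue`.
#' @export
clpp <- function(eqtl_pips, trait_pips, credible_variants = NULL) {
  if (is.numeric(eqtl_pips)) {
    eqtl_pips <- data.table::data.table(variant_id = names(eqtl_pips),
                                        tissue = NA_character_,
                                        pip = as.numeric(eqtl_pips))
  } else eqtl_pips <- data.table::as.data.table(eqtl_pips)
  if (is.data.frame(trait_pips)) {
    trait_pips <- stats::setNames(trait_pips$trait_pip,
                                  trait_pips$variant_id)
  }
  if (is.null(credible_variants))
    credible_variants <- intersect(eqtl_pips$variant_id, names(trait_pips))
  e <- eqtl_pips[variant_id %in% credible_variants &
                   variant_id %in% names(trait_pips)]
  if (nrow(e) == 0L)
    stop_invalid("no overlap between eQTL and trait variants")
  prod <- e$pip * as.numeric(trait_pips[e$variant_id])
  ord <- order(-prod, e$variant_id, e$tissue)
  best <- ord[1]
  list(clpp = prod[best], argmax_variant = e$variant_id[best],
       argmax_tissue = e$tissue[best])
}

#' Prioritize genes by CLPP within regions
#'
#' A gene is prioritized iff its CLPP exceeds `threshold` and is the strict
#' maximum in its region (a tie at the maximum prioritizes no gene). At most
#' one gene per region.
#'
#' @param records Table with `region_id`, `gene_id`, `clpp`.
#' @param threshold CLPP threshold (default 0.1).
#' @return `data.table` of the input with a logical `prioritized` column.
#' @export
prioritize_genes <- function(records, threshold = 0.1) {
  rec <- data.table::as.data.table(records)
  stopifnot(all(c("region_id", "gene_id", "clpp") %in% names(rec)))
  rec[, prioritized := {
    mx <- max(clpp)
    clpp == mx & mx > threshold & sum(clpp == mx) == 1L
  }, by = region_id]
  rec[]
}

#' Precision and recall of gene prioritization
#'
#' Precision: correctly prioritized genes / all prioritized genes (NaN when
#' nothing is prioritized). Recall: correctly prioritized genes / evaluation
#' genes.
#'
#' @param prioritized Table of prioritized genes with `region_id`, `gene_id`
#'   (e.g. the `prioritized == TRUE` rows of [prioritize_genes()] output).
#' @param correct Named character vector region_id -> correct gene.
#' @param evaluation_genes Character vector of evaluation genes (nonempty).
#' @return List with `precision`, `recall`, `n_prioritized`, `n_correct`,
#'   `n_evaluation`.
#' @export
precision_recall <- function(prioritized, correct, evaluation_genes) {
  if (!length(evaluation_genes))
    stop_invalid("evaluation gene list must be nonempty")
  pri <- data.table::as.data.table(prioritized)
  n_pri <- nrow(pri)
  n_correct <- if (n_pri) {
    sum(pri$gene_id == correct[pri$region_id], na.rm = TRUE)
  } else 0L
  list(precision = if (n_pri) n_correct / n_pri else NaN,
       recall = n_correct / length(evaluation_genes),
       n_prioritized = n_pri, n_correct = n_correct,
       n_evaluation = length(evaluation_genes))
}

#' Build evaluation regions around unresolved trait credible sets
#'
#' A region is a 1 Mb window (center +/- 0.5 Mb) around a trait credible set
#' that is unresolved (contains no coding variant with trait PIP > 0.1) and
#' contains at least one evaluation gene (a gene with a coding variant at
#' trait PIP > 0.5). Coding and gene-assignment flags are input columns.
#'
#' @param trait_table Table with `variant_id`, `chrom`, `pos`, `trait_pip`,
#'   logical `coding`, `gene_id` (gene of the coding variant, NA otherwise),
#'   and `cs_id` (trait credible-set id).
#' @param halfwidth Region half-width in bp (default 5e5).
#' @param unresolved_pip Coding-PIP threshold above which a set counts as
#'   resolved (default 0.1).
#' @param evaluation_pip Coding-PIP threshold defining an evaluation gene
#'   (default 0.5).
#' @return `data.table` with `region_id`, `chrom`, `start`, `end`,
#'   `evaluation_gene`.
#' @export
build_regions <- function(trait_table, halfwidth = 5e5,
                          unresolved_pip = 0.1, evaluation_pip = 0.5) {
  tt <- data.table::as.data.table(trait_table)
  out <- list()
  for (cs in unique(tt$cs_id[!is.na(tt$cs_id)])) {
    sub <- tt[cs_id == cs]
    if (any(sub$coding & sub$trait_pip > unresolved_pip)) next  # resolved
    center <- round(mean(range(sub$pos)))
    chrom <- sub$chrom[1]
    lo <- center - halfwidth; hi <- center + halfwidth
    eg <- tt[chrom == sub$chrom[1] & pos >= lo & pos <= hi &
               coding & trait_pip > evaluation_pip & !is.na(gene_id),
             unique(gene_id)]
    if (!length(eg)) next
    out[[length(out) + 1L]] <- data.table::data.table(
      region_id = sprintf("region_%s", cs), chrom = chrom,
      start = lo, end = hi, evaluation_gene = eg[1])
  }
  if (!length(out)) return(data.table::data.table(
    region_id = character(0), chrom = character(0),
    start = numeric(0), end = numeric(0), evaluation_gene = character(0)))
  data.table::rbindlist(out)
}
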