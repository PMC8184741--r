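# Feature assembly: variant-gene pairs + annotation sources -> model-ready
# feature matrix. Variant tables are 1-based inclusive; BED is 0-based
# half-open; the conversion happens here and nowhere else.

#' Signed distance from a variant to a gene's TSS
#'
#' `variant_pos - tss_pos`, with the sign flipped on the minus strand, so a
#' positive distance is always downstream of transcription.
#'
#' @param variant_pos 1-based variant position(s).
#' @param tss_pos 1-based TSS position(s).
#' @param strand `"+"` or `"-"` (recycled).
#' @return Signed distance in bp.
#' @export
distance_to_tss <- function(variant_pos, tss_pos, strand = "+") {
  if (!all(strand %in% c("+", "-")))
    stop_invalid("unknown strand value(s): %s",
                 paste(unique(setdiff(strand, c("+", "-"))), collapse = ","))
  d <- variant_pos - tss_pos
  ifelse(strand == "-", -d, d)
}

#' Read a BED file of annotation intervals
#'
#' Expects at least 3 columns (chrom, start, end), 0-based half-open. Track
#' and browser lines are skipped; a malformed data line raises an error naming
#' its line number.
#'
#' @param path BED file path.
#' @return `data.table` with `chrom`, `start`, `end` (still 0-based
#'   half-open).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3 || is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3]))))
      stop_invalid("malformed BED line %d in %s: %s", i, path, lines[i])
    j <- j + 1L
    out[[j]] <- data.table::data.table(chrom = f[1],
                                       start = as.integer(f[2]),
                                       end = as.integer(f[3]))
  }
  if (j == 0L) return(data.table::data.table(chrom = character(0),
                                             start = integer(0),
                                             end = integer(0)))
  data.table::rbindlist(out)
}

#' Binary overlap features from BED interval sets
#'
#' For each named interval set, a pair scores 1 iff the variant position
#' (converted to 0-based) falls inside at least one interval of that set.
#' Only the position is used; allele-aware scores must arrive as precomputed
#' continuous columns.
#'
#' @param pairs `data.frame` with `chrom` and 1-based `pos`.
#' @param bed_sets Named list; each element a BED `data.table` from
#'   [read_bed()] (or a file path).
#' @return `data.table` of 0/1 columns, one per interval set, aligned to
#'   `pairs` rows.
#' @export
annotate_binary_overlap <- function(pairs, bed_sets) {
  pairs <- data.table::as.data.table(pairs)
  pos0 <- pairs$pos - 1L                    # 1-based -> 0-based
  out <- data.table::data.table(.rows = seq_len(nrow(pairs)))
  for (nm in names(bed_sets)) {
    bed <- bed_sets[[nm]]
    if (is.character(bed)) bed <- read_bed(bed)
    hit <- rep(0L, nrow(pairs))
    if (nrow(bed)) {
      iv <- data.table::data.table(chrom = bed$chrom, s = bed$start,
                                   e = bed$end - 1L)  # closed for foverlaps
      data.table::setkey(iv, chrom, s, e)
      q <- data.table::data.table(chrom = pairs$chrom, s = pos0, e = pos0)
      ov <- data.table::foverlaps(q, iv, type = "within", which = TRUE,
                                  nomatch = NULL)
      hit[unique(ov$xid)] <- 1L
    }
    out[[nm]] <- hit
  }
  out[, .rows := NULL]
  out[]
}

#' Continuous score columns for pairs
#'
#' Joins numeric score columns onto the pairs, keyed by variant
#' (`chrom`,`pos`,`ref`,`alt`) or by pair (additionally `gene_id`). When both
#' tables carry a column of the same name, the per-pair value wins. Missing
#' entries are filled with `default` and the fill count is reported as a
#' message.
#'
#' @param pairs Pair table.
#' @param variant_scores Optional per-variant table (variant key + numeric
#'   columns).
#' @param pair_scores Optional per-pair table (variant key + `gene_id` +
#'   numeric columns).
#' @param default Fill value for missing entries (default 0).
#' @return `data.table` of numeric columns aligned to `pairs`.
#' @export
annotate_continuous <- function(pairs, variant_scores = NULL,
                                pair_scores = NULL, default = 0) {
  pairs <- data.table::as.data.table(pairs)
  vkey <- c("chrom", "pos", "ref", "alt")
  out <- data.table::data.table(.rows = seq_len(nrow(pairs)))
  add_cols <- function(tbl, key) {
    tbl <- data.table::as.data.table(tbl)
    score_cols <- setdiff(names(tbl), c(key, "variant_id"))
    idx <- tbl[pairs, on = key, which = TRUE, mult = "first"]
    for (nm in score_cols) {
      if (!is.numeric(tbl[[nm]]))
        stop_invalid("non-numeric score column '%s'", nm)
      v <- tbl[[nm]][idx]
      if (nm %in% names(out)) {
        # per-pair value wins; fall back to the per-variant value when absent
        old <- out[[nm]]
        v <- ifelse(is.na(v), old, v)
      }
      out[[nm]] <<- v
    }
    score_cols
  }
  filled <- character(0)
  if (!is.null(variant_scores)) filled <- add_cols(variant_scores, vkey)
  if (!is.null(pair_scores)) {
    pcols <- add_cols(pair_scores, c(vkey, "gene_id"))
    filled <- union(filled, pcols)
  }
  n_fill <- 0L
  for (nm in filled) {
    miss <- is.na(out[[nm]])
    n_fill <- n_fill + sum(miss)
    data.table::set(out, which(miss), nm, default)
  }
  if (n_fill > 0)
    message(sprintf("annotate_continuous: filled %d missing entries with %s",
                    n_fill, format(default)))
  out[, .rows := NULL]
  out[]
}

#' Leave-one-chromosome-out split
#'
#' Exact, disjoint partition of the pairs by chromosome, used so that scores
#' on a chromosome never come from a model trained on it.
#'
#' @param pairs Pair table with a `chrom` column.
#' @param holdout_chrom Chromosome to hold out.
#' @return List with `train` and `heldout` tables.
#' @export
loco_split <- function(pairs, holdout_chrom) {
  pairs <- data.table::as.data.table(pairs)
  if (!holdout_chrom %in% pairs$chrom)
    stop_invalid("holdout chromosome %s not present", holdout_chrom)
  held <- pairs[chrom == holdout_chrom]
  train <- pairs[chrom != holdout_chrom]
  if (nrow(train) == 0L)
    stop_invalid("empty training partition: all rows on %s", holdout_chrom)
  list(train = train, heldout = held)
}

#' Assemble the full feature matrix for a pair table
#'
#' Computes the signed TSS distance from a TSS table, binary overlap columns
#' from BED sets, and continuous columns from score tables, and returns one
#' matrix with a `feature_class` attribute. Assembly is deterministic and
#' order-independent (row i of the output always describes row i of `pairs`).
#'
#' @param pairs Pair table (`chrom`,`pos`,`ref`,`alt`,`gene_id`, ...).
#' @param tss Optional TSS table (`gene_id`,`chrom`,`tss_pos`,`strand`); when
#'   absent, an existing `tss_distance` column on `pairs` is used.
#' @param bed_sets Named list of BED interval sets (see
#'   [annotate_binary_overlap()]).
#' @param variant_scores,pair_scores Continuous score tables (see
#'   [annotate_continuous()]).
#' @param default Fill value for missing continuous entries.
#' @return `data.table` feature matrix aligned to `pairs`, with attribute
#'   `feature_class`.
#' @export
build_feature_matrix <- function(pairs, tss = NULL, bed_sets = NULL,
                                 variant_scores = NULL, pair_scores = NULL,
                                 default = 0) {
  pairs <- data.table::as.data.table(pairs)
  if (!is.null(tss)) {
    tss <- data.table::as.data.table(tss)
    idx <- match(pairs$gene_id, tss$gene_id)
    if (anyNA(idx))
      stop_invalid("genes missing from TSS table: %s",
                   paste(unique(pairs$gene_id[is.na(idx)]), collapse = ", "))
    dist <- distance_to_tss(pairs$pos, tss$tss_pos[idx], tss$strand[idx])
  } else if ("tss_distance" %in% names(pairs)) {
    dist <- pairs$tss_distance
  } else {
    stop_invalid("need a TSS table or a tss_distance column")
  }
  out <- data.table::data.table(tss_distance = as.numeric(dist))
  classes <- c(tss_distance = "distance")
  if (!is.null(bed_sets) && length(bed_sets)) {
    bin <- annotate_binary_overlap(pairs, bed_sets)
    out <- cbind(out, bin)
    classes <- c(classes, stats::setNames(rep("binary", ncol(bin)),
                                          names(bin)))
  }
  if (!is.null(variant_scores) || !is.null(pair_scores)) {
    cont <- annotate_continuous(pairs, variant_scores, pair_scores, default)
    out <- cbind(out, cont)
    classes <- c(classes, stats::setNames(rep("continuous", ncol(cont)),
                                          names(cont)))
  }
  if (anyDuplicated(names(out)))
    stop_invalid("duplicate feature column names after assembly")
  data.table::setattr(out, "feature_class", classes)
  out[]
}
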