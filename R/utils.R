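#' @importFrom stats rnorm runif rbinom qnorm quantile cor var sd coef lm
#'   median predict t.test setNames rexp aggregate
#' @importFrom utils head tail
#' @import data.table
NULL

# All randomness in the package flows from one integer seed through this
# hierarchical split: stream ids are small fixed integers per call site.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(stream) * 7919L + 17L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

#' Read a tab-separated table
#'
#' Thin wrapper around [data.table::fread()] used for all delimited inputs.
#'
#' @param path File path.
#' @return A `data.table`.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop_invalid("input file not found: %s", path)
  data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE)
}

#' Write a tab-separated table
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
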