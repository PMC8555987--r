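#' @useDynLib vmte, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile rbinom rnorm rpois runif setNames
#' @importFrom utils read.table write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_vmte <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Construct a table of genomic intervals
#'
#' Intervals are BED-style throughout the package: 0-based, half-open
#' `[start, end)`, strand one of `+`, `-`, `.`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, `0 <= start < end`.
#' @param strand strand characters; recycled; defaults to `.`.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  n <- length(chrom)
  strand <- rep_len(as.character(strand), n)
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop_vmte("non-integer interval coordinates")
  if (any(nchar(chrom) == 0L)) stop_vmte("empty chromosome name")
  if (any(start < 0L) || any(start >= end))
    stop_vmte("invalid interval: require 0 <= start < end")
  if (!all(strand %in% c("+", "-", ".")))
    stop_vmte("strand must be one of '+', '-', '.'")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

# GRanges conversion used internally for interval algebra (IRanges is 1-based
# closed; our tables are 0-based half-open).
as_granges <- function(df) {
  strand <- df$strand %||% rep(".", nrow(df))
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

# Run code with a private RNG stream; never disturbs the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# Derive a reproducible sub-seed (< 2^31) from a root seed and a stage tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + 1) %% 2147483647)
}

is_missing_val <- function(x) is.na(x)
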