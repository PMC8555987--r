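#' Read a RepeatMasker .out annotation file
#'
#' RepeatMasker .out files carry 1-based inclusive coordinates and use `C`
#' for the minus strand; both are converted at this boundary so that every
#' downstream operation sees 0-based half-open intervals and `+`/`-` strands.
#' Instance identifiers are assigned deterministically as
#' `subfamily:chrom:start-end` (post-conversion coordinates).
#'
#' @param path path to a RepeatMasker .out file (3 header lines).
#' @return data.frame of repeat instances with columns `instance_id`,
#'   `chrom`, `start`, `end`, `strand`, `subfamily`, `family`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop_vmte("truncated RepeatMasker file: %s", path)
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) return(empty_instances())
  recs <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[[i]]), "\\s+")[[1]]
    if (length(f) < 11L)
      stop_vmte("malformed RepeatMasker line %d: expected >= 11 fields, got %d",
                i + 3L, length(f))
    begin <- suppressWarnings(as.integer(f[6]))
    end <- suppressWarnings(as.integer(f[7]))
    if (is.na(begin) || is.na(end))
      stop_vmte("malformed RepeatMasker line %d: non-integer coordinates", i + 3L)
    strand <- f[9]
    if (strand == "C") strand <- "-"
    if (!strand %in% c("+", "-"))
      stop_vmte("unknown strand token '%s' on RepeatMasker line %d", f[9], i + 3L)
    list(chrom = f[5], start = begin - 1L, end = end, strand = strand,
         subfamily = f[10], family = f[11])
  })
  out <- do.call(rbind, lapply(recs, as.data.frame, stringsAsFactors = FALSE))
  out$instance_id <- sprintf("%s:%s:%d-%d", out$subfamily, out$chrom,
                             out$start, out$end)
  if (anyDuplicated(out$instance_id))
    out$instance_id <- make.unique(out$instance_id, sep = "#")
  out[, c("instance_id", "chrom", "start", "end", "strand", "subfamily", "family")]
}

empty_instances <- function() {
  data.frame(instance_id = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             subfamily = character(), family = character(),
             stringsAsFactors = FALSE)
}

#' Write repeat instances as a RepeatMasker-style .out file
#'
#' Inverse of [read_repeatmasker_out()]: coordinates converted back to
#' 1-based inclusive and minus strand written as `C`.
#'
#' @param instances data.frame as returned by [read_repeatmasker_out()].
#' @param path output path.
#' @export
write_repeatmasker_out <- function(instances, path) {
  hdr <- c("   SW  perc perc perc  query     position in query    matching repeat",
           "score  div. del. ins.  sequence  begin  end  (left)   repeat  class/family",
           "")
  rows <- sprintf("  100   0.0  0.0  0.0  %s  %d  %d  (0)  %s  %s  1  %d  (0)  %d",
                  instances$chrom, instances$start + 1L, instances$end,
                  ifelse(instances$strand == "-", "C", "+"),
                  paste0(instances$subfamily, "  ", instances$family),
                  instances$end - instances$start, seq_len(nrow(instances)))
  writeLines(c(hdr, rows), path)
}

#' Read a BED3/BED6 file
#'
#' Coordinates are kept as-is (BED is already 0-based half-open). BED3
#' records get strand `.`; narrowPeak and other BED6+ files are accepted,
#' extra columns beyond six are ignored.
#'
#' @param path path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  raw <- tryCatch(
    read.table(path, sep = "", header = FALSE, comment.char = "#",
               colClasses = "character", stringsAsFactors = FALSE,
               fill = TRUE),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (ncol(raw) < 3L) stop_vmte("BED file %s has fewer than 3 columns", path)
  start <- suppressWarnings(as.integer(raw[[2]]))
  end <- suppressWarnings(as.integer(raw[[3]]))
  if (any(is.na(start)) || any(is.na(end)))
    stop_vmte("non-integer coordinate in BED file %s", path)
  if (any(start >= end))
    stop_vmte("BED file %s: start >= end at line %d", path, which(start >= end)[1])
  out <- data.frame(
    chrom = raw[[1]], start = start, end = end,
    name = if (ncol(raw) >= 4L) raw[[4]] else sprintf("feat%d", seq_along(start)),
    score = if (ncol(raw) >= 5L) suppressWarnings(as.numeric(raw[[5]])) else NA_real_,
    strand = if (ncol(raw) >= 6L) raw[[6]] else ".",
    stringsAsFactors = FALSE)
  nm_na <- is.na(out$name) | !nzchar(out$name)
  if (any(nm_na)) out$name[nm_na] <- sprintf("feat%d", which(nm_na))
  bad <- is.na(out$strand) | !out$strand %in% c("+", "-", ".")
  if (any(bad)) out$strand[bad] <- "."
  out
}

#' Write intervals as BED
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  n <- nrow(intervals)
  df <- data.frame(
    chrom = intervals$chrom,
    start = intervals$start,
    end = intervals$end,
    name = intervals$name %||% sprintf("feat%d", seq_len(n)),
    score = {
      s <- intervals$score %||% rep(0, n)
      ifelse(is.na(s), 0, s)
    },
    strand = intervals$strand %||% rep(".", n))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Read a bedGraph file into a dense per-base coverage track
#'
#' @param path path to a bedGraph (0-based half-open records).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return a `CoverageTrack`: named list of per-bp numeric vectors, one per
#'   chromosome in `chrom_sizes`; positions absent from the file are 0.
#'   Overlapping records are an error (ambiguous signal).
#' @export
read_bedgraph <- function(path, chrom_sizes) {
  track <- coverage_track(chrom_sizes)
  raw <- tryCatch(
    read.table(path, sep = "", header = FALSE, colClasses = "character"),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L) return(track)
  if (ncol(raw) < 4L) stop_vmte("bedGraph %s needs 4 columns", path)
  chrom <- raw[[1]]
  start <- suppressWarnings(as.integer(raw[[2]]))
  end <- suppressWarnings(as.integer(raw[[3]]))
  value <- suppressWarnings(as.numeric(raw[[4]]))
  if (any(is.na(start)) || any(is.na(end)) || any(is.na(value)))
    stop_vmte("malformed bedGraph record in %s", path)
  if (any(!chrom %in% names(chrom_sizes)))
    stop_vmte("bedGraph %s refers to unknown chromosome '%s'", path,
              setdiff(chrom, names(chrom_sizes))[1])
  if (any(end > chrom_sizes[chrom]))
    stop_vmte("bedGraph %s: record past chromosome end", path)
  if (any(start >= end)) stop_vmte("bedGraph %s: start >= end", path)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    o <- i[order(start[i])]
    if (any(start[o][-1] < end[o][-length(o)]))
      stop_vmte("bedGraph %s: overlapping records on %s (ambiguous signal)",
                path, ch)
    for (j in o) track[[ch]][(start[j] + 1L):end[j]] <- value[j]
  }
  track
}

#' Create an all-zero coverage track
#'
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return named list of numeric zero vectors with class `CoverageTrack`.
#' @export
coverage_track <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop_vmte("chrom_sizes must be a named vector")
  track <- lapply(chrom_sizes, function(n) numeric(n))
  class(track) <- "CoverageTrack"
  track
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are collapsed; zero runs are omitted.
#'
#' @param track a `CoverageTrack`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track)) {
    r <- rle(track[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%g", ch, starts[keep], ends[keep],
                       r$values[keep]), con)
  }
  invisible(path)
}

#' Read per-CpG methylation calls
#'
#' @param path TSV with header columns `chrom`, `pos`, `methylated`,
#'   `total`, `sample`. `pos` is the 0-based position of the C of the CpG on
#'   the plus strand; counts are assumed strand-collapsed upstream.
#' @return data.frame of calls with a derived `fraction` column.
#' @export
read_methylation_calls <- function(path) {
  raw <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      methylated = integer(), total = integer(),
                      sample = character(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  need <- c("chrom", "pos", "methylated", "total", "sample")
  if (!all(need %in% names(raw)))
    stop_vmte("methylation TSV %s missing columns: %s", path,
              paste(setdiff(need, names(raw)), collapse = ", "))
  out <- raw[, need]
  out$pos <- as.integer(out$pos)
  out$methylated <- as.integer(out$methylated)
  out$total <- as.integer(out$total)
  if (any(out$methylated < 0L) || any(out$total < 0L) ||
      any(out$methylated > out$total))
    stop_vmte("methylation TSV %s: methylated > total", path)
  out$fraction <- ifelse(out$total > 0L, out$methylated / out$total, NA_real_)
  out
}

#' Write methylation calls as TSV
#' @param calls data.frame as from [read_methylation_calls()].
#' @param path output path.
#' @export
write_methylation_calls <- function(calls, path) {
  write.table(calls[, c("chrom", "pos", "methylated", "total", "sample")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an FPKM expression matrix
#'
#' @param path TSV: first column `gene_id`, remaining columns one FPKM value
#'   per sample.
#' @return list with `gene_id` (character) and `fpkm` (numeric matrix,
#'   genes x samples).
#' @export
read_fpkm_matrix <- function(path) {
  raw <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (ncol(raw) < 2L) stop_vmte("FPKM matrix %s needs gene_id + samples", path)
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop_vmte("FPKM matrix %s has negative values", path)
  rownames(m) <- raw[[1]]
  list(gene_id = raw[[1]], fpkm = m)
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return a [Biostrings::DNAStringSet] keyed by chromosome name.
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' Chromosome sizes of a genome
#' @param genome DNAStringSet.
#' @return named integer vector.
#' @export
genome_sizes <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}
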