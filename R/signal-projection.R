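track_slice <- function(track, chrom, start, end) {
  if (!chrom %in% names(track)) stop_vmte("chromosome '%s' not in track", chrom)
  len <- length(track[[chrom]])
  if (start < 0 || end > len)
    stop_vmte("interval [%d,%d) outside %s track bounds", start, end, chrom)
  track[[chrom]][(start + 1L):end]
}

#' Project one element's per-base coverage into alignment-column space
#'
#' Coverage over the instance span is read 5' to 3' in element orientation
#' (reversed for minus-strand instances); the j-th base's value is placed in
#' the alignment column holding the row's j-th non-gap symbol. Gap columns
#' are missing (`NA`) — absent data, never zero. When `column_map` is given
#' the projected full-width row is subset to those (trimmed) columns.
#'
#' @param track a `CoverageTrack`.
#' @param instance single-row repeat instance data.frame.
#' @param msa_row untrimmed gapped row for this instance; its non-gap count
#'   must equal the instance length.
#' @param column_map optional integer vector of retained original columns.
#' @return numeric vector (length = row width or `length(column_map)`) with
#'   `NA` at gaps.
#' @export
project_element_coverage <- function(track, instance, msa_row,
                                     column_map = NULL) {
  codes <- encode_seq(msa_row)
  nongap <- which(codes != 5L)
  ilen <- instance$end - instance$start
  if (length(nongap) != ilen)
    stop_vmte("row for %s has %d bases but instance spans %d bp",
              instance$instance_id %||% "?", length(nongap), ilen)
  cov <- track_slice(track, instance$chrom, instance$start, instance$end)
  if (identical(instance$strand, "-")) cov <- rev(cov)
  row <- rep(NA_real_, length(codes))
  row[nongap] <- cov
  if (!is.null(column_map)) row <- row[column_map]
  row
}

#' Signal matrix over an alignment
#'
#' One projected row per instance, ordered with rows grouped by clade
#' (clade label order, then row order within clade) when clades are given.
#'
#' @param track a `CoverageTrack`.
#' @param instances repeat instance data.frame covering every MSA row.
#' @param msa untrimmed `vmte_msa`.
#' @param clades optional named vector instance_id -> clade label.
#' @param column_map optional trimmed-column map.
#' @return numeric matrix (instances x columns) with `NA` at gap columns and
#'   a `"clades"` attribute when clades were supplied.
#' @export
build_signal_matrix <- function(track, instances, msa, clades = NULL,
                                column_map = NULL) {
  ids <- names(msa$rows)
  miss <- setdiff(ids, instances$instance_id)
  if (length(miss))
    stop_vmte("no instance for MSA row(s): %s", paste(head(miss, 3), collapse = ", "))
  inst <- instances[match(ids, instances$instance_id), , drop = FALSE]
  rows <- lapply(seq_along(ids), function(i)
    project_element_coverage(track, inst[i, ], msa$rows[[i]], column_map))
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  if (!is.null(clades)) {
    ord <- order(clades[ids], seq_along(ids))
    m <- m[ord, , drop = FALSE]
    attr(m, "clades") <- clades[rownames(m)]
  }
  m
}

#' Per-clade mean signal profiles
#'
#' Column means per clade, ignoring missing values; a column with no
#' present value in a clade stays `NA`.
#'
#' @param matrix signal matrix from [build_signal_matrix()].
#' @param clades named vector instance_id -> clade covering every row.
#' @return numeric matrix (clades x columns).
#' @export
clade_mean_profiles <- function(matrix, clades) {
  ids <- rownames(matrix)
  if (any(!ids %in% names(clades))) stop_vmte("unlabeled rows in signal matrix")
  labs <- sort(unique(clades[ids]))
  prof <- t(vapply(labs, function(cl) {
    rows <- matrix[clades[ids] == cl, , drop = FALSE]
    if (nrow(rows) == 0L) stop_vmte("clade %s has zero rows", cl)
    v <- colMeans(rows, na.rm = TRUE)
    v[!is.finite(v)] <- NA_real_
    v
  }, numeric(ncol(matrix))))
  rownames(prof) <- labs
  prof
}

#' Mean per-base signal over one element
#'
#' @param track a `CoverageTrack`.
#' @param instance single-row instance data.frame.
#' @return arithmetic mean of coverage over `[start, end)`; strand has no
#'   effect on a mean.
#' @export
mean_signal_per_element <- function(track, instance) {
  mean(track_slice(track, instance$chrom, instance$start, instance$end))
}

#' Anchor-point signal windows
#'
#' Extracts a `2 * flank` window of coverage centred on each element's
#' 5' end (anchor = `start` for `+`, `end - 1` for `-`), read 5' to 3' in
#' element orientation (i.e. reversed for minus-strand elements).
#' Positions beyond the chromosome ends are missing (`NA`).
#'
#' @param track a `CoverageTrack`.
#' @param instances repeat instance data.frame.
#' @param anchor only `"5prime"` is defined.
#' @param flank half-window in bp (default 2000).
#' @return numeric matrix (instances x 2*flank), columns -flank .. flank-1
#'   relative to the anchor.
#' @export
project_anchor_window <- function(track, instances, anchor = "5prime",
                                  flank = 2000) {
  anchor <- match.arg(anchor, "5prime")
  m <- t(vapply(seq_len(nrow(instances)), function(i) {
    inst <- instances[i, ]
    len <- length(track[[inst$chrom]])
    if (inst$strand == "-") {
      a <- inst$end - 1L
      pos <- a + flank - 0:(2L * flank - 1L)   # read 5'->3' on the element
    } else {
      a <- inst$start
      pos <- a - flank + 0:(2L * flank - 1L)
    }
    v <- rep(NA_real_, 2L * flank)
    ok <- pos >= 0L & pos < len
    v[ok] <- track[[inst$chrom]][pos[ok] + 1L]
    v
  }, numeric(2L * flank)))
  rownames(m) <- instances$instance_id
  colnames(m) <- as.character(seq(-flank, flank - 1L))
  m
}

#' Write a signal matrix as TSV (`NA` for missing)
#' @param m matrix.
#' @param path output path.
#' @export
write_signal_matrix <- function(m, path) {
  write.table(data.frame(instance_id = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}
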