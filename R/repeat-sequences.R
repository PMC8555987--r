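#' Extract the genomic sequence of an instance, element-oriented
#'
#' Minus-strand instances are reverse-complemented so that the returned
#' string reads 5' to 3' in element orientation.
#'
#' @param genome DNAStringSet.
#' @param chrom,start,end 0-based half-open interval.
#' @param strand `+`, `-` or `.` (treated as `+`).
#' @return character sequence.
#' @export
element_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop_vmte("chromosome '%s' not in genome", chrom)
  len <- length(genome[[chrom]])
  if (start < 0 || end > len)
    stop_vmte("interval [%d,%d) outside %s bounds [0,%d)", start, end, chrom, len)
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Extract LTR sequences above a length cutoff
#'
#' Keeps instances of the target subfamilies whose length is strictly
#' greater than `min_len` (an element of exactly `min_len` bp is excluded)
#' and returns their element-oriented sequences. Sequences with more than
#' `max_n_frac` ambiguous bases are dropped and counted in the report.
#'
#' @param genome DNAStringSet.
#' @param instances repeat instance data.frame.
#' @param target_subfamilies character vector of subfamily names.
#' @param min_len minimum length, strict (default 300).
#' @param max_n_frac maximum tolerated N fraction (default 0.10).
#' @return named character vector of sequences (names = instance_id), with
#'   attribute `"report"` listing counts of filtered instances.
#' @export
extract_ltr_sequences <- function(genome, instances, target_subfamilies,
                                  min_len = 300, max_n_frac = 0.10) {
  sel <- instances[instances$subfamily %in% target_subfamilies &
                     (instances$end - instances$start) > min_len, ,
                   drop = FALSE]
  seqs <- vapply(seq_len(nrow(sel)), function(i)
    element_sequence(genome, sel$chrom[i], sel$start[i], sel$end[i],
                     sel$strand[i]), character(1))
  names(seqs) <- sel$instance_id
  nfrac <- vapply(seqs, function(s) {
    mean(strsplit(s, "")[[1]] == "N")
  }, numeric(1))
  if (length(seqs) == 0L) nfrac <- numeric(0)
  keep <- nfrac <= max_n_frac
  out <- seqs[keep]
  attr(out, "report") <- list(
    n_input = nrow(instances),
    n_subfamily = sum(instances$subfamily %in% target_subfamilies),
    n_length_pass = nrow(sel),
    n_dropped_n = sum(!keep))
  out
}

#' Find internal elements flanked by a target LTR at their 5' end
#'
#' An internal element qualifies when an LTR of one of the target
#' subfamilies lies on its 5' side (strand-aware: genomically upstream for
#' `+` instances, downstream for `-`), on the same strand, with an
#' intervening gap of at most `max_gap` bp. A 3'-side LTR is recorded when
#' one exists under the same rule.
#'
#' @param instances repeat instance data.frame (LTRs and internals mixed).
#' @param ltr_subfamilies subfamilies accepted as flanking LTRs.
#' @param int_subfamily subfamily name of the internal elements.
#' @param max_gap maximum gap in bp (default 25).
#' @return data.frame with one row per flanked internal: `int_id`,
#'   `five_prime_ltr`, `three_prime_ltr` (NA when absent), `gap_5p`, `gap_3p`.
#' @export
find_flanked_ints <- function(instances, ltr_subfamilies, int_subfamily,
                              max_gap = 25) {
  ints <- instances[instances$subfamily == int_subfamily, , drop = FALSE]
  ltrs <- instances[instances$subfamily %in% ltr_subfamilies, , drop = FALSE]
  if (nrow(ints) == 0L || nrow(ltrs) == 0L)
    return(data.frame(int_id = character(), five_prime_ltr = character(),
                      three_prime_ltr = character(), gap_5p = integer(),
                      gap_3p = integer(), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(ints)), function(i) {
    it <- ints[i, ]
    same <- ltrs[ltrs$chrom == it$chrom & ltrs$strand == it$strand, ,
                 drop = FALSE]
    if (nrow(same) == 0L) return(NULL)
    if (it$strand == "-") {
      # element 5' end is the genomic right edge
      gap5 <- same$start - it$end
      gap3 <- it$start - same$end
    } else {
      gap5 <- it$start - same$end
      gap3 <- same$start - it$end
    }
    pick <- function(gaps) {
      ok <- which(gaps >= 0L & gaps <= max_gap)
      if (!length(ok)) return(NA_integer_)
      ok[which.min(gaps[ok])]
    }
    i5 <- pick(gap5)
    if (is.na(i5)) return(NULL)
    i3 <- pick(gap3)
    data.frame(int_id = it$instance_id,
               five_prime_ltr = same$instance_id[i5],
               three_prime_ltr = if (is.na(i3)) NA_character_
                                 else same$instance_id[i3],
               gap_5p = gap5[i5],
               gap_3p = if (is.na(i3)) NA_integer_ else gap3[i3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(int_id = character(), five_prime_ltr = character(),
                      three_prime_ltr = character(), gap_5p = integer(),
                      gap_3p = integer(), stringsAsFactors = FALSE)
  out
}

#' Extract the first n bp of internal elements, element-oriented
#'
#' Plus-strand instances yield `genome[start, start + n)`; minus-strand
#' instances yield the reverse complement of `genome[end - n, end)`.
#' Internals shorter than `n` are excluded and counted in the report.
#'
#' @param genome DNAStringSet.
#' @param instances repeat instance data.frame (already restricted to the
#'   flanked internals of interest, e.g. via [find_flanked_ints()]).
#' @param n number of 5'-end bases (default 150).
#' @return named character vector (names = instance_id) with a `"report"`
#'   attribute counting excluded short elements.
#' @export
extract_int_5prime <- function(genome, instances, n = 150) {
  long_enough <- (instances$end - instances$start) >= n
  sel <- instances[long_enough, , drop = FALSE]
  seqs <- vapply(seq_len(nrow(sel)), function(i) {
    if (sel$strand[i] == "-") {
      element_sequence(genome, sel$chrom[i], sel$end[i] - n, sel$end[i], "-")
    } else {
      element_sequence(genome, sel$chrom[i], sel$start[i], sel$start[i] + n, "+")
    }
  }, character(1))
  names(seqs) <- sel$instance_id
  attr(seqs, "report") <- list(n_excluded_short = sum(!long_enough),
                               excluded_ids = instances$instance_id[!long_enough])
  seqs
}
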