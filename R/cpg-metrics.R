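#' CpG observed/expected score of a sequence
#'
#' `score = n_CpG * N / (n_C * n_G)` with `N` the sequence length, `n_CpG`
#' the count of `CG` dinucleotides and `n_C`/`n_G` the base counts; 0 when
#' either base count is 0. Only uppercase `C`/`G` count, so masked
#' (lowercase or `N`) bases contribute length but no CpG signal.
#'
#' @param sequence nucleotide string.
#' @return list with `cpg_count`, `c_count`, `g_count`, `n` and `score`.
#' @export
cpg_score <- function(sequence) {
  if (!nzchar(sequence)) stop_vmte("empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  c_count <- sum(chars == "C")
  g_count <- sum(chars == "G")
  cpg <- if (n >= 2L) sum(chars[-n] == "C" & chars[-1] == "G") else 0L
  score <- if (c_count > 0L && g_count > 0L) cpg * n / (c_count * g_count) else 0
  list(cpg_count = cpg, c_count = c_count, g_count = g_count, n = n,
       score = score)
}

#' Maximum sliding-window CpG score of an element
#'
#' Windows of `window` bp start at offsets `0, step, 2*step, ...` while they
#' fit; a final end-anchored window at `length - window` is added when the
#' grid does not already reach the 3' end, so no element end goes unscored.
#' Elements no longer than `window` are scored with one whole-element window
#' (`N` = element length in the formula).
#'
#' @param sequence nucleotide string.
#' @param window window size in bp (default 200, the minimum CpG-island size).
#' @param step step between window starts (default 10).
#' @return list with `max_score`, `best_offset` and `n_windows`.
#' @export
max_window_cpg_score <- function(sequence, window = 200, step = 10) {
  if (!nzchar(sequence)) stop_vmte("empty sequence")
  len <- nchar(sequence)
  if (len <= window) {
    s <- cpg_score(sequence)
    return(list(max_score = s$score, best_offset = 0L, n_windows = 1L))
  }
  offsets <- seq(0L, len - window, by = step)
  if (offsets[length(offsets)] != len - window)
    offsets <- c(offsets, len - window)
  scores <- vapply(offsets, function(o)
    cpg_score(substr(sequence, o + 1L, o + window))$score, numeric(1))
  best <- which.max(scores)
  list(max_score = scores[best], best_offset = offsets[best],
       n_windows = length(offsets))
}

#' Per-element maximum CpG window scores
#'
#' @param genome DNAStringSet.
#' @param instances repeat instance data.frame.
#' @param window,step see [max_window_cpg_score()].
#' @return data.frame `instance_id`, `subfamily`, `max_score`,
#'   `best_offset`, `n_windows`.
#' @export
element_cpg_scores <- function(genome, instances, window = 200, step = 10) {
  res <- lapply(seq_len(nrow(instances)), function(i) {
    s <- element_sequence(genome, instances$chrom[i], instances$start[i],
                          instances$end[i], instances$strand[i])
    max_window_cpg_score(s, window, step)
  })
  data.frame(instance_id = instances$instance_id,
             subfamily = instances$subfamily,
             max_score = vapply(res, function(r) as.numeric(r$max_score), numeric(1)),
             best_offset = vapply(res, function(r) as.integer(r$best_offset), integer(1)),
             n_windows = vapply(res, function(r) as.integer(r$n_windows), integer(1)),
             stringsAsFactors = FALSE)
}

#' Per-subfamily CpG summary joined with variably methylated status
#'
#' For each subfamily with at least `min_copy` scored elements: the mean of
#' per-element maximum window scores, the count of elements overlapping
#' (>= 1 bp) any variably methylated (VM) locus, and the VM fraction.
#' Low-copy subfamilies are skipped and listed in the `"skipped"` attribute.
#'
#' @param instances repeat instance data.frame.
#' @param element_scores data.frame from [element_cpg_scores()].
#' @param vm_loci interval data.frame of VM loci.
#' @param min_copy minimum copies per reported subfamily (default 50).
#' @return data.frame `subfamily`, `n_elements`, `mean_max_score`,
#'   `vm_count`, `vm_fraction`.
#' @export
subfamily_cpg_summary <- function(instances, element_scores, vm_loci,
                                  min_copy = 50) {
  scored <- merge(instances, element_scores[, c("instance_id", "max_score")],
                  by = "instance_id")
  is_vm <- rep(FALSE, nrow(scored))
  if (nrow(vm_loci) > 0L && nrow(scored) > 0L) {
    hits <- GenomicRanges::countOverlaps(as_granges(scored),
                                         as_granges(vm_loci),
                                         ignore.strand = TRUE)
    is_vm <- hits > 0L
  }
  tab <- split(seq_len(nrow(scored)), scored$subfamily)
  keep <- names(tab)[lengths(tab) >= min_copy]
  skipped <- setdiff(names(tab), keep)
  out <- do.call(rbind, lapply(keep, function(sf) {
    i <- tab[[sf]]
    data.frame(subfamily = sf, n_elements = length(i),
               mean_max_score = mean(scored$max_score[i]),
               vm_count = sum(is_vm[i]),
               vm_fraction = mean(is_vm[i]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(subfamily = character(), n_elements = integer(),
                      mean_max_score = numeric(), vm_count = integer(),
                      vm_fraction = numeric(), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Length-matched random background CpG scores
#'
#' For each instance, samples `n_per_instance` random intervals of identical
#' length uniformly over all valid placements in the genome and scores them
#' with [max_window_cpg_score()]. Deterministic given `seed`.
#'
#' @param genome DNAStringSet.
#' @param instances repeat instance data.frame.
#' @param seed RNG seed.
#' @param n_per_instance samples per instance (default 1).
#' @param window,step window parameters.
#' @return data.frame `source_id`, `chrom`, `start`, `end`, `max_score`.
#' @export
sample_background_scores <- function(genome, instances, seed,
                                     n_per_instance = 1,
                                     window = 200, step = 10) {
  sizes <- genome_sizes(genome)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(instances)), function(i) {
      L <- instances$end[i] - instances$start[i]
      valid <- sizes - L + 1
      if (all(valid <= 0))
        stop_vmte("no chromosome can hold a %d bp interval", L)
      do.call(rbind, lapply(seq_len(n_per_instance), function(j) {
        p <- pmax(valid, 0)
        ch <- sample(names(sizes), 1, prob = p / sum(p))
        st <- sample.int(valid[[ch]], 1) - 1L
        data.frame(source_id = instances$instance_id[i], chrom = ch,
                   start = st, end = st + L, stringsAsFactors = FALSE)
      }))
    })
    bg <- do.call(rbind, rows)
    bg$max_score <- vapply(seq_len(nrow(bg)), function(i) {
      s <- element_sequence(genome, bg$chrom[i], bg$start[i], bg$end[i], "+")
      max_window_cpg_score(s, window, step)$max_score
    }, numeric(1))
    bg
  })
}
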