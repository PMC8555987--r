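#' Mean methylation of one region in one sample
#'
#' CpGs inside the region with `total > min_cov` reads (strict, so exactly
#' `min_cov` reads is dropped) are retained; the value is the unweighted
#' mean of their per-CpG methylated fractions. `NA` (undefined) when no
#' CpG survives the filter.
#'
#' @param calls methylation call data.frame (see
#'   [read_methylation_calls()]).
#' @param region single-row interval data.frame (`chrom`, `start`, `end`).
#' @param sample sample id.
#' @param min_cov coverage threshold, strict (default 5).
#' @return list with `n_cpgs_retained` and `mean_fraction` (`NA` when 0).
#' @export
element_methylation <- function(calls, region, sample, min_cov = 5) {
  sel <- calls[calls$sample == sample & calls$chrom == region$chrom &
                 calls$pos >= region$start & calls$pos < region$end &
                 calls$total > min_cov, , drop = FALSE]
  if (nrow(sel) == 0L)
    return(list(n_cpgs_retained = 0L, mean_fraction = NA_real_))
  list(n_cpgs_retained = nrow(sel),
       mean_fraction = mean(sel$methylated / sel$total))
}

#' Per-region, per-sample methylation table
#'
#' @param calls methylation call data.frame.
#' @param regions interval data.frame with a `name` (region id) column.
#' @param samples sample ids; defaults to all samples in `calls`.
#' @param min_cov coverage threshold (strict).
#' @return data.frame `region_id`, `sample`, `n_cpgs_retained`,
#'   `mean_fraction`.
#' @export
region_methylation_table <- function(calls, regions, samples = NULL,
                                     min_cov = 5) {
  samples <- samples %||% sort(unique(calls$sample))
  out <- list()
  for (s in samples) {
    for (i in seq_len(nrow(regions))) {
      em <- element_methylation(calls, regions[i, ], s, min_cov)
      out[[length(out) + 1L]] <- data.frame(
        region_id = regions$name[i] %||% sprintf("region%d", i), sample = s,
        n_cpgs_retained = em$n_cpgs_retained,
        mean_fraction = em$mean_fraction, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Compare methylation between region groups
#'
#' Summarizes each region set per sample and compares the defined
#' per-region mean fractions of the first two groups with
#' [wilcoxon_rank_sum()]. Undefined regions (no retained CpG) are excluded
#' from the test and counted in the report.
#'
#' @param calls methylation call data.frame.
#' @param region_sets named list (>= 2) of interval data.frames.
#' @param samples sample ids; defaults to all in `calls`.
#' @param min_cov coverage threshold.
#' @return list with `values` (named list of numeric vectors), `test`
#'   (list from [wilcoxon_rank_sum()], first two groups), `n_undefined`
#'   per group.
#' @export
region_group_methylation <- function(calls, region_sets, samples = NULL,
                                     min_cov = 5) {
  if (length(region_sets) < 2L) stop_vmte("need >= 2 region sets")
  tabs <- lapply(region_sets, function(rs)
    region_methylation_table(calls, rs, samples, min_cov))
  values <- lapply(tabs, function(t) t$mean_fraction[!is.na(t$mean_fraction)])
  n_undef <- vapply(tabs, function(t) sum(is.na(t$mean_fraction)), 1L)
  if (length(values[[1]]) < 2L || length(values[[2]]) < 2L)
    stop_vmte("a region group has fewer than 2 defined methylation values")
  list(values = values,
       test = wilcoxon_rank_sum(values[[1]], values[[2]]),
       n_undefined = n_undef)
}

#' Replicate-consistent merged peaks
#'
#' All replicate peaks are union-merged into maximal non-overlapping
#' intervals; each merged interval's support is the number of distinct
#' replicates contributing at least one overlapping peak. Merged peaks with
#' support below `min_support` are dropped, as are peaks overlapping the
#' optional exclusion set (unmappable "dead zones").
#'
#' @param peak_sets_by_replicate named list (replicate -> peak data.frame).
#' @param min_support minimum replicate support (default 2).
#' @param exclusion_bed optional interval data.frame to exclude.
#' @return interval data.frame with a `support` column.
#' @export
reproducible_peaks <- function(peak_sets_by_replicate, min_support = 2,
                               exclusion_bed = NULL) {
  nonempty <- Filter(function(p) !is.null(p) && nrow(p) > 0L,
                     peak_sets_by_replicate)
  if (length(nonempty) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), support = integer(),
                      stringsAsFactors = FALSE))
  all_gr <- do.call(c, unname(lapply(nonempty, as_granges)))
  GenomicRanges::strand(all_gr) <- "*"
  merged <- GenomicRanges::reduce(all_gr)
  support <- Reduce(`+`, lapply(nonempty, function(p)
    as.integer(GenomicRanges::countOverlaps(merged, as_granges(p),
                                            ignore.strand = TRUE) > 0L)))
  keep <- support >= min_support
  merged <- merged[keep]; support <- support[keep]
  if (!is.null(exclusion_bed) && nrow(exclusion_bed) > 0L && length(merged)) {
    drop <- GenomicRanges::countOverlaps(merged, as_granges(exclusion_bed),
                                         ignore.strand = TRUE) > 0L
    merged <- merged[!drop]; support <- support[!drop]
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
             start = GenomicRanges::start(merged) - 1L,
             end = GenomicRanges::end(merged),
             support = support, stringsAsFactors = FALSE)
}

#' Novel peaks: mutant-only with a signal-ratio gate
#'
#' Keeps mutant merged peaks with zero overlap against any wild-type merged
#' peak whose mean mutant/WT coverage ratio over the peak interval (with a
#' pseudocount on both terms) reaches `ratio_thr`.
#'
#' @param mut_merged,wt_merged merged peak data.frames
#'   (see [reproducible_peaks()]).
#' @param mut_track,wt_track depth-normalized `CoverageTrack`s.
#' @param ratio_thr minimum ratio (default 3).
#' @param pseudocount added to both means (default 0.5).
#' @return data.frame `chrom`, `start`, `end`, `mutant_mean`, `wt_mean`,
#'   `ratio`.
#' @export
novel_peaks <- function(mut_merged, wt_merged, mut_track, wt_track,
                        ratio_thr = 3, pseudocount = 0.5) {
  if (nrow(mut_merged) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      mutant_mean = numeric(), wt_mean = numeric(),
                      ratio = numeric(), stringsAsFactors = FALSE))
  no_wt <- if (nrow(wt_merged) == 0L) rep(TRUE, nrow(mut_merged)) else
    GenomicRanges::countOverlaps(as_granges(mut_merged),
                                 as_granges(wt_merged),
                                 ignore.strand = TRUE) == 0L
  cand <- mut_merged[no_wt, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      mutant_mean = numeric(), wt_mean = numeric(),
                      ratio = numeric(), stringsAsFactors = FALSE))
  mm <- vapply(seq_len(nrow(cand)), function(i)
    mean(track_slice(mut_track, cand$chrom[i], cand$start[i], cand$end[i])),
    numeric(1))
  wm <- vapply(seq_len(nrow(cand)), function(i)
    mean(track_slice(wt_track, cand$chrom[i], cand$start[i], cand$end[i])),
    numeric(1))
  ratio <- (mm + pseudocount) / (wm + pseudocount)
  keep <- ratio >= ratio_thr
  data.frame(chrom = cand$chrom[keep], start = cand$start[keep],
             end = cand$end[keep], mutant_mean = mm[keep],
             wt_mean = wm[keep], ratio = ratio[keep],
             stringsAsFactors = FALSE)
}

#' Annotate novel loci by TE subfamily and age bin
#'
#' Each novel peak is assigned to the TE it overlaps most (ties leftmost)
#' or to `"non-TE"`; subfamilies missing from the age table are
#' `"unannotated"`.
#'
#' @param novel data.frame of novel peaks.
#' @param te_instances repeat instance data.frame.
#' @param subfamily_ages data.frame `subfamily`, `age`.
#' @param bin_edges increasing numeric vector of age-bin edges.
#' @return list with `per_peak` (assignment per peak), `by_subfamily` and
#'   `by_age_bin` count tables.
#' @export
annotate_novel_loci <- function(novel, te_instances, subfamily_ages,
                                bin_edges) {
  if (nrow(novel) == 0L)
    return(list(per_peak = data.frame(), by_subfamily = table(character()),
                by_age_bin = table(character())))
  idx <- assign_loci_to_te(as_granges(novel), as_granges(te_instances))
  subfam <- ifelse(is.na(idx), "non-TE", te_instances$subfamily[idx])
  ages <- setNames(subfamily_ages$age, subfamily_ages$subfamily)
  age <- unname(ages[subfam])
  nb <- length(bin_edges) - 1L
  bin_names <- sprintf("[%g,%g)", bin_edges[-length(bin_edges)], bin_edges[-1])
  bin_i <- findInterval(age, bin_edges)
  bin <- ifelse(subfam == "non-TE", "non-TE",
                ifelse(is.na(age), "unannotated",
                       ifelse(bin_i >= 1L & bin_i <= nb, bin_names[bin_i],
                              "unannotated")))
  per_peak <- cbind(novel, data.frame(subfamily = subfam, age_bin = bin,
                                      stringsAsFactors = FALSE))
  list(per_peak = per_peak,
       by_subfamily = table(subfam),
       by_age_bin = table(bin))
}

#' Compare CpG scores of expression-responsive vs non-responsive subfamilies
#'
#' Responsive subfamilies are those with `padj < padj_thr` and
#' `log2FC > 0` in the differential-expression table; they are compared to
#' an equal-size seeded uniform sample of non-responsive subfamilies on
#' mean maximum CpG score. When fewer non-responsive subfamilies exist than
#' responsive ones, all are used with a warning.
#'
#' @param de_table data.frame `subfamily`, `log2FC`, `padj`.
#' @param subfamily_summaries data.frame from [subfamily_cpg_summary()].
#' @param padj_thr adjusted-p threshold (default 0.05).
#' @param seed RNG seed for the comparison sample.
#' @return list with `responsive`, `comparison` (subfamily vectors),
#'   `responsive_scores`, `comparison_scores`, `test`.
#' @export
responsive_subfamily_cpg_compare <- function(de_table, subfamily_summaries,
                                             padj_thr = 0.05, seed = 1) {
  scores <- setNames(subfamily_summaries$mean_max_score,
                     subfamily_summaries$subfamily)
  de <- de_table[de_table$subfamily %in% names(scores), , drop = FALSE]
  resp <- de$subfamily[de$padj < padj_thr & de$log2FC > 0]
  if (length(resp) == 0L)
    stop_vmte("no responsive subfamilies at padj < %g", padj_thr)
  nonresp <- setdiff(names(scores), resp)
  if (length(nonresp) < length(resp)) {
    warning("fewer non-responsive than responsive subfamilies; using all")
    comp <- nonresp
  } else {
    comp <- with_seed(seed, sort(sample(nonresp, length(resp))))
  }
  rs <- unname(scores[resp]); cs <- unname(scores[comp])
  list(responsive = resp, comparison = comp,
       responsive_scores = rs, comparison_scores = cs,
       test = wilcoxon_rank_sum(rs, cs))
}
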