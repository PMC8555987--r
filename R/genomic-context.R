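#' Constitutively expressed genes from an FPKM matrix
#'
#' A gene is constitutive when its FPKM exceeds `fpkm_thr` in strictly more
#' than `sample_frac` of samples (both comparisons strict, so 9/10 samples
#' at the 0.9 default is excluded while 10/11 passes).
#'
#' @param expression list with `gene_id` and `fpkm` matrix
#'   (see [read_fpkm_matrix()]).
#' @param fpkm_thr FPKM threshold (default 2).
#' @param sample_frac sample fraction threshold (default 0.9).
#' @return character vector of constitutive gene ids.
#' @export
constitutive_genes <- function(expression, fpkm_thr = 2, sample_frac = 0.9) {
  m <- as.matrix(expression$fpkm)
  if (ncol(m) == 0L) stop_vmte("expression matrix has zero samples")
  frac <- rowMeans(m > fpkm_thr)
  expression$gene_id[frac > sample_frac]
}

#' Distance from each query interval to its nearest feature
#'
#' Edge-to-edge gap in bp: 0 for any overlap (or adjacency), otherwise
#' `max(start_a, start_b) - min(end_a, end_b)`; `NA` when the feature set
#' is empty. Strand is ignored.
#'
#' @param intervals query interval data.frame.
#' @param features feature interval data.frame.
#' @return numeric vector of distances, one per query.
#' @export
nearest_distance <- function(intervals, features) {
  n <- nrow(intervals)
  if (is.null(features) || nrow(features) == 0L) return(rep(NA_real_, n))
  q <- as_granges(intervals)
  f <- as_granges(features)
  hit <- suppressWarnings(
    GenomicRanges::distanceToNearest(q, f, ignore.strand = TRUE))
  out <- rep(NA_real_, n)
  out[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  out
}

#' Classify elements by genomic context
#'
#' Precedence: an element within `gene_dist` bp (inclusive) of a
#' constitutive gene is `constitutive_proximal`; otherwise, strictly less
#' than `enh_dist` bp from an enhancer is `enhancer_proximal`; otherwise
#' `distal`. The two boundary conventions differ deliberately ("within
#' 50 kb" vs "less than 1 kb").
#'
#' @param instances repeat instance data.frame.
#' @param genes interval data.frame of constitutive genes.
#' @param enhancers interval data.frame of enhancers.
#' @param gene_dist gene proximity threshold, inclusive (default 50000).
#' @param enh_dist enhancer proximity threshold, exclusive (default 1000).
#' @return data.frame `instance_id`, `class`, `dist_gene`, `dist_enhancer`.
#' @export
classify_context <- function(instances, genes, enhancers,
                             gene_dist = 50000, enh_dist = 1000) {
  dg <- nearest_distance(instances, genes)
  de <- nearest_distance(instances, enhancers)
  class <- ifelse(!is.na(dg) & dg <= gene_dist, "constitutive_proximal",
                  ifelse(!is.na(de) & de < enh_dist, "enhancer_proximal",
                         "distal"))
  data.frame(instance_id = instances$instance_id, class = class,
             dist_gene = dg, dist_enhancer = de, stringsAsFactors = FALSE)
}

#' Context class fractions for two element groups
#'
#' @param calls data.frame from [classify_context()].
#' @param group_a_ids,group_b_ids instance id vectors (e.g. VM vs non-VM).
#' @return data.frame with one row per group x class: `group`, `class`,
#'   `n`, `fraction` (fractions sum to 1 within each group).
#' @export
context_fraction_compare <- function(calls, group_a_ids, group_b_ids) {
  groups <- list(group_a = group_a_ids, group_b = group_b_ids)
  lv <- c("constitutive_proximal", "enhancer_proximal", "distal")
  out <- do.call(rbind, lapply(names(groups), function(g) {
    ids <- groups[[g]]
    if (length(ids) == 0L) stop_vmte("empty group: %s", g)
    miss <- setdiff(ids, calls$instance_id)
    if (length(miss)) stop_vmte("ids not in context calls: %s", miss[1])
    cls <- factor(calls$class[match(ids, calls$instance_id)], levels = lv)
    tab <- table(cls)
    data.frame(group = g, class = lv, n = as.integer(tab),
               fraction = as.numeric(tab) / length(ids),
               stringsAsFactors = FALSE)
  }))
  out
}

#' Sweep FPKM and distance thresholds for constitutive proximity
#'
#' Full factorial evaluation of the fraction of each group that is within
#' `gene_dist` of a constitutive gene, across a grid of FPKM thresholds and
#' gene distances.
#'
#' @param instances repeat instance data.frame.
#' @param expression FPKM expression list.
#' @param gene_intervals interval data.frame with a `name` column matching
#'   `expression$gene_id`.
#' @param fpkm_grid,dist_grid numeric grids.
#' @param groups named list of instance id vectors.
#' @param sample_frac passed to [constitutive_genes()].
#' @return data.frame `fpkm_thr`, `gene_dist`, `group`, `fraction_proximal`.
#' @export
threshold_sweep <- function(instances, expression, gene_intervals,
                            fpkm_grid, dist_grid, groups,
                            sample_frac = 0.9) {
  if (!length(fpkm_grid) || !length(dist_grid)) stop_vmte("empty sweep grid")
  out <- list()
  for (fp in fpkm_grid) {
    cg <- constitutive_genes(expression, fpkm_thr = fp,
                             sample_frac = sample_frac)
    gi <- gene_intervals[gene_intervals$name %in% cg, , drop = FALSE]
    dg <- nearest_distance(instances, gi)
    for (dd in dist_grid) {
      prox <- !is.na(dg) & dg <= dd
      for (g in names(groups)) {
        i <- match(groups[[g]], instances$instance_id)
        out[[length(out) + 1L]] <- data.frame(
          fpkm_thr = fp, gene_dist = dd, group = g,
          fraction_proximal = mean(prox[i]), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
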