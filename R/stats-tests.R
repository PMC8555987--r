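#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by probability-mass summation: with margins fixed, the
#' hypergeometric probabilities of all tables no more probable than the
#' observed one (relative tie tolerance 1e-7) are summed. A table with a
#' zero margin carries no information and returns p = 1 by convention.
#'
#' @param table 2x2 integer matrix (rows: in-group / out-group, columns:
#'   e.g. VM / not-VM).
#' @return list with `p_two_sided`, `odds_ratio` (sample odds ratio; can be
#'   infinite or NaN with zero cells), `method`, `n`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) ||
      any(table != round(table)))
    stop_vmte("need a 2x2 table of non-negative integers")
  n <- sum(table)
  if (n == 0L) stop_vmte("empty table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(p_two_sided = 1, odds_ratio = NA_real_,
                method = "fisher_exact", n = n))
  }
  r1 <- sum(table[1, ]); c1 <- sum(table[, 1])
  a_range <- max(0L, r1 + c1 - n):min(r1, c1)
  # log-space hypergeometric mass over all tables with these margins
  logp <- lchoose(c1, a_range) + lchoose(n - c1, r1 - a_range) -
    lchoose(n, r1)
  probs <- exp(logp)
  p_obs <- probs[match(table[1, 1], a_range)]
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(p_two_sided = p,
       odds_ratio = (table[1, 1] * table[2, 2]) /
         (table[1, 2] * table[2, 1]),
       method = "fisher_exact", n = n)
}

#' Per-clade enrichment of variably methylated elements
#'
#' For each clade, a 2x2 table of (in-clade vs rest) x (VM vs not-VM) is
#' tested with [fisher_exact()]; the reported odds ratio is the sample odds
#' ratio with a Haldane correction (+0.5 to every cell) when any cell is 0.
#'
#' @param clades named vector instance_id -> clade label (>= 2 clades).
#' @param vm_status named logical vector instance_id -> is VM.
#' @return data.frame `clade`, `a`, `b`, `c`, `d`, `odds_ratio`, `p`.
#' @export
clade_vm_enrichment <- function(clades, vm_status) {
  ids <- names(clades)
  if (is.null(ids) || any(!ids %in% names(vm_status)))
    stop_vmte("every instance needs both a clade and a VM label")
  vm <- vm_status[ids]
  labs <- sort(unique(clades))
  if (length(labs) < 2L) stop_vmte("need >= 2 clades for an enrichment contrast")
  do.call(rbind, lapply(labs, function(cl) {
    inc <- clades == cl
    a <- sum(inc & vm); b <- sum(inc & !vm)
    c_ <- sum(!inc & vm); d <- sum(!inc & !vm)
    tab <- matrix(c(a, c_, b, d), 2)
    or <- if (any(tab == 0)) ((a + .5) * (d + .5)) / ((b + .5) * (c_ + .5))
          else (a * d) / (b * c_)
    data.frame(clade = cl, a = a, b = b, c = c_, d = d, odds_ratio = or,
               p = fisher_exact(tab)$p_two_sided, stringsAsFactors = FALSE)
  }))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact two-sided p by enumeration when `n_x + n_y <= 20` and there are no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction. The statistic is the Mann-Whitney U for `x`.
#' When all values are identical across both samples, p = 1 by convention.
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (U), `p_two_sided`, `method`, `n`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop_vmte("both samples must be non-empty")
  n <- length(x) + length(y)
  if (length(unique(c(x, y))) == 1L) {
    return(list(statistic = length(x) * length(y) / 2, p_two_sided = 1,
                method = "wilcoxon_rank_sum", n = n))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n <= 20L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  list(statistic = unname(wt$statistic), p_two_sided = min(1, p),
       method = if (exact) "wilcoxon_exact" else "wilcoxon_normal_approx",
       n = n)
}

# Assign each locus to the overlapped TE with the largest overlap
# (ties -> leftmost TE); returns the TE row index per locus (NA = no overlap).
assign_loci_to_te <- function(loci_gr, te_gr) {
  hits <- GenomicRanges::findOverlaps(loci_gr, te_gr, ignore.strand = TRUE)
  if (length(hits) == 0L) return(rep(NA_integer_, length(loci_gr)))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(loci_gr)[qh], IRanges::ranges(te_gr)[sh]))
  starts <- GenomicRanges::start(te_gr)[sh]
  ord <- order(qh, -ov, starts, sh)
  qh <- qh[ord]; sh <- sh[ord]
  first <- !duplicated(qh)
  out <- rep(NA_integer_, length(loci_gr))
  out[qh[first]] <- sh[first]
  out
}

#' Observed/expected age-bin enrichment of VM loci
#'
#' Each VM locus overlapping at least one TE is assigned to the overlapped
#' TE with the largest overlap (ties to the leftmost), then to that TE
#' subfamily's age bin. The expected distribution comes from `R` replicate
#' sets of uniformly placed, length-matched random loci; per bin,
#' `oe = observed / mean(null counts)` with an empirical 95% interval of
#' the null counts.
#'
#' @param vm_loci interval data.frame of VM loci.
#' @param te_instances repeat instance data.frame with `subfamily`.
#' @param subfamily_ages data.frame `subfamily`, `age` (same units as
#'   `bin_edges`, e.g. My).
#' @param bin_edges increasing numeric vector; bins are
#'   `[e1,e2), [e2,e3), ...`; ages outside the edges are unassigned.
#' @param chrom_sizes named integer vector.
#' @param R number of null replicates (default 1000; < 100 warns).
#' @param seed RNG seed.
#' @return data.frame per bin: `bin`, `observed`, `expected`, `oe`,
#'   `null_lo`, `null_hi`; attributes `unassigned` (observed loci not on a
#'   binned TE) and `R`, `seed`.
#' @export
oe_age_enrichment <- function(vm_loci, te_instances, subfamily_ages,
                              bin_edges, chrom_sizes, R = 1000, seed = 1) {
  if (R < 100) warning("R < 100 gives unstable null intervals")
  lens <- vm_loci$end - vm_loci$start
  if (any(lens > max(chrom_sizes)))
    stop_vmte("a VM locus is longer than every chromosome")
  ages <- setNames(subfamily_ages$age, subfamily_ages$subfamily)
  te_age <- ages[te_instances$subfamily]
  nb <- length(bin_edges) - 1L
  bin_names <- sprintf("[%g,%g)", bin_edges[-length(bin_edges)], bin_edges[-1])
  te_bin <- findInterval(te_age, bin_edges, rightmost.closed = FALSE)
  te_bin[is.na(te_age) | te_bin < 1L | te_bin > nb] <- NA_integer_
  te_gr <- as_granges(te_instances)

  count_bins <- function(loci_df) {
    idx <- assign_loci_to_te(as_granges(loci_df), te_gr)
    bins <- te_bin[idx[!is.na(idx)]]
    counts <- tabulate(bins[!is.na(bins)], nbins = nb)
    list(counts = counts,
         unassigned = nrow(loci_df) - sum(!is.na(idx) & !is.na(te_bin[idx])))
  }
  obs <- count_bins(vm_loci)

  # Uniform placement over all valid start positions genome-wide: a
  # chromosome is chosen proportional to its number of valid placements for
  # the locus length, then a start uniform within it. Vectorized per
  # replicate over loci.
  sizes <- as.numeric(chrom_sizes)
  nchrom <- length(sizes)
  valid <- outer(sizes, lens, function(s, l) pmax(s - l + 1, 0)) # chrom x locus
  tot <- colSums(valid)
  if (any(tot <= 0)) stop_vmte("a VM locus is longer than every chromosome")
  cumv <- matrix(apply(valid, 2, cumsum), nrow = nchrom)         # chrom x locus
  null_counts <- with_seed(seed, {
    raw <- vapply(seq_len(R), function(r) {
      u <- runif(length(lens)) * tot
      ch <- rep(1L, length(lens))
      if (nchrom > 1L) for (k in seq_len(nchrom - 1L))
        ch <- ch + as.integer(u > cumv[k, ])
      lo <- ifelse(ch > 1L, cumv[cbind(ch - 1L, seq_along(lens))], 0)
      st <- as.integer(floor(u - lo))                 # 0 .. valid[ch,i]-1
      st <- pmin(st, as.integer(valid[cbind(ch, seq_along(lens))] - 1))
      df <- data.frame(chrom = names(chrom_sizes)[ch], start = st,
                       end = st + lens, stringsAsFactors = FALSE)
      count_bins(df)$counts
    }, numeric(nb))
    # replicates in rows, bins in columns (robust to nb == 1)
    t(matrix(raw, nrow = nb))
  })
  expected <- colMeans(null_counts)
  qs <- apply(null_counts, 2, quantile, probs = c(0.025, 0.975))
  out <- data.frame(bin = bin_names, observed = obs$counts,
                    expected = expected,
                    oe = ifelse(expected > 0, obs$counts / expected, NA_real_),
                    null_lo = unname(qs[1, ]), null_hi = unname(qs[2, ]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "unassigned") <- obs$unassigned
  attr(out, "R") <- R
  attr(out, "seed") <- seed
  out
}
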