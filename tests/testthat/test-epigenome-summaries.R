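mk_calls <- function(pos, meth, total, sample = "s1", chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, methylated = meth, total = total,
             sample = sample, fraction = meth / total,
             stringsAsFactors = FALSE)
}

region <- function(start, end, name = "r1")
  data.frame(chrom = "chr1", start = start, end = end, name = name,
             stringsAsFactors = FALSE)

test_that("element methylation applies the strict coverage filter", {
  calls <- mk_calls(c(10, 20, 30), c(5, 0, 10), c(10, 4, 10))
  em <- element_methylation(calls, region(0, 100), "s1", min_cov = 5)
  expect_equal(em$n_cpgs_retained, 2L)       # the 4-read CpG is dropped
  expect_equal(em$mean_fraction, 0.75)       # (0.5 + 1.0) / 2
  # exactly min_cov reads is dropped (strict >)
  em5 <- element_methylation(mk_calls(10, 3, 5), region(0, 100), "s1")
  expect_equal(em5$n_cpgs_retained, 0L)
  expect_true(is.na(em5$mean_fraction))
})

test_that("element methylation ignores CpG order and outside positions", {
  inside <- mk_calls(c(10, 50, 90), c(2, 4, 6), c(10, 10, 10))
  outside <- mk_calls(c(150, 300), c(10, 0), c(10, 10))
  em1 <- element_methylation(rbind(inside, outside), region(0, 100), "s1")
  em2 <- element_methylation(rbind(outside, inside[3:1, ]),
                             region(0, 100), "s1")
  expect_equal(em1, em2)
  expect_equal(em1$mean_fraction, 0.4)
  # half-open region: position == end is outside
  em3 <- element_methylation(mk_calls(100, 5, 10), region(0, 100), "s1")
  expect_equal(em3$n_cpgs_retained, 0L)
})

test_that("region group comparison separates planted regimes", {
  ds <- get_small_dataset()
  st <- ds$truth$vm_status
  prim <- ds$instances[ds$instances$subfamily == "SynLTR1", ]
  prim$name <- prim$instance_id
  esc <- prim[st[prim$instance_id] == "escaped", ]
  sil <- prim[st[prim$instance_id] == "silenced", ]
  res <- region_group_methylation(ds$methylation,
                                  list(escaped = esc, silenced = sil))
  expect_lt(mean(res$values$escaped), mean(res$values$silenced))
  expect_lt(res$test$p_two_sided, 0.05)
  expect_error(region_group_methylation(ds$methylation, list(a = esc)),
               ">= 2 region sets")
})

peak <- function(start, end, chrom = "chr1")
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)

test_that("reproducible peaks merge, count support and filter", {
  sets <- list(A = peak(100, 200), B = peak(150, 250), C = peak(300, 400))
  merged <- reproducible_peaks(sets, min_support = 2)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 100L)
  expect_equal(merged$end, 250L)
  expect_equal(merged$support, 2L)
  # identical peaks in three replicates
  same <- list(A = peak(10, 50), B = peak(10, 50), C = peak(10, 50))
  m3 <- reproducible_peaks(same, 2)
  expect_equal(m3$support, 3L)
  # exclusion removes overlapping merged peaks
  excl <- reproducible_peaks(sets, 2, exclusion_bed = peak(240, 260))
  expect_equal(nrow(excl), 0L)
  # output intervals are disjoint
  many <- list(A = peak(c(0, 90, 300), c(50, 120, 350)),
               B = peak(c(40, 310), c(100, 360)))
  mm <- reproducible_peaks(many, 1)
  expect_true(all(mm$start[-1] >= mm$end[-nrow(mm)]))
})

test_that("novel peaks require WT absence and the signal ratio", {
  sizes <- c(chr1 = 1000L)
  mut_tr <- coverage_track(sizes); wt_tr <- coverage_track(sizes)
  mut_tr$chr1[101:200] <- 9; wt_tr$chr1[101:200] <- 2     # ratio 3.8
  mut_tr$chr1[301:400] <- 4; wt_tr$chr1[301:400] <- 2     # ratio 1.8
  mut_tr$chr1[501:600] <- 50
  mut_merged <- peak(c(100, 300, 500), c(200, 400, 600))
  wt_merged <- peak(590, 650)                             # overlaps 3rd
  nv <- novel_peaks(mut_merged, wt_merged, mut_tr, wt_tr,
                    ratio_thr = 3, pseudocount = 0.5)
  expect_equal(nv$start, 100L)
  expect_equal(nv$ratio, 9.5 / 2.5)
  # ratio recomputable from the tracks bit-for-bit
  expect_equal(nv$ratio,
               (mean(mut_tr$chr1[101:200]) + 0.5) /
                 (mean(wt_tr$chr1[101:200]) + 0.5))
})

test_that("novel loci annotate to the largest-overlap TE or non-TE", {
  te <- rbind(
    data.frame(instance_id = "t1", chrom = "chr1", start = 0L, end = 500L,
               strand = "+", subfamily = "YOUNG", family = "F"),
    data.frame(instance_id = "t2", chrom = "chr1", start = 600L, end = 900L,
               strand = "+", subfamily = "OLD", family = "F"))
  ages <- data.frame(subfamily = c("YOUNG", "OLD"), age = c(5, 80))
  nv <- peak(c(100, 950), c(200, 990))
  ann <- annotate_novel_loci(nv, te, ages, c(0, 10, 100))
  expect_equal(ann$per_peak$subfamily, c("YOUNG", "non-TE"))
  expect_equal(sum(ann$by_subfamily), nrow(nv))
  expect_equal(unname(ann$by_age_bin[ann$per_peak$age_bin[1]]), 1L)
})

test_that("responsive subfamily comparison is seeded and directional", {
  summaries <- data.frame(
    subfamily = sprintf("S%d", 1:16),
    n_elements = 20, mean_max_score = c(rep(1.8, 5), rep(0.4, 11)),
    vm_count = 0, vm_fraction = 0, stringsAsFactors = FALSE)
  de <- data.frame(subfamily = sprintf("S%d", 1:16),
                   log2FC = c(rep(2, 5), rep(0, 11)),
                   padj = c(rep(1e-5, 5), rep(0.8, 11)),
                   stringsAsFactors = FALSE)
  r1 <- responsive_subfamily_cpg_compare(de, summaries, seed = 3)
  r2 <- responsive_subfamily_cpg_compare(de, summaries, seed = 3)
  expect_identical(r1$comparison, r2$comparison)
  expect_equal(sort(r1$responsive), sprintf("S%d", 1:5))
  expect_gt(median(r1$responsive_scores), median(r1$comparison_scores))
  expect_lt(r1$test$p_two_sided, 0.05)
  de0 <- de; de0$padj <- 1
  expect_error(responsive_subfamily_cpg_compare(de0, summaries),
               "no responsive")
})
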