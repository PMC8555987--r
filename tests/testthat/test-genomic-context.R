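iv <- function(start, end, chrom = "chr1", name = NULL) {
  df <- data.frame(chrom = rep_len(chrom, length(start)), start = start,
                   end = end, stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- name
  df
}

inst <- function(start, end, id, strand = "+") {
  data.frame(instance_id = id, chrom = "chr1", start = start, end = end,
             strand = strand, subfamily = "S", family = "F",
             stringsAsFactors = FALSE)
}

test_that("constitutive gene filter applies both strict thresholds", {
  m10 <- rbind(c(rep(5, 9), 0),   # 9/10 = 0.90, not > 0.9 -> excluded
               rep(5, 10),        # 10/10 -> included
               rep(0, 10))        # all zero -> excluded
  rownames(m10) <- c("g1", "g2", "g3")
  expr <- list(gene_id = c("g1", "g2", "g3"), fpkm = m10)
  expect_equal(constitutive_genes(expr), "g2")
  m11 <- rbind(c(rep(5, 10), 0))  # 10/11 = 0.909 > 0.9 -> included
  rownames(m11) <- "g4"
  expect_equal(constitutive_genes(list(gene_id = "g4", fpkm = m11)), "g4")
  # FPKM exactly 2 does not pass the strict > 2
  m <- rbind(rep(2, 10)); rownames(m) <- "g5"
  expect_equal(length(constitutive_genes(list(gene_id = "g5", fpkm = m))), 0L)
  expect_error(constitutive_genes(list(gene_id = "g",
                                       fpkm = m[, 0, drop = FALSE])),
               "zero samples")
})

test_that("nearest distance is the half-open edge gap", {
  q <- iv(0, 1000)
  expect_equal(nearest_distance(q, iv(500, 1500)), 0)      # overlap
  expect_equal(nearest_distance(q, iv(2000, 3000)), 1000)
  expect_equal(nearest_distance(q, iv(1000, 1100)), 0)     # adjacency
  expect_true(is.na(nearest_distance(q, iv(integer(), integer()))))
  # feature on another chromosome does not count
  expect_true(is.na(nearest_distance(q, iv(0, 10, chrom = "chr2"))))
})

test_that("nearest distance matches brute force on random fixtures", {
  withr::local_seed(31)
  for (rep in 1:20) {
    q <- iv(sample(0:5000, 5), 0)
    q$end <- q$start + sample(50:500, 5, replace = TRUE)
    f <- iv(sample(0:5000, 8), 0)
    f$end <- f$start + sample(50:500, 8, replace = TRUE)
    expect_equal(nearest_distance(q, f), oracle_nearest(q, f))
  }
})

test_that("context classification applies precedence and boundaries", {
  genes <- iv(100000, 101000)
  enh <- iv(c(140600, 200000), c(141100, 200500))
  calls <- classify_context(
    rbind(inst(49001, 50001, "at_gene_limit"),    # gene gap 49,999
          inst(140000, 140500, "near_both"),      # gene 39 kb, enh 100 bp
          inst(900000, 900500, "far")),
    genes, enh, gene_dist = 50000, enh_dist = 1000)
  got <- setNames(calls$class, calls$instance_id)
  expect_equal(unname(got["at_gene_limit"]), "constitutive_proximal")
  # precedence: gene rule wins although the enhancer is much closer
  expect_equal(unname(got["near_both"]), "constitutive_proximal")
  # 60 kb from gene cases: enhancer rule strict less-than
  calls2 <- classify_context(
    rbind(inst(300001, 300501, "e999"), inst(300000, 300500, "e1000")),
    iv(800000, 801000), iv(301500, 301999),
    gene_dist = 50000, enh_dist = 1000)
  expect_equal(calls2$class, c("enhancer_proximal", "distal"))
  expect_equal(unname(got["far"]), "distal")
})

test_that("group context fractions sum to one per group", {
  calls <- data.frame(
    instance_id = c("a", "b", "c", "d"),
    class = c("constitutive_proximal", "constitutive_proximal",
              "enhancer_proximal", "distal"),
    dist_gene = 0, dist_enhancer = 0, stringsAsFactors = FALSE)
  cmp <- context_fraction_compare(calls, c("a", "b", "c", "d"),
                                  c("a", "b", "c", "d"))
  expect_equal(as.numeric(tapply(cmp$fraction, cmp$group, sum)), c(1, 1))
  expect_equal(cmp$fraction[cmp$group == "group_a"], c(0.5, 0.25, 0.25))
  expect_error(context_fraction_compare(calls, character(), "a"), "empty")
  expect_error(context_fraction_compare(calls, "zz", "a"), "not in context")
})

test_that("threshold sweep is monotone in both grid directions", {
  ds <- get_small_dataset()
  prim <- ds$instances[ds$instances$subfamily == "SynLTR1", ]
  groups <- list(all = prim$instance_id)
  sw <- threshold_sweep(prim, ds$context$expression, ds$context$genes,
                        fpkm_grid = c(1, 2, 60),
                        dist_grid = c(500, 2000, 5000, 20000),
                        groups = groups)
  expect_equal(nrow(sw), 12L)
  for (fp in unique(sw$fpkm_thr)) {
    fr <- sw$fraction_proximal[sw$fpkm_thr == fp][order(
      sw$gene_dist[sw$fpkm_thr == fp])]
    expect_true(all(diff(fr) >= 0))      # non-decreasing in distance
  }
  for (dd in unique(sw$gene_dist)) {
    fr <- sw$fraction_proximal[sw$gene_dist == dd][order(
      sw$fpkm_thr[sw$gene_dist == dd])]
    expect_true(all(diff(fr) <= 0))      # non-increasing in FPKM threshold
  }
})

test_that("classification ignores strand and feature order", {
  genes <- iv(c(5000, 1000), c(6000, 1500))
  i1 <- classify_context(inst(2000, 2300, "x", "+"), genes, iv(integer(0), integer(0)),
                         gene_dist = 1000, enh_dist = 100)
  i2 <- classify_context(inst(2000, 2300, "x", "-"), genes[2:1, ], iv(integer(0), integer(0)),
                         gene_dist = 1000, enh_dist = 100)
  expect_equal(i1$class, i2$class)
  expect_equal(i1$dist_gene, i2$dist_gene)
})
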