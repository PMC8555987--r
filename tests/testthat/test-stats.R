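test_that("Fisher exact reproduces hand-enumerated tables", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_two_sided, 1.0)
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2))$p_two_sided, 1 / 3)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2))$p_two_sided,
               2 / 184756)
  # zero margin -> p = 1 by convention
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2))$p_two_sided, 1)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Fisher exact agrees with enumeration and stats::fisher.test", {
  withr::local_seed(41)
  for (i in 1:300) {
    t <- matrix(rpois(4, sample(1:8, 1)), 2)
    if (sum(t) == 0) next
    p <- fisher_exact(t)$p_two_sided
    expect_equal(p, oracle_fisher_p(t), tolerance = 1e-12)
    if (all(rowSums(t) > 0) && all(colSums(t) > 0))
      expect_equal(p, stats::fisher.test(t)$p.value, tolerance = 1e-9)
  }
})

test_that("Wilcoxon reproduces enumerated examples and conventions", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_two_sided, 1 / 3)
  r2 <- wilcoxon_rank_sum(c(1, 4), c(2, 3))
  expect_equal(r2$statistic, 2)
  expect_equal(r2$p_two_sided, 1.0)
  expect_equal(wilcoxon_rank_sum(rep(3, 5), rep(3, 4))$p_two_sided, 1)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("exact Wilcoxon path equals assignment enumeration", {
  withr::local_seed(42)
  for (i in 1:40) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    vals <- sample(1000, nx + ny)          # no ties
    x <- vals[1:nx]; y <- vals[-(1:nx)]
    expect_equal(wilcoxon_rank_sum(x, y)$p_two_sided,
                 oracle_wilcoxon_p(x, y), tolerance = 1e-12)
  }
})

test_that("large-sample Wilcoxon approximates a permutation oracle", {
  withr::local_seed(43)
  x <- rnorm(25); y <- rnorm(30, 0.4)
  res <- wilcoxon_rank_sum(x, y)
  expect_equal(res$method, "wilcoxon_normal_approx")
  pool <- c(x, y)
  perm <- replicate(20000, {
    i <- sample(length(pool), length(x))
    abs(mann_whitney_u(pool[i], pool[-i]) - length(x) * length(y) / 2)
  })
  p_perm <- mean(perm >= abs(res$statistic - length(x) * length(y) / 2) - 1e-9)
  expect_lt(abs(res$p_two_sided - p_perm), 0.015)
})

test_that("clade/VM enrichment tables conserve counts and find the signal", {
  ds <- get_small_dataset()
  clades <- ds$truth$clades
  vm <- ds$truth$vm_status == "variable"
  enr <- clade_vm_enrichment(clades, vm)
  expect_true(all(enr$a + enr$b + enr$c + enr$d == length(clades)))
  esc <- sprintf("clade%d", ds$config$escape_clade)
  row <- enr[enr$clade == esc, ]
  expect_lt(row$p, 0.01)
  expect_gt(row$odds_ratio, 1)
  expect_error(clade_vm_enrichment(setNames(rep("c1", 4),
                                            names(clades)[1:4]), vm),
               ">= 2 clades")
})

test_that("random VM labels give calibrated clade enrichment p-values", {
  withr::local_seed(44)
  ids <- sprintf("e%d", 1:120)
  clades <- setNames(rep(sprintf("clade%d", 1:4), each = 30), ids)
  rates <- replicate(200, {
    vm <- setNames(sample(c(TRUE, FALSE), 120, replace = TRUE,
                          prob = c(0.25, 0.75)), ids)
    clade_vm_enrichment(clades, vm)$p < 0.05
  })
  # per-test false positive rate near (at most, Fisher is conservative) 5%
  expect_lt(mean(rates), 0.08)
})

test_that("age enrichment is seed-deterministic and conserves counts", {
  withr::local_seed(45)
  sizes <- c(chr1 = 200000L)
  te <- do.call(rbind, lapply(1:60, function(i)
    data.frame(instance_id = sprintf("t%d", i), chrom = "chr1",
               start = i * 3000L, end = i * 3000L + 1000L, strand = "+",
               subfamily = sprintf("S%d", (i %% 3) + 1), family = "F",
               stringsAsFactors = FALSE)))
  ages <- data.frame(subfamily = c("S1", "S2", "S3"), age = c(5, 30, 80))
  vm <- data.frame(chrom = "chr1", start = seq(1000, 190000, by = 5000))
  vm$end <- vm$start + 200L
  oe1 <- oe_age_enrichment(vm, te, ages, c(0, 10, 50, 100), sizes,
                           R = 150, seed = 9)
  oe2 <- oe_age_enrichment(vm, te, ages, c(0, 10, 50, 100), sizes,
                           R = 150, seed = 9)
  expect_identical(oe1, oe2)
  expect_equal(sum(oe1$observed) + attr(oe1, "unassigned"), nrow(vm))
  expect_warning(oe_age_enrichment(vm, te, ages, c(0, 10, 50, 100), sizes,
                                   R = 50, seed = 9), "unstable")
})

test_that("largest-overlap assignment breaks ties leftmost", {
  te <- rbind(
    data.frame(instance_id = "left", chrom = "chr1", start = 0L, end = 100L,
               strand = "+", subfamily = "A", family = "F"),
    data.frame(instance_id = "right", chrom = "chr1", start = 100L,
               end = 200L, strand = "+", subfamily = "B", family = "F"))
  ages <- data.frame(subfamily = c("A", "B"), age = c(5, 80))
  # locus straddles both TEs with equal 50 bp overlaps
  vm <- data.frame(chrom = "chr1", start = 50L, end = 150L)
  oe <- oe_age_enrichment(vm, te, ages, c(0, 10, 100), c(chr1 = 200L),
                          R = 100, seed = 1)
  expect_equal(oe$observed, c(1L, 0L))   # assigned to the left/young TE
})
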