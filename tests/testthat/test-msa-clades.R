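test_that("pairwise alignment reproduces worked examples", {
  r <- align_pair("ACGT", "ACGT")
  expect_equal(r$score, 4)
  expect_equal(r$aligned_a, "ACGT")
  r <- align_pair("ACGT", "AGT")
  expect_equal(r$score, 1)            # 3 matches, 1 gap
  expect_equal(r$aligned_a, "ACGT")
  expect_equal(r$aligned_b, "A-GT")
  expect_equal(align_pair("A", "T")$score, -1)   # mismatch beats two gaps
  expect_error(align_pair("", "ACGT"), "empty")
})

test_that("alignment DP matches exhaustive enumeration for short strings", {
  withr::local_seed(11)
  for (i in 1:60) {
    a <- random_dna_str(sample(1:6, 1))
    b <- random_dna_str(sample(1:6, 1))
    expect_equal(align_pair(a, b)$score, oracle_align_score(a, b),
                 info = paste(a, b))
  }
  # N is a universal mismatch
  expect_equal(align_pair("NN", "NN")$score, -2)
})

test_that("UPGMA reproduces the hand-worked merge order", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(d)
  expect_equal(tr$merges[[1]]$members, c("A", "B"))
  expect_equal(tr$merges[[1]]$height, 1)
  expect_equal(tr$merges[[2]]$height, 2)
  expect_error(upgma_tree(d - 1), "negative")
  expect_error(upgma_tree(matrix(c(0, NA, NA, 0), 2)), "NaN|NA")
})

test_that("UPGMA agrees with a brute-force oracle on random matrices", {
  withr::local_seed(5)
  for (rep in 1:100) {
    n <- sample(3:7, 1)
    m <- matrix(runif(n * n), n)
    d <- (m + t(m)) / 2; diag(d) <- 0
    dimnames(d) <- list(letters[1:n], letters[1:n])
    tr <- upgma_tree(d)
    orc <- oracle_upgma(d)
    for (k in seq_along(orc)) {
      expect_equal(tr$merges[[k]]$members, orc[[k]]$members)
      expect_equal(tr$merges[[k]]$height, orc[[k]]$height, tolerance = 1e-10)
    }
  }
})

test_that("merge heights are non-decreasing (ultrametric)", {
  withr::local_seed(6)
  for (rep in 1:30) {
    n <- sample(3:10, 1)
    m <- matrix(runif(n * n), n)
    d <- (m + t(m)) / 2; diag(d) <- 0
    tr <- upgma_tree(d)
    h <- vapply(tr$merges, `[[`, numeric(1), "height")
    expect_true(all(diff(h) >= -1e-12))
  }
})

test_that("guide tree joins the most k-mer-similar pair first", {
  seqs <- c(x = paste(rep("ACGTACGTAA", 5), collapse = ""),
            y = paste(rep("ACGTACGTAA", 5), collapse = ""),
            z = random_dna_str(50))
  withr::local_seed(2)
  tr <- build_guide_tree(seqs, k = 6)
  expect_equal(tr$merges[[1]]$members, c("x", "y"))
  expect_equal(tr$merges[[1]]$height, 0)   # identical -> distance 0
  expect_error(build_guide_tree(c(a = "ACG", b = "ACGTACG"), k = 6),
               "shorter than k")
})

test_that("progressive MSA preserves inputs and finds obvious gaps", {
  m <- progressive_msa(c(a = "ACGT", b = "AGT"))
  expect_equal(m$rows[["a"]], "ACGT")
  expect_equal(m$rows[["b"]], "A-GT")
  m2 <- progressive_msa(c(a = "ACGTA", b = "ACGTA"))
  expect_false(grepl("-", paste(m2$rows, collapse = "")))
  # de-gapping is lossless for random inputs (structural invariant)
  withr::local_seed(8)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    seqs <- setNames(vapply(seq_len(n), function(i)
      random_dna_str(sample(20:60, 1)), character(1)),
      sprintf("s%d", seq_len(n)))
    msa <- progressive_msa(seqs)
    expect_identical(vapply(msa$rows, function(r)
      gsub("-", "", r, fixed = TRUE), character(1)), seqs)
    expect_equal(unique(nchar(msa$rows)), msa$width)
  }
})

test_that("low-occupancy trimming follows the strict less-than rule", {
  rows <- setNames(c("A--A", "A--A", "A--A", "A--A", "A--A",
                     "A--A", "A--A", "A--A", "AC-A", "ACGA"),
                   sprintf("r%d", 1:10))
  msa <- vmte:::new_msa(rows)
  tr <- trim_low_occupancy_columns(msa, min_frac = 0.10)
  # col2 has 2/10 = 20% (kept), col3 has 1/10 = 10% (kept: strictly-less),
  # a 0% column would be removed
  expect_equal(tr$width, 4L)
  rows0 <- setNames(c("A-A", "A-A"), c("r1", "r2"))
  tr0 <- trim_low_occupancy_columns(vmte:::new_msa(rows0), min_frac = 0.10)
  expect_equal(tr0$width, 2L)
  expect_equal(tr0$column_map, c(1L, 3L))
  expect_error(trim_low_occupancy_columns(vmte:::new_msa(
    setNames(c("--", "--"), c("a", "b"))), 0.1), "degenerate")
})

test_that("trimming keeps a consistent column map", {
  withr::local_seed(9)
  seqs <- setNames(vapply(1:6, function(i) random_dna_str(sample(30:50, 1)),
                          character(1)), sprintf("s%d", 1:6))
  msa <- progressive_msa(seqs)
  tr <- trim_low_occupancy_columns(msa, 0.4)
  full <- vmte:::msa_matrix(msa)
  sub <- vmte:::msa_matrix(tr)
  expect_identical(full[, tr$column_map, drop = FALSE], sub,
                   ignore_attr = TRUE)
})

test_that("p-distances use comparable columns only", {
  msa <- vmte:::new_msa(setNames(c("ACGT", "ACGA", "AC-T"),
                                 c("a", "b", "c")))
  d <- pdistance_matrix(msa)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)          # 3 comparable, 0 mismatches
  expect_equal(nrow(attr(d, "low_comparable")), 3L)  # all pairs < 20 cols
  expect_error(pdistance_matrix(vmte:::new_msa(
    setNames(c("A-", "-A"), c("a", "b")))), "comparable")
})

test_that("clade cutting spans k = 1 to k = n and orders labels", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(d)
  expect_equal(unname(assign_clades(tr, 1)$clades), rep("clade1", 3))
  cl2 <- assign_clades(tr, 2)$clades
  expect_equal(unname(cl2), c("clade1", "clade1", "clade2"))
  cl3 <- assign_clades(tr, 3)$clades
  expect_equal(length(unique(cl3)), 3L)
  expect_error(assign_clades(tr, 0), "k must be")
  expect_error(assign_clades(tr, 4), "k must be")
})
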