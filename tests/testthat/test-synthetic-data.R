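test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 99)
  a <- simulate_repeat_genome(cfg)
  b <- simulate_repeat_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$instances, b$instances)
  expect_identical(a$truth$table, b$truth$table)
  expect_identical(simulate_methylation(a$truth, cfg),
                   simulate_methylation(b$truth, cfg))
  expect_identical(simulate_peaks(a$truth, cfg)$novel_truth,
                   simulate_peaks(b$truth, cfg)$novel_truth)
})

test_that("planted clade structure has the configured shape", {
  ds <- get_small_dataset()
  primary <- ds$truth$table
  expect_equal(nrow(primary), 4L * 10L)
  expect_equal(sort(unique(primary$clade)), sprintf("clade%d", 1:4))
  expect_equal(unname(table(primary$clade)), rep(10L, 4L),
               ignore_attr = TRUE)
  # every instance has exactly one truth record
  expect_false(anyDuplicated(primary$instance_id) > 0)
  # roughly half of the copies sit on the minus strand
  prim_inst <- ds$instances[ds$instances$subfamily == "SynLTR1", ]
  expect_gt(mean(prim_inst$strand == "-"), 0.2)
  expect_lt(mean(prim_inst$strand == "-"), 0.8)
})

test_that("element-oriented sequences match their clade consensus", {
  # strand handling check: the reverse complement of a minus-strand genomic
  # slice must be close to the clade consensus (2% divergence + 8
  # diagnostic sites), while the raw slice is not
  ds <- get_small_dataset()
  prim <- ds$instances[ds$instances$subfamily == "SynLTR1", ]
  cons <- strsplit(ds$truth$consensus, "")[[1]]
  mism <- function(s) mean(strsplit(s, "")[[1]] != cons)
  minus <- prim[prim$strand == "-", ][1:5, ]
  for (i in seq_len(nrow(minus))) {
    oriented <- element_sequence(ds$genome, minus$chrom[i], minus$start[i],
                                 minus$end[i], "-")
    raw <- element_sequence(ds$genome, minus$chrom[i], minus$start[i],
                            minus$end[i], "+")
    expect_lt(mism(oriented), 0.15)
    expect_gt(mism(raw), 0.4)
  }
})

test_that("noise-free binding tracks equal the clade profile heights", {
  cfg <- small_sim_config(seed = 7)
  cfg$binding_noise <- FALSE
  g <- simulate_repeat_genome(cfg)
  tracks <- simulate_binding_coverage(g$truth, cfg)
  prim <- g$instances[g$instances$subfamily == "SynLTR1", ]
  iv <- cfg$factors$KAP1
  for (i in c(1L, 2L, nrow(prim))) {
    cl <- as.integer(sub("clade", "", g$truth$clades[prim$instance_id[i]]))
    h <- cfg$binding_heights[cl]
    row <- project_element_coverage(
      tracks$KAP1, prim[i, ],
      paste(rep("A", prim$end[i] - prim$start[i]), collapse = ""))
    expect_equal(unname(row[(iv[1] + 1):iv[2]]), rep(h, iv[2] - iv[1]))
  }
})

test_that("the escape clade has the lowest mean binding signal", {
  ds <- get_small_dataset()
  prim <- ds$instances[ds$instances$subfamily == "SynLTR1", ]
  m <- vapply(seq_len(nrow(prim)), function(i)
    mean_signal_per_element(ds$binding_tracks$KAP1, prim[i, ]), numeric(1))
  clade_means <- tapply(m, ds$truth$clades[prim$instance_id], mean)
  esc <- sprintf("clade%d", ds$config$escape_clade)
  expect_equal(names(which.min(clade_means)), esc)
})

test_that("methylation regimes behave as planted", {
  ds <- get_small_dataset()
  calls <- ds$methylation
  prim <- ds$instances[ds$instances$subfamily == "SynLTR1", ]
  prim$name <- prim$instance_id
  tab <- region_methylation_table(calls, prim, min_cov = 5)
  elem_mean <- tapply(tab$mean_fraction, tab$region_id, mean, na.rm = TRUE)
  elem_sd <- tapply(tab$mean_fraction, tab$region_id, sd, na.rm = TRUE)
  st <- ds$truth$vm_status[names(elem_sd)]
  # across-individual variance separates the variable regime
  expect_gt(mean(elem_sd[st == "variable"]), mean(elem_sd[st == "silenced"]))
  # silenced elements stay methylated in every individual
  sil <- tab[tab$region_id %in% names(st)[st == "silenced"], ]
  expect_true(all(sil$mean_fraction >= 0.7, na.rm = TRUE))
  expect_lt(mean(elem_mean[st == "escaped"]), 0.3)
})

test_that("planted context constraints hold by construction", {
  ds <- get_small_dataset()
  cfg <- ds$config
  prim <- ds$instances[ds$instances$subfamily == "SynLTR1", ]
  ctxcls <- ds$truth$context_class[prim$instance_id]
  dg <- nearest_distance(prim, ds$context$genes)
  de <- nearest_distance(prim, ds$context$enhancers)
  cp <- ctxcls == "constitutive_proximal"
  expect_true(all(dg[cp] <= cfg$context_gene_dist))
  ep <- ctxcls == "enhancer_proximal"
  expect_true(all(de[ep] < cfg$context_enh_dist, na.rm = FALSE))
  # distal elements are beyond both planted thresholds from constitutive genes
  cg <- constitutive_genes(ds$context$expression)
  gi <- ds$context$genes[ds$context$genes$name %in% cg, ]
  dgc <- nearest_distance(prim, gi)
  dist <- ctxcls == "distal"
  expect_true(all(is.na(dgc[dist]) | dgc[dist] > cfg$context_gene_dist))
})

test_that("strain deletions fully cover their target elements", {
  ds <- get_small_dataset()
  prim <- ds$instances[ds$instances$subfamily == "SynLTR1", ]
  dels <- ds$context$deletions_by_strain
  expect_equal(length(dels), ds$config$n_strains)
  for (s in names(dels)[1:3]) {
    if (nrow(dels[[s]]) == 0L) next
    # every deletion that touches an element covers 100% of it
    hits <- GenomicRanges::findOverlaps(
      vmte:::as_granges(prim), vmte:::as_granges(dels[[s]]),
      ignore.strand = TRUE)
    for (h in seq_len(length(hits))) {
      i <- S4Vectors::queryHits(hits)[h]; j <- S4Vectors::subjectHits(hits)[h]
      expect_true(dels[[s]]$start[j] <= prim$start[i] &&
                    dels[[s]]$end[j] >= prim$end[i])
    }
  }
})

test_that("planted peak sets obey the replicate and ratio rules", {
  ds <- get_small_dataset()
  cfg <- ds$config
  novel <- ds$peaks$novel_truth
  expect_equal(nrow(novel), cfg$n_novel)
  ngr <- vmte:::as_granges(novel)
  for (g in c("MUT", "WT")) {
    support <- Reduce(`+`, lapply(ds$peaks$peaks[[g]], function(p)
      as.integer(GenomicRanges::countOverlaps(
        ngr, vmte:::as_granges(p), ignore.strand = TRUE) > 0L)))
    if (g == "MUT") expect_true(all(support >= 2L))
    else expect_true(all(support == 0L))
  }
  for (i in seq_len(nrow(novel))) {
    mm <- mean(ds$peaks$tracks$MUT$chr1[(novel$start[i] + 1):novel$end[i]])
    wm <- mean(ds$peaks$tracks$WT$chr1[(novel$start[i] + 1):novel$end[i]])
    expect_gte((mm + 0.5) / (wm + 0.5), 3)
  }
})

test_that("written dataset files load back consistently", {
  dir <- get_small_dir()
  ds <- get_small_dataset()
  inst <- read_repeatmasker_out(file.path(dir, "repeats.out"))
  expect_equal(inst[, c("chrom", "start", "end", "strand", "subfamily")],
               ds$instances[, c("chrom", "start", "end", "strand", "subfamily")])
  genome <- read_genome(file.path(dir, "genome.fa"))
  expect_equal(unname(genome_sizes(genome)),
               unname(ds$truth$chrom_sizes))
  tr <- read_bedgraph(file.path(dir, "tracks", "KAP1.bedgraph"),
                      genome_sizes(genome))
  expect_equal(tr$chr1, ds$binding_tracks$KAP1$chr1)
})
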