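#' Simulation configuration
#'
#' Defaults define the study conditions emulated by the generator: a young
#' LTR subfamily of `n_clades` sequence clades (one of which escapes
#' KZFP/KAP1 silencing), CpG-enriched element consensus on a CpG-depleted
#' background genome, clade-dependent binding, three methylation regimes
#' (silenced / variably methylated / escaped), planted genomic context,
#' strain-biased deletions and genotype-dependent peak sets. See the
#' methods vignette for the rationale behind each default.
#'
#' @param seed root RNG seed; all stage sub-seeds derive from it.
#' @param n_clades number of planted sequence clades.
#' @param instances_per_clade copies per clade.
#' @param consensus_length LTR consensus length in bp.
#' @param within_clade_divergence per-bp substitution probability per copy.
#' @param n_diagnostic_sites private diagnostic substitutions per clade.
#' @param escape_clade index of the clade escaping silencing.
#' @param ... overrides for the remaining fields (see Details in the
#'   vignette); unknown names are an error.
#' @return a `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1, n_clades = 4, instances_per_clade = 50,
                       consensus_length = 330,
                       within_clade_divergence = 0.02,
                       n_diagnostic_sites = 8,
                       escape_clade = n_clades, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_clades = n_clades,
    instances_per_clade = instances_per_clade,
    consensus_length = consensus_length,
    within_clade_divergence = within_clade_divergence,
    n_diagnostic_sites = n_diagnostic_sites,
    escape_clade = escape_clade,
    subfamily = "SynLTR1",
    int_subfamily = "SynInt",
    # genome layout: one territory (slot) per primary element on chr1,
    # compact slots for background subfamilies on chr2
    slot_bp = 16000,
    proviral_fraction = 0.5,
    int_length = 1500,
    int_max_gap = 25,
    consensus_cpg_oe = 1.5,
    background_cpg_keep = 0.25,
    n_bg_subfamilies = 16,
    n_bg_cpg_rich = 5,
    bg_copies = 12,
    bg_length = 300,
    bg_slot_bp = 1200,
    # binding (consensus-interval profiles per factor; heights per clade,
    # escape clade lowest)
    factors = list(KZFP = c(60L, 140L), KAP1 = c(50L, 150L)),
    binding_heights = NULL,
    escape_height = 1,
    binding_noise = TRUE,
    # methylation regimes
    n_individuals = 8,
    silenced_mean = 0.85, silenced_sd = 0.05,
    escaped_mean = 0.10, escaped_sd = 0.05,
    vm_range = c(0.1, 0.9),
    read_lambda = 20,
    p_variable_escape = 0.6,
    p_variable_other = 0.02,
    # genomic context (desk-scale distances; see vignette)
    context_gene_dist = 5000,
    context_enh_dist = 200,
    gene_length = 1000,
    enhancer_length = 200,
    n_expr_samples = 10,
    p_context_vm = c(constitutive_proximal = 0.83,
                     enhancer_proximal = 0.17, distal = 0.00),
    p_context_nonvm = c(constitutive_proximal = 0.12,
                        enhancer_proximal = 0.07, distal = 0.81),
    # strains
    n_strains = 8,
    branches = list(branch1 = "strain1", branch2 = c("strain2", "strain3"),
                    branch3 = c("strain4", "strain5"),
                    branch4 = c("strain6", "strain7", "strain8")),
    del_prob_escape = 0.25,
    del_prob_other = 0.05,
    # peaks
    n_replicates = 3,
    n_novel = 15,
    n_background_peaks = 40,
    n_noise_peaks = 10,
    n_deadzone_decoys = 2,
    novel_height = 10,
    background_height = 8,
    # expression / ages
    primary_age = 3,
    age_bin_edges = c(0, 10, 25, 50, 100, Inf)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop_vmte("unknown config field(s): %s", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  if (is.null(cfg$binding_heights)) {
    h <- seq(8, 6, length.out = max(1L, cfg$n_clades - 1L))
    heights <- rep(cfg$escape_height, cfg$n_clades)
    heights[setdiff(seq_len(cfg$n_clades), cfg$escape_clade)] <- h
    cfg$binding_heights <- heights
  }
  stopifnot(cfg$n_clades >= 2, cfg$instances_per_clade > 0,
            cfg$within_clade_divergence >= 0, cfg$within_clade_divergence <= 1,
            cfg$escape_clade >= 1, cfg$escape_clade <= cfg$n_clades)
  class(cfg) <- "SimulationConfig"
  cfg
}

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) sample(BASES, n, replace = TRUE)

# Break CG dinucleotides until only ~keep_frac of them survive; gives a
# background at CpG O/E roughly equal to keep_frac.
deplete_cpg <- function(x, keep_frac) {
  cg <- which(x[-length(x)] == "C" & x[-1] == "G")
  kill <- cg[runif(length(cg)) > keep_frac]
  if (length(kill)) x[kill + 1L] <- sample(c("A", "T"), length(kill), TRUE)
  x
}

# Plant CG dinucleotides at random positions until the O/E target is met.
enrich_cpg <- function(x, target_oe) {
  for (i in seq_len(5L * length(x))) {
    s <- cpg_score(paste(x, collapse = ""))
    if (s$score >= target_oe) break
    p <- sample.int(length(x) - 1L, 1)
    x[p] <- "C"; x[p + 1L] <- "G"
  }
  x
}

mutate_seq <- function(x, prob) {
  hit <- which(runif(length(x)) < prob)
  for (i in hit) x[i] <- sample(setdiff(BASES, x[i]), 1)
  x
}

revcomp_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[x]))
}

#' Simulate a repeat-bearing genome with planted clades
#'
#' Builds a CpG-depleted random background genome and inserts
#' `n_clades * instances_per_clade` copies of a CpG-enriched LTR consensus,
#' each carrying its clade's private diagnostic substitutions plus i.i.d.
#' within-clade substitutions; about half of the copies are placed on the
#' minus strand (reverse-complemented into the genome). A configurable
#' fraction of LTRs is paired with an adjacent internal element (small
#' strand-aware 5' gap), and compact background subfamilies are placed on a
#' second chromosome for subfamily-level analyses. Deterministic given the
#' config seed.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (DNAStringSet), `instances` (all placed
#'   repeats), and `truth` (per-instance clade / VM labels, planted context
#'   class, CpG positions, consensus and diagnostic sites, chromosome
#'   sizes).
#' @export
simulate_repeat_genome <- function(config) {
  with_seed(derive_seed(config$seed, "genome"), {
    n_primary <- config$n_clades * config$instances_per_clade
    chr1_len <- n_primary * config$slot_bp
    chr2_len <- config$n_bg_subfamilies * config$bg_copies * config$bg_slot_bp +
      2L * config$bg_slot_bp
    if (config$slot_bp < 2L * (config$consensus_length + config$int_length))
      stop_vmte("genome too short: slot_bp cannot hold the planted elements")

    chr1 <- deplete_cpg(random_dna(chr1_len), config$background_cpg_keep)
    chr2 <- deplete_cpg(random_dna(chr2_len), config$background_cpg_keep)

    consensus <- enrich_cpg(random_dna(config$consensus_length),
                            config$consensus_cpg_oe)
    # private diagnostic substitutions per clade
    diag_pool <- sample.int(config$consensus_length,
                            config$n_clades * config$n_diagnostic_sites)
    diag_sites <- split(diag_pool,
                        rep(seq_len(config$n_clades),
                            each = config$n_diagnostic_sites))
    clade_cons <- lapply(seq_len(config$n_clades), function(cl) {
      x <- consensus
      for (p in diag_sites[[cl]]) x[p] <- sample(setdiff(BASES, x[p]), 1)
      x
    })
    int_consensus <- random_dna(config$int_length)

    clade_of <- sample(rep(seq_len(config$n_clades),
                           each = config$instances_per_clade))
    strand <- sample(c("+", "-"), n_primary, replace = TRUE)
    proviral <- runif(n_primary) < config$proviral_fraction

    inst <- list(); truth_rows <- list(); cpg_pos <- list()
    place <- function(chr_chars, chrom, start, seq_chars, strand) {
      s <- if (strand == "-") revcomp_chars(seq_chars) else seq_chars
      chr_chars[(start + 1L):(start + length(s))] <- s
      chr_chars
    }
    half <- config$slot_bp %/% 2L
    for (i in seq_len(n_primary)) {
      cl <- clade_of[i]
      eseq <- mutate_seq(clade_cons[[cl]], config$within_clade_divergence)
      slot0 <- (i - 1L) * config$slot_bp
      jitter <- sample.int(1001L, 1) - 501L
      start <- slot0 + half - config$consensus_length %/% 2L + jitter
      end <- start + config$consensus_length
      chr1 <- place(chr1, "chr1", start, eseq, strand[i])
      id <- sprintf("%s:chr1:%d-%d", config$subfamily, start, end)
      inst[[length(inst) + 1L]] <- data.frame(
        instance_id = id, chrom = "chr1", start = start, end = end,
        strand = strand[i], subfamily = config$subfamily,
        family = "SynERV", stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        instance_id = id, clade = sprintf("clade%d", cl),
        is_primary = TRUE, stringsAsFactors = FALSE)
      if (proviral[i]) {
        gap <- sample.int(config$int_max_gap + 1L, 1) - 1L
        iseq <- mutate_seq(int_consensus, config$within_clade_divergence)
        if (strand[i] == "-") {
          iend <- start - gap; istart <- iend - config$int_length
        } else {
          istart <- end + gap; iend <- istart + config$int_length
        }
        chr1 <- place(chr1, "chr1", istart, iseq, strand[i])
        iid <- sprintf("%s:chr1:%d-%d", config$int_subfamily, istart, iend)
        inst[[length(inst) + 1L]] <- data.frame(
          instance_id = iid, chrom = "chr1", start = istart, end = iend,
          strand = strand[i], subfamily = config$int_subfamily,
          family = "SynERV", stringsAsFactors = FALSE)
      }
    }

    # background subfamilies on chr2
    bg_names <- sprintf("SynBG%d", seq_len(config$n_bg_subfamilies))
    cpg_rich <- seq_len(config$n_bg_cpg_rich)
    slot_i <- 0L
    for (b in seq_len(config$n_bg_subfamilies)) {
      cons <- random_dna(config$bg_length)
      cons <- if (b %in% cpg_rich) enrich_cpg(cons, runif(1, 1.2, 1.8))
              else deplete_cpg(cons, config$background_cpg_keep)
      for (cpy in seq_len(config$bg_copies)) {
        slot0 <- slot_i * config$bg_slot_bp
        slot_i <- slot_i + 1L
        st <- slot0 + sample.int(config$bg_slot_bp - config$bg_length, 1) - 1L
        sq <- mutate_seq(cons, config$within_clade_divergence)
        sd_ <- sample(c("+", "-"), 1)
        chr2 <- place(chr2, "chr2", st, sq, sd_)
        id <- sprintf("%s:chr2:%d-%d", bg_names[b], st, st + config$bg_length)
        inst[[length(inst) + 1L]] <- data.frame(
          instance_id = id, chrom = "chr2", start = st,
          end = st + config$bg_length, strand = sd_,
          subfamily = bg_names[b], family = "SynBG",
          stringsAsFactors = FALSE)
      }
    }

    instances <- do.call(rbind, inst)
    truth_tab <- do.call(rbind, truth_rows)

    # VM status per primary element (clade-dependent)
    esc_lab <- sprintf("clade%d", config$escape_clade)
    vm_status <- vapply(seq_len(nrow(truth_tab)), function(i) {
      if (truth_tab$clade[i] == esc_lab) {
        if (runif(1) < config$p_variable_escape) "variable" else "escaped"
      } else {
        if (runif(1) < config$p_variable_other) "variable" else "silenced"
      }
    }, character(1))
    truth_tab$vm_status <- vm_status

    # planted context class
    ctx <- vapply(seq_len(nrow(truth_tab)), function(i) {
      p <- if (vm_status[i] == "variable") config$p_context_vm
           else config$p_context_nonvm
      sample(names(p), 1, prob = p)
    }, character(1))
    truth_tab$context_class <- ctx

    genome <- Biostrings::DNAStringSet(c(
      chr1 = paste(chr1, collapse = ""),
      chr2 = paste(chr2, collapse = "")))

    # genomic CpG positions (C of CG on + strand) per primary element
    chars <- list(chr1 = chr1, chr2 = chr2)
    for (i in which(instances$subfamily == config$subfamily)) {
      x <- chars[[instances$chrom[i]]][(instances$start[i] + 1L):instances$end[i]]
      cg <- which(x[-length(x)] == "C" & x[-1] == "G")
      cpg_pos[[instances$instance_id[i]]] <- instances$start[i] + cg - 1L
    }

    truth <- list(
      table = truth_tab,
      clades = setNames(truth_tab$clade, truth_tab$instance_id),
      vm_status = setNames(truth_tab$vm_status, truth_tab$instance_id),
      context_class = setNames(truth_tab$context_class,
                               truth_tab$instance_id),
      cpg_positions = cpg_pos,
      consensus = paste(consensus, collapse = ""),
      diagnostic_sites = diag_sites,
      chrom_sizes = c(chr1 = chr1_len, chr2 = chr2_len),
      instances = instances)
    list(genome = genome, instances = instances, truth = truth)
  })
}

#' Simulate clade-dependent binding coverage tracks
#'
#' Each primary element receives its clade's profile — a constant height
#' over a consensus sub-interval, mapped strand-aware onto genomic
#' coordinates — with optional Poisson noise (`value ~ Pois(height)` per
#' bp). The escape clade's height is configured lowest.
#'
#' @param truth truth list from [simulate_repeat_genome()].
#' @param config the [sim_config()].
#' @return named list of `CoverageTrack`s, one per factor.
#' @export
simulate_binding_coverage <- function(truth, config) {
  with_seed(derive_seed(config$seed, "binding"), {
    primary <- truth$instances[truth$instances$subfamily == config$subfamily, ]
    tracks <- list()
    for (f in names(config$factors)) {
      iv <- config$factors[[f]]
      if (iv[2] > config$consensus_length)
        stop_vmte("binding profile interval exceeds consensus length")
      tr <- coverage_track(truth$chrom_sizes)
      for (i in seq_len(nrow(primary))) {
        cl <- as.integer(sub("clade", "", truth$clades[primary$instance_id[i]]))
        h <- config$binding_heights[cl]
        w <- iv[2] - iv[1]
        if (primary$strand[i] == "-") {
          g0 <- primary$end[i] - iv[2]
        } else {
          g0 <- primary$start[i] + iv[1]
        }
        vals <- if (config$binding_noise) rpois(w, h) else rep(h, w)
        tr[[primary$chrom[i]]][(g0 + 1L):(g0 + w)] <- vals
      }
      tracks[[f]] <- tr
    }
    tracks
  })
}

#' Simulate per-CpG methylation calls across individuals
#'
#' Silenced elements draw per-CpG methylation near `silenced_mean`; escaped
#' elements near `escaped_mean`; variably methylated elements draw one
#' level per individual per element, uniform on `vm_range`, shared by all
#' of the element's CpGs (a coherent epiallele). Read totals are
#' Poisson-distributed; methylated counts are binomial.
#'
#' @param truth truth list from [simulate_repeat_genome()].
#' @param config the [sim_config()].
#' @return methylation call data.frame (`chrom`, `pos`, `methylated`,
#'   `total`, `sample`, `fraction`).
#' @export
simulate_methylation <- function(truth, config) {
  with_seed(derive_seed(config$seed, "methylation"), {
    rows <- list()
    inds <- sprintf("ind%d", seq_len(config$n_individuals))
    for (id in names(truth$cpg_positions)) {
      pos <- truth$cpg_positions[[id]]
      if (!length(pos)) next
      chrom <- truth$instances$chrom[match(id, truth$instances$instance_id)]
      status <- truth$vm_status[[id]]
      for (ind in inds) {
        p <- switch(status,
          silenced = pmin(1, pmax(0, rnorm(length(pos), config$silenced_mean,
                                           config$silenced_sd))),
          escaped = pmin(1, pmax(0, rnorm(length(pos), config$escaped_mean,
                                          config$escaped_sd))),
          variable = rep(runif(1, config$vm_range[1], config$vm_range[2]),
                         length(pos)))
        total <- rpois(length(pos), config$read_lambda - 1) + 1L
        meth <- rbinom(length(pos), total, p)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, pos = pos, methylated = meth, total = total,
          sample = ind, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out$fraction <- out$methylated / out$total
    out
  })
}

#' Simulate genomic context, expression and strain deletions
#'
#' Plants a constitutive gene (FPKM above threshold in every sample) on
#' the 5' side of every `constitutive_proximal` element within the
#' configured gene distance, an enhancer within the enhancer distance of
#' every `enhancer_proximal` element, and non-constitutive filler genes
#' near some distal elements. Deletions fully cover selected elements with
#' clade-dependent probability (escape clade highest); the strain tree
#' groups strains into ordered branches.
#'
#' @param truth truth list from [simulate_repeat_genome()].
#' @param config the [sim_config()].
#' @return list with `genes` (intervals + `name`), `expression`
#'   (FPKM list), `enhancers`, `deletions_by_strain`, `tree`.
#' @export
simulate_context_and_strains <- function(truth, config) {
  with_seed(derive_seed(config$seed, "context"), {
    primary <- truth$instances[truth$instances$subfamily == config$subfamily, ]
    genes <- list(); fpkm <- list(); enh <- list()
    nS <- config$n_expr_samples
    gid <- 0L
    five_prime_gap <- function(inst, extent, gap) {
      # feature wholly on the element's 5' side at the given edge gap
      if (inst$strand == "-") c(inst$end + gap, inst$end + gap + extent)
      else c(inst$start - gap - extent, inst$start - gap)
    }
    for (i in seq_len(nrow(primary))) {
      inst <- primary[i, ]
      ctx <- truth$context_class[[inst$instance_id]]
      if (ctx == "constitutive_proximal") {
        gap <- sample(200:(config$context_gene_dist - config$gene_length - 1000), 1)
        iv <- five_prime_gap(inst, config$gene_length, gap)
        gid <- gid + 1L
        genes[[length(genes) + 1L]] <- data.frame(
          chrom = inst$chrom, start = iv[1], end = iv[2],
          name = sprintf("gene%d", gid), stringsAsFactors = FALSE)
        fpkm[[length(fpkm) + 1L]] <- runif(nS, 5, 50)
      } else if (ctx == "enhancer_proximal") {
        gap <- sample(0:(config$context_enh_dist - 50), 1)
        iv <- five_prime_gap(inst, config$enhancer_length, gap)
        enh[[length(enh) + 1L]] <- data.frame(
          chrom = inst$chrom, start = iv[1], end = iv[2],
          name = sprintf("enh%d", length(enh) + 1L), stringsAsFactors = FALSE)
      } else if (runif(1) < 0.3) {
        # non-constitutive filler gene near a distal element: high FPKM in
        # only half the samples, so the constitutive filter must drop it
        gap <- sample(200:2000, 1)
        iv <- five_prime_gap(inst, config$gene_length, gap)
        gid <- gid + 1L
        genes[[length(genes) + 1L]] <- data.frame(
          chrom = inst$chrom, start = iv[1], end = iv[2],
          name = sprintf("gene%d", gid), stringsAsFactors = FALSE)
        v <- numeric(nS); on <- sample.int(nS, nS %/% 2L)
        v[on] <- runif(length(on), 5, 50)
        fpkm[[length(fpkm) + 1L]] <- v
      }
    }
    genes <- do.call(rbind, genes) %||%
      data.frame(chrom = character(), start = integer(), end = integer(),
                 name = character(), stringsAsFactors = FALSE)
    fpkm_m <- if (length(fpkm)) do.call(rbind, fpkm) else
      matrix(numeric(), 0, nS)
    rownames(fpkm_m) <- genes$name
    colnames(fpkm_m) <- sprintf("s%d", seq_len(nS))
    enh <- do.call(rbind, enh) %||%
      data.frame(chrom = character(), start = integer(), end = integer(),
                 name = character(), stringsAsFactors = FALSE)

    # sanity: every planted constitutive_proximal element has its gene in range
    cp <- primary$instance_id[
      truth$context_class[primary$instance_id] == "constitutive_proximal"]
    if (length(cp)) {
      d <- nearest_distance(primary[match(cp, primary$instance_id), ], genes)
      if (any(is.na(d)) || any(d > config$context_gene_dist))
        stop_vmte("irreconcilable context constraints")
    }

    strains <- sprintf("strain%d", seq_len(config$n_strains))
    esc_lab <- sprintf("clade%d", config$escape_clade)
    deletions <- setNames(lapply(strains, function(s) {
      rows <- list()
      for (i in seq_len(nrow(primary))) {
        pdel <- if (truth$clades[[primary$instance_id[i]]] == esc_lab)
          config$del_prob_escape else config$del_prob_other
        if (runif(1) < pdel) {
          pad <- sample(10:200, 2)
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = primary$chrom[i],
            start = max(0L, primary$start[i] - pad[1]),
            end = primary$end[i] + pad[2], stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows) %||%
        data.frame(chrom = character(), start = integer(), end = integer(),
                   stringsAsFactors = FALSE)
    }), strains)

    list(genes = genes,
         expression = list(gene_id = genes$name, fpkm = fpkm_m),
         enhancers = enh,
         deletions_by_strain = deletions,
         tree = config$branches)
  })
}

#' Simulate replicate peak sets and genotype coverage tracks
#'
#' A configured number of escape-clade elements carries mutant-only peaks
#' present in at least two mutant replicates with high mutant coverage and
#' zero wild-type coverage; background peaks are shared by both genotypes
#' at equal height; single-replicate noise peaks and dead-zone decoy peaks
#' exercise the support and exclusion filters.
#'
#' @param truth truth list from [simulate_repeat_genome()].
#' @param config the [sim_config()].
#' @return list with `peaks` (genotype -> replicate -> data.frame),
#'   `tracks` (`WT`, `MUT` CoverageTracks), `deadzones`, and
#'   `novel_truth` (planted novel loci intervals).
#' @export
simulate_peaks <- function(truth, config) {
  with_seed(derive_seed(config$seed, "peaks"), {
    primary <- truth$instances[truth$instances$subfamily == config$subfamily, ]
    esc_lab <- sprintf("clade%d", config$escape_clade)
    esc <- primary[truth$clades[primary$instance_id] == esc_lab, ]
    oth <- primary[truth$clades[primary$instance_id] != esc_lab, ]
    if (nrow(esc) < config$n_novel)
      stop_vmte("not enough escape-clade elements for %d novel loci",
                config$n_novel)
    novel <- esc[sort(sample.int(nrow(esc), config$n_novel)), ]
    bg <- oth[sort(sample.int(nrow(oth),
                              min(nrow(oth), config$n_background_peaks))), ]

    wt <- coverage_track(truth$chrom_sizes)
    mut <- coverage_track(truth$chrom_sizes)
    fill <- function(track, df, height) {
      for (i in seq_len(nrow(df)))
        track[[df$chrom[i]]][(df$start[i] + 1L):df$end[i]] <- height
      track
    }
    mut <- fill(mut, novel, config$novel_height)
    wt <- fill(wt, bg, config$background_height)
    mut <- fill(mut, bg, config$background_height)

    jitter_peak <- function(df) {
      j <- sample(-30:30, nrow(df), replace = TRUE)
      data.frame(chrom = df$chrom, start = pmax(0L, df$start + j),
                 end = df$end + sample(-30:30, nrow(df), replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    reps <- seq_len(config$n_replicates)
    # support pattern: each novel locus in >= 2 mutant replicates
    novel_support <- lapply(seq_len(nrow(novel)), function(i)
      sort(sample(reps, sample(2:config$n_replicates, 1))))

    # noise peaks (1 replicate only) in element-free space between slots
    rand_free <- function(n) {
      st <- sample.int(truth$chrom_sizes[["chr1"]] - 500L, n)
      data.frame(chrom = "chr1", start = st, end = st + 400L,
                 stringsAsFactors = FALSE)
    }
    noise <- rand_free(config$n_noise_peaks)
    decoys <- rand_free(config$n_deadzone_decoys)
    # keep decoys/noise clear of planted peaks
    clear <- function(df) {
      used <- rbind(novel[, c("chrom", "start", "end")],
                    bg[, c("chrom", "start", "end")])
      ok <- GenomicRanges::countOverlaps(
        as_granges(df), as_granges(used), ignore.strand = TRUE,
        maxgap = 200L) == 0L
      df[ok, , drop = FALSE]
    }
    noise <- clear(noise); decoys <- clear(decoys)
    mut <- fill(mut, decoys, config$novel_height)
    deadzones <- data.frame(chrom = decoys$chrom,
                            start = pmax(0L, decoys$start - 100L),
                            end = decoys$end + 100L, stringsAsFactors = FALSE)

    peaks <- list(WT = list(), MUT = list())
    for (r in reps) {
      wt_r <- jitter_peak(bg)
      mut_keep <- vapply(novel_support, function(s) r %in% s, TRUE)
      mut_r <- rbind(jitter_peak(bg), jitter_peak(novel[mut_keep, ]),
                     if (r >= 2) jitter_peak(decoys))
      if (r == 1L && nrow(noise)) {
        half <- seq_len(nrow(noise)) <= nrow(noise) %/% 2L
        wt_r <- rbind(wt_r, noise[half, , drop = FALSE])
        mut_r <- rbind(mut_r, noise[!half, , drop = FALSE])
      }
      peaks$WT[[sprintf("rep%d", r)]] <- wt_r
      peaks$MUT[[sprintf("rep%d", r)]] <- mut_r
    }
    list(peaks = peaks, tracks = list(WT = wt, MUT = mut),
         deadzones = deadzones,
         novel_truth = novel[, c("instance_id", "chrom", "start", "end")])
  })
}

#' Simulate subfamily age and differential-expression tables
#'
#' The primary subfamily and the CpG-rich background subfamilies are young
#' and expression-responsive (positive log2 fold change, small adjusted p);
#' the remaining subfamilies are older and non-responsive.
#'
#' @param truth truth list from [simulate_repeat_genome()].
#' @param config the [sim_config()].
#' @return list with `ages` (`subfamily`, `age`) and `de_table`
#'   (`subfamily`, `log2FC`, `padj`).
#' @export
simulate_subfamily_tables <- function(truth, config) {
  with_seed(derive_seed(config$seed, "tables"), {
    bg_names <- sprintf("SynBG%d", seq_len(config$n_bg_subfamilies))
    rich <- bg_names[seq_len(config$n_bg_cpg_rich)]
    subfams <- c(config$subfamily, bg_names)
    age <- c(config$primary_age,
             ifelse(bg_names %in% rich, runif(length(bg_names), 2, 9),
                    runif(length(bg_names), 12, 145)))
    responsive <- subfams %in% c(config$subfamily, rich)
    de <- data.frame(
      subfamily = subfams,
      log2FC = ifelse(responsive, runif(length(subfams), 1, 3),
                      runif(length(subfams), -0.4, 0.4)),
      padj = ifelse(responsive, 10^runif(length(subfams), -8, -3),
                    runif(length(subfams), 0.2, 1)),
      stringsAsFactors = FALSE)
    list(ages = data.frame(subfamily = subfams, age = age,
                           stringsAsFactors = FALSE),
         de_table = de)
  })
}

#' Generate the complete synthetic dataset
#'
#' Runs every stage generator off one root seed (each stage derives its own
#' sub-seed, so stages are independently re-generable) and returns all
#' inputs a full pipeline run needs, plus the ground truth.
#'
#' @param config a [sim_config()].
#' @return named list: `config`, `genome`, `instances`, `truth`,
#'   `binding_tracks`, `methylation`, `context` (genes / expression /
#'   enhancers / deletions / tree), `peaks`, `tables` (ages, de_table),
#'   `vm_loci`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  g <- simulate_repeat_genome(config)
  binding <- simulate_binding_coverage(g$truth, config)
  meth <- simulate_methylation(g$truth, config)
  ctx <- simulate_context_and_strains(g$truth, config)
  pk <- simulate_peaks(g$truth, config)
  tabs <- simulate_subfamily_tables(g$truth, config)
  vm_ids <- names(g$truth$vm_status)[g$truth$vm_status == "variable"]
  vm_loci <- g$instances[match(vm_ids, g$instances$instance_id),
                         c("chrom", "start", "end", "strand")]
  vm_loci$name <- vm_ids
  list(config = config, genome = g$genome, instances = g$instances,
       truth = g$truth, binding_tracks = binding, methylation = meth,
       context = ctx, peaks = pk, tables = tabs, vm_loci = vm_loci)
}

#' Write a synthetic dataset to disk in standard formats
#'
#' Writes genome.fa, repeats.out / repeats.bed, tracks/*.bedgraph,
#' methylation.tsv, genes.bed + fpkm.tsv, enhancers.bed, vm_loci.bed,
#' strains/*.deletions.bed + tree.txt, peaks/*.bed, deadzones.bed,
#' ages.tsv, de_table.tsv, chrom_sizes.tsv and truth.json.
#'
#' @param dataset list from [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("tracks", "strains", "peaks"))
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)

  Biostrings::writeXStringSet(dataset$genome, p("genome.fa"))
  write_repeatmasker_out(dataset$instances, p("repeats.out"))
  bed <- dataset$instances
  bed$name <- bed$instance_id
  write_bed(bed, p("repeats.bed"))
  for (f in names(dataset$binding_tracks))
    write_bedgraph(dataset$binding_tracks[[f]],
                   p("tracks", paste0(f, ".bedgraph")))
  for (g in names(dataset$peaks$tracks))
    write_bedgraph(dataset$peaks$tracks[[g]],
                   p("tracks", paste0("H3K4me3_", g, ".bedgraph")))
  write_methylation_calls(dataset$methylation, p("methylation.tsv"))
  write_bed(dataset$context$genes, p("genes.bed"))
  fp <- dataset$context$expression
  write.table(data.frame(gene_id = fp$gene_id, fp$fpkm, check.names = FALSE),
              p("fpkm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(dataset$context$enhancers, p("enhancers.bed"))
  write_bed(dataset$vm_loci, p("vm_loci.bed"))
  for (s in names(dataset$context$deletions_by_strain)) {
    dels <- dataset$context$deletions_by_strain[[s]]
    if (nrow(dels) == 0L) file.create(p("strains", paste0(s, ".deletions.bed")))
    else write_bed(dels, p("strains", paste0(s, ".deletions.bed")))
  }
  writeLines(vapply(dataset$context$tree, paste, character(1), collapse = ","),
             p("tree.txt"))
  for (g in names(dataset$peaks$peaks))
    for (r in names(dataset$peaks$peaks[[g]]))
      write_bed(dataset$peaks$peaks[[g]][[r]],
                p("peaks", sprintf("%s_%s.bed", g, r)))
  if (nrow(dataset$peaks$deadzones)) {
    write_bed(dataset$peaks$deadzones, p("deadzones.bed"))
  } else file.create(p("deadzones.bed"))
  write.table(dataset$tables$ages, p("ages.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dataset$tables$de_table, p("de_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(chrom = names(dataset$truth$chrom_sizes),
                         size = unname(dataset$truth$chrom_sizes)),
              p("chrom_sizes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(table = dataset$truth$table,
         novel_loci = dataset$peaks$novel_truth,
         diagnostic_sites = dataset$truth$diagnostic_sites,
         consensus = dataset$truth$consensus,
         seed = dataset$config$seed),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
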