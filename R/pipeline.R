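#' Pipeline configuration
#'
#' Collects the input paths (as laid out by [write_synthetic_dataset()], or
#' any dataset in the same formats) and the stage parameters into one
#' validated object.
#'
#' @param data_dir directory containing the inputs.
#' @param k number of sequence clades to cut.
#' @param ltr_subfamily,int_subfamily subfamily names to profile.
#' @param min_len LTR length cutoff (strict, bp).
#' @param trim_min_frac alignment column occupancy threshold.
#' @param window,step CpG window parameters (bp).
#' @param min_copy minimum copies per reported subfamily.
#' @param fpkm_thr,sample_frac constitutive-gene thresholds.
#' @param gene_dist,enh_dist context proximity thresholds (bp).
#' @param min_cov methylation coverage threshold (strict).
#' @param min_support peak replicate support.
#' @param ratio_thr novel-peak signal ratio.
#' @param oe_R null replicates for age enrichment.
#' @param age_bin_edges age-bin edges.
#' @param kap1_factor name of the KAP1-like binding track.
#' @param seed seed for all stochastic stages.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(data_dir, k = 4,
                            ltr_subfamily = "SynLTR1",
                            int_subfamily = "SynInt",
                            min_len = 300, trim_min_frac = 0.10,
                            window = 200, step = 10, min_copy = 10,
                            fpkm_thr = 2, sample_frac = 0.9,
                            gene_dist = 5000, enh_dist = 200,
                            min_cov = 5, min_support = 2, ratio_thr = 3,
                            oe_R = 1000,
                            age_bin_edges = c(0, 10, 25, 50, 100, Inf),
                            kap1_factor = "KAP1", seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @return data.frame of issues (`severity` in error/warning, `message`);
#'   zero rows when the pipeline is runnable.
#' @export
validate_config <- function(config) {
  issues <- list()
  add <- function(sev, msg)
    issues[[length(issues) + 1L]] <<- data.frame(severity = sev, message = msg,
                                                 stringsAsFactors = FALSE)
  need <- c("genome.fa", "repeats.out", "methylation.tsv", "genes.bed",
            "fpkm.tsv", "enhancers.bed", "vm_loci.bed", "tree.txt",
            "ages.tsv", "de_table.tsv")
  for (f in need) {
    if (!file.exists(file.path(config$data_dir, f)))
      add("error", sprintf("missing input: %s", f))
  }
  if (config$k < 1) add("error", "k must be >= 1")
  if (config$window < config$step)
    add("warning", "window smaller than step leaves gaps between tiles")
  if (config$oe_R < 100) add("warning", "oe_R < 100 gives unstable intervals")
  if (length(issues) == 0L)
    return(data.frame(severity = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

read_stage_input <- function(stage, path, reader, ...) {
  if (!file.exists(path))
    stop_vmte("stage '%s': missing input %s", stage, path)
  reader(path, ...)
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order: sequence extraction, clade calling,
#' consensus-space signal projection, CpG scoring, genomic context,
#' clade/VM and age enrichment, strain conservation, methylation
#' summaries, and peak analysis. Deterministic given `config$seed`; any
#' failure aborts with an error naming the stage.
#'
#' @param config a [pipeline_config()].
#' @return a `ReportBundle`: list of per-stage tables plus a `summary`
#'   list of the headline quantities (recomputable from the tables) and a
#'   `provenance` block (parameters and seed).
#' @export
run_pipeline <- function(config) {
  issues <- validate_config(config)
  if (any(issues$severity == "error"))
    stop_vmte("invalid config: %s", paste(issues$message, collapse = "; "))
  d <- function(...) file.path(config$data_dir, ...)

  genome <- read_stage_input("load", d("genome.fa"), read_genome)
  chrom_sizes <- genome_sizes(genome)
  instances <- read_stage_input("load", d("repeats.out"), read_repeatmasker_out)
  vm_loci <- read_stage_input("load", d("vm_loci.bed"), read_bed)

  ## stage: extract
  ltr_seqs <- extract_ltr_sequences(genome, instances, config$ltr_subfamily,
                                    min_len = config$min_len)
  if (length(ltr_seqs) < 2L)
    stop_vmte("stage 'extract': fewer than 2 LTR sequences pass filters")
  flanked <- find_flanked_ints(instances, config$ltr_subfamily,
                               config$int_subfamily)

  ## stage: clades
  cl <- call_clades(ltr_seqs, k = config$k, min_frac = config$trim_min_frac)
  clades <- cl$clades
  primary <- instances[match(names(clades), instances$instance_id), ]

  ## stage: projection
  kap1_path <- d("tracks", paste0(config$kap1_factor, ".bedgraph"))
  kap1 <- read_stage_input("projection", kap1_path, read_bedgraph, chrom_sizes)
  sig <- build_signal_matrix(kap1, primary, cl$msa, clades = clades,
                             column_map = cl$trimmed$column_map)
  profiles <- clade_mean_profiles(sig, clades)
  elem_mean <- vapply(seq_len(nrow(primary)), function(i)
    mean_signal_per_element(kap1, primary[i, ]), numeric(1))
  names(elem_mean) <- primary$instance_id
  clade_signal <- tapply(elem_mean, clades[names(elem_mean)], mean)

  ## stage: cpg
  scores <- element_cpg_scores(genome, instances, config$window, config$step)
  subfam_summary <- subfamily_cpg_summary(instances, scores, vm_loci,
                                          min_copy = config$min_copy)
  background <- sample_background_scores(
    genome, primary, seed = derive_seed(config$seed, "background"),
    window = config$window, step = config$step)

  ## stage: context
  expression <- read_stage_input("context", d("fpkm.tsv"), read_fpkm_matrix)
  gene_iv <- read_stage_input("context", d("genes.bed"), read_bed)
  enhancers <- read_stage_input("context", d("enhancers.bed"), read_bed)
  cg <- constitutive_genes(expression, config$fpkm_thr, config$sample_frac)
  ctx <- classify_context(primary,
                          gene_iv[gene_iv$name %in% cg, , drop = FALSE],
                          enhancers, config$gene_dist, config$enh_dist)
  vm_hit <- GenomicRanges::countOverlaps(as_granges(primary),
                                         as_granges(vm_loci),
                                         ignore.strand = TRUE) > 0L
  names(vm_hit) <- primary$instance_id
  vm_ids <- primary$instance_id[vm_hit]
  nonvm_ids <- primary$instance_id[!vm_hit]
  ctx_compare <- context_fraction_compare(ctx, vm_ids, nonvm_ids)

  ## stage: enrichment
  enrich <- clade_vm_enrichment(clades, vm_hit)
  ages <- read_stage_input("enrichment", d("ages.tsv"),
                           function(p) read.table(p, header = TRUE,
                                                  sep = "\t",
                                                  stringsAsFactors = FALSE))
  oe <- oe_age_enrichment(vm_loci, instances, ages, config$age_bin_edges,
                          chrom_sizes, R = config$oe_R,
                          seed = derive_seed(config$seed, "oe"))

  ## stage: conservation
  tree <- read_stage_input("conservation", d("tree.txt"), read_strain_tree)
  del_files <- list.files(d("strains"), pattern = "\\.deletions\\.bed$",
                          full.names = TRUE)
  if (length(del_files) == 0L)
    stop_vmte("stage 'conservation': no strain deletion files in %s",
              d("strains"))
  deletions <- setNames(lapply(del_files, function(f) {
    if (file.size(f) == 0L)
      data.frame(chrom = character(), start = integer(), end = integer())
    else read_bed(f)
  }), sub("\\.deletions\\.bed$", "", basename(del_files)))
  pres <- presence_matrix(primary, deletions)
  branch_pres <- collapse_branches(pres, tree)
  poly <- clade_polymorphism_rate(branch_pres, clades)

  ## stage: methylation
  calls <- read_stage_input("methylation", d("methylation.tsv"),
                            read_methylation_calls)
  samples <- sort(unique(calls$sample))
  regions <- primary
  regions$name <- regions$instance_id
  meth_tab <- region_methylation_table(calls, regions, samples,
                                       min_cov = config$min_cov)
  elem_sd <- tapply(meth_tab$mean_fraction, meth_tab$region_id,
                    function(x) stats::sd(x, na.rm = TRUE))
  sd_vm <- elem_sd[vm_ids]; sd_nonvm <- elem_sd[nonvm_ids]
  sd_vm <- sd_vm[!is.na(sd_vm)]; sd_nonvm <- sd_nonvm[!is.na(sd_nonvm)]
  meth_test <- wilcoxon_rank_sum(sd_vm, sd_nonvm)

  ## stage: peaks
  read_peak_set <- function(genotype) {
    files <- list.files(d("peaks"),
                        pattern = sprintf("^%s_rep\\d+\\.bed$", genotype),
                        full.names = TRUE)
    setNames(lapply(files, read_bed),
             sub("\\.bed$", "", basename(files)))
  }
  deadzones <- if (file.exists(d("deadzones.bed")) &&
                   file.size(d("deadzones.bed")) > 0L)
    read_bed(d("deadzones.bed")) else NULL
  wt_sets <- read_peak_set("WT"); mut_sets <- read_peak_set("MUT")
  if (!length(wt_sets) || !length(mut_sets))
    stop_vmte("stage 'peaks': missing replicate peak files")
  wt_track <- read_stage_input("peaks", d("tracks", "H3K4me3_WT.bedgraph"),
                               read_bedgraph, chrom_sizes)
  mut_track <- read_stage_input("peaks", d("tracks", "H3K4me3_MUT.bedgraph"),
                                read_bedgraph, chrom_sizes)
  wt_merged <- reproducible_peaks(wt_sets, config$min_support, deadzones)
  mut_merged <- reproducible_peaks(mut_sets, config$min_support, deadzones)
  novel <- novel_peaks(mut_merged, wt_merged, mut_track, wt_track,
                       config$ratio_thr)
  novel_annot <- annotate_novel_loci(novel, instances, ages,
                                     config$age_bin_edges)
  de_table <- read_stage_input("peaks", d("de_table.tsv"),
                               function(p) read.table(p, header = TRUE,
                                                      sep = "\t",
                                                      stringsAsFactors = FALSE))
  resp <- responsive_subfamily_cpg_compare(
    de_table, subfam_summary, seed = derive_seed(config$seed, "responsive"))

  ## summary
  clade_sizes <- table(clades)
  vm_frac <- tapply(vm_hit[names(clades)], clades, mean)
  ctx_by_clade <- tapply(
    ctx$class[match(names(clades), ctx$instance_id)] == "constitutive_proximal",
    clades, mean)
  best_enrich <- enrich[which.min(enrich$p), ]
  summary <- list(
    n_ltr_profiled = length(ltr_seqs),
    n_flanked_ints = nrow(flanked),
    clade_sizes = as.list(clade_sizes),
    lowest_kap1_clade = names(which.min(clade_signal)),
    clade_mean_kap1 = as.list(clade_signal),
    vm_fraction_by_clade = as.list(vm_frac),
    most_vm_enriched_clade = best_enrich$clade,
    vm_enrichment_p = best_enrich$p,
    vm_enrichment_or = best_enrich$odds_ratio,
    mean_max_cpg_primary =
      subfam_summary$mean_max_score[subfam_summary$subfamily ==
                                      config$ltr_subfamily],
    mean_background_cpg = mean(background$max_score),
    context_fractions = ctx_compare,
    most_constitutive_proximal_clade = names(which.max(ctx_by_clade)),
    constitutive_fraction_by_clade = as.list(ctx_by_clade),
    polymorphism_rate_by_clade = setNames(as.list(poly$rate), poly$clade),
    most_polymorphic_clade = poly$clade[which.max(poly$rate)],
    oe_by_bin = setNames(as.list(oe$oe), oe$bin),
    methylation_sd_vm = mean(sd_vm),
    methylation_sd_nonvm = mean(sd_nonvm),
    methylation_test_p = meth_test$p_two_sided,
    n_novel_peaks = nrow(novel),
    responsive_cpg_p = resp$test$p_two_sided)

  structure(list(
    tables = list(
      flanked_ints = flanked, clades = data.frame(
        instance_id = names(clades), clade = unname(clades),
        stringsAsFactors = FALSE),
      clade_profiles = profiles, element_signal = elem_mean,
      element_cpg = scores, subfamily_cpg = subfam_summary,
      background_cpg = background, context = ctx,
      context_compare = ctx_compare, enrichment = enrich, oe_age = oe,
      polymorphism = poly, methylation = meth_tab,
      merged_peaks_wt = wt_merged, merged_peaks_mut = mut_merged,
      novel_peaks = novel_annot$per_peak),
    summary = summary,
    provenance = list(parameters = unclass(config), seed = config$seed)),
    class = "ReportBundle")
}

#' Write a report bundle to disk
#'
#' Stage tables as TSV plus the summary and provenance as JSON.
#'
#' @param report a `ReportBundle` from [run_pipeline()].
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$tables)) {
    t <- report$tables[[nm]]
    if (is.data.frame(t))
      write.table(t, file.path(outdir, paste0(nm, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(summary = report$summary,
                            provenance = report$provenance),
                       file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}

#' @export
print.ReportBundle <- function(x, ...) {
  s <- x$summary
  cat("vmte pipeline report\n")
  cat(sprintf("  LTRs profiled: %d (clades: %s)\n", s$n_ltr_profiled,
              paste(sprintf("%s=%d", names(s$clade_sizes),
                            unlist(s$clade_sizes)), collapse = ", ")))
  cat(sprintf("  most VM-enriched clade: %s (Fisher p = %.3g, OR = %.2f)\n",
              s$most_vm_enriched_clade, s$vm_enrichment_p,
              s$vm_enrichment_or))
  cat(sprintf("  lowest KAP1-like signal: %s\n", s$lowest_kap1_clade))
  cat(sprintf("  most polymorphic clade: %s\n", s$most_polymorphic_clade))
  cat(sprintf("  novel peaks: %d\n", s$n_novel_peaks))
  invisible(x)
}
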