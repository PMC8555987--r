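#' Is an element fully deleted in a strain?
#'
#' TRUE iff a single deletion interval covers 100% of the element
#' (`del.start <= start` and `del.end >= end`), mirroring a per-feature
#' full-fraction intersection test. Adjacent deletions that jointly cover
#' the element do not count.
#'
#' @param instance single-row instance data.frame.
#' @param strain_deletions interval data.frame of deletions for one strain.
#' @return logical.
#' @export
is_fully_deleted <- function(instance, strain_deletions) {
  d <- strain_deletions[strain_deletions$chrom == instance$chrom, ,
                        drop = FALSE]
  any(d$start <= instance$start & d$end >= instance$end)
}

#' Presence/absence matrix of elements across strains
#'
#' Present = not fully deleted (see [is_fully_deleted()]).
#'
#' @param instances repeat instance data.frame.
#' @param deletions_by_strain named list (strain -> deletion data.frame).
#' @return logical matrix, instances x strains (TRUE = present).
#' @export
presence_matrix <- function(instances, deletions_by_strain) {
  gr <- as_granges(instances)
  m <- vapply(deletions_by_strain, function(dels) {
    if (is.null(dels) || nrow(dels) == 0L) return(rep(TRUE, nrow(instances)))
    hits <- GenomicRanges::countOverlaps(gr, as_granges(dels),
                                         type = "within",
                                         ignore.strand = TRUE)
    hits == 0L
  }, logical(nrow(instances)))
  m <- matrix(m, nrow = nrow(instances),
              dimnames = list(instances$instance_id,
                              names(deletions_by_strain)))
  m
}

#' Read a strain tree description
#'
#' One branch per line, comma-separated strain ids, ordered by divergence.
#'
#' @param path text file path.
#' @return named list of character vectors (branch -> strains).
#' @export
read_strain_tree <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  branches <- lapply(lines, function(l) trimws(strsplit(l, ",")[[1]]))
  names(branches) <- sprintf("branch%d", seq_along(branches))
  all <- unlist(branches)
  if (anyDuplicated(all)) stop_vmte("strain tree branches are not disjoint")
  branches
}

#' Collapse a strain presence matrix into phylogeny branches
#'
#' A branch scores present when the element is present in any of its member
#' strains.
#'
#' @param matrix logical presence matrix from [presence_matrix()].
#' @param tree named list of branches (strain id vectors).
#' @return logical matrix, instances x branches.
#' @export
collapse_branches <- function(matrix, tree) {
  out <- vapply(tree, function(strains) {
    miss <- setdiff(strains, colnames(matrix))
    if (length(miss) == length(strains))
      stop_vmte("branch has no profiled strain: %s", paste(strains, collapse = ","))
    strains <- intersect(strains, colnames(matrix))
    rowSums(matrix[, strains, drop = FALSE]) > 0L
  }, logical(nrow(matrix)))
  matrix(out, nrow = nrow(matrix),
         dimnames = list(rownames(matrix), names(tree)))
}

#' Per-clade polymorphism rate
#'
#' An element is polymorphic when it is absent from at least one branch;
#' the rate is the polymorphic fraction per clade.
#'
#' @param branch_presence logical matrix from [collapse_branches()].
#' @param clades named vector instance_id -> clade covering every row.
#' @return data.frame `clade`, `n`, `n_polymorphic`, `rate`.
#' @export
clade_polymorphism_rate <- function(branch_presence, clades) {
  ids <- rownames(branch_presence)
  if (any(!ids %in% names(clades))) stop_vmte("clade label missing for some rows")
  poly <- rowSums(!branch_presence) > 0L
  labs <- sort(unique(clades[ids]))
  do.call(rbind, lapply(labs, function(cl) {
    i <- which(clades[ids] == cl)
    if (!length(i)) stop_vmte("empty clade %s", cl)
    data.frame(clade = cl, n = length(i), n_polymorphic = sum(poly[i]),
               rate = mean(poly[i]), stringsAsFactors = FALSE)
  }))
}
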