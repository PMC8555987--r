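ALPHABET <- c("A", "C", "G", "T", "N", "-")

encode_seq <- function(s) {
  codes <- match(strsplit(toupper(s), "")[[1]], ALPHABET) - 1L
  if (anyNA(codes)) stop_vmte("sequence contains symbols outside {A,C,G,T,N,-}")
  codes
}

decode_seq <- function(codes) paste(ALPHABET[codes + 1L], collapse = "")

#' Alignment scoring scheme
#'
#' Linear-gap scheme used by all alignment steps. `N` matches nothing and
#' always scores as a mismatch (including against another `N`); a gap paired
#' with a gap scores 0.
#'
#' @param match,mismatch,gap scores per aligned symbol pair.
#' @return a `ScoringScheme` list.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap = -2) {
  if (!(match > mismatch)) stop_vmte("require match > mismatch")
  if (!(gap < 0)) stop_vmte("require gap < 0")
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "ScoringScheme")
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch with a linear gap penalty and deterministic traceback
#' (tie order: diagonal, then up, then left).
#'
#' @param a,b nucleotide strings over `A,C,G,T,N`.
#' @param scoring a [scoring_scheme()].
#' @return list with `aligned_a`, `aligned_b` (gapped strings) and `score`.
#' @export
align_pair <- function(a, b, scoring = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop_vmte("cannot align an empty sequence")
  res <- .align_pair_cpp(encode_seq(a), encode_seq(b),
                         scoring$match, scoring$mismatch, scoring$gap)
  list(aligned_a = decode_seq(res$a), aligned_b = decode_seq(res$b),
       score = res$score)
}

# k-mer presence matrix (rows = sequences, 4^k columns); k-mers containing
# N are skipped.
kmer_presence <- function(sequences, k) {
  enc <- lapply(sequences, encode_seq)
  short <- vapply(enc, length, 1L) < k
  if (any(short)) stop_vmte("sequence shorter than k = %d", k)
  m <- matrix(FALSE, nrow = length(sequences), ncol = 4L^k)
  pow <- 4L^(0:(k - 1L))
  for (i in seq_along(enc)) {
    x <- enc[[i]]
    n <- length(x) - k + 1L
    idx <- vapply(seq_len(n), function(j) {
      w <- x[j:(j + k - 1L)]
      if (any(w >= 4L)) return(NA_real_)
      sum(w * pow) + 1
    }, numeric(1))
    idx <- idx[!is.na(idx)]
    if (length(idx)) m[i, unique(idx)] <- TRUE
  }
  m
}

#' Guide tree from k-mer distances
#'
#' UPGMA on the Jaccard k-mer distance
#' `d(x, y) = 1 - |kmers(x) ∩ kmers(y)| / |kmers(x) ∪ kmers(y)|`.
#'
#' @param sequences named character vector of sequences.
#' @param k k-mer length (default 6).
#' @return a `vmte_tree` (see [upgma_tree()]).
#' @export
build_guide_tree <- function(sequences, k = 6) {
  if (length(sequences) < 2L) stop_vmte("need at least 2 sequences")
  pm <- kmer_presence(sequences, k) * 1
  inter <- tcrossprod(pm)
  sizes <- rowSums(pm)
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - ifelse(uni > 0, inter / uni, 1)
  diag(d) <- 0
  dimnames(d) <- list(names(sequences), names(sequences))
  upgma_tree(d)
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage (size-weighted) agglomeration; merge height is half the
#' cluster distance, so leaf-to-root heights are ultrametric. Equal minimum
#' distances are broken by the lowest cluster-index pair, making the tree a
#' deterministic function of the matrix and its row order.
#'
#' @param d symmetric non-negative distance matrix with dimnames.
#' @return object of class `vmte_tree`: list with `root` (nested nodes with
#'   `height` and `children`), `labels` (leaf labels, input order) and
#'   `merges` (merge-ordered list of `members`/`height` records).
#' @export
upgma_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop_vmte("need at least 2 items to cluster")
  if (any(is.na(d)) || any(is.nan(d))) stop_vmte("NaN/NA in distance matrix")
  if (any(d < 0)) stop_vmte("negative distances")
  if (max(abs(d - t(d))) > 1e-9) stop_vmte("distance matrix not symmetric")
  labels <- rownames(d) %||% as.character(seq_len(n))

  nodes <- lapply(seq_len(n), function(i)
    list(leaf = TRUE, id = labels[i], height = 0))
  members <- lapply(seq_len(n), function(i) i)
  sizes <- rep(1L, n)
  born <- seq_len(n)          # creation index, for tie-breaking
  active <- rep(TRUE, n)
  D <- d
  merges <- vector("list", n - 1L)
  next_born <- n

  for (m in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL
    for (ii in seq_along(idx)) {
      for (jj in seq_along(idx)) {
        if (jj <= ii) next
        i <- idx[ii]; j <- idx[jj]
        a <- min(born[i], born[j]); b <- max(born[i], born[j])
        key <- c(D[i, j], a, b)
        if (is.null(best) || key[1] < best$key[1] - 1e-12 ||
            (abs(key[1] - best$key[1]) <= 1e-12 &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    h <- D[i, j] / 2
    # order children so the one containing the smallest original index is first
    first <- if (min(members[[i]]) <= min(members[[j]])) i else j
    second <- if (first == i) j else i
    node <- list(leaf = FALSE, height = h,
                 children = list(nodes[[first]], nodes[[second]]))
    new_members <- sort(c(members[[i]], members[[j]]))
    merges[[m]] <- list(members = labels[new_members], height = h)
    # size-weighted average-linkage update, stored in slot i
    for (k2 in which(active)) {
      if (k2 == i || k2 == j) next
      D[i, k2] <- D[k2, i] <-
        (sizes[i] * D[i, k2] + sizes[j] * D[j, k2]) / (sizes[i] + sizes[j])
    }
    nodes[[i]] <- node
    members[[i]] <- new_members
    sizes[i] <- sizes[i] + sizes[j]
    next_born <- next_born + 1L
    born[i] <- next_born
    active[j] <- FALSE
  }
  structure(list(root = nodes[[which(active)]], labels = labels,
                 merges = merges),
            class = "vmte_tree")
}

#' @export
print.vmte_tree <- function(x, ...) {
  cat(sprintf("UPGMA tree: %d leaves, root height %.4g\n",
              length(x$labels), x$root$height))
  invisible(x)
}

tree_leaves <- function(node) {
  if (node$leaf) return(node$id)
  c(tree_leaves(node$children[[1]]), tree_leaves(node$children[[2]]))
}

#' Progressive multiple sequence alignment
#'
#' Profile-profile Needleman-Wunsch up a guide tree (leaves first). The
#' score of aligning two profile columns is the mean pairwise symbol score
#' over all row pairs; a profile column against a gap column costs the flat
#' gap penalty. De-gapping any output row reproduces its input sequence.
#'
#' @param sequences named character vector.
#' @param guide_tree a `vmte_tree` whose leaves are `names(sequences)`;
#'   built with [build_guide_tree()] when `NULL`.
#' @param scoring a [scoring_scheme()].
#' @return object of class `vmte_msa`: list with `rows` (named gapped
#'   strings, input order), `width`, and `column_map` (original column index
#'   of each retained column; identity until trimming).
#' @export
progressive_msa <- function(sequences, guide_tree = NULL,
                            scoring = scoring_scheme()) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop_vmte("sequences must have unique names")
  if (length(sequences) == 1L) {
    return(new_msa(setNames(as.character(sequences), names(sequences))))
  }
  if (is.null(guide_tree))
    guide_tree <- build_guide_tree(sequences,
                                   k = min(6, min(nchar(sequences))))
  if (!setequal(tree_leaves(guide_tree$root), names(sequences)))
    stop_vmte("guide tree leaves do not match sequence names")

  rec <- function(node) {
    if (node$leaf) {
      m <- matrix(encode_seq(sequences[[node$id]]), nrow = 1)
      rownames(m) <- node$id
      return(m)
    }
    A <- rec(node$children[[1]])
    B <- rec(node$children[[2]])
    res <- .align_profiles_cpp(A, B, scoring$match, scoring$mismatch,
                               scoring$gap)
    out <- res$alignment
    rownames(out) <- c(rownames(A), rownames(B))
    out
  }
  aln <- rec(guide_tree$root)
  aln <- aln[names(sequences), , drop = FALSE]   # restore input order
  rows <- setNames(apply(aln, 1, decode_seq), rownames(aln))
  msa <- new_msa(rows)
  # structural invariant: projection of rows back to sequences is lossless
  for (id in names(sequences)) {
    if (gsub("-", "", msa$rows[[id]], fixed = TRUE) != toupper(sequences[[id]]))
      stop_vmte("internal error: alignment row does not reproduce input %s", id)
  }
  msa
}

new_msa <- function(rows, column_map = NULL) {
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop_vmte("alignment rows have unequal widths")
  structure(list(rows = rows, width = w,
                 column_map = column_map %||% seq_len(w)),
            class = "vmte_msa")
}

#' @export
print.vmte_msa <- function(x, ...) {
  cat(sprintf("MSA: %d rows x %d columns\n", length(x$rows), x$width))
  invisible(x)
}

#' Alignment as an integer code matrix
#' @param msa a `vmte_msa`.
#' @return integer matrix (rows x columns), codes A=0,C=1,G=2,T=3,N=4,gap=5.
#' @export
msa_matrix <- function(msa) {
  m <- do.call(rbind, lapply(msa$rows, encode_seq))
  rownames(m) <- names(msa$rows)
  m
}

#' Trim low-occupancy alignment columns
#'
#' Removes columns whose non-gap fraction is strictly below `min_frac`
#' (a column occupied in exactly 10 percent of rows survives the default).
#' `column_map` records each surviving column's index in the pre-trim
#' alignment so that base-wise projections can be subset consistently.
#'
#' @param msa a `vmte_msa`.
#' @param min_frac minimum non-gap fraction (default 0.10).
#' @return trimmed `vmte_msa`.
#' @export
trim_low_occupancy_columns <- function(msa, min_frac = 0.10) {
  m <- msa_matrix(msa)
  frac <- colMeans(m != 5L)
  keep <- frac >= min_frac - 1e-12
  if (!any(keep)) stop_vmte("degenerate alignment: all columns trimmed")
  m2 <- m[, keep, drop = FALSE]
  rows <- setNames(apply(m2, 1, decode_seq), rownames(m2))
  new_msa(rows, column_map = msa$column_map[keep])
}

#' Pairwise p-distance matrix of an alignment
#'
#' `d(i, j)` is the mismatch fraction over comparable columns (both rows
#' non-gap; `N` counts as mismatch). Pairs with fewer than 20 comparable
#' columns are flagged in the `"low_comparable"` attribute; a pair with no
#' comparable columns is an error.
#'
#' @param msa a `vmte_msa` (typically trimmed).
#' @return symmetric numeric matrix with instance ids as dimnames.
#' @export
pdistance_matrix <- function(msa) {
  m <- msa_matrix(msa)
  res <- .pdistance_cpp(m)
  d <- res$d
  if (any(is.na(d))) stop_vmte("row pair with no comparable columns")
  dimnames(d) <- list(rownames(m), rownames(m))
  comp <- res$comparable
  low <- which(comp < 20L & upper.tri(comp), arr.ind = TRUE)
  attr(d, "low_comparable") <-
    if (nrow(low)) data.frame(i = rownames(m)[low[, 1]],
                              j = rownames(m)[low[, 2]],
                              comparable = comp[low])
    else data.frame(i = character(), j = character(), comparable = integer())
  d
}

#' Cut a UPGMA tree into k clades
#'
#' Removes the k-1 highest (last) merges; the connected components below
#' the cut are the clades. Labels `clade1..cladeK` are assigned in order of
#' each clade's smallest member index (tree leaf input order).
#'
#' @param tree a `vmte_tree`.
#' @param k number of clades, `1 <= k <=` number of leaves.
#' @return list with `clades` (named character vector instance_id -> label)
#'   and `k`.
#' @export
assign_clades <- function(tree, k) {
  labels <- tree$labels
  n <- length(labels)
  if (k < 1L || k > n) stop_vmte("k must be in [1, %d]", n)
  comp <- seq_len(n)                     # union-find by smallest index
  names(comp) <- labels
  apply_n <- n - k
  if (apply_n > 0) {
    for (m in seq_len(apply_n)) {
      idx <- match(tree$merges[[m]]$members, labels)
      comp[idx] <- min(comp[idx])
    }
  }
  roots <- sort(unique(comp))
  lab <- setNames(sprintf("clade%d", seq_along(roots)), roots)
  clades <- setNames(unname(lab[as.character(comp)]), labels)
  list(clades = clades, k = k)
}

#' Run the full clade-calling chain on a set of sequences
#'
#' Convenience wrapper: guide tree, progressive alignment, low-occupancy
#' trimming, p-distance, UPGMA and tree cutting.
#'
#' @param sequences named character vector of element sequences.
#' @param k number of clades.
#' @param min_frac trimming threshold (see [trim_low_occupancy_columns()]).
#' @param scoring a [scoring_scheme()].
#' @return list with `msa` (untrimmed), `trimmed`, `tree`, `clades`
#'   (named vector) and `k`.
#' @export
call_clades <- function(sequences, k, min_frac = 0.10,
                        scoring = scoring_scheme()) {
  guide <- build_guide_tree(sequences)
  msa <- progressive_msa(sequences, guide, scoring)
  trimmed <- trim_low_occupancy_columns(msa, min_frac)
  d <- pdistance_matrix(trimmed)
  tree <- upgma_tree(d)
  cl <- assign_clades(tree, k)
  list(msa = msa, trimmed = trimmed, tree = tree,
       clades = cl$clades, k = k)
}

#' Write an MSA as gapped FASTA
#' @param msa a `vmte_msa`.
#' @param path output path.
#' @export
write_msa_fasta <- function(msa, path) {
  x <- Biostrings::BStringSet(unlist(msa$rows))
  Biostrings::writeXStringSet(x, path)
}
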