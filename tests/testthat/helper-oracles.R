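# Independent brute-force oracles used to validate the optimized paths.
# Each oracle is written from the definition, not from the implementation.

# naive CpG O/E recount: explicit loop over characters
oracle_cpg_score <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  nc <- 0L; ng <- 0L; ncpg <- 0L
  for (i in seq_len(n)) {
    if (ch[i] == "C") nc <- nc + 1L
    if (ch[i] == "G") ng <- ng + 1L
    if (i < n && ch[i] == "C" && ch[i + 1L] == "G") ncpg <- ncpg + 1L
  }
  if (nc == 0L || ng == 0L) return(0)
  ncpg * n / (nc * ng)
}

# exhaustive global alignment score by recursion over all monotone paths
oracle_align_score <- function(a, b, sc = vmte::scoring_scheme()) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  sym <- function(x, y) {
    if (x == "N" || y == "N") return(sc$mismatch)
    if (x == y) sc$match else sc$mismatch
  }
  rec <- function(i, j) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best, sym(av[i], bv[j]) + rec(i + 1L, j + 1L))
    if (i <= length(av)) best <- max(best, sc$gap + rec(i + 1L, j))
    if (j <= length(bv)) best <- max(best, sc$gap + rec(i, j + 1L))
    best
  }
  rec(1L, 1L)
}

# UPGMA from the definition: cluster distance = mean over all original
# cross pairs; returns the merge list (member label sets + heights)
oracle_upgma <- function(d) {
  labels <- rownames(d)
  clusters <- lapply(seq_len(nrow(d)), identity)
  merges <- list()
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best[1]) best <- c(dd, i, j)
    }
    i <- best[2]; j <- best[3]
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    merges[[length(merges) + 1L]] <- list(members = labels[merged],
                                          height = best[1] / 2)
    clusters[[i]] <- merged
    clusters[[j]] <- NULL
  }
  merges
}

# full enumeration Fisher two-sided p from factorials
oracle_fisher_p <- function(t) {
  n <- sum(t); r1 <- sum(t[1, ]); r2 <- sum(t[2, ])
  c1 <- sum(t[, 1]); c2 <- sum(t[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  lf <- lfactorial
  const <- lf(r1) + lf(r2) + lf(c1) + lf(c2) - lf(n)
  as_ <- max(0, r1 - c2):min(r1, c1)
  probs <- vapply(as_, function(a) {
    b <- r1 - a; cc <- c1 - a; dd <- r2 - cc
    exp(const - (lf(a) + lf(b) + lf(cc) + lf(dd)))
  }, numeric(1))
  pobs <- probs[match(t[1, 1], as_)]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

mann_whitney_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact two-sided rank-sum p by enumerating all group assignments
oracle_wilcoxon_p <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  mid <- nx * length(y) / 2
  dev_obs <- abs(mann_whitney_u(x, y) - mid)
  combs <- utils::combn(length(pool), nx)
  devs <- apply(combs, 2, function(i)
    abs(mann_whitney_u(pool[i], pool[-i]) - mid))
  mean(devs >= dev_obs - 1e-9)
}

# all-pairs nearest gap (0-based half-open, 0 on overlap)
oracle_nearest <- function(iv, feats) {
  vapply(seq_len(nrow(iv)), function(i) {
    same <- feats[feats$chrom == iv$chrom[i], , drop = FALSE]
    if (nrow(same) == 0L) return(NA_real_)
    min(vapply(seq_len(nrow(same)), function(j)
      max(0, max(iv$start[i], same$start[j]) -
            min(iv$end[i], same$end[j])), numeric(1)))
  }, numeric(1))
}

random_dna_str <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
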