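#' Neighbor-joining tree construction
#'
#' Saitou-Nei agglomeration over a distance matrix: at each step the pair
#' minimizing Q(i, j) = (r - 2) d(i, j) - R_i - R_j is joined, with ties
#' broken by the lowest index pair in the current matrix order. Negative
#' branch lengths are clamped to zero with the deficit moved to the sister
#' edge, so path lengths through the new node are preserved. On additive
#' distances the true tree (topology and branch lengths) is recovered
#' exactly.
#'
#' @param d symmetric labelled distance matrix (n >= 3), e.g. from
#'   [pairwise_distance()].
#' @return An unrooted \pkg{ape} `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) .stopf("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (any(!is.finite(d))) .stopf("distance matrix contains non-finite entries")
  if (max(abs(d - t(d))) > 1e-8) .stopf("distance matrix is not symmetric")
  labs <- rownames(d)
  frag <- labs   # newick fragment per active node
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  while (nrow(d) > 3) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    best <- Inf; bi <- 1L; bj <- 2L
    for (i in 1:(r - 1)) for (j in (i + 1):r)
      if (Q[i, j] < best - 1e-12) { best <- Q[i, j]; bi <- i; bj <- j }
    li <- 0.5 * d[bi, bj] + (R[bi] - R[bj]) / (2 * (r - 2))
    lj <- d[bi, bj] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[bi], fmt(li), frag[bj], fmt(lj))
    others <- setdiff(seq_len(r), c(bi, bj))
    dn <- 0.5 * (d[bi, others] + d[bj, others] - d[bi, bj])
    d2 <- rbind(cbind(d[others, others, drop = FALSE], dn),
                c(dn, 0))
    frag <- c(frag[others], newfrag)
    rownames(d2) <- colnames(d2) <- paste0("n", seq_len(r - 1))
    d <- d2
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(la), frag[2], fmt(lb), frag[3], fmt(lc))
  ape::read.tree(text = nwk)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `bootstrap_n` times,
#' rebuilds the NJ tree for every replicate, and reports the fraction of
#' replicate trees containing each internal bipartition of the reference
#' tree (counted with `ape::prop.clades`). Column resampling depends only
#' on the seed and the column count, so supports are invariant under taxon
#' reordering. Replicates whose distance matrix is saturated are skipped
#' and the support denominator reduced accordingly.
#'
#' @param aln an [msa].
#' @param model,gap_handling passed to [pairwise_distance()].
#' @param bootstrap_n number of replicates (default 1000).
#' @param seed RNG seed for column resampling.
#' @return the reference `phylo` tree with `node.label` set to support
#'   fractions in `[0, 1]` and a numeric `"support"` attribute.
#' @export
bootstrap_support <- function(aln, model = "jtt",
                              gap_handling = "pairwise_deletion",
                              bootstrap_n = 1000L, seed = 1L) {
  stopifnot(bootstrap_n >= 1)
  ref <- neighbor_joining(pairwise_distance(aln, model, gap_handling))
  L <- nchar(aln[[1]])
  idx_mat <- .seeded(seed,
    matrix(sample.int(L, L * bootstrap_n, replace = TRUE), nrow = bootstrap_n))
  rows <- .msa_charmat(aln)
  reps <- list()
  for (b in seq_len(bootstrap_n)) {
    sub <- rows[, idx_mat[b, ], drop = FALSE]
    rows_b <- stats::setNames(apply(sub, 1, paste, collapse = ""), names(aln))
    db <- tryCatch(pairwise_distance(msa(rows_b), model, gap_handling),
                   error = function(e) NULL)
    if (is.null(db) || any(!is.finite(db))) next
    reps[[length(reps) + 1]] <- neighbor_joining(db)
  }
  if (!length(reps)) .stopf("all bootstrap replicates were saturated")
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supp <- counts / length(reps)
  ref$node.label <- sprintf("%.3f", supp)
  attr(ref, "support") <- supp
  attr(ref, "n_replicates") <- length(reps)
  ref
}
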