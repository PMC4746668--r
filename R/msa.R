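#' Multiple sequence alignments
#'
#' An `msa` is a named character vector of equal-length aligned rows with
#' `-` gaps; removing the gaps from row i returns input sequence i exactly.
#'
#' @param rows named character vector of aligned sequences.
#' @return An `msa` object.
#' @export
msa <- function(rows) {
  if (length(unique(nchar(rows))) != 1) .stopf("aligned rows differ in length")
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    .stopf("msa rows need unique names")
  structure(rows, class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns\n", length(x), nchar(x[[1]])))
  invisible(x)
}

#' @rdname msa
#' @param x an `msa`.
#' @export
degap <- function(x) gsub("-", "", unclass(x), fixed = TRUE)

.msa_charmat <- function(x) {
  do.call(rbind, strsplit(unclass(x), ""))
}

# fractional common k-mer distance used for the guide tree
.kmer_distance <- function(seqs, k = 3L) {
  n <- length(seqs)
  kmers <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(table(character(0)))
    table(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  })
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ki <- kmers[[i]]; kj <- kmers[[j]]
    common <- intersect(names(ki), names(kj))
    shared <- sum(pmin(ki[common], kj[common]))
    denom <- min(sum(ki), sum(kj))
    d[i, j] <- d[j, i] <- if (denom > 0) 1 - shared / denom else 1
  }
  d
}

.profile_counts <- function(rows) {
  cm <- .msa_charmat(msa(rows))
  t(vapply(AA20, function(a) colSums(cm == a), numeric(ncol(cm))))
}

# merge two sub-alignments via profile-profile affine alignment
.merge_profiles <- function(rows_a, rows_b, sub, gap_open, gap_extend) {
  pa <- .profile_counts(rows_a)
  pb <- .profile_counts(rows_b)
  r <- .profile_align_cpp(pa, pb, sub[AA20, AA20], length(rows_a), length(rows_b),
                          gap_open, gap_extend)
  expand <- function(rows, mask) {
    vapply(rows, function(s) {
      ch <- strsplit(s, "")[[1]]
      out <- character(length(mask))
      out[mask == 1] <- ch
      out[mask == 0] <- "-"
      paste(out, collapse = "")
    }, "")
  }
  c(expand(rows_a, r$a), expand(rows_b, r$b))
}

#' Progressive multiple sequence alignment
#'
#' Builds a k-mer distance matrix, a neighbor-joining guide tree
#' (midpoint-rooted), and merges sub-alignments by profile-profile affine
#' alignment in post-order. Defaults are standard protein settings:
#' BLOSUM62, gap open 10, gap extend 0.5, k = 3.
#'
#' @param seqs a [seq_set] (>= 2 sequences).
#' @param substitution_matrix scoring matrix; default BLOSUM62.
#' @param gap_open,gap_extend affine gap penalties.
#' @param k k-mer size for guide distances.
#' @return An [msa].
#' @export
build_msa <- function(seqs, substitution_matrix = NULL,
                      gap_open = 10, gap_extend = 0.5, k = 3L) {
  n <- length(seqs)
  if (n < 2) .stopf("need at least two sequences")
  sub <- if (is.null(substitution_matrix)) .blosum62() else substitution_matrix
  rows <- stats::setNames(as.character(seqs), names(seqs))
  if (n == 2) {
    aln <- global_align(rows[[1]], rows[[2]], sub, gap_open, gap_extend)
    return(msa(stats::setNames(c(aln$a, aln$b), names(rows))))
  }
  d <- .kmer_distance(rows, k = k)
  guide <- phangorn::midpoint(neighbor_joining(d))
  merge_node <- function(node) {
    if (node <= length(guide$tip.label)) return(rows[guide$tip.label[node]])
    kids <- guide$edge[guide$edge[, 1] == node, 2]
    acc <- merge_node(kids[1])
    for (kk in kids[-1])
      acc <- .merge_profiles(acc, merge_node(kk), sub, gap_open, gap_extend)
    acc
  }
  root <- length(guide$tip.label) + 1L
  out <- merge_node(root)
  msa(out[names(rows)])
}
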