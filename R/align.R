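#' Global pairwise alignment with affine gaps
#'
#' Gotoh dynamic programming over a substitution matrix. A gap of length
#' k costs `gap_open + (k - 1) * gap_extend`. Traceback ties are broken
#' deterministically: match > delete (gap in `b`) > insert (gap in `a`).
#'
#' @param a,b sequence strings.
#' @param substitution_matrix scoring matrix with residue dimnames;
#'   default BLOSUM62 (from \pkg{Biostrings}).
#' @param gap_open,gap_extend positive gap penalties.
#' @return list with `a`, `b` (aligned strings with `-` gaps) and `score`.
#' @export
global_align <- function(a, b, substitution_matrix = NULL,
                         gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) .stopf("empty sequence")
  sub <- if (is.null(substitution_matrix)) .blosum62() else substitution_matrix
  alpha <- rownames(sub)
  ia <- .encode_residues(toupper(a), alpha)
  ib <- .encode_residues(toupper(b), alpha)
  r <- .gotoh_align_cpp(ia, ib, sub, gap_open, gap_extend)
  decode <- function(v) {
    ch <- rep("-", length(v))
    ch[v >= 0] <- alpha[v[v >= 0] + 1L]
    paste(ch, collapse = "")
  }
  list(a = decode(r$a), b = decode(r$b), score = r$score)
}

#' Coverage, identity and similarity of an aligned pair
#'
#' Aligns two proteins globally and summarizes the aligned region (the
#' span between the first and last columns where both sequences have a
#' residue): `coverage` is the fraction of the *longer* sequence inside
#' that region, `identity` the fraction of identical residues over
#' both-residue columns, and `similarity` the fraction of identical or
#' positively scoring (BLOSUM62 > 0) residue pairs.
#'
#' @param a,b protein sequence strings.
#' @param ... passed to [global_align()].
#' @return list with `coverage`, `identity`, `similarity`, `alignment`.
#' @export
pair_stats <- function(a, b, ...) {
  aln <- global_align(a, b, ...)
  ca <- strsplit(aln$a, "")[[1]]
  cb <- strsplit(aln$b, "")[[1]]
  both <- which(ca != "-" & cb != "-")
  if (!length(both)) .stopf("alignment has no aligned residue pair")
  span <- both[1]:both[length(both)]
  longer <- max(nchar(a), nchar(b))
  cover_n <- if (nchar(a) >= nchar(b)) sum(ca[span] != "-") else sum(cb[span] != "-")
  sub <- .blosum62()
  ident <- ca[both] == cb[both]
  pos <- sub[cbind(ca[both], cb[both])] > 0
  list(coverage = cover_n / longer,
       identity = mean(ident),
       similarity = mean(ident | pos),
       alignment = aln)
}

#' Remove redundant sequences
#'
#' Clusters sequences by single linkage, linking two sequences when their
#' global-alignment identity is at least `identity_threshold` *and* the
#' aligned region covers at least `coverage_threshold` of the longer
#' sequence (so a fragment is not merged with its full-length source).
#' The longest member of each cluster is kept (ties broken by
#' lexicographically smallest id). Applying the function twice gives the
#' same kept set as applying it once.
#'
#' @param seqs a [seq_set] of proteins.
#' @param identity_threshold default 0.95.
#' @param coverage_threshold default 0.90.
#' @return list with `kept`, `removed` (both [seq_set]s; `removed` may be
#'   empty) and `map`, a named character vector removed-id -> kept-id.
#' @export
remove_redundant <- function(seqs, identity_threshold = 0.95,
                             coverage_threshold = 0.90) {
  n <- length(seqs)
  if (n < 1) .stopf("need at least one sequence")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      st <- pair_stats(seqs[[i]], seqs[[j]])
      if (st$identity >= identity_threshold && st$coverage >= coverage_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  ids <- names(seqs)
  keep <- logical(n)
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    o <- members[order(-nchar(seqs[members]), ids[members])]
    keep[o[1]] <- TRUE
  }
  rep_of <- vapply(comp, function(cc) ids[keep & comp == cc][1], "")
  map <- stats::setNames(rep_of[!keep], ids[!keep])
  list(kept = seqs[keep],
       removed = if (any(!keep)) seqs[!keep] else seqs[0],
       map = map)
}
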