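#' Sequence sets
#'
#' Sequences are represented as a named character vector with attributes
#' `alphabet` (`"protein"` or `"dna"`) and `descriptions` (free text per
#' record, possibly empty). Names are record ids and must be unique,
#' non-empty and whitespace-free. Ambiguity codes (`X` for protein, `N` for
#' DNA) are permitted on input and treated as missing data by every scoring
#' stage.
#'
#' @param residues character vector of sequences.
#' @param ids record identifiers (tokens).
#' @param alphabet `"protein"` or `"dna"`.
#' @param descriptions optional free-text descriptions.
#' @return A `seq_set`: named character vector with attributes.
#' @export
seq_set <- function(residues, ids = names(residues),
                    alphabet = c("protein", "dna"),
                    descriptions = NULL) {
  alphabet <- match.arg(alphabet)
  if (is.null(ids)) .stopf("sequence records need ids")
  ids <- as.character(ids)
  residues <- toupper(as.character(residues))
  if (length(ids) != length(residues)) .stopf("ids/residues length mismatch")
  if (any(!nzchar(ids)) || any(grepl("[[:space:]]", ids)))
    .stopf("record ids must be non-empty and whitespace-free")
  if (anyDuplicated(ids))
    .stopf("duplicate record id: %s", ids[duplicated(ids)][1])
  if (any(!nzchar(residues))) {
    .stopf("record '%s' has empty residues", ids[!nzchar(residues)][1])
  }
  legal <- if (alphabet == "protein") paste0(c(AA20, "X", "*"), collapse = "") else "ACGTN"
  bad <- grepl(sprintf("[^%s]", legal), residues)
  if (any(bad))
    .stopf("record '%s' contains illegal %s characters", ids[bad][1], alphabet)
  structure(stats::setNames(residues, ids),
            alphabet = alphabet,
            descriptions = if (is.null(descriptions)) rep("", length(ids)) else descriptions,
            class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set of %d %s sequences (lengths %d..%d)\n",
              length(x), attr(x, "alphabet"),
              min(nchar(x)), max(nchar(x))))
  invisible(x)
}

#' @export
`[.seq_set` <- function(x, i) {
  y <- NextMethod()
  d <- attr(x, "descriptions")
  idx <- seq_along(x); names(idx) <- names(x)
  structure(y, alphabet = attr(x, "alphabet"),
            descriptions = d[idx[names(y)]], class = "seq_set")
}

#' Read a FASTA file
#'
#' Parsing is delegated to \pkg{Biostrings}; this wrapper enforces the
#' sequence-set invariants (non-empty residues, unique whitespace-free ids,
#' legal alphabet).
#'
#' @param path FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @return A [seq_set].
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) .stopf("no such file: %s", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) .stopf("malformed FASTA '%s': %s", path, conditionMessage(e)))
  if (length(x) == 0) .stopf("empty FASTA file: %s", path)
  headers <- names(x)
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- sub("^[^[:space:]]+[[:space:]]*", "", headers)
  seq_set(as.character(x), ids = ids, alphabet = alphabet, descriptions = desc)
}

#' Write a FASTA file
#'
#' @param seqs a [seq_set] (or named character vector).
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ids <- names(seqs)
  desc <- attr(seqs, "descriptions")
  hdr <- if (!is.null(desc)) ifelse(nzchar(desc), paste(ids, desc), ids) else ids
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", hdr[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
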