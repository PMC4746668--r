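#' Read and write newick trees
#'
#' Thin wrappers over \pkg{ape} with explicit validation errors.
#'
#' @param path newick file.
#' @return An \pkg{ape} `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  nopen <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  nclose <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (nopen != nclose) .stopf("unbalanced parentheses in '%s'", path)
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL)
  if (is.null(tr)) .stopf("cannot parse newick in '%s'", path)
  tr
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Expects a TSV with header columns `gene`, `condition`, `replicate`
#' (biological), `ct`, and optionally `tech_rep`. Rows sharing
#' (gene, condition, replicate) without an explicit `tech_rep` column are
#' numbered as successive technical replicates.
#'
#' @param path TSV file.
#' @return A `ct_table` data frame with columns gene, condition, bio_rep,
#'   tech_rep, ct.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "condition", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("Ct table missing column(s): %s", paste(miss, collapse = ", "))
  out <- data.frame(gene = as.character(df$gene),
                    condition = as.character(df$condition),
                    bio_rep = as.integer(df$replicate),
                    ct = as.numeric(df$ct),
                    stringsAsFactors = FALSE)
  out$tech_rep <- if ("tech_rep" %in% names(df)) as.integer(df$tech_rep) else
    stats::ave(seq_len(nrow(out)),
               paste(out$gene, out$condition, out$bio_rep, sep = "\r"),
               FUN = seq_along)
  ct_table(out)
}

#' @rdname read_ct_table
#' @param df data frame with columns gene, condition, bio_rep, tech_rep, ct.
#' @export
ct_table <- function(df) {
  need <- c("gene", "condition", "bio_rep", "tech_rep", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("ct_table missing column(s): %s", paste(miss, collapse = ", "))
  if (any(is.na(df$ct)) || any(df$ct <= 0))
    .stopf("Ct values must be positive (row %d)",
           which(is.na(df$ct) | df$ct <= 0)[1])
  if (any(df$bio_rep < 1) || any(df$tech_rep < 1))
    .stopf("replicate indices must be >= 1")
  class(df) <- c("ct_table", "data.frame")
  df
}

#' @rdname read_ct_table
#' @param x a `ct_table`.
#' @export
write_ct_table <- function(x, path) {
  out <- data.frame(gene = x$gene, condition = x$condition,
                    replicate = x$bio_rep, tech_rep = x$tech_rep, ct = x$ct)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
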