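#' Exon/intron architecture of a gene model
#'
#' Converts genomic exon intervals to gene-local coordinates (1-based from
#' the gene's 5' end, oriented 5'-to-3': minus-strand models are flipped).
#' Introns are derived as the gaps between consecutive exons; exons plus
#' introns tile the gene span exactly.
#'
#' @param model a [gene_model].
#' @return list with `gene_id`, `strand`, `span_length`, `exons` and
#'   `introns` (two-column local-coordinate matrices) and `intron_count`.
#' @export
gene_structure <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  gstart <- min(model$exons); gend <- max(model$exons)
  span <- gend - gstart + 1L
  if (model$strand == "+") {
    ex <- cbind(start = model$exons[, 1] - gstart + 1L,
                end = model$exons[, 2] - gstart + 1L)
  } else {
    ex <- cbind(start = gend - model$exons[, 2] + 1L,
                end = gend - model$exons[, 1] + 1L)
    ex <- ex[order(ex[, 1]), , drop = FALSE]
  }
  nE <- nrow(ex)
  introns <- if (nE > 1)
    cbind(start = unname(ex[-nE, 2]) + 1L, end = unname(ex[-1, 1]) - 1L)
  else matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  list(gene_id = model$gene_id, strand = model$strand, span_length = span,
       exons = ex, introns = introns, intron_count = nrow(introns))
}

#' Tabulate gene structures
#'
#' @param models list of [gene_model]s.
#' @return data.frame with gene_id, chromosome, strand, n_exons,
#'   n_introns, span_length.
#' @export
structure_table <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    gs <- gene_structure(m)
    data.frame(gene_id = m$gene_id, chromosome = m$chromosome,
               strand = m$strand, n_exons = nrow(gs$exons),
               n_introns = gs$intron_count, span_length = gs$span_length,
               stringsAsFactors = FALSE)
  }))
}
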