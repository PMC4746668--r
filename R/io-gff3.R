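#' Gene models
#'
#' A `gene_model` stores one mRNA's structure: chromosome, strand, and
#' 1-based inclusive exon and CDS intervals in genomic (ascending)
#' coordinates, as in GFF3. Minus-strand models are *not* flipped here;
#' 5'-to-3' orientation is applied downstream by [gene_structure()].
#'
#' @param gene_id,chromosome tokens.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds two-column matrices (start, end), 1-based inclusive.
#' @return A `gene_model` object.
#' @export
gene_model <- function(gene_id, chromosome, strand, exons, cds = NULL) {
  stopifnot(.is_token(gene_id), .is_token(chromosome), strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 1] > exons[, 2]))
    .stopf("gene '%s': interval with start > end", gene_id)
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    .stopf("gene '%s': overlapping exons", gene_id)
  if (is.null(cds)) cds <- exons
  cds <- matrix(as.integer(cds), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
  cds <- cds[order(cds[, 1]), , drop = FALSE]
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds[i, 1] >= exons[, 1] & cds[i, 2] <= exons[, 2])
    if (!inside)
      .stopf("gene '%s': CDS interval (%d,%d) outside exon bounds",
             gene_id, cds[i, 1], cds[i, 2])
  }
  structure(list(gene_id = gene_id, chromosome = chromosome, strand = strand,
                 exons = exons, cds = cds),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s %s%s, %d exon(s), span %d..%d\n",
              x$gene_id, x$chromosome, x$strand, nrow(x$exons),
              min(x$exons), max(x$exons)))
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 file (via \pkg{rtracklayer}) assuming canonical
#' gene -> mRNA -> exon/CDS nesting and returns one [gene_model] per mRNA.
#'
#' @param path GFF3 file with a `##gff-version` header.
#' @return Named list of [gene_model]s (by mRNA ID).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  first <- readLines(path, n = 1L)
  if (!grepl("^##gff-version", first))
    .stopf("'%s' lacks a ##gff-version header", path)
  g <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(g)
  df$type <- as.character(df$type)
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  parts <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(mrna) == 0) .stopf("'%s' contains no mRNA features", path)
  pl <- df$Parent[df$type %in% c("exon", "CDS")]
  if (any(lengths(pl) == 0))
    .stopf("'%s': exon/CDS feature missing a Parent attribute", path)
  parts$parent <- vapply(parts$Parent, function(p) as.character(p)[1], "")
  out <- list()
  for (i in seq_len(nrow(mrna))) {
    mid <- as.character(mrna$ID[i])
    sub <- parts[parts$parent == mid, , drop = FALSE]
    ex <- sub[sub$type == "exon", c("start", "end"), drop = FALSE]
    cd <- sub[sub$type == "CDS", c("start", "end"), drop = FALSE]
    if (nrow(ex) == 0) ex <- mrna[i, c("start", "end"), drop = FALSE]
    out[[mid]] <- gene_model(
      gene_id = mid,
      chromosome = as.character(mrna$seqnames[i]),
      strand = as.character(mrna$strand[i]),
      exons = as.matrix(ex),
      cds = if (nrow(cd) > 0) as.matrix(cd) else NULL)
  }
  out
}

#' Write gene models to GFF3
#'
#' @param models list of [gene_model]s.
#' @param path output path.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- c(min(m$exons), max(m$exons))
    gid <- paste0(m$gene_id, ".gene")
    lines <- c(lines,
      sprintf("%s\tfamsurvey\tgene\t%d\t%d\t.\t%s\t.\tID=%s", m$chromosome,
              span[1], span[2], m$strand, gid),
      sprintf("%s\tfamsurvey\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              m$chromosome, span[1], span[2], m$strand, m$gene_id, gid),
      sprintf("%s\tfamsurvey\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
              m$chromosome, m$exons[, 1], m$exons[, 2], m$strand, m$gene_id,
              seq_len(nrow(m$exons)), m$gene_id),
      sprintf("%s\tfamsurvey\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
              m$chromosome, m$cds[, 1], m$cds[, 2], m$strand, m$gene_id,
              m$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a chromosome location string
#'
#' Accepts the `"chr3:16012758:16014321"` layout used in family survey
#' tables.
#'
#' @param s location string `chromosome:start:end`.
#' @return list with `chromosome`, `start`, `end` (1-based inclusive).
#' @export
parse_location <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3 || !nzchar(parts[1]))
    .stopf("malformed location string: '%s'", s)
  start <- suppressWarnings(as.integer(parts[2]))
  end <- suppressWarnings(as.integer(parts[3]))
  if (is.na(start) || is.na(end)) .stopf("non-numeric coordinates in '%s'", s)
  if (start < 1) .stopf("start < 1 in '%s'", s)
  if (start > end) .stopf("start > end in '%s'", s)
  list(chromosome = parts[1], start = start, end = end)
}

#' @rdname parse_location
#' @param loc a location list as returned by [parse_location()].
#' @export
format_location <- function(loc) {
  sprintf("%s:%d:%d", loc$chromosome, loc$start, loc$end)
}
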