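#' Detect paralogous pairs by the 70/70 criterion
#'
#' Every unordered protein pair whose global alignment covers more than
#' `coverage_threshold` of the longer sequence *and* whose similarity over
#' aligned columns exceeds `similarity_threshold` (both strict, matching
#' the published "over 70%" wording) is reported. Output ordering is
#' deterministic: gene1 < gene2 lexicographically, pairs sorted.
#'
#' @param proteins a [seq_set] (>= 2 proteins).
#' @param coverage_threshold,similarity_threshold defaults 0.70.
#' @return data.frame with gene1, gene2, coverage, identity, similarity.
#' @export
detect_paralogs <- function(proteins, coverage_threshold = 0.70,
                            similarity_threshold = 0.70) {
  n <- length(proteins)
  if (n < 2) .stopf("need at least two proteins")
  ids <- names(proteins)
  rows <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    st <- pair_stats(proteins[[i]], proteins[[j]])
    if (st$coverage > coverage_threshold && st$similarity > similarity_threshold) {
      g <- sort(c(ids[i], ids[j]))
      rows[[length(rows) + 1]] <- data.frame(
        gene1 = g[1], gene2 = g[2], coverage = st$coverage,
        identity = st$identity, similarity = st$similarity,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      coverage = numeric(0), identity = numeric(0),
                      similarity = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$gene1, out$gene2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a duplication as tandem or segmental
#'
#' Tandem requires the two genes on the same chromosome and either
#' separated by at most `tandem_max_separation` bp or with at most
#' `tandem_max_intervening_genes` other genes between them; everything
#' else is segmental.
#'
#' @param gene1,gene2 gene ids.
#' @param locations named list of location lists (as from
#'   [parse_location()]) covering at least the two genes.
#' @param all_gene_locations optional full location list used to count
#'   intervening genes; when absent only the separation rule applies.
#' @param tandem_max_separation bp, default 1e5.
#' @param tandem_max_intervening_genes default 5.
#' @return `"tandem"` or `"segmental"`.
#' @export
classify_duplication <- function(gene1, gene2, locations,
                                 all_gene_locations = NULL,
                                 tandem_max_separation = 100000,
                                 tandem_max_intervening_genes = 5) {
  for (g in c(gene1, gene2))
    if (is.null(locations[[g]])) .stopf("no location for gene '%s'", g)
  l1 <- locations[[gene1]]; l2 <- locations[[gene2]]
  if (l1$chromosome != l2$chromosome) return("segmental")
  sep <- max(0, max(l1$start, l2$start) - min(l1$end, l2$end) - 1)
  if (sep <= tandem_max_separation) return("tandem")
  if (!is.null(all_gene_locations)) {
    lo <- min(l1$end, l2$end); hi <- max(l1$start, l2$start)
    others <- setdiff(names(all_gene_locations), c(gene1, gene2))
    between <- sum(vapply(all_gene_locations[others], function(l)
      l$chromosome == l1$chromosome && l$start > lo && l$end < hi, TRUE))
    if (between <= tandem_max_intervening_genes) return("tandem")
  }
  "segmental"
}

#' Back-translate an aligned protein pair to a codon alignment
#'
#' Each aligned protein column becomes a codon triplet column; protein
#' gaps become `---`. The CDS must translate exactly to its protein
#' (a trailing stop codon is trimmed; internal stops are an error).
#'
#' @param prot1_aln,prot2_aln aligned protein strings (equal length).
#' @param cds1,cds2 coding sequences of the two (ungapped) proteins.
#' @return list with aligned `cds1`, `cds2`.
#' @export
codon_align <- function(prot1_aln, prot2_aln, cds1, cds2) {
  if (nchar(prot1_aln) != nchar(prot2_aln))
    .stopf("aligned proteins differ in length")
  expand_one <- function(paln, cds) {
    p <- gsub("-", "", paln, fixed = TRUE)
    cds <- toupper(cds)
    if (nchar(cds) == 3 * (nchar(p) + 1)) {
      last <- substr(cds, nchar(cds) - 2, nchar(cds))
      if (.genetic_code()[[last]] == "*") cds <- substr(cds, 1, nchar(cds) - 3)
    }
    if (nchar(cds) != 3 * nchar(p))
      .stopf("CDS length %d does not match protein length %d", nchar(cds), nchar(p))
    tr <- translate_cds(cds)
    if (grepl("*", tr, fixed = TRUE))
      .stopf("internal stop codon at codon %d", regexpr("*", tr, fixed = TRUE)[1])
    mism <- which(strsplit(tr, "")[[1]] != strsplit(p, "")[[1]] &
                    strsplit(p, "")[[1]] != "X" & strsplit(tr, "")[[1]] != "X")
    if (length(mism))
      .stopf("CDS does not translate to protein (first mismatch at codon %d)", mism[1])
    codons <- .split_codons(cds)
    out <- character(nchar(paln)); k <- 0
    ch <- strsplit(paln, "")[[1]]
    for (i in seq_along(ch)) {
      if (ch[i] == "-") out[i] <- "---"
      else { k <- k + 1; out[i] <- codons[k] }
    }
    paste(out, collapse = "")
  }
  list(cds1 = expand_one(prot1_aln, cds1), cds2 = expand_one(prot2_aln, cds2))
}

#' Full paralog table: 70/70 detection, Ka/Ks, dating, mode
#'
#' Convenience wrapper chaining [detect_paralogs()], [codon_align()],
#' [nei_gojobori()], [date_duplication()] and [classify_duplication()].
#'
#' @param proteins a [seq_set] of proteins.
#' @param cds matching [seq_set] of coding sequences (same ids).
#' @param locations optional named location list for mode classification.
#' @param coverage_threshold,similarity_threshold 70/70 thresholds.
#' @param lambda_rate clock rate for [date_duplication()].
#' @return data.frame with gene1, gene2, coverage, identity, similarity,
#'   ka, ks, omega, t_mya and (when located) mode.
#' @export
paralog_table <- function(proteins, cds, locations = NULL,
                          coverage_threshold = 0.70,
                          similarity_threshold = 0.70,
                          lambda_rate = 1.5e-8) {
  pairs <- detect_paralogs(proteins, coverage_threshold, similarity_threshold)
  if (!nrow(pairs)) return(pairs)
  extra <- lapply(seq_len(nrow(pairs)), function(i) {
    g1 <- pairs$gene1[i]; g2 <- pairs$gene2[i]
    aln <- global_align(proteins[[g1]], proteins[[g2]])
    ca <- codon_align(aln$a, aln$b, cds[[g1]], cds[[g2]])
    ng <- nei_gojobori(ca)
    data.frame(ka = ng$ka, ks = ng$ks, omega = ng$omega,
               t_mya = as.numeric(date_duplication(ng$ks, lambda_rate)),
               mode = if (!is.null(locations))
                 classify_duplication(g1, g2, locations, locations)
               else NA_character_,
               stringsAsFactors = FALSE)
  })
  cbind(pairs, do.call(rbind, extra))
}
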