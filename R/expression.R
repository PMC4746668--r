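#' Reference-normalized relative expression from Ct measurements
#'
#' Per biological replicate, technical-replicate Ct values are averaged on
#' the Ct scale, delta-Ct = Ct(gene) - Ct(reference) is formed, and the
#' relative expression 2^-delta-Ct computed. The matrix cell is the mean
#' over biological replicates and `sd` the standard deviation over
#' biological replicates (linear scale). With `calibrator` set, the
#' delta-delta-Ct variant divides every gene's values by its value in the
#' calibrator condition.
#'
#' @param table a `ct_table` (see [read_ct_table()]).
#' @param reference_gene id of the stably expressed reference (must be
#'   measured in every condition x biological replicate).
#' @param conditions optional condition ordering for the output columns.
#' @param calibrator optional condition id for delta-delta-Ct mode.
#' @return An `expression_matrix`: list with `values` and `sd`
#'   (genes x conditions matrices; cells missing a measurement are `NA`)
#'   and `conditions`.
#' @export
relative_expression <- function(table, reference_gene, conditions = NULL,
                                calibrator = NULL) {
  stopifnot(inherits(table, "ct_table") || is.data.frame(table))
  if (!reference_gene %in% table$gene)
    .stopf("reference gene '%s' absent from the table", reference_gene)
  conds <- if (is.null(conditions)) unique(table$condition) else conditions
  genes <- unique(table$gene)
  # mean tech-rep Ct per (gene, condition, bio_rep)
  agg <- stats::aggregate(ct ~ gene + condition + bio_rep, data = table, FUN = mean)
  ref <- agg[agg$gene == reference_gene, ]
  need <- unique(agg[, c("condition", "bio_rep")])
  have <- paste(ref$condition, ref$bio_rep)
  miss <- !paste(need$condition, need$bio_rep) %in% have
  if (any(miss))
    .stopf("reference gene '%s' missing in condition '%s' bio_rep %d",
           reference_gene, need$condition[miss][1], need$bio_rep[miss][1])
  refct <- stats::setNames(ref$ct, paste(ref$condition, ref$bio_rep))
  agg$rel <- 2^-(agg$ct - refct[paste(agg$condition, agg$bio_rep)])
  val <- matrix(NA_real_, length(genes), length(conds),
                dimnames = list(genes, conds))
  sdm <- val
  for (g in genes) for (cc in conds) {
    v <- agg$rel[agg$gene == g & agg$condition == cc]
    if (!length(v)) next  # flagged missing, not zero
    val[g, cc] <- mean(v)
    sdm[g, cc] <- if (length(v) > 1) stats::sd(v) else 0
  }
  if (!is.null(calibrator)) {
    if (!calibrator %in% conds) .stopf("calibrator condition '%s' not present", calibrator)
    val <- val / val[, calibrator]
  }
  structure(list(values = val, sd = sdm, conditions = conds,
                 reference_gene = reference_gene),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d conditions (reference %s)\n",
              nrow(x$values), ncol(x$values), x$reference_gene))
  invisible(x)
}

#' Heatmap-ready matrix from relative expression
#'
#' @param expr an `expression_matrix`.
#' @param transform `"none"` or `"log2"`.
#' @param row_scale `"none"` or `"zscore"` (constant rows become zeros).
#' @param cluster_rows reorder rows by average-linkage hierarchical
#'   clustering on Euclidean distance.
#' @return numeric matrix (transformed, optionally scaled and reordered).
#' @export
heatmap_matrix <- function(expr, transform = c("none", "log2"),
                           row_scale = c("none", "zscore"),
                           cluster_rows = FALSE) {
  transform <- match.arg(transform)
  row_scale <- match.arg(row_scale)
  m <- expr$values
  if (transform == "log2") {
    if (any(m <= 0, na.rm = TRUE)) .stopf("nonpositive value with log2 transform")
    m <- log2(m)
  }
  if (row_scale == "zscore") {
    mu <- rowMeans(m, na.rm = TRUE)
    s <- apply(m, 1, stats::sd, na.rm = TRUE)
    s[!is.finite(s) | s == 0] <- Inf  # constant row -> all zeros
    m <- (m - mu) / s
  }
  if (cluster_rows && nrow(m) > 2) {
    hc <- stats::hclust(stats::dist(m), method = "average")
    m <- m[hc$order, , drop = FALSE]
  }
  m
}

#' Rule-based expression profile classes
#'
#' Works on the canonical seven conditions (leaf, sepal, and fiber at
#' -2, 0, 2, 5 and 10 days post anthesis). A gene is fiber-enriched when
#' its mean fiber expression is at least `fold_threshold` times its mean
#' leaf/sepal expression; fiber-enriched genes are split into
#' initiation-stage (-2..2 DPA window holds the maximum) versus
#' elongation-stage (5..10 DPA); non-enriched genes with at most
#' `uniform_cv` coefficient of variation are ubiquitous, the rest
#' leaf/sepal-preferential.
#'
#' @param expr an `expression_matrix` with the canonical conditions.
#' @param fold_threshold fiber/vegetative fold cutoff (default 2).
#' @param uniform_cv coefficient-of-variation cutoff for "ubiquitous".
#' @param conditions names of the seven canonical conditions, in order:
#'   leaf, sepal, then the five fiber stages.
#' @return named character vector of labels.
#' @export
classify_profiles <- function(expr, fold_threshold = 2, uniform_cv = 0.35,
                              conditions = c("leaf", "sepal", "fiber_m2DPA",
                                             "fiber_0DPA", "fiber_2DPA",
                                             "fiber_5DPA", "fiber_10DPA")) {
  m <- expr$values
  miss <- setdiff(conditions, colnames(m))
  if (length(miss)) .stopf("missing condition(s): %s", paste(miss, collapse = ", "))
  m <- m[, conditions, drop = FALSE]
  veg <- conditions[1:2]
  init <- conditions[3:5]
  elong <- conditions[6:7]
  fiber <- c(init, elong)
  vapply(rownames(m), function(g) {
    x <- m[g, ]
    if (any(is.na(x))) return(NA_character_)
    if (mean(x[fiber]) >= fold_threshold * mean(x[veg])) {
      if (max(x[init]) >= max(x[elong])) "initiation-stage" else "elongation-stage"
    } else if (stats::sd(x) / mean(x) <= uniform_cv) {
      "ubiquitous"
    } else if (mean(x[veg]) > mean(x[fiber])) {
      "leaf/sepal-preferential"
    } else {
      "fiber-enriched"
    }
  }, "")
}
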