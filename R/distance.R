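# JTT rate-matrix machinery. The exchangeability and frequency constants
# are loaded at run time from phangorn's model data and eigendecomposed
# once per session.
.jtt_model <- function() {
  if (!is.null(.fam_env$jtt)) return(.fam_env$jtt)
  jtt <- get(".JTT", environment(phangorn::pml))
  paml_order <- toupper(names(jtt$bf))
  bf <- as.numeric(jtt$bf)
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- jtt$Q
  S <- S + t(S)
  Q <- S %*% diag(bf)
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(bf * diag(Q))          # mean rate 1 substitution/site/unit t
  D <- sqrt(bf)
  B <- diag(D) %*% Q %*% diag(1 / D)   # symmetric similar matrix
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  perm <- match(AA20, paml_order)
  .fam_env$jtt <- list(bf = bf, values = e$values,
                       left = diag(1 / D) %*% e$vectors,
                       right = t(e$vectors) %*% diag(D),
                       perm = perm)
  .fam_env$jtt
}

# transition probability matrix P(t) in this package's AA20 order
.jtt_P <- function(t) {
  m <- .jtt_model()
  P <- m$left %*% diag(exp(m$values * t)) %*% m$right
  P[P < 1e-300] <- 1e-300
  P[m$perm, m$perm]
}

.jtt_bf20 <- function() {
  m <- .jtt_model()
  m$bf[m$perm]
}

# maximum-likelihood JTT distance for one pair of residue index vectors
.jtt_pair_distance <- function(ia, ib) {
  tab <- matrix(tabulate(ia + 20L * (ib - 1L), 400L), 20, 20)
  bf <- .jtt_bf20()
  nz <- tab > 0
  nll <- function(t) -sum(tab[nz] * log((bf * .jtt_P(t))[nz]))
  opt <- stats::optimize(nll, interval = c(1e-6, 10), tol = 1e-8)
  opt$minimum
}

#' Pairwise evolutionary distances from an alignment
#'
#' For each sequence pair, columns gapped or ambiguous in that pair are
#' excluded (`pairwise_deletion`), or all columns gapped/ambiguous in any
#' sequence are excluded up front (`complete_deletion`). Models:
#' `p` (raw mismatch proportion), `poisson` (`-ln(1 - p)`), and `jtt`
#' (maximum-likelihood distance under the Jones-Taylor-Thornton amino-acid
#' replacement model, maximized by bounded scalar search on t in
#' `[1e-6, 10]`).
#'
#' Pairs with zero valid columns, and Poisson pairs with p >= 1, are
#' returned as `NA` and flagged in the `"saturated"` attribute rather than
#' silently producing NaN.
#'
#' @param aln an [msa].
#' @param model `"p"`, `"poisson"` or `"jtt"`.
#' @param gap_handling `"pairwise_deletion"` or `"complete_deletion"`.
#' @return symmetric labelled distance matrix with zero diagonal and a
#'   logical `"saturated"` attribute matrix.
#' @export
pairwise_distance <- function(aln, model = c("p", "poisson", "jtt"),
                              gap_handling = c("pairwise_deletion", "complete_deletion")) {
  model <- match.arg(model)
  gap_handling <- match.arg(gap_handling)
  stopifnot(inherits(aln, "msa"), length(aln) >= 2)
  cm <- .msa_charmat(aln)
  valid <- matrix(match(cm, AA20), nrow(cm))  # NA for gaps/ambiguity
  if (gap_handling == "complete_deletion") {
    keep <- colSums(is.na(valid)) == 0
    valid <- valid[, keep, drop = FALSE]
  }
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(valid[i, ]) & !is.na(valid[j, ])
    if (!any(ok)) { d[i, j] <- d[j, i] <- NA; sat[i, j] <- sat[j, i] <- TRUE; next }
    ia <- valid[i, ok]; ib <- valid[j, ok]
    p <- mean(ia != ib)
    val <- switch(model,
      p = p,
      poisson = if (p >= 1) NA_real_ else -log(1 - p),
      jtt = if (p == 0) 0 else .jtt_pair_distance(ia, ib))
    if (is.na(val)) sat[i, j] <- sat[j, i] <- TRUE
    d[i, j] <- d[j, i] <- val
  }
  attr(d, "saturated") <- sat
  d
}
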