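# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
#
# Site counting uses the classic convention: each codon position
# contributes the fraction of its three possible nucleotide changes that
# are synonymous, with changes to stop codons counted as nonsynonymous,
# so S + N = 3 exactly for every codon. Pathway counting between two
# codons averages the synonymous/nonsynonymous step counts over all
# minimal mutational orderings with equal weights, discarding orderings
# that pass through a stop codon (falling back to all orderings in the
# rare case every one is blocked).

.genetic_code <- function() Biostrings::GENETIC_CODE

#' Translate a coding sequence
#'
#' @param cds DNA string, length a multiple of 3.
#' @return protein string (stops as `*`).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) .stopf("CDS length not a multiple of 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  gc <- .genetic_code()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"   # ambiguous codons
  paste(aa, collapse = "")
}

.ng_tables <- function() {
  if (!is.null(.fam_env$ng)) return(.fam_env$ng)
  gc <- .genetic_code()
  codons <- names(gc)
  sense <- codons[gc != "*"]
  nt <- c("A", "C", "G", "T")
  # per-codon synonymous site potential
  syn_sites <- vapply(sense, function(cod) {
    ch <- strsplit(cod, "")[[1]]
    s <- 0
    for (p in 1:3) for (b in setdiff(nt, ch[p])) {
      mut <- ch; mut[p] <- b
      mc <- paste(mut, collapse = "")
      if (gc[[mc]] != "*" && gc[[mc]] == gc[[cod]]) s <- s + 1 / 3
    }
    s
  }, 0)
  # pathway-averaged (Sd, Nd) for every ordered sense-codon pair
  pair_sd <- matrix(0, 61, 61, dimnames = list(sense, sense))
  pair_nd <- matrix(0, 61, 61, dimnames = list(sense, sense))
  for (a in sense) for (b in sense) {
    if (a == b) next
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    pos <- which(ca != cb)
    perms <- if (length(pos) == 1) list(pos) else {
      pp <- list()
      rec <- function(left, acc) {
        if (!length(left)) { pp[[length(pp) + 1]] <<- acc; return() }
        for (x in left) rec(setdiff(left, x), c(acc, x))
      }
      rec(pos, integer(0)); pp
    }
    score_path <- function(ord) {
      cur <- ca; sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur; nxt[p] <- cb[p]
        c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
        if (gc[[c2]] == "*") return(NULL)
        if (gc[[c1]] == gc[[c2]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- lapply(perms, score_path)
    ok <- res[!vapply(res, is.null, TRUE)]
    if (!length(ok)) {  # every ordering passes through a stop: count anyway
      ok <- lapply(perms, function(ord) {
        cur <- ca; sd <- 0; nd <- 0
        for (p in ord) {
          nxt <- cur; nxt[p] <- cb[p]
          if (gc[[paste(cur, collapse = "")]] == gc[[paste(nxt, collapse = "")]])
            sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        c(sd, nd)
      })
    }
    m <- colMeans(do.call(rbind, ok))
    pair_sd[a, b] <- m[1]; pair_nd[a, b] <- m[2]
  }
  .fam_env$ng <- list(sense = sense, syn_sites = syn_sites,
                      pair_sd = pair_sd, pair_nd = pair_nd)
  .fam_env$ng
}

.split_codons <- function(s) {
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

#' Nei-Gojobori Ka/Ks from a pairwise codon alignment
#'
#' Gapped or ambiguous codon columns are excluded pairwise. Proportions
#' are corrected for multiple hits with the Jukes-Cantor formula
#' `d = -3/4 ln(1 - 4/3 p)`; a proportion at or above 3/4 yields `NA`
#' with the corresponding `saturated` flag set.
#'
#' @param codon_aln list with aligned CDS strings `cds1`, `cds2`
#'   (as from [codon_align()]), or two such strings.
#' @param cds2 second aligned CDS when `codon_aln` is a string.
#' @return list with `ka`, `ks`, `omega`, raw counts `S`, `N`, `Sd`, `Nd`,
#'   proportions `pn`, `ps`, `n_codons`, and `saturated` flags.
#' @export
nei_gojobori <- function(codon_aln, cds2 = NULL) {
  if (is.character(codon_aln)) codon_aln <- list(cds1 = codon_aln, cds2 = cds2)
  a <- toupper(codon_aln$cds1); b <- toupper(codon_aln$cds2)
  if (nchar(a) != nchar(b) || nchar(a) %% 3 != 0)
    .stopf("aligned CDS must have equal lengths divisible by 3")
  tb <- .ng_tables()
  ca <- .split_codons(a); cb <- .split_codons(b)
  ok <- ca %in% tb$sense & cb %in% tb$sense
  if (!any(ok)) .stopf("no countable (gap-free, sense) codon columns")
  ca <- ca[ok]; cb <- cb[ok]
  S <- sum((tb$syn_sites[ca] + tb$syn_sites[cb]) / 2)
  N <- 3 * length(ca) - S
  Sd <- sum(tb$pair_sd[cbind(ca, cb)])
  Nd <- sum(tb$pair_nd[cbind(ca, cb)])
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(ps); ka <- jc(pn)
  list(ka = ka, ks = ks,
       omega = if (!is.na(ks) && !is.na(ka) && ks > 0) ka / ks else NA_real_,
       S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       n_codons = length(ca),
       saturated = c(ks = is.na(ks) && ps >= 0.75, ka = is.na(ka) && pn >= 0.75))
}

#' Date a duplication event from synonymous divergence
#'
#' T = Ks / (2 lambda), reported in million years (Mya). The default
#' clock rate is 1.5 synonymous substitutions per site per 10^8 years,
#' the standard value for cotton.
#'
#' @param ks synonymous substitutions per synonymous site (vectorized).
#' @param lambda_rate synonymous substitution rate per site per year.
#' @param ks_saturation_cutoff Ks above this is flagged (but still dated).
#' @return numeric Mya vector with a logical `"saturated"` attribute.
#' @export
date_duplication <- function(ks, lambda_rate = 1.5e-8,
                             ks_saturation_cutoff = 2.0) {
  stopifnot(lambda_rate > 0)
  if (any(ks < 0, na.rm = TRUE)) .stopf("negative ks")
  t_mya <- ks / (2 * lambda_rate) / 1e6
  attr(t_mya, "saturated") <- !is.na(ks) & ks > ks_saturation_cutoff
  t_mya
}

#' Summarize a table of dated duplication events
#'
#' @param pairs data.frame with at least `ks` and `t_mya` columns
#'   (optionally `mode`).
#' @return list with `n_pairs`, `min_t_mya`, `mean_t_mya`, `max_t_mya`
#'   and `mode_tally`.
#' @export
duplication_report <- function(pairs) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1,
            all(c("ks", "t_mya") %in% names(pairs)))
  list(n_pairs = nrow(pairs),
       min_t_mya = min(pairs$t_mya),
       mean_t_mya = mean(pairs$t_mya),
       max_t_mya = max(pairs$t_mya),
       mode_tally = if ("mode" %in% names(pairs)) table(pairs$mode) else NULL)
}
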