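# Average (isotope-abundance-weighted) residue masses, Daltons.
.RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.0153

# EMBOSS-style pKa values used for the net-charge model.
.PKA <- list(
  positive = c(Nterm = 8.6, H = 6.5, K = 10.8, R = 12.5),
  negative = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch over the termini and the ionizable side chains
#' (D, E, C, Y, H, K, R), with EMBOSS-style pKa values.
#'
#' @param seq protein sequence string (no ambiguity codes).
#' @param ph pH.
#' @return net charge (elementary charges).
#' @export
net_charge <- function(seq, ph) {
  aa <- strsplit(toupper(seq), "")[[1]]
  cnt <- table(factor(aa, levels = AA20))
  pos <- 1 / (1 + 10^(ph - .PKA$positive["Nterm"]))
  for (r in c("H", "K", "R"))
    pos <- pos + cnt[[r]] / (1 + 10^(ph - .PKA$positive[[r]]))
  neg <- 1 / (1 + 10^(.PKA$negative["Cterm"] - ph))
  for (r in c("D", "E", "C", "Y"))
    neg <- neg + cnt[[r]] / (1 + 10^(.PKA$negative[[r]] - ph))
  unname(pos - neg)
}

#' Protein length, molecular weight and isoelectric point
#'
#' MW is the sum of average residue masses plus one water (18.0153 Da);
#' pI is found by bisection of [net_charge()] (strictly decreasing in pH)
#' to |charge| < 1e-4.
#'
#' @param seq protein sequence string; ambiguity codes (X) are an error.
#' @return list with `length`, `mw` (Da), `pi` (pH units).
#' @export
protein_stats <- function(seq) {
  s <- toupper(seq)
  if (!nzchar(s)) .stopf("empty sequence")
  aa <- strsplit(s, "")[[1]]
  if (any(!aa %in% AA20))
    .stopf("ambiguity or illegal code '%s' not supported by protein_stats",
           setdiff(aa, AA20)[1])
  mw <- sum(.RESIDUE_MASS[aa]) + .WATER_MASS
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(s, mid)
    if (abs(q) < 1e-4 || hi - lo < 1e-9) break
    if (q > 0) lo <- mid else hi <- mid
  }
  list(length = length(aa), mw = mw, pi = mid)
}
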