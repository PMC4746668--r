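# HMMER3-style text serialization of profile HMMs.
# Emission/transition values are stored as -ln(p), '*' meaning p = 0,
# matching the layout of hmmbuild output closely enough that real profile
# files with the canonical 20-letter amino alphabet parse losslessly
# (annotation columns after the 20 match scores are ignored).

#' Read a profile HMM from HMMER3-style text
#'
#' @param path profile file.
#' @return A [profile_hmm]. The background is taken from the COMPO line
#'   when present, otherwise uniform.
#' @export
read_hmm_profile <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^HMMER3", lines[1]))
    .stopf("'%s' is not an HMMER3-style profile (bad version line)", path)
  hdr <- function(key, default = NULL) {
    i <- grep(sprintf("^%s ", key), lines)
    if (!length(i)) return(default)
    trimws(sub(sprintf("^%s +", key), "", lines[i[1]]))
  }
  name <- hdr("NAME", "profile")
  L <- as.integer(hdr("LENG"))
  alph <- hdr("ALPH", "amino")
  if (is.na(L) || L < 1) .stopf("'%s': missing or invalid LENG", path)
  if (tolower(alph) != "amino")
    .stopf("'%s': alphabet '%s' not supported (amino only)", path, alph)
  ihmm <- grep("^HMM\\s", lines)[1]
  if (is.na(ihmm)) .stopf("'%s': no HMM section", path)
  syms <- strsplit(trimws(sub("^HMM", "", lines[ihmm])), "\\s+")[[1]]
  if (length(syms) != 20 || !identical(sort(syms), sort(AA20)))
    .stopf("'%s': expected the 20 amino-acid symbols on the HMM line", path)
  perm <- match(AA20, syms)
  val <- function(x) ifelse(x == "*", Inf, suppressWarnings(as.numeric(x)))
  body <- lines[(ihmm + 2):length(lines)]
  body <- body[!grepl("^//", body)]
  toks <- lapply(trimws(body), function(l) strsplit(l, "\\s+")[[1]])
  background <- rep(1 / 20, 20)
  pos <- 1
  if (length(toks[[1]]) && toks[[1]][1] == "COMPO") {
    background <- exp(-val(toks[[1]][2:21]))[perm]
    background <- background / sum(background)
    pos <- 2
  }
  # optional node-0 (BEGIN) insert-emission + transition lines:
  # a bare 20-value line followed by a 7-value line before node 1
  if (length(toks) >= pos + 1 && length(toks[[pos]]) == 20 &&
      length(toks[[pos + 1]]) == 7) {
    pos <- pos + 2
  }
  match_e <- matrix(NA_real_, L, 20)
  insert_e <- matrix(NA_real_, L, 20)
  trans <- matrix(NA_real_, L, 7)
  for (i in seq_len(L)) {
    if (pos + 2 > length(toks)) .stopf("'%s': truncated at node %d", path, i)
    ml <- toks[[pos]]
    if (suppressWarnings(as.integer(ml[1])) != i)
      .stopf("'%s': expected node %d, found '%s'", path, i, ml[1])
    match_e[i, ] <- exp(-val(ml[2:21]))[perm]
    insert_e[i, ] <- exp(-val(toks[[pos + 1]][1:20]))[perm]
    trans[i, ] <- exp(-val(toks[[pos + 2]][1:7]))
    pos <- pos + 3
  }
  match_e <- match_e / rowSums(match_e)
  insert_e <- insert_e / rowSums(insert_e)
  # renormalize transition groups; final node may have '*' placeholders
  trans[L, ] <- c(1, 0, 0, 1, 0, 1, 0)
  if (L > 1) {
    idx <- seq_len(L - 1)
    trans[idx, 1:3] <- trans[idx, 1:3] / rowSums(trans[idx, 1:3, drop = FALSE])
    trans[idx, 4:5] <- trans[idx, 4:5] / rowSums(trans[idx, 4:5, drop = FALSE])
    trans[idx, 6:7] <- trans[idx, 6:7] / rowSums(trans[idx, 6:7, drop = FALSE])
  }
  profile_hmm(match_e, insert_e, trans, background, name = name)
}

#' @rdname read_hmm_profile
#' @param hmm a [profile_hmm].
#' @export
write_hmm_profile <- function(hmm, path) {
  stopifnot(inherits(hmm, "profile_hmm"))
  fmt <- function(p) {
    v <- -log(p)
    v[v == 0] <- 0  # avoid "-0.00000"
    ifelse(p <= 0, "*", sprintf("%.5f", v))
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("HMMER3/f [famsurvey profile]")
  w("NAME  %s", hmm$name)
  w("LENG  %d", hmm$length)
  w("ALPH  amino")
  w("HMM          %s", paste(sprintf("%9s", AA20), collapse = ""))
  w("            %s", paste(sprintf("%9s", c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")), collapse = ""))
  w("  COMPO   %s", paste(sprintf("%9s", fmt(hmm$background)), collapse = ""))
  w("          %s", paste(sprintf("%9s", fmt(hmm$background)), collapse = ""))
  w("          %s", paste(sprintf("%9s", fmt(c(1, 0, 0, 1, 0, 1, 0))), collapse = ""))
  for (i in seq_len(hmm$length)) {
    w("  %5d   %s", i, paste(sprintf("%9s", fmt(hmm$match[i, ])), collapse = ""))
    w("          %s", paste(sprintf("%9s", fmt(hmm$insert[i, ])), collapse = ""))
    tr <- if (i == hmm$length) c(1, 0, 0, 1, 0, 1, 0) else hmm$trans[i, ]
    w("          %s", paste(sprintf("%9s", fmt(tr)), collapse = ""))
  }
  writeLines("//", con)
  invisible(path)
}
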