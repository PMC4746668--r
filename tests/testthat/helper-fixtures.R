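# Shared fixtures (memoized per test session) and independent oracles.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(build)
  .fixture_env[[name]]
}

# small family bundle used by unit tests (paper-sized bundle lives in
# the acceptance suite)
small_family <- function() fixture("small_family", {
  make_family(seed = 42, n_true = 10, n_redundant = 4, n_decoys = 90,
              n_pairs = 5, gene_len = 200)
})

small_family_calibrated <- function() fixture("small_family_cal", {
  fam <- small_family()
  calibrate_profile(fam$hmm, seed = 42,
                    background = proteome_background(fam$proteome))
})

random_toy_hmm <- function(L) {
  nr <- function(k, m) {
    x <- matrix(stats::rgamma(k * m, 1), k, m)
    x / rowSums(x)
  }
  profile_hmm(nr(L, 20), nr(L, 20),
              cbind(nr(L, 3), nr(L, 2), nr(L, 2)))
}

# ---- oracle: exhaustive uni-local path enumeration for profile HMMs ----
enum_hmm_scores <- function(hmm, seq) {
  L <- hmm$length
  idx <- match(strsplit(seq, "")[[1]], AA20)
  n <- length(idx)
  lt <- log2(hmm$trans)
  lom <- log2(t(hmm$match) / hmm$background)
  loi <- log2(t(hmm$insert) / hmm$background)
  res <- numeric(0)
  rec <- function(type, node, k, score) {
    if (type == "M") res <<- c(res, score)
    if (node < L) {
      if (type == "M") {
        if (k < n) rec("M", node + 1, k + 1, score + lt[node, "MM"] + lom[idx[k + 1], node + 1])
        if (k < n) rec("I", node, k + 1, score + lt[node, "MI"] + loi[idx[k + 1], node])
        rec("D", node + 1, k, score + lt[node, "MD"])
      } else if (type == "I") {
        if (k < n) rec("M", node + 1, k + 1, score + lt[node, "IM"] + lom[idx[k + 1], node + 1])
        if (k < n) rec("I", node, k + 1, score + lt[node, "II"] + loi[idx[k + 1], node])
      } else {
        if (k < n) rec("M", node + 1, k + 1, score + lt[node, "DM"] + lom[idx[k + 1], node + 1])
        rec("D", node + 1, k, score + lt[node, "DD"])
      }
    }
  }
  for (a in 1:L) for (k in 1:n) rec("M", a, k, lom[idx[k], a])
  mx <- max(res)
  list(viterbi = mx, forward = mx + log2(sum(2^(res - mx))))
}

# ---- oracle: exhaustive global-alignment enumeration (tiny inputs) ----
enum_align_score <- function(a, b, sub, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  best <- -Inf
  # state: i consumed of a, j consumed of b, last move (0 none, 1 M, 2 D, 3 I)
  rec <- function(i, j, last, score) {
    if (i == n && j == m) { best <<- max(best, score); return() }
    if (i < n && j < m)
      rec(i + 1, j + 1, 1, score + sub[ca[i + 1], cb[j + 1]])
    if (i < n)
      rec(i + 1, j, 2, score - if (last == 2) gap_extend else gap_open)
    if (j < m)
      rec(i, j + 1, 3, score - if (last == 3) gap_extend else gap_open)
  }
  rec(0, 0, 0, 0)
  best
}

# ---- oracle: brute-force mutational pathway enumeration for codons ----
codon_oracle_sd_nd <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
  paths <- list()
  walk <- function(cur, sd, nd) {
    diffs <- which(cur != ch2)
    if (!length(diffs)) { paths[[length(paths) + 1]] <<- c(sd, nd); return(TRUE) }
    any_ok <- FALSE
    for (p in diffs) {
      nxt <- cur; nxt[p] <- ch2[p]
      if (gc[[paste(nxt, collapse = "")]] == "*") next
      syn <- gc[[paste(cur, collapse = "")]] == gc[[paste(nxt, collapse = "")]]
      if (walk(nxt, sd + syn, nd + !syn)) any_ok <- TRUE
    }
    any_ok
  }
  walk(ch1, 0, 0)
  if (!length(paths)) return(NULL)  # fully blocked by stops
  m <- colMeans(do.call(rbind, paths))
  c(sd = m[1], nd = m[2])
}

canonical_conditions <- c("leaf", "sepal", "fiber_m2DPA", "fiber_0DPA",
                          "fiber_2DPA", "fiber_5DPA", "fiber_10DPA")
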