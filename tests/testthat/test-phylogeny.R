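test_that("global alignment matches the exhaustive enumeration oracle", {
  sub <- famsurvey:::.blosum62()
  set.seed(7)
  for (trial in 1:40) {
    a <- paste(sample(AA20, sample(1:6, 1), TRUE), collapse = "")
    b <- paste(sample(AA20, sample(1:6, 1), TRUE), collapse = "")
    got <- global_align(a, b)
    expect_equal(got$score, enum_align_score(a, b, sub, 10, 0.5), tolerance = 1e-9)
    # the reported trace realizes the reported score and degaps correctly
    expect_identical(gsub("-", "", got$a), a)
    expect_identical(gsub("-", "", got$b), b)
  }
  ident <- global_align("AAA", "AAA")
  expect_equal(ident$score, 3 * sub["A", "A"])
  expect_equal(ident$a, "AAA")
  one_gap <- global_align("AAA", "AA")
  expect_equal(sum(strsplit(one_gap$b, "")[[1]] == "-"), 1)
})

test_that("progressive MSA keeps the degapping identity and aligns homologs", {
  m <- build_msa(seq_set(c(a = "ACDEF", b = "ACEF"), alphabet = "protein"))
  expect_equal(nchar(m[["a"]]), 5)
  expect_equal(m[["b"]], "AC-EF")  # single gap at the D column
  two <- build_msa(seq_set(c(x = "MKVH", y = "MKVH"), alphabet = "protein"))
  expect_false(any(grepl("-", two)))

  sim <- simulate_homologs(seed = 3, n = 10, len = 120, sub_rate = 0.05)
  aln <- build_msa(sim$seqs)
  expect_identical(as.character(degap(aln)), as.character(sim$seqs))
  # column homology recovery: residue pairs from the same ancestral column
  # must co-occur in the same alignment column >= 95% of the time
  colof <- lapply(names(aln), function(id) {
    ch <- strsplit(aln[[id]], "")[[1]]
    which(ch != "-")
  })
  names(colof) <- names(aln)
  total <- 0; good <- 0
  ids <- names(aln)
  for (i in 1:(length(ids) - 1)) for (j in (i + 1):length(ids)) {
    mi <- sim$column_map[[ids[i]]]; mj <- sim$column_map[[ids[j]]]
    common <- intersect(mi[!is.na(mi)], mj[!is.na(mj)])
    for (anc_col in common) {
      total <- total + 1
      ci <- colof[[ids[i]]][match(anc_col, mi)]
      cj <- colof[[ids[j]]][match(anc_col, mj)]
      if (ci == cj) good <- good + 1
    }
  }
  expect_gte(good / total, 0.95)
})

test_that("pairwise distances follow the closed forms and flag saturation", {
  rows <- msa(c(a = "AAAAAAAAAA", b = "AAAAAAAAAC"))
  expect_equal(pairwise_distance(rows, "p")["a", "b"], 0.1)
  expect_equal(pairwise_distance(rows, "poisson")["a", "b"], -log(0.9),
               tolerance = 1e-12)
  same <- msa(c(a = "MKVH", b = "MKVH"))
  for (mod in c("p", "poisson", "jtt"))
    expect_equal(pairwise_distance(same, mod)["a", "b"], 0)
  # pairwise deletion: gapped columns excluded per pair
  g <- msa(c(a = "A-CD", b = "AACD", c = "AAC-"))
  expect_equal(pairwise_distance(g, "p")["a", "b"], 0)
  disjoint <- msa(c(a = "AA--", b = "--CC"))
  d <- pairwise_distance(disjoint, "p")
  expect_true(is.na(d["a", "b"]))
  expect_true(attr(d, "saturated")["a", "b"])
  # monotone: adding mismatches never decreases p
  base <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA")
  prev <- -1
  for (k in 0:5) {
    bb <- base
    substr(bb["b"], 1, k) <- paste(rep("C", k), collapse = "")
    if (k > 0) {
      p <- pairwise_distance(msa(bb), "p")["a", "b"]
      expect_gte(p, prev); prev <- p
    }
  }
})

test_that("JTT ML distance agrees with an independent implementation", {
  sim <- simulate_homologs(seed = 11, n = 5, len = 300, sub_rate = 0.2,
                           max_indels = 0)
  aln <- msa(stats::setNames(as.character(sim$seqs), names(sim$seqs)))
  mine <- pairwise_distance(aln, "jtt")
  pd <- phangorn::as.phyDat(do.call(rbind, strsplit(unclass(aln), "")), type = "AA")
  ref <- as.matrix(phangorn::dist.ml(pd, model = "JTT", exclude = "pairwise"))
  expect_equal(unclass(mine)[rownames(ref), colnames(ref)], unname(ref),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("NJ solves the three-taxon case in closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
})

test_that("NJ recovers random additive trees exactly and ignores taxon order", {
  set.seed(9)
  for (trial in 1:15) {
    n <- sample(8:12, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
    D <- ape::cophenetic.phylo(tr)
    est <- neighbor_joining(D)
    D2 <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
    expect_lt(max(abs(D2 - D)), 1e-9)
    perm <- sample(rownames(D))
    est_p <- neighbor_joining(D[perm, perm])
    expect_equal(phangorn::RF.dist(ape::unroot(est), ape::unroot(est_p)), 0)
  }
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
})

test_that("bootstrap supports are deterministic, in [0,1], and find clean clades", {
  # two well-separated 4-taxon clades
  set.seed(5)
  anc1 <- paste(sample(AA20, 150, TRUE), collapse = "")
  anc2 <- paste({
    ch <- strsplit(anc1, "")[[1]]
    pos <- sample(150, 75)
    for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1)
    ch
  }, collapse = "")
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    for (p in sample(length(ch), k)) ch[p] <- sample(setdiff(AA20, ch[p]), 1)
    paste(ch, collapse = "")
  }
  seqs <- seq_set(c(a1 = mut(anc1, 8), a2 = mut(anc1, 8), a3 = mut(anc1, 8),
                    a4 = mut(anc1, 8), b1 = mut(anc2, 8), b2 = mut(anc2, 8),
                    b3 = mut(anc2, 8), b4 = mut(anc2, 8)), alphabet = "protein")
  aln <- build_msa(seqs)
  t1 <- bootstrap_support(aln, model = "poisson", bootstrap_n = 100, seed = 5)
  t2 <- bootstrap_support(aln, model = "poisson", bootstrap_n = 100, seed = 5)
  expect_identical(attr(t1, "support"), attr(t2, "support"))
  expect_true(all(attr(t1, "support") >= 0 & attr(t1, "support") <= 1))
  # the a-vs-b split must be strongly supported
  split_edge <- which(vapply(seq_len(t1$Nnode) + length(t1$tip.label), function(nd) {
    tips <- ape::extract.clade(t1, nd)$tip.label
    setequal(tips, c("a1", "a2", "a3", "a4")) || setequal(tips, c("b1", "b2", "b3", "b4"))
  }, TRUE))
  expect_true(length(split_edge) >= 1)
  expect_true(all(attr(t1, "support")[split_edge] >= 0.9))
})

test_that("an alignment whose every column supports one split gives support 1", {
  rows <- msa(c(a = "AAAA", b = "AAAA", c = "CCCC", d = "CCCC", e = "CCCG"))
  tr <- bootstrap_support(rows, model = "p", bootstrap_n = 50, seed = 1)
  supp <- attr(tr, "support")
  # the ab|cde bipartition is present in every replicate
  nd <- which(vapply(seq_len(tr$Nnode) + length(tr$tip.label), function(n) {
    setequal(ape::extract.clade(tr, n)$tip.label, c("a", "b")) ||
      setequal(ape::extract.clade(tr, n)$tip.label, c("c", "d", "e"))
  }, TRUE))
  expect_true(any(supp[nd] == 1))
})
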