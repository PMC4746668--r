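test_that("pair_stats reports coverage over the longer sequence", {
  s <- paste(rep("MKVLHAGCWR", 10), collapse = "")
  st <- pair_stats(s, s)
  expect_equal(st$coverage, 1)
  expect_equal(st$identity, 1)
  expect_equal(st$similarity, 1)
  half <- substr(s, 1, 50)
  expect_equal(pair_stats(s, half)$coverage, 0.5)
  # 100-residue sequence with 20 substitutions to dissimilar residues
  set.seed(3)
  a <- paste(sample(AA20, 100, TRUE), collapse = "")
  ch <- strsplit(a, "")[[1]]
  sub <- famsurvey:::.blosum62()
  pos <- sample(100, 20)
  for (p in pos) {
    cands <- AA20[sub[ch[p], AA20] < 0 & AA20 != ch[p]]
    ch[p] <- cands[1]
  }
  b <- paste(ch, collapse = "")
  st <- pair_stats(a, b)
  expect_equal(st$identity, 0.80)
  expect_equal(st$coverage, 1.0)
  expect_equal(st$similarity, 0.80)
})

test_that("70/70 detection is strict, symmetric under relabeling, order-stable", {
  fam <- small_family()
  prot <- fam$proteome[fam$truth$true_ids]
  pairs <- detect_paralogs(prot)
  key <- paste(pairs$gene1, pairs$gene2)
  tkey <- with(fam$truth$pair_truth,
               paste(pmin(gene1, gene2), pmax(gene1, gene2)))
  expect_setequal(key, tkey)
  expect_identical(pairs$gene1, sort(pairs$gene1))
  # thresholds at zero -> all pairs
  all_pairs <- detect_paralogs(prot, 0, 0)
  expect_equal(nrow(all_pairs), choose(length(prot), 2))
  # input order permutation leaves the output invariant
  perm <- detect_paralogs(prot[rev(names(prot))])
  expect_equal(perm, pairs)
})

test_that("tandem versus segmental classification follows the proximity rule", {
  locs <- list(
    g1 = list(chromosome = "chr1", start = 1000, end = 2000),
    g2 = list(chromosome = "chr1", start = 7000, end = 8000),       # 5 kb away
    g3 = list(chromosome = "chr1", start = 30000000, end = 30001000),
    g4 = list(chromosome = "chr2", start = 1000, end = 2000))
  expect_equal(classify_duplication("g1", "g2", locs), "tandem")
  expect_equal(classify_duplication("g1", "g4", locs), "segmental")
  # same chromosome, 30 Mb apart, many intervening genes
  many <- c(locs, stats::setNames(lapply(1:200, function(i)
    list(chromosome = "chr1", start = 10000 + i * 100000,
         end = 10000 + i * 100000 + 500)), paste0("x", 1:200)))
  expect_equal(classify_duplication("g1", "g3", many, many), "segmental")
  # few intervening genes rescues tandem even beyond the bp cutoff
  sparse <- locs
  expect_equal(classify_duplication("g1", "g3", sparse, sparse), "tandem")
  expect_error(classify_duplication("g1", "nope", locs), "nope")
})

test_that("codon back-translation expands columns and validates the CDS", {
  ca <- codon_align("MK", "MK", "ATGAAA", "ATGAAG")
  expect_equal(ca$cds1, "ATGAAA")
  expect_equal(ca$cds2, "ATGAAG")
  ca <- codon_align("M-K", "MGK", "ATGAAA", "ATGGGGAAA")
  expect_equal(ca$cds1, "ATG---AAA")
  # trailing stop trimmed, internal stop rejected, mistranslation rejected
  expect_equal(codon_align("M", "M", "ATGTAA", "ATG")$cds1, "ATG")
  expect_error(codon_align("MQK", "MQK", "ATGTAAAAA", "ATGCAGAAA"), "stop")
  expect_error(codon_align("MK", "MK", "ATGCCC", "ATGAAA"), "translate")
  expect_error(codon_align("MK", "MK", "ATGAA", "ATGAAA"), "length")
})

test_that("Nei-Gojobori counts match the hand-worked single-codon case", {
  ng <- nei_gojobori("TTT", "TTA")
  expect_equal(ng$Sd, 0)
  expect_equal(ng$Nd, 1)
  expect_equal(ng$S, 0.5)
  expect_equal(ng$N, 2.5)
  expect_equal(ng$pn, 0.4)
  expect_equal(ng$ka, -0.75 * log(1 - 4 / 3 * 0.4), tolerance = 1e-12)
  expect_equal(ng$ks, 0)
  ident <- nei_gojobori("ATGAAA", "ATGAAA")
  expect_equal(ident$ka, 0)
  expect_equal(ident$ks, 0)
})

test_that("site and pathway counts obey the core invariants", {
  tb <- famsurvey:::.ng_tables()
  # S + N = 3 per codon
  expect_equal(unname(tb$syn_sites + (3 - tb$syn_sites)), rep(3, 61))
  set.seed(12)
  codons <- tb$sense
  for (trial in 1:50) {
    c1 <- sample(codons, 3); c2 <- sample(codons, 3)
    a <- paste(c1, collapse = ""); b <- paste(c2, collapse = "")
    x <- nei_gojobori(a, b); y <- nei_gojobori(b, a)
    expect_equal(x$ks, y$ks)
    expect_equal(x$ka, y$ka)
    expect_equal(x$S + x$N, 3 * 3, tolerance = 1e-9)
  }
  # gapped codons are deleted pairwise
  g <- nei_gojobori("ATG---AAA", "ATGCCCAAA")
  expect_equal(g$n_codons, 2)
  expect_error(nei_gojobori("---", "---"), "countable")
})

test_that("pathway averaging matches the brute-force oracle on sampled pairs", {
  tb <- famsurvey:::.ng_tables()
  set.seed(4)
  pairs <- cbind(sample(tb$sense, 150, TRUE), sample(tb$sense, 150, TRUE))
  for (i in seq_len(nrow(pairs))) {
    c1 <- pairs[i, 1]; c2 <- pairs[i, 2]
    if (c1 == c2) next
    o <- codon_oracle_sd_nd(c1, c2)
    if (is.null(o)) next
    expect_equal(unname(tb$pair_sd[c1, c2]), unname(o["sd"]), tolerance = 1e-12)
    expect_equal(unname(tb$pair_nd[c1, c2]), unname(o["nd"]), tolerance = 1e-12)
  }
})

test_that("duplication dating is linear and reproduces the published rows", {
  expect_equal(round(as.numeric(date_duplication(0.3869)), 5), 12.89667)
  expect_equal(round(as.numeric(date_duplication(1.0954)), 5), 36.51333)
  expect_equal(as.numeric(date_duplication(0)), 0)
  ks <- c(0.1, 0.5, 1.3)
  expect_equal(as.numeric(date_duplication(3 * ks)),
               3 * as.numeric(date_duplication(ks)))
  expect_true(attr(date_duplication(2.5), "saturated"))
  expect_false(attr(date_duplication(1.1), "saturated"))
  expect_error(date_duplication(-0.1), "negative")
})

test_that("duplication_report summarizes a dated pair table", {
  df <- data.frame(ks = c(0.3, 0.6), t_mya = as.numeric(date_duplication(c(0.3, 0.6))),
                   mode = c("segmental", "segmental"))
  rep <- duplication_report(df)
  expect_equal(rep$n_pairs, 2)
  expect_equal(rep$min_t_mya, 10)
  expect_equal(rep$max_t_mya, 20)
  expect_equal(rep$mean_t_mya, 15)
  expect_equal(unname(rep$mode_tally["segmental"]), 2)
  one <- duplication_report(df[1, ])
  expect_equal(one$min_t_mya, one$max_t_mya)
  expect_equal(one$min_t_mya, one$mean_t_mya)
  expect_error(duplication_report(df[0, ]), "nrow")
})
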