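test_that("gene structures derive introns and respect strand orientation", {
  single <- gene_model("s", "chr1", "+", rbind(c(1, 900)))
  gs <- gene_structure(single)
  expect_equal(gs$intron_count, 0)
  expect_equal(nrow(gs$introns), 0)

  plus <- gene_model("p", "chr1", "+", rbind(c(1, 100), c(201, 300)))
  gp <- gene_structure(plus)
  expect_equal(gp$exons, cbind(start = c(1L, 201L), end = c(100L, 300L)))
  expect_equal(gp$introns, cbind(start = 101L, end = 200L))

  minus <- gene_model("m", "chr1", "-", rbind(c(1, 100), c(201, 300)))
  gm <- gene_structure(minus)
  # 5'->3' flip on a 300 bp gene: the (201,300) exon becomes (1,100)
  expect_equal(gm$exons, cbind(start = c(1L, 201L), end = c(100L, 300L)))
  # the genomic first exon is now last in transcription order
  expect_equal(gm$intron_count, 1)

  # exons + introns tile the span exactly
  for (g in list(gp, gm)) {
    covered <- sort(c(unlist(apply(g$exons, 1, function(r) r[1]:r[2])),
                      unlist(apply(g$introns, 1, function(r) r[1]:r[2]))))
    expect_identical(as.integer(covered), seq_len(g$span_length))
  }
})

test_that("structure_table counts intronless genes", {
  models <- list(gene_model("a", "chr1", "+", rbind(c(1, 500))),
                 gene_model("b", "chr2", "-", rbind(c(1, 100), c(301, 600))))
  tab <- structure_table(models)
  expect_equal(tab$n_introns, c(0, 1))
  expect_equal(tab$n_exons, c(1, 2))
})

test_that("ZOOPS EM recovers a planted motif with a monotone objective", {
  prof <- make_domain_profile(seed = 13, width = 10, mut_rate = 0.05)
  base <- seq_set(stats::setNames(
    vapply(1:20, function(i) {
      set.seed(1300 + i)
      paste(sample(AA20, 80, TRUE), collapse = "")
    }, ""), sprintf("s%02d", 1:20)), alphabet = "protein")
  pl <- plant_motifs(base, prof$hmm$match, occupancy = 1.0, seed = 13)
  mot <- em_motif_search(pl$seqs, max_motifs = 1, widths = 10,
                         n_starts = 5, seed = 13)
  m1 <- mot[[1]]
  expect_true(all(diff(m1$objective_trace) >= -1e-9))
  expect_equal(dim(m1$pwm), c(10, 20))
  expect_equal(rowSums(m1$pwm), rep(1, 10), tolerance = 1e-9)
  ov <- merge(m1$sites, pl$sites, by = "seq_id")
  overlap <- pmin(ov$end.x, ov$end.y) - pmax(ov$start.x, ov$start.y) + 1
  expect_gte(sum(overlap > 0), 18)
})

test_that("EM is deterministic under the seed and erasure bounds overlap", {
  fam <- small_family()
  seqs <- fam$proteome[fam$truth$true_ids[1:8]]
  a <- em_motif_search(seqs, max_motifs = 2, widths = c(8, 10), n_starts = 2, seed = 4)
  b <- em_motif_search(seqs, max_motifs = 2, widths = c(8, 10), n_starts = 2, seed = 4)
  expect_identical(a, b)
  s1 <- a[[1]]$sites; s2 <- a[[2]]$sites
  both <- merge(s1, s2, by = "seq_id")
  if (nrow(both)) {
    ov <- pmax(0, pmin(both$end.x, both$end.y) - pmax(both$start.x, both$start.y) + 1)
    expect_true(all(ov < 0.5 * a[[2]]$width))
  }
})

test_that("degenerate repeated-letter input is flagged low complexity", {
  seqs <- seq_set(c(a = strrep("A", 30), b = strrep("A", 30)), alphabet = "protein")
  mot <- em_motif_search(seqs, max_motifs = 1, widths = 6, n_starts = 1, seed = 1)
  expect_true(mot[[1]]$low_complexity)
})

test_that("motif occurrence scanning honors thresholds and finds the consensus", {
  prof <- make_domain_profile(seed = 17, width = 8, mut_rate = 0.02)
  base <- seq_set(stats::setNames(vapply(1:6, function(i) {
    set.seed(1700 + i); paste(sample(AA20, 60, TRUE), collapse = "")
  }, ""), paste0("q", 1:6)), alphabet = "protein")
  pl <- plant_motifs(base, prof$hmm$match, occupancy = 1.0, seed = 17)
  mot <- em_motif_search(pl$seqs, max_motifs = 1, widths = 8, n_starts = 4, seed = 17)[[1]]
  # scanning the motif's own consensus hits at its position
  probe <- seq_set(c(cons = paste0(strrep("G", 5), mot$consensus, strrep("G", 5))),
                   alphabet = "protein")
  occ <- motif_occurrences(mot, probe, score_threshold = 0)
  expect_equal(occ$start[which.max(occ$score)], 6)
  expect_equal(nrow(motif_occurrences(mot, probe, score_threshold = Inf)), 0)
  # planted truth recovered with FNR <= 0.1
  occ2 <- motif_occurrences(mot, pl$seqs, score_threshold = 5)
  ov <- merge(occ2, pl$sites, by = "seq_id")
  found <- tapply(pmin(ov$end.x, ov$end.y) - pmax(ov$start.x, ov$start.y) + 1 > 0,
                  ov$seq_id, any)
  expect_gte(mean(found), 0.9)
})
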