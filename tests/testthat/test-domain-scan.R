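test_that("consensus of a sharply peaked profile scores the closed-form sum", {
  # 3 match states, 0.9 on the consensus letter, no indels allowed
  cons <- c("M", "K", "V")
  match_e <- matrix(0.1 / 19, 3, 20, dimnames = list(NULL, AA20))
  for (i in 1:3) match_e[i, cons[i]] <- 0.9
  trans <- matrix(rep(c(1, 0, 0, 1, 0, 1, 0), each = 3), 3, 7)
  hmm <- profile_hmm(match_e, trans = trans)
  hit <- viterbi_score(hmm, "MKV")
  expected <- 3 * log2(0.9 / (1 / 20))  # per-state log-odds, free transitions
  expect_equal(hit$bit_score, expected, tolerance = 1e-12)
  expect_equal(hit$env_start, 1)
  expect_equal(hit$env_end, 3)
  expect_equal(hit$state_path, "MMM")
  # maximality: no other 3-mer scores higher
  others <- replicate(25, paste(sample(AA20, 3, TRUE), collapse = ""))
  for (s in others)
    expect_lte(viterbi_score(hmm, s)$bit_score, expected)
})

test_that("viterbi and forward match exhaustive path enumeration on toy profiles", {
  set.seed(101)
  for (trial in 1:60) {
    L <- sample(1:3, 1)
    n <- sample(1:5, 1)
    hmm <- random_toy_hmm(L)
    s <- paste(sample(AA20, n, TRUE), collapse = "")
    o <- enum_hmm_scores(hmm, s)
    v <- viterbi_score(hmm, s)$bit_score
    f <- forward_score(hmm, s)
    expect_equal(v, o$viterbi, tolerance = 1e-9)
    expect_equal(f, o$forward, tolerance = 1e-9)
    expect_gte(f, v - 1e-12)
  }
})

test_that("a single-path degenerate profile has forward equal to viterbi", {
  match_e <- matrix(c(1, rep(0, 19)), 1, 20, byrow = TRUE,
                    dimnames = list(NULL, AA20))
  hmm <- profile_hmm(match_e)
  expect_equal(forward_score(hmm, "A"), viterbi_score(hmm, "A")$bit_score)
})

test_that("scan is monotone in the threshold and errors when uncalibrated", {
  fam <- small_family()
  hmm <- small_family_calibrated()
  expect_error(scan_proteome(fam$hmm, fam$proteome), "calibrat")
  h1 <- scan_proteome(hmm, fam$proteome, 1e-4)
  h2 <- scan_proteome(hmm, fam$proteome, 0.0011)
  h3 <- scan_proteome(hmm, fam$proteome, 1.0)
  expect_true(all(h1$target_id %in% h2$target_id))
  expect_true(all(h2$target_id %in% h3$target_id))
  expect_equal(nrow(h3), length(fam$proteome))  # vacuous cutoff
  expect_false(is.unsorted(rev(h2$bit_score)))
})

test_that("planted domain genes are recovered and decoys rejected", {
  fam <- small_family()
  hmm <- small_family_calibrated()
  hits <- scan_proteome(hmm, fam$proteome, 0.0011)
  planted <- c(fam$truth$true_ids, fam$truth$redundant_ids)
  expect_true(all(planted %in% hits$target_id))
  expect_equal(sum(hits$target_id %in% fam$truth$decoy_ids), 0)
  # shuffled decoys only, stringent threshold -> empty
  expect_equal(nrow(scan_proteome(hmm, fam$proteome[fam$truth$decoy_ids], 1e-6)), 0)
})

test_that("PROSITE patterns match with 1-based leftmost non-overlap semantics", {
  expect_equal(match_prosite("R-x(2)-K", "ARTTKA"),
               data.frame(start = 2L, end = 5L))
  expect_equal(match_prosite("A", "AAA"),
               data.frame(start = 1:3, end = 1:3))
  expect_equal(nrow(match_prosite("[DE]-x-{P}", "DAP")), 0)
  expect_equal(match_prosite("[DE]-x-{P}", "DAG"),
               data.frame(start = 1L, end = 3L))
  expect_equal(match_prosite("<M-x(0,2)-K", "MAK"),
               data.frame(start = 1L, end = 3L))
  expect_equal(nrow(match_prosite("<K", "MK")), 0)
  expect_error(read_prosite("R-(2x)-K"), "malformed")
  expect_error(read_prosite(""), "empty")
})

test_that("redundancy removal merges near-copies, keeps fragments, is idempotent", {
  s <- seq_set(c(a = "MKVLHAGCWRTESA", b = "MKVLHAGCWRTESA", half = "MKVLHAG"),
               alphabet = "protein")
  r <- remove_redundant(s, identity_threshold = 0.98)
  expect_setequal(names(r$kept), c("a", "half"))   # tie a/b -> id order; fragment kept
  expect_equal(unname(r$map[["b"]]), "a")
  r2 <- remove_redundant(r$kept, identity_threshold = 0.98)
  expect_identical(names(r2$kept), names(r$kept))
  expect_equal(length(r2$removed), 0)
})

test_that("the 58-to-36 curation outcome holds on the small fixture scaled down", {
  fam <- small_family()  # 10 true + 4 redundant
  bearing <- c(fam$truth$true_ids, fam$truth$redundant_ids)
  r <- remove_redundant(fam$proteome[bearing])
  expect_setequal(names(r$kept), fam$truth$true_ids)
  expect_equal(length(r$removed), 4)
  expect_true(all(r$map == fam$truth$redundancy_map[names(r$map)]))
})

test_that("protein stats match residue-mass sums and pI zeroes the net charge", {
  expect_equal(protein_stats("G")$mw, 75.07, tolerance = 1e-3)
  expect_equal(protein_stats("GG")$mw, 2 * 57.0519 + 18.0153, tolerance = 1e-6)
  for (s in c("MKVLH", "DDEEKKRRH", "ACDEFGHIKLMNPQRSTVWY")) {
    st <- protein_stats(s)
    expect_lt(abs(net_charge(s, st$pi)), 1e-3)
    expect_true(st$pi > 0 && st$pi < 14)
    expect_equal(st$length, nchar(s))
  }
  expect_error(protein_stats("MKX"), "ambiguity")
  expect_error(protein_stats(""), "empty")
})

test_that("net charge is strictly decreasing in pH (bisection converges)", {
  s <- "MKRDEHCY"
  ph <- seq(0.5, 13.5, by = 0.5)
  q <- vapply(ph, function(p) net_charge(s, p), 0)
  expect_true(all(diff(q) < 0))
})
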