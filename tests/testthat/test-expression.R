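make_truth <- function(vals) {
  matrix(vals, nrow = length(vals) %/% 7, ncol = 7, byrow = TRUE,
         dimnames = list(paste0("g", seq_len(length(vals) %/% 7)),
                         canonical_conditions))
}

test_that("2^-deltaCt inverts a noiseless generator exactly", {
  truth <- make_truth(c(8, 8, 8, 8, 8, 8, 8,
                        1, 2, 4, 8, 16, 32, 64))
  ct <- simulate_ct(truth, bio_sd = 0, tech_sd = 0, seed = 21)
  ex <- relative_expression(ct, "SAD1")
  expect_equal(ex$values[rownames(truth), colnames(truth)], truth)
  expect_true(all(ex$values["SAD1", ] == 1))
  expect_true(all(ex$sd["SAD1", ] == 0))
})

test_that("one cycle is a two-fold change and sd comes from biological reps", {
  df <- expand.grid(bio_rep = 1:3, tech_rep = 1:3)
  rows <- rbind(
    data.frame(gene = "g", condition = "leaf", df, ct = 24),
    data.frame(gene = "SAD1", condition = "leaf", df, ct = 25))
  ex <- relative_expression(ct_table(rows), "SAD1")
  expect_equal(unname(ex$values["g", "leaf"]), 2.0)
  expect_equal(unname(ex$sd["g", "leaf"]), 0)
})

test_that("deltaCt is invariant to per-block Ct shifts and linear in input", {
  truth <- make_truth(c(3, 1, 5, 2, 8, 0.5, 4))
  ct <- simulate_ct(truth, bio_sd = 0.3, tech_sd = 0.1, seed = 8)
  ex1 <- relative_expression(ct, "SAD1")
  shifted <- ct
  for (cc in unique(ct$condition)) for (b in unique(ct$bio_rep)) {
    sel <- shifted$condition == cc & shifted$bio_rep == b
    shifted$ct[sel] <- shifted$ct[sel] + stats::runif(1, -3, 3)
  }
  ex2 <- relative_expression(ct_table(shifted), "SAD1")
  expect_equal(ex2$values, ex1$values, tolerance = 1e-12)
  # doubling input RNA (Ct - 1 everywhere for one gene) doubles its values
  doubled <- ct
  doubled$ct[doubled$gene == "g1"] <- doubled$ct[doubled$gene == "g1"] - 1
  ex3 <- relative_expression(ct_table(doubled), "SAD1")
  expect_equal(ex3$values["g1", ], 2 * ex1$values["g1", ], tolerance = 1e-12)
})

test_that("missing references are named and absent cells flagged NA", {
  rows <- data.frame(gene = "g", condition = "leaf", bio_rep = 1, tech_rep = 1, ct = 20)
  expect_error(relative_expression(ct_table(rows), "SAD1"), "SAD1")
  truth <- make_truth(rep(2, 7))
  ct <- simulate_ct(truth, bio_sd = 0, tech_sd = 0, seed = 1)
  ct2 <- ct_table(ct[!(ct$gene == "g1" & ct$condition == "leaf"), ])
  ex <- relative_expression(ct2, "SAD1")
  expect_true(is.na(ex$values["g1", "leaf"]))
  expect_equal(unname(ex$values["g1", "sepal"]), 2)
})

test_that("noisy estimates stay near the generator truth", {
  truth <- make_truth(rep(8, 7))
  ct <- simulate_ct(truth, bio_sd = 0, tech_sd = 0.1, seed = 21)
  ex <- relative_expression(ct, "SAD1")
  expect_true(all(ex$values["g1", ] > 6.5 & ex$values["g1", ] < 9.8))
})

test_that("heatmap transforms behave and constant rows z-score to zero", {
  truth <- make_truth(c(2, 2, 2, 2, 2, 2, 2,
                        1, 2, 4, 8, 16, 32, 64))
  ct <- simulate_ct(truth, bio_sd = 0, tech_sd = 0, seed = 2)
  ex <- relative_expression(ct, "SAD1")
  expect_equal(heatmap_matrix(ex), ex$values)
  expect_equal(heatmap_matrix(ex, transform = "log2")["g1", ],
               stats::setNames(rep(1, 7), canonical_conditions))
  z <- heatmap_matrix(ex, row_scale = "zscore")
  expect_equal(unname(z["g1", ]), rep(0, 7))
  expect_equal(mean(z["g2", ]), 0, tolerance = 1e-12)
})

test_that("profile classes follow the stage-window rules on planted cohorts", {
  truth <- rbind(
    make_truth(c(1, 1, 8, 8, 8, 1, 1)),      # initiation window
    make_truth(c(1, 1, 1, 1, 1, 12, 12)),    # elongation window
    make_truth(c(5, 5, 5, 5, 5, 5, 5)),      # ubiquitous
    make_truth(c(10, 12, 1, 1, 1, 1, 1)))    # leaf/sepal
  rownames(truth) <- paste0("g", 1:4)
  ct <- simulate_ct(truth, bio_sd = 0, tech_sd = 0, seed = 33)
  ex <- relative_expression(ct, "SAD1")
  cls <- classify_profiles(ex)
  expect_equal(unname(cls[paste0("g", 1:4)]),
               c("initiation-stage", "elongation-stage", "ubiquitous",
                 "leaf/sepal-preferential"))
  # larger planted cohort: >= 90% agreement
  set.seed(33)
  n <- 30
  lab <- sample(c("initiation-stage", "elongation-stage", "ubiquitous"), n, TRUE)
  big <- do.call(rbind, lapply(seq_len(n), function(i) {
    base <- switch(lab[i],
      "initiation-stage" = c(1, 1, 9, 9, 9, 1, 1),
      "elongation-stage" = c(1, 1, 1, 1, 1, 9, 9),
      "ubiquitous" = rep(4, 7))
    base * exp(stats::rnorm(7, 0, 0.1))
  }))
  dimnames(big) <- list(sprintf("G%02d", seq_len(n)), canonical_conditions)
  ctb <- simulate_ct(big, bio_sd = 0.1, tech_sd = 0.05, seed = 34)
  exb <- relative_expression(ctb, "SAD1")
  agree <- mean(classify_profiles(exb)[rownames(big)] == lab)
  expect_gte(agree, 0.9)
})

test_that("missing canonical conditions raise an error", {
  truth <- make_truth(rep(2, 7))[, 1:5, drop = FALSE]
  ct <- simulate_ct(truth, bio_sd = 0, tech_sd = 0, seed = 3)
  ex <- relative_expression(ct, "SAD1")
  expect_error(classify_profiles(ex), "missing condition")
})
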