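#!/usr/bin/env Rscript
# Stage 1: generate the synthetic survey substrate with recorded truth.
#
# Emulates the study conditions of a diploid-cotton TCP survey: 58
# domain-bearing proteins (36 true genes organized as 15 paralog pairs
# plus 6 singletons, and 22 redundant near-copies), 500 shuffled decoys,
# coding sequences with correlated synonymous divergence inside pairs, a
# 13-chromosome gene layout with pair members on different chromosomes,
# and a replicated qPCR Ct table over leaf, sepal and five fiber stages.

library(famsurvey)

outdir <- "results/fixtures"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 7L

fam <- make_family(seed = seed, with_cds = TRUE)
write_fasta(fam$proteome, file.path(outdir, "proteome.fa"))
write_fasta(fam$cds, file.path(outdir, "cds.fa"))
write_hmm_profile(fam$hmm, file.path(outdir, "toy.hmm"))

# 13-chromosome layout; every fifth gene gets introns so roughly 80% of
# the family is intronless, as is typical for this family
ids <- fam$truth$true_ids
n <- length(ids)
chr <- sprintf("chr%d", 1 + ((seq_len(n) - 1) %% 13))
slot <- integer(n)
for (cc in unique(chr)) slot[chr == cc] <- seq_len(sum(chr == cc))
specs <- data.frame(gene_id = ids, chr = chr,
                    start = 1000000L + (slot - 1L) * 2000000L,
                    n_exons = rep(c(1L, 1L, 1L, 1L, 2L), length.out = n))
gen <- make_genome_gff(specs, seed = seed)
write_gff3(gen$models, file.path(outdir, "genes.gff3"))

# planted expression classes over the canonical seven conditions
conds <- c("leaf", "sepal", "fiber_m2DPA", "fiber_0DPA", "fiber_2DPA",
           "fiber_5DPA", "fiber_10DPA")
set.seed(seed)
classes <- sample(c("initiation-stage", "elongation-stage", "ubiquitous",
                    "leaf/sepal-preferential"), n, TRUE,
                  prob = c(0.3, 0.3, 0.25, 0.15))
truth_expr <- t(vapply(classes, function(cl) {
  base <- switch(cl,
    "initiation-stage"        = c(1, 1, 9, 9, 9, 1, 1),
    "elongation-stage"        = c(1, 1, 1, 1, 1, 9, 9),
    "ubiquitous"              = rep(4, 7),
    "leaf/sepal-preferential" = c(10, 12, 1, 1, 1, 1, 1))
  base * exp(rnorm(7, 0, 0.15))
}, numeric(7)))
dimnames(truth_expr) <- list(ids, conds)
ct <- simulate_ct(truth_expr, bio_sd = 0.2, tech_sd = 0.1, seed = seed)
write_ct_table(ct, file.path(outdir, "ct.tsv"))

jsonlite::write_json(
  list(seed = seed,
       true_ids = fam$truth$true_ids,
       redundant_ids = fam$truth$redundant_ids,
       redundancy_map = as.list(fam$truth$redundancy_map),
       pair_truth = fam$truth$pair_truth,
       domain_positions = fam$truth$domain_positions,
       consensus = fam$truth$consensus,
       expression_classes = as.list(stats::setNames(classes, ids))),
  file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = 8)

cat(sprintf("wrote %d proteins (%d domain-bearing, %d decoys), %d CDS,\n",
            length(fam$proteome),
            length(fam$truth$true_ids) + length(fam$truth$redundant_ids),
            length(fam$truth$decoy_ids), length(fam$cds)))
cat(sprintf("%d gene models on 13 chromosomes, Ct table with %d rows\n",
            length(gen$models), nrow(ct)))
cat("fixtures under", outdir, "\n")
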