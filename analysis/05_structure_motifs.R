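#!/usr/bin/env Rscript
# Stage 5: exon/intron architectures of the family's gene models and
# ZOOPS EM motif discovery on the curated proteins, marking which motif
# covers the planted domain region.

library(famsurvey)

truth <- jsonlite::read_json("results/fixtures/truth.json", simplifyVector = TRUE)
fam <- read_fasta("results/curated.fa")
gff <- read_gff3("results/fixtures/genes.gff3")

tab <- structure_table(gff)
write.table(tab, "results/structures.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("%d/%d genes (%.0f%%) are intronless\n",
            sum(tab$n_introns == 0), nrow(tab),
            100 * mean(tab$n_introns == 0)))

motifs <- em_motif_search(fam, max_motifs = 3, widths = c(10, 15, 20, 29),
                          n_starts = 4, seed = truth$seed)
jsonlite::write_json(
  lapply(motifs, function(m)
    list(width = m$width, consensus = m$consensus, site_prior = m$site_prior,
         log_likelihood = m$log_likelihood, sites = m$sites)),
  "results/motifs.json", auto_unbox = TRUE, digits = 8)

# which motif covers the planted domain region (positions 101-159)?
dom <- c(101, 159)
for (k in seq_along(motifs)) {
  s <- motifs[[k]]$sites
  cov <- mean(s$start <= dom[2] & s$end >= dom[1])
  cat(sprintf("motif %d: width %d, sites in %d/%d sequences, %.0f%% inside the domain region\n",
              k, motifs[[k]]$width, nrow(s), length(fam), 100 * cov))
}
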