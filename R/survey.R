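#' Run the full gene-family survey
#'
#' Orchestrates the stages in order: domain scan, curation, phylogeny,
#' duplication/dating, gene structure, motif discovery, expression. Every
#' stage's output is written under `outdir`; a stage failure stops the
#' run with a stage-named error, preserving earlier outputs. All
#' stochastic stages derive their RNG streams from the single `seed`.
#'
#' @param config list with elements: `proteome` ([seq_set]), `hmm`
#'   (calibrated or not [profile_hmm]), and optionally `cds` ([seq_set]),
#'   `models` ([gene_model] list), `locations`, `ct` (`ct_table`),
#'   `reference_gene`, `prosite` (pattern string), `p_value_threshold`
#'   (default 0.0011), `bootstrap_n` (default 100), `distance_model`
#'   (default "jtt"), `lambda_rate` (default 1.5e-8), `max_motifs`
#'   (default 3), `motif_widths`, `seed` (default 1), `outdir`.
#' @return invisible list of stage results (`hits`, `curated`, `tree`,
#'   `paralogs`, `structures`, `motifs`, `expression`).
#' @export
run_survey <- function(config) {
  cfg <- utils::modifyList(list(p_value_threshold = 0.0011, bootstrap_n = 100L,
                                distance_model = "jtt", lambda_rate = 1.5e-8,
                                max_motifs = 3L, motif_widths = NULL,
                                reference_gene = "SAD1", seed = 1L,
                                outdir = tempfile("survey")), config)
  for (need in c("proteome", "hmm"))
    if (is.null(cfg[[need]])) .stopf("config missing '%s'", need)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  log <- c(sprintf("famsurvey %s", as.character(utils::packageVersion("famsurvey"))),
           sprintf("seed %d", cfg$seed),
           sprintf("p_value_threshold %g", cfg$p_value_threshold),
           sprintf("distance_model %s", cfg$distance_model),
           sprintf("lambda_rate %g", cfg$lambda_rate))
  writeLines(log, file.path(cfg$outdir, "log.txt"))

  out$hits <- stage("scan", {
    hmm <- cfg$hmm
    if (is.null(hmm$calibration))
      hmm <- calibrate_profile(hmm, seed = cfg$seed)
    scan_proteome(hmm, cfg$proteome, cfg$p_value_threshold)
  })
  if (!is.null(cfg$prosite)) {
    pat <- read_prosite(cfg$prosite)
    out$hits$prosite_confirmed <- vapply(out$hits$target_id, function(id)
      nrow(match_prosite(pat, cfg$proteome[[id]])) > 0, TRUE)
  }
  utils::write.table(out$hits, file.path(cfg$outdir, "hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  out$curated <- stage("curate", {
    remove_redundant(cfg$proteome[out$hits$target_id])
  })
  fam <- out$curated$kept
  fam <- fam[order(names(fam))]
  stats_tab <- stage("protein_stats", {
    do.call(rbind, lapply(names(fam), function(id) {
      st <- protein_stats(fam[[id]])
      data.frame(gene = id, length = st$length, mw = round(st$mw, 2),
                 pi = round(st$pi, 2),
                 location = if (!is.null(cfg$locations) && !is.null(cfg$locations[[id]]))
                   format_location(cfg$locations[[id]]) else NA_character_,
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.table(stats_tab, file.path(cfg$outdir, "family_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  out$tree <- stage("tree", {
    aln <- build_msa(fam)
    tr <- bootstrap_support(aln, model = cfg$distance_model,
                            bootstrap_n = cfg$bootstrap_n, seed = cfg$seed)
    write_newick(tr, file.path(cfg$outdir, "tree.nwk"))
    tr
  })

  if (!is.null(cfg$cds)) {
    out$paralogs <- stage("duplication", {
      paralog_table(fam, cfg$cds, locations = cfg$locations,
                    lambda_rate = cfg$lambda_rate)
    })
    tab2 <- out$paralogs
    if (nrow(tab2)) {
      tab2$ks <- round(tab2$ks, 4)
      tab2$t_mya <- round(tab2$t_mya, 5)
    }
    utils::write.table(tab2, file.path(cfg$outdir, "duplication_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(cfg$models)) {
    out$structures <- stage("structure", structure_table(cfg$models))
    utils::write.table(out$structures, file.path(cfg$outdir, "structures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  out$motifs <- stage("motifs", {
    em_motif_search(fam, max_motifs = cfg$max_motifs,
                    widths = cfg$motif_widths, seed = cfg$seed)
  })
  jsonlite::write_json(
    lapply(out$motifs, function(m)
      list(width = m$width, consensus = m$consensus,
           site_prior = m$site_prior, log_likelihood = m$log_likelihood,
           sites = m$sites, pwm = unname(m$pwm))),
    file.path(cfg$outdir, "motifs.json"), auto_unbox = TRUE, digits = 8)

  if (!is.null(cfg$ct)) {
    out$expression <- stage("expression", {
      relative_expression(cfg$ct, cfg$reference_gene)
    })
    utils::write.table(cbind(gene = rownames(out$expression$values),
                             as.data.frame(out$expression$values)),
                       file.path(cfg$outdir, "expr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
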