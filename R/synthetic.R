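# Seeded synthetic-data generators. Every generator records its ground
# truth so downstream stages can be tested without any external data; all
# are byte-deterministic given the seed.

.sample_protein <- function(n, bg = NULL) {
  if (is.null(bg)) bg <- rep(1 / 20, 20)
  paste(sample(AA20, n, replace = TRUE, prob = bg), collapse = "")
}

.mutate_protein <- function(s, n_sub, positions = NULL) {
  ch <- strsplit(s, "")[[1]]
  if (is.null(positions)) positions <- seq_along(ch)
  pos <- sample(positions, min(n_sub, length(positions)))
  for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1)
  paste(ch, collapse = "")
}

#' Build a toy domain profile HMM from a random alignment
#'
#' Draws a consensus of the requested width, derives `n_instances`
#' mutated copies, and estimates match emissions from the implied gapless
#' alignment (with pseudocounts). Used in place of a curated domain
#' profile so the testing loop needs no downloads; real HMMER3-style
#' profile files are read by [read_hmm_profile()].
#'
#' @param seed RNG seed.
#' @param width domain width (default 59, a TCP-domain-sized block).
#' @param n_instances alignment depth.
#' @param mut_rate per-residue mutation rate within instances.
#' @return list with `hmm`, `consensus`, `instances`.
#' @export
make_domain_profile <- function(seed = 1L, width = 59L, n_instances = 20L,
                                mut_rate = 0.15) {
  .seeded(seed, {
    consensus <- .sample_protein(width)
    instances <- vapply(seq_len(n_instances), function(i)
      .mutate_protein(consensus, stats::rbinom(1, width, mut_rate)), "")
    cm <- do.call(rbind, strsplit(instances, ""))
    cnt <- t(vapply(AA20, function(a) colSums(cm == a), numeric(width)))
    match_e <- t((cnt + 0.2) / (colSums(cnt) + 4))
    trans <- matrix(rep(c(0.95, 0.025, 0.025, 0.5, 0.5, 0.5, 0.5), each = width),
                    width, 7)
    hmm <- profile_hmm(match_e, trans = trans, name = sprintf("toy%d", width))
    list(hmm = hmm, consensus = consensus, instances = instances)
  })
}

#' Generate a synthetic gene family with decoys and redundancies
#'
#' Emulates a family-survey substrate: `n_true` genes carrying a planted
#' domain (organized as `n_pairs` paralog pairs evolved from common
#' ancestors plus singletons), `n_redundant` near-copies/slight
#' truncations of true genes, and `n_decoys` composition-matched shuffles.
#' Paralog-pair divergence is placed well inside the 70/70
#' coverage-similarity acceptance region while unrelated genes fall well
#' outside it, and redundancies sit above the 0.95-identity curation
#' cutoff.
#'
#' @param seed RNG seed.
#' @param n_true true family size (default 36).
#' @param n_redundant redundant entries (default 22).
#' @param n_decoys decoy sequences (default 500).
#' @param n_pairs planted paralog pairs among the true genes (default 15).
#' @param gene_len protein length of every true gene.
#' @param pair_sub_rate per-lineage substitution fraction outside the
#'   domain for paralog pairs.
#' @param with_cds also generate coding sequences (paralog pairs get
#'   correlated synonymous divergence via [evolve_pair()]-style events).
#' @return list with `proteome` ([seq_set]), `hmm`, `cds` (or NULL) and
#'   `truth` (ids, redundancy map, pair table, domain positions).
#' @export
make_family <- function(seed = 7L, n_true = 36L, n_redundant = 22L,
                        n_decoys = 500L, n_pairs = 15L, gene_len = 300L,
                        pair_sub_rate = 0.10, with_cds = FALSE) {
  stopifnot(n_true >= 2 * n_pairs, n_redundant <= n_true)
  prof <- make_domain_profile(seed)
  width <- prof$hmm$length
  .seeded(seed + 1L, {
    sample_domain <- function() .mutate_protein(prof$consensus, stats::rbinom(1, width, 0.12))
    dom_start <- 101L  # fixed placement keeps the truth table simple
    build_gene <- function(core) {
      paste0(substr(core, 1, dom_start - 1), sample_domain(),
             substr(core, dom_start, gene_len - width))
    }
    ids <- sprintf("FAM%02d", seq_len(n_true))
    prots <- character(n_true)
    dom_positions <- list()
    pair_truth <- data.frame(gene1 = character(0), gene2 = character(0))
    # paralog pairs: common ancestor, per-lineage substitutions outside the domain
    nonflank <- gene_len - width
    for (k in seq_len(n_pairs)) {
      anc_core <- .sample_protein(nonflank)
      anc <- build_gene(anc_core)
      outside <- setdiff(seq_len(gene_len), dom_start:(dom_start + width - 1))
      nsub <- round(pair_sub_rate * gene_len)
      i1 <- 2 * k - 1; i2 <- 2 * k
      prots[i1] <- .mutate_protein(anc, nsub, outside)
      prots[i2] <- .mutate_protein(anc, nsub, outside)
      pair_truth <- rbind(pair_truth, data.frame(gene1 = ids[i1], gene2 = ids[i2],
                                                 stringsAsFactors = FALSE))
    }
    for (k in seq.int(2 * n_pairs + 1, length.out = n_true - 2 * n_pairs))
      prots[k] <- build_gene(.sample_protein(nonflank))
    for (k in seq_len(n_true))
      dom_positions[[ids[k]]] <- c(dom_start, dom_start + width - 1)
    # redundancies: slight truncation (<= 4% of length) plus <= 1% substitutions
    red_src <- ids[seq_len(n_redundant)]
    red_ids <- if (n_redundant > 0) paste0(red_src, "r") else character(0)
    reds <- vapply(seq_len(n_redundant), function(k) {
      s <- prots[k]
      trim <- sample.int(10L, 1)
      s <- if (k %% 2 == 0) substr(s, trim + 1, nchar(s)) else substr(s, 1, nchar(s) - trim)
      .mutate_protein(s, stats::rbinom(1, nchar(s), 0.005))
    }, "")
    # decoys: residue-shuffles of the true genes (composition-matched)
    decoys <- vapply(seq_len(n_decoys), function(k) {
      src <- prots[1 + (k - 1) %% n_true]
      paste(sample(strsplit(src, "")[[1]]), collapse = "")
    }, "")
    proteome <- seq_set(c(prots, reds, decoys),
                        ids = c(ids, red_ids, sprintf("DEC%03d", seq_len(n_decoys))),
                        alphabet = "protein")
    cds <- NULL
    if (with_cds) {
      cds_strings <- vapply(prots, .reverse_translate, "")
      # correlated synonymous divergence within pairs
      for (k in seq_len(n_pairs)) {
        i1 <- 2 * k - 1; i2 <- 2 * k
        anc_like <- cds_strings[i1]
        cds_strings[i2] <- .retarget_cds(anc_like, prots[i2])
        target_ks <- stats::runif(1, 0.25, 1.1)
        cds_strings[i1] <- .add_synonymous(cds_strings[i1], target_ks / 2)
        cds_strings[i2] <- .add_synonymous(cds_strings[i2], target_ks / 2)
        pair_truth$target_ks[k] <- target_ks
      }
      cds <- seq_set(cds_strings, ids = ids, alphabet = "dna")
    }
    list(proteome = proteome, hmm = prof$hmm, cds = cds,
         truth = list(seed = seed, true_ids = ids, redundant_ids = red_ids,
                      decoy_ids = sprintf("DEC%03d", seq_len(n_decoys)),
                      redundancy_map = stats::setNames(red_src, red_ids),
                      pair_truth = pair_truth,
                      domain_positions = dom_positions,
                      consensus = prof$consensus))
  })
}

# uniform-synonymous reverse translation (uses current RNG state)
.reverse_translate <- function(protein) {
  gc <- .genetic_code()
  by_aa <- split(names(gc), gc)
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) sample(by_aa[[a]], 1), ""), collapse = "")
}

# re-derive a CDS for a mutated protein, keeping codons where the
# amino acid is unchanged
.retarget_cds <- function(cds, protein) {
  gc <- .genetic_code()
  by_aa <- split(names(gc), gc)
  codons <- .split_codons(cds)
  aa <- strsplit(protein, "")[[1]]
  stopifnot(length(codons) == length(aa))
  for (i in seq_along(aa))
    if (gc[[codons[i]]] != aa[i]) codons[i] <- sample(by_aa[[aa[i]]], 1)
  paste(codons, collapse = "")
}

# per-codon single-nucleotide change inventories, split syn/nonsyn
.codon_changes <- function() {
  if (!is.null(.fam_env$codon_changes)) return(.fam_env$codon_changes)
  gc <- .genetic_code()
  sense <- names(gc)[gc != "*"]
  nt <- c("A", "C", "G", "T")
  out <- lapply(sense, function(cod) {
    ch <- strsplit(cod, "")[[1]]
    syn <- character(0); non <- character(0)
    for (p in 1:3) for (b in setdiff(nt, ch[p])) {
      mut <- ch; mut[p] <- b
      mc <- paste(mut, collapse = "")
      if (gc[[mc]] == "*") next
      if (gc[[mc]] == gc[[cod]]) syn <- c(syn, mc) else non <- c(non, mc)
    }
    list(syn = syn, non = non)
  })
  names(out) <- sense
  .fam_env$codon_changes <- out
  out
}

# apply approximately ks_branch expected synonymous substitutions/site
.add_synonymous <- function(cds, ks_branch) {
  tb <- .ng_tables()
  codons <- .split_codons(cds)
  S <- sum(tb$syn_sites[codons])
  n_events <- stats::rpois(1, ks_branch * S)
  ch <- .codon_changes()
  for (e in seq_len(n_events)) {
    counts <- vapply(ch[codons], function(x) length(x$syn), 0L)
    i <- sample.int(length(codons), 1, prob = counts)
    codons[i] <- sample(ch[[codons[i]]]$syn, 1)
  }
  paste(codons, collapse = "")
}

#' Evolve a duplicated CDS pair to a target synonymous divergence
#'
#' Two descendants of `ancestor_cds` each receive a Poisson number of
#' synonymous events (expectation `target_ks / 2` per synonymous site)
#' and nonsynonymous events (expectation `omega * target_ks / 2` per
#' nonsynonymous site), applied as uniformly chosen single-nucleotide
#' changes of the required class; stop codons are never created. Realized
#' event counts are recorded so estimator tests can compare against the
#' realization rather than the expectation.
#'
#' @param ancestor_cds ancestral coding sequence (no stops).
#' @param target_ks expected pairwise synonymous divergence (0..2].
#' @param omega dN/dS of the substitution process (0..1].
#' @param seed RNG seed.
#' @return list with `cds1`, `cds2`, per-lineage event counts, and
#'   `realized_ks`/`realized_ka` (events per Nei-Gojobori site).
#' @export
evolve_pair <- function(ancestor_cds, target_ks, omega = 0.3, seed = 1L) {
  stopifnot(target_ks >= 0, omega > 0, omega <= 1)
  tb <- .ng_tables()
  ch <- .codon_changes()
  anc <- .split_codons(toupper(ancestor_cds))
  if (!all(anc %in% tb$sense)) .stopf("ancestor contains stop or ambiguous codons")
  S0 <- sum(tb$syn_sites[anc]); N0 <- 3 * length(anc) - S0
  .seeded(seed, {
    evolve_one <- function() {
      codons <- anc
      ns <- stats::rpois(1, target_ks / 2 * S0)
      nn <- stats::rpois(1, omega * target_ks / 2 * N0)
      events <- sample(c(rep("s", ns), rep("n", nn)))
      for (ev in events) {
        repeat {
          counts <- vapply(ch[codons], function(x)
            if (ev == "s") length(x$syn) else length(x$non), 0L)
          if (sum(counts) == 0) break
          i <- sample.int(length(codons), 1, prob = counts)
          opts <- if (ev == "s") ch[[codons[i]]]$syn else ch[[codons[i]]]$non
          codons[i] <- sample(opts, 1)
          break
        }
      }
      list(cds = paste(codons, collapse = ""), ns = ns, nn = nn)
    }
    d1 <- evolve_one(); d2 <- evolve_one()
    c1 <- .split_codons(d1$cds); c2 <- .split_codons(d2$cds)
    S_pair <- sum((tb$syn_sites[c1] + tb$syn_sites[c2]) / 2)
    N_pair <- 3 * length(c1) - S_pair
    list(cds1 = d1$cds, cds2 = d2$cds,
         n_syn_events = d1$ns + d2$ns, n_nonsyn_events = d1$nn + d2$nn,
         realized_ks = (d1$ns + d2$ns) / S_pair,
         realized_ka = (d1$nn + d2$nn) / N_pair)
  })
}

#' Lay out genes on a toy 13-chromosome genome
#'
#' @param gene_specs data.frame with columns `gene_id`, `chr`, `start`,
#'   and optionally `n_exons`, `exon_len`, `intron_len`, `strand`.
#' @param seed RNG seed (strand assignment when unspecified).
#' @return list with `models` (named [gene_model] list), `locations`
#'   (named [parse_location()]-style list) and `chromosomes` (lengths).
#' @export
make_genome_gff <- function(gene_specs, seed = 1L) {
  stopifnot(all(c("gene_id", "chr", "start") %in% names(gene_specs)))
  gs <- gene_specs
  if (is.null(gs$n_exons)) gs$n_exons <- 1L
  if (is.null(gs$exon_len)) gs$exon_len <- 900L
  if (is.null(gs$intron_len)) gs$intron_len <- 200L
  if (is.null(gs$strand)) gs$strand <- .seeded(seed, sample(c("+", "-"), nrow(gs), TRUE))
  models <- list(); locations <- list()
  for (i in seq_len(nrow(gs))) {
    st <- gs$start[i]
    ex <- matrix(NA_integer_, gs$n_exons[i], 2)
    pos <- st
    for (e in seq_len(gs$n_exons[i])) {
      ex[e, ] <- c(pos, pos + gs$exon_len[i] - 1L)
      pos <- pos + gs$exon_len[i] + gs$intron_len[i]
    }
    m <- gene_model(gs$gene_id[i], gs$chr[i], gs$strand[i], ex)
    models[[gs$gene_id[i]]] <- m
    locations[[gs$gene_id[i]]] <- list(chromosome = gs$chr[i],
                                       start = min(ex), end = max(ex))
  }
  # overlap check per chromosome
  for (cc in unique(gs$chr)) {
    on_c <- locations[vapply(locations, function(l) l$chromosome == cc, TRUE)]
    if (length(on_c) < 2) next
    o <- order(vapply(on_c, `[[`, 0, "start"))
    s <- vapply(on_c, `[[`, 0, "start")[o]; e <- vapply(on_c, `[[`, 0, "end")[o]
    if (any(s[-1] <= e[-length(e)]))
      .stopf("overlapping genes on %s", cc)
  }
  chrom_len <- tapply(vapply(locations, `[[`, 0, "end"),
                      vapply(locations, function(l) l$chromosome, ""),
                      function(x) max(x) + 50000)
  list(models = models, locations = locations, chromosomes = chrom_len)
}

#' Default inter-chromosomal layout for a synthetic family
#'
#' Places the `n_true` genes of [make_family()] across 13 chromosomes so
#' that the two members of every planted paralog pair land on different
#' chromosomes (the all-segmental layout).
#'
#' @param truth the `truth` element of [make_family()].
#' @param seed RNG seed.
#' @return as [make_genome_gff()].
#' @export
layout_family_genome <- function(truth, seed = 1L) {
  ids <- truth$true_ids
  n <- length(ids)
  chr <- sprintf("chr%d", 1 + ((seq_len(n) - 1) %% 13))
  # pair members are consecutive ids (2k-1, 2k) -> consecutive chromosomes
  slot <- integer(n)
  for (cc in unique(chr)) slot[chr == cc] <- seq_len(sum(chr == cc))
  specs <- data.frame(gene_id = ids, chr = chr,
                      start = 1000000L + (slot - 1L) * 2000000L,
                      stringsAsFactors = FALSE)
  make_genome_gff(specs, seed = seed)
}

#' Plant PWM-sampled motif sites into sequences
#'
#' @param seqs a [seq_set] of proteins.
#' @param pwm w x 20 probability matrix.
#' @param occupancy probability a sequence receives a site.
#' @param seed RNG seed.
#' @return list with `seqs` (sites written in) and `sites` truth table.
#' @export
plant_motifs <- function(seqs, pwm, occupancy = 1.0, seed = 1L) {
  stopifnot(occupancy >= 0, occupancy <= 1)
  w <- nrow(pwm)
  .seeded(seed, {
    out <- as.character(seqs)
    sites <- list()
    for (i in seq_along(out)) {
      if (stats::runif(1) > occupancy) next
      L <- nchar(out[i])
      if (L < w) next
      pos <- sample.int(L - w + 1, 1)
      site <- paste(vapply(seq_len(w), function(k)
        sample(AA20, 1, prob = pwm[k, ]), ""), collapse = "")
      substr(out[i], pos, pos + w - 1) <- site
      sites[[length(sites) + 1]] <- data.frame(
        seq_id = names(seqs)[i], start = pos, end = pos + w - 1,
        stringsAsFactors = FALSE)
    }
    list(seqs = seq_set(out, ids = names(seqs), alphabet = "protein"),
         sites = do.call(rbind, sites))
  })
}

#' Simulate a replicated qPCR Ct table from an expression truth
#'
#' Ct = base - log2(truth) + biological + technical noise; the reference
#' gene (truth 1 in every condition) sits at `base`. With zero noise,
#' [relative_expression()] inverts the generator exactly.
#'
#' @param truth genes x conditions matrix of true relative expression.
#' @param bio_sd,tech_sd noise standard deviations (cycles).
#' @param seed RNG seed.
#' @param n_bio,n_tech replicate structure (default 3 x 3).
#' @param base reference Ct level (cycles).
#' @param reference_gene id appended as the reference row.
#' @return a `ct_table`.
#' @export
simulate_ct <- function(truth, bio_sd = 0.2, tech_sd = 0.1, seed = 1L,
                        n_bio = 3L, n_tech = 3L, base = 25,
                        reference_gene = "SAD1") {
  stopifnot(bio_sd >= 0, tech_sd >= 0, all(truth > 0))
  full <- rbind(truth, matrix(1, 1, ncol(truth),
                              dimnames = list(reference_gene, colnames(truth))))
  .seeded(seed, {
    rows <- list()
    for (cc in colnames(full)) for (b in seq_len(n_bio)) {
      bshift <- stats::rnorm(nrow(full), 0, bio_sd)
      for (g in seq_len(nrow(full))) for (tr in seq_len(n_tech)) {
        rows[[length(rows) + 1]] <- data.frame(
          gene = rownames(full)[g], condition = cc, bio_rep = b, tech_rep = tr,
          ct = base - log2(full[g, cc]) + bshift[g] + stats::rnorm(1, 0, tech_sd),
          stringsAsFactors = FALSE)
      }
    }
    ct_table(do.call(rbind, rows))
  })
}

#' Simulate homologous proteins with a known column map
#'
#' One ancestor, `n` descendants with independent substitutions and a few
#' short indels; the per-descendant map from residue position to ancestral
#' column is recorded for alignment-accuracy tests.
#'
#' @param seed RNG seed.
#' @param n number of descendants.
#' @param len ancestor length.
#' @param sub_rate per-residue substitution probability.
#' @param max_indels at most this many 1-3 residue indels per descendant.
#' @return list with `seqs` ([seq_set]) and `column_map` (list of integer
#'   vectors; NA marks inserted residues).
#' @export
simulate_homologs <- function(seed = 3L, n = 10L, len = 120L,
                              sub_rate = 0.05, max_indels = 2L) {
  .seeded(seed, {
    anc <- strsplit(.sample_protein(len), "")[[1]]
    seqs <- character(n); maps <- list()
    for (i in seq_len(n)) {
      ch <- anc
      map <- seq_len(len)
      nsub <- stats::rbinom(1, len, sub_rate)
      for (p in sample(len, nsub)) ch[p] <- sample(setdiff(AA20, ch[p]), 1)
      nid <- sample(0:max_indels, 1)
      for (k in seq_len(nid)) {
        L <- length(ch)
        w <- sample(1:3, 1)
        if (stats::runif(1) < 0.5 && L > w + 2) {     # deletion
          at <- sample(L - w, 1)
          ch <- ch[-(at:(at + w - 1))]
          map <- map[-(at:(at + w - 1))]
        } else {                                      # insertion
          at <- sample(L, 1)
          ins <- strsplit(.sample_protein(w), "")[[1]]
          ch <- append(ch, ins, after = at)
          map <- append(map, rep(NA_integer_, w), after = at)
        }
      }
      seqs[i] <- paste(ch, collapse = "")
      maps[[i]] <- map
    }
    ids <- sprintf("h%02d", seq_len(n))
    names(maps) <- ids
    list(seqs = seq_set(seqs, ids = ids, alphabet = "protein"),
         column_map = maps)
  })
}
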