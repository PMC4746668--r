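#' Profile hidden Markov models
#'
#' A `profile_hmm` holds per-node match/insert emission probabilities over
#' the 20 amino acids and the seven core transitions (MM, MI, MD, IM, II,
#' DM, DD), plus a background composition. Scoring is "uni-local": an
#' alignment may enter at any match state and exit at any match state at no
#' cost, and flanking residues are scored against the background (log-odds
#' zero), the standard topology for domain search.
#'
#' @param match L x 20 matrix of match emission probabilities (rows sum to 1).
#' @param insert L x 20 matrix of insert emission probabilities.
#' @param trans L x 7 matrix of transition probabilities with columns
#'   MM, MI, MD, IM, II, DM, DD; row i holds transitions out of node i.
#'   Row L is ignored (exit is free).
#' @param background length-20 amino-acid frequency vector.
#' @param name model name token.
#' @return A `profile_hmm` object.
#' @export
profile_hmm <- function(match, insert = NULL, trans = NULL,
                        background = NULL, name = "profile") {
  match <- as.matrix(match)
  L <- nrow(match)
  if (L < 1 || ncol(match) != 20) .stopf("match emissions must be L x 20 with L >= 1")
  if (is.null(background)) background <- rep(1 / 20, 20)
  if (is.null(insert)) insert <- matrix(background, L, 20, byrow = TRUE)
  if (is.null(trans)) {
    trans <- matrix(rep(c(0.9, 0.05, 0.05, 0.5, 0.5, 0.5, 0.5), each = L), L, 7)
  }
  colnames(match) <- colnames(insert) <- AA20
  colnames(trans) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  chk <- function(x, what) {
    s <- rowSums(x)
    if (any(abs(s - 1) > 1e-6))
      .stopf("%s probabilities do not sum to 1 (node %d)", what, which(abs(s - 1) > 1e-6)[1])
  }
  chk(match, "match emission")
  chk(insert, "insert emission")
  if (L > 1) {
    idx <- seq_len(L - 1)
    chk(trans[idx, 1:3, drop = FALSE], "M-transition")
    chk(trans[idx, 4:5, drop = FALSE], "I-transition")
    chk(trans[idx, 6:7, drop = FALSE], "D-transition")
  }
  if (abs(sum(background) - 1) > 1e-6) .stopf("background must sum to 1")
  structure(list(name = name, length = L, match = match, insert = insert,
                 trans = trans, background = stats::setNames(background, AA20),
                 calibration = NULL),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm '%s', %d match states%s\n", x$name, x$length,
              if (is.null(x$calibration)) "" else ", calibrated"))
  invisible(x)
}

# per-sequence log-odds emission matrices; ambiguity (X) scores 0
.hmm_lom <- function(hmm, idx) {
  n <- length(idx)
  lom <- matrix(0, hmm$length, n)
  loi <- matrix(0, hmm$length, n)
  ok <- which(idx > 0)
  if (length(ok)) {
    lom[, ok] <- log2(hmm$match[, idx[ok], drop = FALSE] /
                        rep(hmm$background[idx[ok]], each = hmm$length))
    loi[, ok] <- log2(hmm$insert[, idx[ok], drop = FALSE] /
                        rep(hmm$background[idx[ok]], each = hmm$length))
  }
  list(lom = lom, loi = loi)
}

.hmm_encode <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  idx <- match(ch, AA20)
  idx[is.na(idx)] <- 0L  # X and other ambiguity -> background
  idx
}

#' Score a sequence against a profile HMM
#'
#' `viterbi_score()` returns the best local alignment (maximum log2-odds
#' path score, envelope coordinates, state path); `forward_score()` returns
#' the log2 sum over all local alignment paths, so
#' `forward_score() >= viterbi_score()` always.
#'
#' @param hmm a [profile_hmm].
#' @param seq protein sequence string.
#' @param id target id recorded in the hit.
#' @return `viterbi_score()`: a `domain_hit` list with `target_id`,
#'   `bit_score`, `env_start`, `env_end`, `state_path`;
#'   `forward_score()`: a numeric log2-odds score.
#' @export
viterbi_score <- function(hmm, seq, id = "seq") {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (!nzchar(seq)) .stopf("empty sequence")
  idx <- .hmm_encode(seq)
  e <- .hmm_lom(hmm, idx)
  lt <- log2(hmm$trans)
  lt[!is.finite(lt)] <- -1e300
  r <- .hmm_viterbi_cpp(e$lom, e$loi, lt)
  structure(list(target_id = id, bit_score = r$score, p_value = NA_real_,
                 env_start = r$env_start, env_end = r$env_end,
                 state_path = r$path),
            class = "domain_hit")
}

#' @rdname viterbi_score
#' @export
forward_score <- function(hmm, seq) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (!nzchar(seq)) .stopf("empty sequence")
  idx <- .hmm_encode(seq)
  e <- .hmm_lom(hmm, idx)
  lt <- log2(hmm$trans)
  lt[!is.finite(lt)] <- -1e300
  .hmm_forward_cpp(e$lom, e$loi, lt)
}

#' Calibrate the score null distribution of a profile
#'
#' Simulates i.i.d. background-composition sequences at a ladder of lengths
#' and fits a Gumbel distribution (location mu, scale 1/lambda) to their
#' forward scores by the method of moments. [score_to_pvalue()]
#' interpolates (mu, lambda) linearly in log length.
#'
#' @param hmm a [profile_hmm].
#' @param lengths ladder of null sequence lengths.
#' @param n_sim null sequences per length (>= 1000 recommended).
#' @param seed RNG seed.
#' @param score_mode `"forward"` or `"viterbi"`: which score the null is
#'   fitted to (must match the score later converted to P-values).
#' @param background null composition; defaults to the profile's
#'   background. Pass [proteome_background()] of the scanned set when the
#'   targets' composition differs from the profile background.
#' @return The profile with a `calibration` table attached.
#' @export
calibrate_profile <- function(hmm, lengths = c(60L, 120L, 250L, 500L),
                              n_sim = 1000L, seed = 1L,
                              score_mode = c("forward", "viterbi"),
                              background = NULL) {
  score_mode <- match.arg(score_mode)
  stopifnot(inherits(hmm, "profile_hmm"))
  if (is.null(background)) background <- hmm$background
  lt <- log2(hmm$trans)
  lt[!is.finite(lt)] <- -1e300
  cal <- .seeded(seed, {
    do.call(rbind, lapply(lengths, function(len) {
      scores <- vapply(seq_len(n_sim), function(i) {
        idx <- sample.int(20L, len, replace = TRUE, prob = background)
        e <- .hmm_lom(hmm, idx)
        if (score_mode == "forward") .hmm_forward_cpp(e$lom, e$loi, lt)
        else .hmm_viterbi_cpp(e$lom, e$loi, lt)$score
      }, 0)
      fit <- .fit_gumbel(scores)
      data.frame(length = len, mu = fit$mu, lambda = fit$lambda)
    }))
  })
  hmm$calibration <- cal
  hmm$calibration_mode <- score_mode
  hmm
}

# Gumbel fit by censored maximum likelihood on the upper tail: scores
# below the (1 - tail_frac) quantile contribute only their censoring mass.
# P-values live in the tail, so the fit privileges tail shape over bulk.
.fit_gumbel <- function(x, tail_frac = 0.10) {
  n <- length(x)
  c0 <- stats::quantile(x, 1 - tail_frac, names = FALSE)
  xt <- x[x > c0]
  m <- n - length(xt)
  lam0 <- pi / (stats::sd(x) * sqrt(6))
  nll <- function(par) {
    mu <- par[1]; lam <- exp(par[2])
    z <- lam * (xt - mu)
    -(length(xt) * log(lam) - sum(z) - sum(exp(-z)) +
        m * (-exp(-lam * (c0 - mu))))
  }
  opt <- stats::optim(c(mean(x), log(lam0)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(mu = opt$par[1], lambda = exp(opt$par[2]))
}

#' Residue composition of a sequence set
#'
#' @param seqs a [seq_set] of proteins.
#' @return length-20 frequency vector over the amino-acid alphabet
#'   (ambiguity codes excluded), suitable as a calibration background.
#' @export
proteome_background <- function(seqs) {
  cnt <- table(factor(strsplit(paste(seqs, collapse = ""), "")[[1]], levels = AA20))
  f <- as.numeric(cnt) + 1
  stats::setNames(f / sum(f), AA20)
}

#' Convert a calibrated score to a P-value
#'
#' @param score log2-odds score.
#' @param calibration calibration table from [calibrate_profile()].
#' @param target_length length of the scored sequence.
#' @return Upper-tail Gumbel P-value in (0, 1].
#' @export
score_to_pvalue <- function(score, calibration, target_length) {
  if (is.null(calibration)) .stopf("profile is not calibrated; run calibrate_profile() first")
  lx <- log(calibration$length)
  t <- log(max(min(target_length, max(calibration$length)), min(calibration$length)))
  mu <- stats::approx(lx, calibration$mu, xout = t, rule = 2)$y
  lam <- stats::approx(lx, calibration$lambda, xout = t, rule = 2)$y
  p <- -expm1(-exp(-lam * (score - mu)))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Scan a proteome for domain hits
#'
#' Scores every sequence, converts scores to P-values using the profile's
#' calibration, and returns hits at or below the P-value cutoff, sorted by
#' score (descending). The default cutoff of 0.0011 follows the published
#' survey protocol this package reimplements.
#'
#' @param hmm a calibrated [profile_hmm].
#' @param proteome a [seq_set] of proteins.
#' @param p_value_threshold per-target P-value cutoff, default 0.0011.
#' @param score_mode `"forward"` (default; matches total-sequence scoring)
#'   or `"viterbi"`.
#' @return data.frame with columns target_id, bit_score, p_value,
#'   env_start, env_end.
#' @export
scan_proteome <- function(hmm, proteome, p_value_threshold = 0.0011,
                          score_mode = c("forward", "viterbi")) {
  score_mode <- match.arg(score_mode)
  if (is.null(hmm$calibration))
    .stopf("profile is not calibrated; run calibrate_profile() first")
  if (!is.null(hmm$calibration_mode) && hmm$calibration_mode != score_mode)
    .stopf("profile calibrated for %s scores, not %s", hmm$calibration_mode, score_mode)
  stopifnot(length(proteome) >= 1, p_value_threshold > 0, p_value_threshold <= 1)
  lt <- log2(hmm$trans)
  lt[!is.finite(lt)] <- -1e300
  rows <- lapply(names(proteome), function(id) {
    s <- proteome[[id]]
    idx <- .hmm_encode(s)
    e <- .hmm_lom(hmm, idx)
    v <- .hmm_viterbi_cpp(e$lom, e$loi, lt)
    sc <- if (score_mode == "forward") .hmm_forward_cpp(e$lom, e$loi, lt) else v$score
    data.frame(target_id = id, bit_score = sc,
               p_value = score_to_pvalue(sc, hmm$calibration, nchar(s)),
               env_start = v$env_start, env_end = v$env_end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$p_value <= p_value_threshold, , drop = FALSE]
  out <- out[order(-out$bit_score, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
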