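# Ungapped motif discovery by ZOOPS (zero-or-one occurrence per sequence)
# expectation-maximization, with MEME-style probabilistic erasure between
# successive motifs. The monitored objective is the log posterior (data
# log-likelihood plus the Dirichlet smoothing term corresponding to the
# 0.01 pseudocount), which EM theory guarantees to be non-decreasing.

.encode_prot <- function(s) {
  idx <- match(strsplit(toupper(s), "")[[1]], AA20)
  idx[is.na(idx)] <- 0L
  idx
}

# one EM run from a given PWM start; u = per-position erasure weights
.zoops_em <- function(X, u, w, bg, pwm0, gamma0 = 0.5,
                      pseudocount = 0.01, tol = 1e-6, max_iter = 500L) {
  n <- length(X)
  pwm <- pwm0; gam <- gamma0
  lbg <- log(bg)
  # background LL of every sequence (constant across iterations)
  ll0 <- vapply(X, function(x) sum(lbg[x[x > 0]]), 0)
  trace <- numeric(0)
  Z <- vector("list", n)
  for (it in seq_len(max_iter)) {
    lpwm_r <- log(pwm) - matrix(lbg, w, 20, byrow = TRUE)  # log ratios
    ll <- 0
    cnt <- matrix(0, w, 20)
    zsum_total <- 0
    for (i in seq_len(n)) {
      x <- X[[i]]; L <- length(x); m <- L - w + 1
      lr <- numeric(m)
      for (j in seq_len(m)) {
        win <- x[j:(j + w - 1)]
        ok <- win > 0
        lr[j] <- sum(lpwm_r[cbind(which(ok), win[ok])]) +
          sum(log(u[[i]][j:(j + w - 1)]))
      }
      mx <- max(lr, 0)
      denom_log <- mx + log((1 - gam) * exp(-mx) + (gam / m) * sum(exp(lr - mx)))
      z <- (gam / m) * exp(lr - denom_log)
      Z[[i]] <- z
      ll <- ll + ll0[i] + denom_log
      zsum_total <- zsum_total + sum(z)
      for (j in seq_len(m)) {
        if (z[j] < 1e-12) next
        win <- x[j:(j + w - 1)]
        ok <- win > 0
        idx <- cbind(which(ok), win[ok])
        cnt[idx] <- cnt[idx] + z[j]
      }
    }
    obj <- ll + pseudocount * sum(log(pwm))
    trace <- c(trace, obj)
    if (it > 1 && trace[it] - trace[it - 1] < tol &&
        trace[it] >= trace[it - 1] - 1e-9) break
    pwm <- (cnt + pseudocount) / (rowSums(cnt) + 20 * pseudocount)
    gam <- min(max(zsum_total / n, 1e-4), 1 - 1e-4)
  }
  list(pwm = pwm, gamma = gam, Z = Z, objective = trace[length(trace)],
       trace = trace, log_likelihood = ll)
}

.motif_sites <- function(X, Z, w, ids) {
  rows <- lapply(seq_along(X), function(i) {
    z <- Z[[i]]
    j <- which.max(z)
    if (!length(j) || z[j] <= 0.5) return(NULL)
    data.frame(seq_id = ids[i], start = j, end = j + w - 1, z = z[j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(seq_id = character(0), start = integer(0),
                               end = integer(0), z = numeric(0))
  else out
}

#' Discover ungapped motifs by ZOOPS EM
#'
#' For each motif, EM is run from several subsequence-derived starts at
#' each candidate width; the best (width, start) is chosen by a
#' size-penalized log-likelihood-ratio criterion. Found sites are
#' probabilistically erased before the next motif is sought. Fully
#' deterministic given `seed`.
#'
#' @param seqs a [seq_set] of proteins (>= 2, each at least `min_width`).
#' @param max_motifs number of motifs to report (significance order).
#' @param min_width,max_width motif width bounds (defaults 6 and 250).
#' @param widths candidate width grid; defaults to
#'   `c(6, 8, 10, 15, 20, 29, 50)` clipped to the bounds.
#' @param n_starts EM restarts per width.
#' @param em_tol,max_iter EM convergence controls.
#' @param seed RNG seed (start selection).
#' @return list of motifs, each with `width`, `pwm`, `site_prior`,
#'   `sites`, `log_likelihood`, `objective_trace`, `consensus`,
#'   `low_complexity`.
#' @export
em_motif_search <- function(seqs, max_motifs = 1L, min_width = 6L,
                            max_width = 250L, widths = NULL,
                            n_starts = 5L, em_tol = 1e-6, max_iter = 500L,
                            seed = 1L) {
  stopifnot(length(seqs) >= 2, min_width <= max_width, max_motifs >= 1)
  if (any(nchar(seqs) < min_width))
    .stopf("sequence '%s' shorter than min_width",
           names(seqs)[nchar(seqs) < min_width][1])
  if (is.null(widths))
    widths <- unique(pmax(pmin(c(6L, 8L, 10L, 15L, 20L, 29L, 50L), max_width), min_width))
  widths <- widths[widths <= min(nchar(seqs))]
  X <- lapply(seqs, .encode_prot)
  ids <- names(seqs)
  res_counts <- table(factor(unlist(X), levels = 0:20))[-1]
  bg <- (as.numeric(res_counts) + 1) / (sum(res_counts) + 20)
  u <- lapply(X, function(x) rep(1, length(x)))
  total_pos <- sum(lengths(X))
  motifs <- list()
  starts_rng <- .seeded(seed, lapply(seq_len(max_motifs), function(k)
    lapply(widths, function(w) {
      lapply(seq_len(n_starts), function(s) {
        i <- sample.int(length(X), 1)
        j <- sample.int(length(X[[i]]) - w + 1, 1)
        c(i, j)
      })
    })))
  for (k in seq_len(max_motifs)) {
    best <- NULL; best_crit <- -Inf; best_w <- NA
    for (wi in seq_along(widths)) {
      w <- widths[wi]
      for (s in seq_len(n_starts)) {
        st <- starts_rng[[k]][[wi]][[s]]
        win <- X[[st[1]]][st[2]:(st[2] + w - 1)]
        pwm0 <- matrix(rep(bg, each = w), w, 20)
        pwm0 <- pwm0 * 0.3 / rowSums(pwm0)
        ok <- win > 0
        pwm0[cbind(which(ok), win[ok])] <- pwm0[cbind(which(ok), win[ok])] + 0.7
        pwm0 <- pwm0 / rowSums(pwm0)
        fit <- .zoops_em(X, u, w, bg, pwm0, tol = em_tol, max_iter = max_iter)
        # size-penalized LLR (BIC-like) for width selection
        ll_bg <- sum(vapply(X, function(x) sum(log(bg)[x[x > 0]]), 0))
        crit <- (fit$log_likelihood - ll_bg) - 0.5 * (19 * w) * log(total_pos)
        if (crit > best_crit) { best_crit <- crit; best <- fit; best_w <- w }
      }
    }
    sites <- .motif_sites(X, best$Z, best_w, ids)
    cons <- AA20[apply(best$pwm, 1, which.max)]
    motifs[[k]] <- list(width = best_w, pwm = best$pwm,
                        site_prior = best$gamma, sites = sites,
                        log_likelihood = best$log_likelihood,
                        objective_trace = best$trace,
                        selection_criterion = best_crit,
                        consensus = paste(cons, collapse = ""),
                        low_complexity = length(unique(cons)) == 1)
    # probabilistic erasure for the next motif
    for (i in seq_along(X)) {
      z <- best$Z[[i]]
      for (j in seq_along(z)) {
        if (z[j] < 1e-6) next
        rng <- j:(j + best_w - 1)
        u[[i]][rng] <- u[[i]][rng] * (1 - z[j])
      }
      u[[i]] <- pmax(u[[i]], 1e-8)
    }
  }
  motifs
}

#' Scan sequences for occurrences of a fitted motif
#'
#' Log2-odds scan of the motif PWM against the background; windows
#' scoring above `score_threshold` are selected greedily by score with
#' overlaps forbidden.
#'
#' @param motif one motif from [em_motif_search()].
#' @param seqs a [seq_set].
#' @param score_threshold minimum log2-odds window score (default 0).
#' @param background optional length-20 background; defaults to the
#'   composition of `seqs`.
#' @return data.frame with seq_id, start, end, score.
#' @export
motif_occurrences <- function(motif, seqs, score_threshold = 0,
                              background = NULL) {
  w <- motif$width
  X <- lapply(seqs, .encode_prot)
  if (is.null(background)) {
    res_counts <- table(factor(unlist(X), levels = 0:20))[-1]
    background <- (as.numeric(res_counts) + 1) / (sum(res_counts) + 20)
  }
  lodds <- log2(motif$pwm) - matrix(log2(background), w, 20, byrow = TRUE)
  rows <- list()
  for (i in seq_along(X)) {
    x <- X[[i]]
    if (length(x) < w) next
    m <- length(x) - w + 1
    sc <- vapply(seq_len(m), function(j) {
      win <- x[j:(j + w - 1)]
      ok <- win > 0
      sum(lodds[cbind(which(ok), win[ok])])
    }, 0)
    cand <- order(-sc)
    taken <- rep(FALSE, length(x))
    for (j in cand) {
      if (sc[j] <= score_threshold) break
      rng <- j:(j + w - 1)
      if (any(taken[rng])) next
      taken[rng] <- TRUE
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = names(seqs)[i], start = j, end = j + w - 1, score = sc[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), score = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$seq_id, out$start), , drop = FALSE]
}
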