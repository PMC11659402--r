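# Independent oracles used to freeze expected values. Each is a deliberately
# naive re-derivation (counting, explicit loops, closed forms) kept separate
# from the implementation paths it checks.

# Pool-ranking percentile oracle: per gene, count its position within the
# up or down pool directly (mid-position for ties).
oracle_percentile <- function(fc) {
  out <- numeric(length(fc))
  names(out) <- names(fc)
  up <- fc[fc > 0]
  dn <- fc[fc < 0]
  for (g in names(fc)) {
    v <- fc[[g]]
    if (v > 0) {
      pos <- sum(up < v) + (sum(up == v) + 1) / 2
      out[g] <- 100 * pos / length(up)
    } else if (v < 0) {
      pos <- sum(dn > v) + (sum(dn == v) + 1) / 2
      out[g] <- -100 * pos / length(dn)
    }
  }
  out
}

# Exhaustive running-sum GSEA oracle: explicit step-by-step walk down the
# sorted list, tracking the extreme deviation.
oracle_gsea_es <- function(ranking, set, weight = 1) {
  ord <- order(ranking, decreasing = TRUE)
  values <- unname(ranking[ord])
  genes <- names(ranking)[ord]
  hit <- genes %in% set
  nh <- sum(hit)
  n <- length(genes)
  if (nh == 0 || nh == n) return(0)
  wsum <- sum(abs(values[hit])^weight)
  running <- 0
  best_pos <- 0
  best_neg <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      running <- running + (if (wsum == 0) 1 / nh else
        abs(values[i])^weight / wsum)
    } else {
      running <- running - 1 / (n - nh)
    }
    if (running > best_pos) best_pos <- running
    if (running < best_neg) best_neg <- running
  }
  # same magnitude-tie convention as the statistic: positive deviation wins
  if (best_pos + best_neg >= -1e-12) best_pos else best_neg
}

# Closed-form hypergeometric upper tail P(X >= k) by explicit choose()
# summation (no phyper, no fisher.test).
oracle_hyper_tail <- function(k, q, t, N) {
  if (k == 0) return(1)
  i <- k:min(q, t)
  sum(exp(lchoose(t, i) + lchoose(N - t, q - i) - lchoose(N, q)))
}

# Quadratic all-pairs gained-peak oracle.
oracle_gained <- function(case, control, min_overlap = 1) {
  keep <- logical(nrow(case))
  for (i in seq_len(nrow(case))) {
    ov <- 0
    for (j in seq_len(nrow(control))) {
      if (case$chrom[i] != control$chrom[j]) next
      shared <- min(case$end[i], control$end[j]) -
        max(case$start[i], control$start[j])
      ov <- max(ov, shared)
    }
    keep[i] <- ov < min_overlap
  }
  case[keep, , drop = FALSE]
}

# Brute-force doubly trimmed weighted mean of M-values for one sample pair,
# by explicit sorting rather than rank arithmetic.
oracle_tmm_pair <- function(obs, ref, trim_M = 0.3, trim_A = 0.05) {
  n_obs <- sum(obs); n_ref <- sum(ref)
  keep <- obs > 0 & ref > 0
  M <- log2((obs[keep] / n_obs) / (ref[keep] / n_ref))
  A <- 0.5 * log2((obs[keep] / n_obs) * (ref[keep] / n_ref))
  w <- (n_obs - obs[keep]) / (n_obs * obs[keep]) +
    (n_ref - ref[keep]) / (n_ref * ref[keep])
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  in_M <- rank(M) >= floor(n * trim_M) + 1 & rank(M) <= n - floor(n * trim_M)
  in_A <- rank(A) >= floor(n * trim_A) + 1 & rank(A) <= n - floor(n * trim_A)
  sel <- in_M & in_A
  2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
}

# Tie-corrected rank AUC (Mann-Whitney normalization), written from the
# U-statistic definition with explicit pair counting.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  wins <- 0
  for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# Power-set region enumeration oracle for multi-set intersections.
oracle_regions <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  pattern <- vapply(universe, function(e) {
    paste(names(sets)[vapply(sets, function(s) e %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  tab <- table(pattern)
  data.frame(pattern = names(tab), count = as.integer(tab),
             row.names = NULL)[order(names(tab)), , drop = FALSE]
}
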