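#' Read a GMT gene-set collection
#'
#' Tab-separated, one set per line: name, description, then genes. Empty sets
#' and duplicate set names are rejected.
#'
#' @param path GMT path.
#' @param category optional category label (e.g. "Hallmark").
#' @return list with `sets` (named list of character vectors) and `category`.
#' @export
read_gmt <- function(path, category = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm))
    stop("duplicate set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nm
  if (any(lengths(sets) == 0))
    stop("empty gene set(s): ",
         paste(nm[lengths(sets) == 0], collapse = ", "), call. = FALSE)
  list(sets = sets, category = category)
}

#' @rdname read_gmt
#' @param collection a collection as returned by [read_gmt()].
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(n) {
    paste(c(n, ifelse(is.na(collection$category), "na", collection$category),
            collection$sets[[n]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Fisher over-representation analysis
#'
#' One-sided Fisher exact test of a query gene set against each set of a
#' collection over a finite universe, from the 2x2 table (overlap,
#' query-only, term-only, neither), with BH adjustment across terms and the
#' sample odds ratio (cross-product; 0 when the overlap is empty).
#'
#' @param query character vector of gene ids; genes outside the universe are
#'   dropped with a warning.
#' @param collection gene-set collection (list with `sets`), or a named list
#'   of character vectors.
#' @param universe character vector of all assayable gene ids.
#' @param top_k optional: keep only the k smallest-padj terms.
#' @return data.frame (term, overlap, size_query, size_term, universe,
#'   odds_ratio, p, padj) sorted by padj then p.
#' @export
fisher_ora <- function(query, collection, universe, top_k = NULL) {
  sets <- if (!is.null(collection$sets)) collection$sets else collection
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    term <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(query, term))
    t_ <- length(term)
    tab <- matrix(c(k, q - k, t_ - k, N - q - t_ + k), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    or <- if (k == 0) 0 else {
      denom <- (q - k) * (t_ - k)
      if (denom == 0) Inf else k * (N - q - t_ + k) / denom
    }
    data.frame(term = nm, overlap = k, size_query = q, size_term = t_,
               universe = N, odds_ratio = or, p = p)
  })
  df <- do.call(rbind, rows)
  df$padj <- stats::p.adjust(df$p, method = "BH")
  df <- df[order(df$padj, df$p), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(top_k)) df <- utils::head(df, top_k)
  df
}

# Weighted Kolmogorov-Smirnov enrichment score of one set on a ranking
# sorted in decreasing order. Returns the maximum-deviation running sum.
.gsea_es <- function(sorted_values, in_set, weight = 1) {
  n <- length(sorted_values)
  nh <- sum(in_set)
  if (nh == 0 || nh == n) return(0)
  w <- abs(sorted_values)^weight
  hit <- numeric(n)
  hit[in_set] <- w[in_set]
  denom_hit <- sum(hit)
  if (denom_hit == 0) hit[in_set] <- 1 / nh else hit <- hit / denom_hit
  miss <- numeric(n)
  miss[!in_set] <- 1 / (n - nh)
  running <- cumsum(hit - miss)
  mx <- max(running); mn <- min(running)
  # deviation magnitudes can tie exactly (both sides rational); the positive
  # deviation wins ties so the statistic is deterministic
  if (mx + mn >= -1e-12) mx else mn
}

#' Preranked gene-set enrichment with permutation NES and FDR
#'
#' Weighted Kolmogorov-Smirnov preranked GSEA: genes are sorted by the
#' ranking metric (e.g. average regulatory percentile) in decreasing order;
#' for each set the enrichment score (ES) is the maximum deviation of the
#' running sum in which set hits increment proportionally to
#' |metric|^weight and misses decrement uniformly (an exact magnitude tie
#' between the positive and negative deviation resolves to the positive
#' one). Significance comes from
#' gene-label permutations: NES = ES / mean(|permuted ES| of the same sign),
#' nominal p is the same-sign permutation tail, and FDR follows the
#' sign-stratified permutation convention of the GSEA method family
#' (observed-vs-permuted NES tail ratio within each sign). A fixed seed
#' makes the run bit-reproducible.
#'
#' @param ranking named numeric vector, no missing values, not all equal.
#' @param collection gene-set collection (list with `sets`) or named list.
#' @param min_size,max_size set-size bounds after restriction to the ranking
#'   universe (defaults 5 and 1000).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed (default 6).
#' @param weight metric exponent (default 1; 0 gives the classic unweighted
#'   KS statistic).
#' @return data.frame (term, size, es, nes, p, fdr) in input set order.
#' @export
preranked_gsea <- function(ranking, collection, min_size = 5, max_size = 1000,
                           n_perm = 1000, seed = 6, weight = 1) {
  sets <- if (!is.null(collection$sets)) collection$sets else collection
  if (anyNA(ranking)) stop("ranking contains missing values", call. = FALSE)
  if (is.null(names(ranking))) stop("ranking must be named", call. = FALSE)
  if (length(unique(ranking)) == 1)
    stop("degenerate ranking: all values equal", call. = FALSE)
  ord <- order(ranking, decreasing = TRUE)
  values <- ranking[ord]
  genes <- names(values)
  n <- length(genes)

  sets <- lapply(sets, function(s) intersect(unique(s), genes))
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  sets <- sets[keep]
  if (length(sets) == 0)
    return(data.frame(term = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p = numeric(0), fdr = numeric(0)))
  sizes <- lengths(sets)

  es <- vapply(names(sets), function(nm)
    .gsea_es(values, genes %in% sets[[nm]], weight), numeric(1))

  # gene-label permutation null, one stream shared across sets per permutation
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  uniq_sizes <- sort(unique(sizes))
  perm_es <- matrix(NA_real_, n_perm, length(uniq_sizes),
                    dimnames = list(NULL, as.character(uniq_sizes)))
  for (b in seq_len(n_perm)) {
    shuffled <- sample.int(n)
    for (s in uniq_sizes) {
      idx <- shuffled[seq_len(s)]
      in_set <- logical(n)
      in_set[idx] <- TRUE
      perm_es[b, as.character(s)] <- .gsea_es(values, in_set, weight)
    }
  }

  nes <- numeric(length(es)); pval <- numeric(length(es))
  perm_nes <- matrix(NA_real_, n_perm, length(es))
  for (i in seq_along(es)) {
    null_es <- perm_es[, as.character(sizes[i])]
    same <- if (es[i] >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    denom <- mean(abs(same))
    if (length(same) == 0 || !is.finite(denom) || denom == 0) {
      nes[i] <- 0; pval[i] <- 1
    } else {
      nes[i] <- es[i] / denom
      pval[i] <- if (es[i] >= 0) mean(same >= es[i]) else mean(same <= es[i])
      pval[i] <- max(pval[i], 1 / max(length(same), 1))
    }
    pos <- null_es >= 0; neg <- null_es < 0
    perm_nes[pos, i] <- null_es[pos] / mean(null_es[pos])
    if (any(neg)) perm_nes[neg, i] <- -null_es[neg] / mean(null_es[neg])
  }

  # sign-stratified permutation FDR on the NES scale
  fdr <- numeric(length(es))
  all_perm <- as.vector(perm_nes)
  all_perm <- all_perm[!is.na(all_perm)]
  for (i in seq_along(es)) {
    if (nes[i] >= 0) {
      num <- mean(all_perm[all_perm >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num <- mean(all_perm[all_perm < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    fdr[i] <- if (!is.finite(num / den)) 1 else min(1, num / den)
  }
  data.frame(term = names(sets), size = sizes, es = es, nes = nes,
             p = pval, fdr = fdr, row.names = NULL)
}

#' Signature fold change across comparisons (geometric-mean mode)
#'
#' Per-sample signature value = geometric mean of the signature genes'
#' expression (a +1 offset is applied, with a message, when any value is
#' non-positive); per comparison, the fold change is the ratio of treated to
#' control group means of the signature value, with a two-sided Welch test
#' on the log signature values and BH adjustment across comparisons.
#'
#' @param exprs list of expression matrices (genes x samples), one per
#'   comparison, or a single matrix.
#' @param groups list of per-sample group vectors ("control"/"treated")
#'   matching `exprs`.
#' @param signature character vector of gene ids.
#' @return data.frame (comparison, n_genes, fold_change, p, padj).
#' @export
signature_fold_change <- function(exprs, groups, signature) {
  if (is.matrix(exprs)) { exprs <- list(exprs); groups <- list(groups) }
  ids <- names(exprs)
  if (is.null(ids)) ids <- paste0("comparison_", seq_along(exprs))
  rows <- lapply(seq_along(exprs), function(i) {
    e <- exprs[[i]]; g <- as.character(groups[[i]])
    sig <- intersect(signature, rownames(e))
    if (length(sig) == 0)
      stop("no signature gene present in comparison ", ids[i], call. = FALSE)
    sub <- e[sig, , drop = FALSE]
    if (any(sub <= 0)) {
      message("non-positive expression values: applying +1 offset")
      sub <- sub + 1
    }
    logsig <- colMeans(log(sub))
    sigval <- exp(logsig)
    tr <- logsig[g == "treated"]; ct <- logsig[g == "control"]
    fc <- mean(sigval[g == "treated"]) / mean(sigval[g == "control"])
    p <- if (length(tr) > 1 && length(ct) > 1)
      tryCatch(stats::t.test(tr, ct)$p.value, error = function(e) NA_real_)
    else NA_real_
    data.frame(comparison = ids[i], n_genes = length(sig),
               fold_change = fc, p = p)
  })
  df <- do.call(rbind, rows)
  df$padj <- stats::p.adjust(df$p, method = "BH")
  rownames(df) <- NULL
  df
}

#' Single-sample gene-set score (rank z)
#'
#' A monotone set-level score per sample: expression values are ranked within
#' each sample, ranks are z-scored within the sample, and the score is the
#' mean rank z-score of the set genes. Constant samples score 0. The score
#' rises when every set gene's expression rises with other genes fixed,
#' which is all the downstream classification stage requires.
#'
#' @param expr expression matrix, genes x samples.
#' @param gene_set character vector; at least `min_genes` must be present.
#' @param min_genes minimum set genes present (default 5).
#' @return named numeric vector of per-sample scores.
#' @export
single_sample_score <- function(expr, gene_set, min_genes = 5) {
  expr <- as.matrix(expr)
  present <- intersect(unique(gene_set), rownames(expr))
  if (length(present) < min_genes)
    stop("fewer than ", min_genes, " set genes present (",
         length(present), ")", call. = FALSE)
  apply(expr, 2, function(col) {
    r <- rank(col)
    s <- stats::sd(r)
    if (s == 0) return(0)
    z <- (r - mean(r)) / s
    mean(z[rownames(expr) %in% present])
  })
}

# Oncotype DX recurrence-score gene groups (reference genes and the two
# panel genes excluded for sparse coverage are absent by design).
.oncotype_groups <- list(
  HER2 = c("GRB7", "ERBB2"),
  ER = c("ESR1", "PGR", "BCL2", "SCUBE2"),
  Proliferation = c("MKI67", "AURKA", "BIRC5", "CCNB1", "MYBL2"),
  Invasion = c("MMP11"),
  CD68 = "CD68", GSTM1 = "GSTM1", BAG1 = "BAG1")

.oncotype_coefs <- c(HER2 = 0.47, ER = -0.34, Proliferation = 1.04,
                     Invasion = 0.1, CD68 = 0.05, GSTM1 = -0.08, BAG1 = -0.07)

#' Weighted impact on the Oncotype DX recurrence score
#'
#' Applies the recurrence-score linear combination to regulatory percentiles
#' of the Oncotype DX panel genes: 0.47 x HER2 group - 0.34 x ER group +
#' 1.04 x Proliferation group + 0.1 x Invasion group + 0.05 x CD68 -
#' 0.08 x GSTM1 - 0.07 x BAG1, where each group term is the mean percentile
#' of its (non-missing) member genes. CTSL2 and GUS are not part of the
#' panel used here.
#'
#' @param percentiles named numeric vector of regulatory percentiles keyed
#'   by gene symbol, or a named list/vector keyed by group name (HER2, ER,
#'   Proliferation, Invasion, CD68, GSTM1, BAG1) giving group averages
#'   directly.
#' @param groups group -> gene map; defaults to the standard panel grouping.
#' @return single numeric weighted impact.
#' @export
oncotype_weighted_impact <- function(percentiles,
                                     groups = .oncotype_groups) {
  pv <- unlist(percentiles)
  if (all(names(.oncotype_coefs) %in% names(pv))) {
    gm <- pv[names(.oncotype_coefs)]
  } else {
    gm <- vapply(names(groups), function(g) {
      present <- intersect(groups[[g]], names(pv))
      vals <- pv[present]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0)
        stop("no percentile available for group ", g, call. = FALSE)
      mean(vals)
    }, numeric(1))
  }
  sum(.oncotype_coefs * gm[names(.oncotype_coefs)])
}
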