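#' Per-gene heterogeneity statistic log10(CV^2)
#'
#' Measures cross-comparison variability of a gene's regulatory percentile as
#' log10((sd / |mean|)^2) with the sample standard deviation. Genes with
#' zero mean or zero variance over the scope are excluded and reported.
#'
#' @param m percentile matrix.
#' @param scope comparison ids (>= 3 required).
#' @param min_obs minimum non-missing observations per gene (default 3).
#' @return list with `stat` (named numeric vector) and `excluded`
#'   (character vector of gene ids dropped for zero mean/sd or too few
#'   observations).
#' @export
heterogeneity_cv <- function(m, scope = colnames(m), min_obs = 3) {
  scope <- .check_scope(m, scope)
  if (length(scope) < 3) stop("scope must contain at least 3 comparisons",
                              call. = FALSE)
  sub <- m[, scope, drop = FALSE]
  n <- rowSums(!is.na(sub))
  mu <- rowMeans(sub, na.rm = TRUE)
  sd_ <- apply(sub, 1, stats::sd, na.rm = TRUE)
  ok <- n >= min_obs & !is.na(mu) & mu != 0 & !is.na(sd_) & sd_ > 0
  stat <- log10((sd_[ok] / abs(mu[ok]))^2)
  list(stat = stat, excluded = rownames(sub)[!ok])
}

#' Compare two heterogeneity scopes by Mann-Whitney U
#'
#' Two-sided Wilcoxon rank-sum test on the per-gene heterogeneity statistics
#' of two comparison scopes (e.g. tamoxifen vs fulvestrant experiments).
#'
#' @param m percentile matrix.
#' @param scope_a,scope_b comparison ids defining the two groups.
#' @return list with the two statistic vectors, their medians, and the
#'   two-sided p-value.
#' @export
heterogeneity_test <- function(m, scope_a, scope_b) {
  a <- heterogeneity_cv(m, scope_a)$stat
  b <- heterogeneity_cv(m, scope_b)$stat
  ht <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
  list(stat_a = a, stat_b = b,
       median_a = stats::median(a), median_b = stats::median(b),
       p = ht$p.value)
}

#' Pairwise Pearson correlation of average percentile profiles
#'
#' For a named grouping of comparisons (compounds, cell lines, or single
#' comparisons), computes the average percentile profile of each group on the
#' matrix's gene universe, then the Pearson correlation between every pair of
#' profiles on pairwise-complete genes, with average-linkage hierarchical
#' clustering on distance 1 - r for the leaf order.
#'
#' @param m percentile matrix (apply [presence_filter()] first to work on the
#'   shared filtered universe).
#' @param grouping named list mapping group name -> comparison ids; or NULL
#'   to correlate single comparisons.
#' @param min_shared minimum pairwise-complete genes for a defined cell
#'   (default 2; fewer gives NA with a warning).
#' @return list with `r` (symmetric correlation matrix, unit diagonal) and
#'   `order` (leaf order from clustering; NULL if < 3 groups or missing
#'   cells).
#' @export
pairwise_correlation <- function(m, grouping = NULL, min_shared = 2) {
  if (is.null(grouping))
    grouping <- stats::setNames(as.list(colnames(m)), colnames(m))
  prof <- vapply(grouping, function(ids) average_percentile(m, ids),
                 numeric(nrow(m)))
  rownames(prof) <- rownames(m)
  g <- ncol(prof)
  r <- matrix(NA_real_, g, g, dimnames = list(colnames(prof), colnames(prof)))
  for (i in seq_len(g)) for (j in i:g) {
    ok <- !is.na(prof[, i]) & !is.na(prof[, j])
    if (i == j) { r[i, j] <- 1; next }
    if (sum(ok) < min_shared) {
      warning("groups ", colnames(prof)[i], " and ", colnames(prof)[j],
              " share < ", min_shared, " genes; correlation set NA",
              call. = FALSE)
      next
    }
    r[i, j] <- r[j, i] <- stats::cor(prof[ok, i], prof[ok, j])
  }
  ord <- NULL
  if (g >= 3 && !anyNA(r)) {
    hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
    ord <- colnames(prof)[hc$order]
  }
  list(r = r, order = ord, profiles = prof)
}

.call_set <- function(label, genes, params) {
  structure(list(label = label, genes = genes, params = params),
            class = "gene_call_set")
}

#' @export
print.gene_call_set <- function(x, ...) {
  cat("<gene_call_set> ", x$label, ": ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Concordance quadrants between two average-percentile profiles
#'
#' Splits genes into consistently and inconsistently regulated sets using the
#' boundary-inclusive cuts >= +cut and <= -cut on both axes.
#'
#' @param avg_x,avg_y named average-percentile vectors on a shared universe.
#' @param cut percentile cut (default 25).
#' @return named list of four gene_call_set objects: up_up, down_down,
#'   x_up_y_down, x_down_y_up.
#' @export
concordance_quadrants <- function(avg_x, avg_y, cut = 25) {
  genes <- intersect(names(avg_x), names(avg_y))
  x <- avg_x[genes]; y <- avg_y[genes]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; genes <- genes[ok]
  p <- list(cut = cut)
  list(
    up_up       = .call_set("up_up", genes[x >= cut & y >= cut], p),
    down_down   = .call_set("down_down", genes[x <= -cut & y <= -cut], p),
    x_up_y_down = .call_set("x_up_y_down", genes[x >= cut & y <= -cut], p),
    x_down_y_up = .call_set("x_down_y_up", genes[x <= -cut & y >= cut], p))
}

#' Preferentially regulated (discordant) genes between two profiles
#'
#' A gene is a-preferential when pct_a - pct_b strictly exceeds `delta_cut`
#' (and symmetrically for b).
#'
#' @param avg_a,avg_b named average-percentile vectors.
#' @param delta_cut positive percentile difference cut (default 70).
#' @return list of two gene_call_set objects (`a_pref`, `b_pref`) plus the
#'   per-gene delta vector.
#' @export
discordance_genes <- function(avg_a, avg_b, delta_cut = 70) {
  if (delta_cut <= 0) stop("delta_cut must be positive", call. = FALSE)
  genes <- intersect(names(avg_a), names(avg_b))
  d <- avg_a[genes] - avg_b[genes]
  d <- d[!is.na(d)]
  p <- list(delta_cut = delta_cut)
  list(a_pref = .call_set("a_pref", names(d)[d > delta_cut], p),
       b_pref = .call_set("b_pref", names(d)[-d > delta_cut], p),
       delta = d)
}

#' Bidirectional genes
#'
#' Calls genes that fall into the top decile of up-regulation in at least
#' `min_frac` of comparisons AND into the top decile of down-regulation in at
#' least `min_frac` of comparisons (boundaries inclusive). Top-decile
#' membership is on the percentile value: >= +100(1 - top_frac) up,
#' <= -100(1 - top_frac) down. Fractions are over comparisons where the gene
#' is non-missing.
#'
#' @param m percentile matrix.
#' @param scope comparison ids (>= 5 required).
#' @param top_frac top fraction defining extreme regulation (default 0.10).
#' @param min_frac minimum fraction of comparisons in each direction
#'   (default 0.15).
#' @return gene_call_set with a `table` attribute holding per-gene up/down
#'   fractions for all genes.
#' @export
bidirectional_genes <- function(m, scope = colnames(m), top_frac = 0.10,
                                min_frac = 0.15) {
  scope <- .check_scope(m, scope)
  if (length(scope) < 5) stop("scope must contain at least 5 comparisons",
                              call. = FALSE)
  sub <- m[, scope, drop = FALSE]
  thr <- 100 * (1 - top_frac)
  n <- rowSums(!is.na(sub))
  f_up <- rowSums(sub >= thr, na.rm = TRUE) / n
  f_dn <- rowSums(sub <= -thr, na.rm = TRUE) / n
  called <- n > 0 & f_up >= min_frac & f_dn >= min_frac
  out <- .call_set("bidirectional", rownames(sub)[called],
                   list(top_frac = top_frac, min_frac = min_frac))
  attr(out, "table") <- data.frame(gene_id = rownames(sub), n_obs = n,
                                   frac_up = f_up, frac_down = f_dn,
                                   row.names = NULL)
  out
}

#' Consensus targets of a model class
#'
#' Ranks genes by the fraction of comparisons in which they fall into the top
#' decile of regulation in the given direction; genes at or above `min_frac`
#' consistency are called. Fractions use comparisons where the gene is
#' non-missing; ties in consistency are broken by average percentile.
#'
#' @param m percentile matrix.
#' @param scope comparison ids.
#' @param direction "up" or "down".
#' @param top_frac top fraction defining extreme regulation (default 0.10).
#' @param min_frac minimum consistency fraction (e.g. 0.5); 0 returns all
#'   genes ranked.
#' @return data.frame (gene_id, n_obs, consistency, avg_pct) of called genes
#'   sorted by consistency then |average percentile|, descending.
#' @export
consensus_targets <- function(m, scope = colnames(m),
                              direction = c("up", "down"),
                              top_frac = 0.10, min_frac = 0.5) {
  direction <- match.arg(direction)
  scope <- .check_scope(m, scope)
  sub <- m[, scope, drop = FALSE]
  thr <- 100 * (1 - top_frac)
  n <- rowSums(!is.na(sub))
  hit <- if (direction == "up") rowSums(sub >= thr, na.rm = TRUE)
         else rowSums(sub <= -thr, na.rm = TRUE)
  cons <- ifelse(n > 0, hit / n, NA_real_)
  avg <- average_percentile(m[, scope, drop = FALSE])
  keep <- !is.na(cons) & cons >= min_frac
  df <- data.frame(gene_id = rownames(sub)[keep], n_obs = n[keep],
                   consistency = cons[keep], avg_pct = avg[keep],
                   row.names = NULL)
  sgn <- if (direction == "up") 1 else -1
  df[order(-df$consistency, -sgn * df$avg_pct), , drop = FALSE]
}

#' Ligand-dependence gating of model-vs-E2 averages
#'
#' Splits genes by their average percentile in a resistance-model condition
#' versus estrogen treatment: ligand-independent up (both above `high_cut`),
#' ligand-independent down (both below -`high_cut`), and de novo (model
#' average above `high_cut` while the E2 average sits inside the null band
#' [-null_band, +null_band]).
#'
#' @param avg_model,avg_e2 named average-percentile vectors.
#' @param high_cut activation/repression cut (default 50; the alternative 40
#'   is also in circulation for this gate).
#' @param null_band half-width of the E2 null band (default 15).
#' @return named list of gene_call_set: ligand_up, ligand_down, de_novo.
#' @export
ligand_dependence_gate <- function(avg_model, avg_e2, high_cut = 50,
                                   null_band = 15) {
  if (high_cut <= null_band)
    stop("high_cut must exceed null_band", call. = FALSE)
  genes <- intersect(names(avg_model), names(avg_e2))
  mo <- avg_model[genes]; e2 <- avg_e2[genes]
  ok <- !is.na(mo) & !is.na(e2)
  mo <- mo[ok]; e2 <- e2[ok]; genes <- genes[ok]
  p <- list(high_cut = high_cut, null_band = null_band)
  list(
    ligand_up   = .call_set("ligand_up", genes[mo > high_cut & e2 > high_cut], p),
    ligand_down = .call_set("ligand_down",
                            genes[mo < -high_cut & e2 < -high_cut], p),
    de_novo     = .call_set("de_novo",
                            genes[mo > high_cut & abs(e2) <= null_band], p))
}

#' Per-gene mixed-effect regression on experimental covariates
#'
#' Models one gene's regulatory percentile across comparisons as
#' percentile ~ cell_line + modality + compound_class * duration_h with a
#' random intercept per batch_id, each comparison one observation. Duration
#' enters as a continuous covariate in hours, centered at the mean observed
#' duration so the drug main effect is reported at a representative
#' duration rather than extrapolated to 0 h. Categorical terms reduced to a
#' single level are dropped with a warning; if no random-effect structure
#' survives (single batch) an ordinary linear model is fitted instead.
#' Non-convergence and singular fits are flagged, not raised.
#'
#' @param y named percentile vector for one gene (names = comparison ids).
#' @param metas metadata data.frame from [read_metadata()].
#' @param min_obs minimum observations (default 10).
#' @return list with `coef` (named vector), `p` (named vector of two-sided
#'   p-values per fixed term), `converged`, `singular`, `degenerate`,
#'   `n_obs`.
#' @export
fit_gene_mixed_model <- function(y, metas, min_obs = 10) {
  ids <- intersect(names(y)[!is.na(y)], metas$comparison_id)
  if (length(ids) < min_obs)
    stop("need at least ", min_obs, " observations", call. = FALSE)
  md <- metas[match(ids, metas$comparison_id), , drop = FALSE]
  dur <- as.numeric(md$duration_h)
  dat <- data.frame(pct = as.numeric(y[ids]),
                    cell_line = factor(md$cell_line),
                    modality = factor(md$modality),
                    drug = factor(md$compound_class),
                    # centered so the drug main effect is evaluated at the
                    # average treatment duration, not extrapolated to 0 h
                    duration = dur - mean(dur, na.rm = TRUE),
                    batch = factor(md$batch_id))
  empty <- list(coef = numeric(0), p = numeric(0), converged = FALSE,
                singular = TRUE, degenerate = TRUE, n_obs = nrow(dat))
  if (stats::sd(dat$pct) == 0) {
    res <- empty
    res$coef <- c(`(Intercept)` = dat$pct[1])
    res$p <- c(`(Intercept)` = NA_real_)
    return(res)
  }
  terms <- c("cell_line", "modality", "drug")
  keep <- terms[vapply(terms, function(t) nlevels(droplevels(dat[[t]])) > 1,
                       logical(1))]
  dropped <- setdiff(terms, keep)
  if (length(dropped) > 0)
    warning("term(s) with a single level dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  has_dur <- !anyNA(dat$duration) && stats::sd(dat$duration) > 0
  rhs <- keep
  if (has_dur) {
    rhs <- c(rhs, if ("drug" %in% keep) "drug * duration" else "duration")
    rhs <- setdiff(rhs, if ("drug" %in% keep) "drug" else character(0))
  }
  if (length(rhs) == 0) rhs <- "1"
  use_lmm <- nlevels(droplevels(dat$batch)) > 1
  fixed <- paste(rhs, collapse = " + ")

  fit <- tryCatch({
    if (use_lmm) {
      fo <- stats::as.formula(paste("pct ~", fixed, "+ (1 | batch)"))
      suppressMessages(lmerTest::lmer(fo, data = dat,
                                      control = lme4::lmerControl(
                                        check.conv.singular = "ignore")))
    } else {
      stats::lm(stats::as.formula(paste("pct ~", fixed)), data = dat)
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(empty)

  if (use_lmm) {
    ct <- stats::coef(summary(fit))
    singular <- lme4::isSingular(fit)
    conv <- length(fit@optinfo$conv$lme4$messages) == 0
  } else {
    ct <- stats::coef(summary(fit))
    singular <- any(is.na(stats::coef(fit)))
    conv <- TRUE
  }
  pcol <- grep("^Pr", colnames(ct))
  list(coef = ct[, "Estimate"],
       p = stats::setNames(ct[, pcol], rownames(ct)),
       converged = conv, singular = singular, degenerate = FALSE,
       n_obs = nrow(dat))
}

#' Genes with a similar regulation pattern to a query gene
#'
#' Pearson correlation of the query gene's percentile profile against every
#' other gene over the scoped comparisons (pairwise-complete), ranked by r
#' descending, with two-sided correlation-test p-values and BH adjustment.
#'
#' @param m percentile matrix.
#' @param query_gene gene id present in the matrix.
#' @param scope comparison ids (default all).
#' @param r_cut optional minimum |r| filter applied after ranking (default
#'   NULL = no filter).
#' @param min_shared minimum pairwise-complete comparisons per candidate
#'   (default 3).
#' @return data.frame (gene_id, r, n, p, padj) sorted by r descending.
#' @export
similar_genes <- function(m, query_gene, scope = colnames(m), r_cut = NULL,
                          min_shared = 3) {
  scope <- .check_scope(m, scope)
  if (!query_gene %in% rownames(m))
    stop("query gene not in matrix: ", query_gene, call. = FALSE)
  q <- m[query_gene, scope]
  if (sum(!is.na(q)) < 3)
    stop("query gene has fewer than 3 non-missing values", call. = FALSE)
  others <- setdiff(rownames(m), query_gene)
  sub <- m[others, scope, drop = FALSE]
  res <- lapply(others, function(g) {
    ok <- !is.na(q) & !is.na(sub[g, ])
    n <- sum(ok)
    if (n < min_shared) return(c(NA_real_, n, NA_real_))
    x <- q[ok]; y <- sub[g, ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(c(NA_real_, n, NA_real_))
    ct <- stats::cor.test(x, y, alternative = "two.sided")
    c(unname(ct$estimate), n, ct$p.value)
  })
  res <- do.call(rbind, res)
  df <- data.frame(gene_id = others, r = res[, 1], n = res[, 2],
                   p = res[, 3], row.names = NULL)
  df <- df[!is.na(df$r), , drop = FALSE]
  df$padj <- stats::p.adjust(df$p, method = "BH")
  df <- df[order(-df$r), , drop = FALSE]
  if (!is.null(r_cut)) df <- df[abs(df$r) >= r_cut, , drop = FALSE]
  df
}

#' Exact multi-set intersection regions
#'
#' For k named sets, enumerates every membership pattern (Venn region) with
#' its element count and members, in deterministic order.
#'
#' @param sets named list of >= 2 character vectors.
#' @return list with `membership` (logical data.frame, one row per element)
#'   and `regions` (data.frame of pattern, count), both ordered
#'   deterministically.
#' @export
intersect_sets <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named", call. = FALSE)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  mem <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) mem <- matrix(mem, nrow = 1,
                                           dimnames = list(NULL, names(sets)))
  membership <- data.frame(element = universe, mem, check.names = FALSE)
  pattern <- apply(mem, 1, function(r) paste(names(sets)[r], collapse = "&"))
  counts <- table(pattern)
  regions <- data.frame(pattern = names(counts),
                        count = as.integer(counts), row.names = NULL)
  regions <- regions[order(regions$pattern), , drop = FALSE]
  list(membership = membership, regions = regions)
}
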