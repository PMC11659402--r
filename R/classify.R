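#' Integrated activation-minus-repression signature score
#'
#' Per-sample integrated enrichment score: the single-sample score of the
#' activation set minus the single-sample score of the repression set (see
#' [single_sample_score()]).
#'
#' @param expr expression matrix, genes x samples.
#' @param up_set,down_set character vectors of gene ids.
#' @param min_genes minimum set genes present per set (default 5).
#' @return named numeric vector of per-sample integrated scores.
#' @export
integrated_score <- function(expr, up_set, down_set, min_genes = 5) {
  single_sample_score(expr, up_set, min_genes) -
    single_sample_score(expr, down_set, min_genes)
}

#' Univariate logistic fit and empirical ROC/AUC
#'
#' Maximum-likelihood logistic regression of a binary label on a single
#' score, with an empirical ROC curve over score thresholds and the
#' tie-corrected rank (Mann-Whitney) AUC. Perfect separation flags the fit
#' but the rank-based ROC and AUC are still returned.
#'
#' @param scores numeric vector.
#' @param labels binary vector (logical, 0/1, or 2-level factor); the
#'   positive class is `TRUE`, `1`, or the second factor level.
#' @param min_per_class minimum samples per class (default 5).
#' @return list with `coef` (intercept, slope), `separation_flag`, `roc`
#'   (data.frame fpr/tpr/threshold), and `auc`.
#' @export
fit_logistic_roc <- function(scores, labels, min_per_class = 5) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L
       else as.integer(as.logical(labels))
  if (anyNA(y) || anyNA(scores)) stop("missing scores or labels",
                                      call. = FALSE)
  if (min(table(y)) < min_per_class)
    stop("need at least ", min_per_class, " samples per class", call. = FALSE)

  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ scores, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  sep <- sep_warn || !fit$converged

  # empirical ROC over the distinct score thresholds (predict positive when
  # score >= threshold), anchored at (0,0) and (1,1)
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n_neg, numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))

  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  list(coef = stats::coef(fit), separation_flag = sep, roc = roc, auc = auc)
}

#' Trapezoidal area under an ROC curve
#'
#' @param roc data.frame with fpr and tpr columns ordered along the curve.
#' @return numeric AUC.
#' @export
roc_auc_trapezoid <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
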