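#' Regulatory percentile transform of one comparison
#'
#' Rank-scales per-gene fold changes into regulatory percentiles in
#' [-100, +100]: genes with positive log2fc are ranked within the up pool and
#' mapped to (0, 100] (rank / pool size x 100, the most up-regulated gene
#' hitting +100 exactly); negative genes are ranked by magnitude within the
#' down pool and mapped to [-100, 0); zero fold change maps to 0. Ties take
#' the mean of tied ranks.
#'
#' An alternative linear scaling of the raw fold change itself (most extreme
#' values pinned to +/-100) is available via `scale = "fc"`; rank scaling is
#' the default because it matches percentile semantics and is robust across
#' sequencing modalities.
#'
#' @param de DE table (gene_id, log2fc) or named numeric vector of log2fc.
#' @param scale "rank" (default) or "fc".
#' @return named numeric vector of percentiles in [-100, 100].
#' @export
percentile_rank <- function(de, scale = c("rank", "fc")) {
  scale <- match.arg(scale)
  if (is.data.frame(de)) {
    de <- validate_de_table(de)
    fc <- stats::setNames(de$log2fc, de$gene_id)
  } else {
    fc <- de
    if (is.null(names(fc))) stop("log2fc vector must be named", call. = FALSE)
  }
  if (length(fc) == 0) stop("empty table", call. = FALSE)
  if (any(!is.finite(fc)))
    stop("non-finite log2fc for gene(s): ",
         paste(utils::head(names(fc)[!is.finite(fc)], 5), collapse = ", "),
         call. = FALSE)
  out <- numeric(length(fc))
  names(out) <- names(fc)
  if (scale == "fc") {
    up <- fc > 0; dn <- fc < 0
    if (any(up)) out[up] <- 100 * fc[up] / max(fc[up])
    if (any(dn)) out[dn] <- -100 * fc[dn] / min(fc[dn])
    return(out)
  }
  up <- which(fc > 0)
  dn <- which(fc < 0)
  if (length(up) > 0) out[up] <- 100 * rank(fc[up]) / length(up)
  if (length(dn) > 0) out[dn] <- -100 * rank(-fc[dn]) / length(dn)
  out
}

#' Assemble a percentile matrix from per-comparison columns
#'
#' Takes named percentile vectors (one per comparison) and builds the
#' genes x comparisons matrix on the union of gene ids; a gene absent from a
#' comparison is missing (NA), never zero.
#'
#' @param columns named list of percentile vectors (names = comparison ids).
#' @param metas optional metadata data.frame; when given, every column id
#'   must appear in `metas$comparison_id`.
#' @return numeric matrix with gene rownames and comparison colnames.
#' @export
build_matrix <- function(columns, metas = NULL) {
  ids <- names(columns)
  if (length(columns) == 0)
    return(matrix(numeric(0), nrow = 0, ncol = 0))
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every column must be named by its comparison id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate comparison id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (!is.null(metas)) {
    unknown <- setdiff(ids, metas$comparison_id)
    if (length(unknown) > 0)
      stop("comparison id(s) missing from metadata: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  genes <- sort(unique(unlist(lapply(columns, names), use.names = FALSE)))
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(columns),
              dimnames = list(genes, ids))
  for (j in seq_along(columns)) m[names(columns[[j]]), j] <- columns[[j]]
  rng <- range(m, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < -100 || rng[2] > 100))
    stop("percentile values outside [-100, 100]", call. = FALSE)
  m
}

#' Presence filter across comparisons
#'
#' Drops genes observed in fewer than `min_frac` of the scoped comparisons
#' (genes present in exactly the boundary fraction are retained).
#'
#' @param m percentile matrix.
#' @param min_frac minimum fraction of scoped comparisons, in (0, 1];
#'   default 0.8.
#' @param scope comparison ids to consider (default: all columns).
#' @return the matrix restricted to retained genes (all columns kept).
#' @export
presence_filter <- function(m, min_frac = 0.8, scope = colnames(m)) {
  if (!(min_frac > 0 && min_frac <= 1)) stop("min_frac must be in (0, 1]",
                                             call. = FALSE)
  scope <- .check_scope(m, scope)
  frac <- rowMeans(!is.na(m[, scope, drop = FALSE]))
  m[frac >= min_frac, , drop = FALSE]
}

#' Average regulatory percentile over a scope
#'
#' Per-gene mean of non-missing percentiles over the scoped comparisons;
#' genes with no scoped observation are NA.
#'
#' @param m percentile matrix.
#' @param scope comparison ids (default: all).
#' @return named numeric vector, one value per gene (NA allowed).
#' @export
average_percentile <- function(m, scope = colnames(m)) {
  scope <- .check_scope(m, scope)
  rowMeans(m[, scope, drop = FALSE], na.rm = TRUE) |> .nan_to_na()
}

.nan_to_na <- function(x) { x[is.nan(x)] <- NA_real_; x }

.check_scope <- function(m, scope) {
  if (length(scope) == 0) stop("empty scope", call. = FALSE)
  unknown <- setdiff(scope, colnames(m))
  if (length(unknown) > 0)
    stop("scope id(s) not in matrix: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  scope
}

#' Read / write a percentile matrix as TSV
#'
#' Genes x comparisons, first column `gene_id`, "NA" for missing.
#'
#' @param m percentile matrix.
#' @param path TSV path.
#' @export
write_percentile_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_percentile_matrix
#' @export
read_percentile_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}
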