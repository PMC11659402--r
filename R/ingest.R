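# Enumerations used by the metadata registry. Values are matched
# case-insensitively on ingestion and stored in canonical form.
.sections <- c("E2", "modulator", "TamR", "LTED", "ESR1mut")
.compound_classes <- c("SERM", "SERD", "hybrid", "SERCA", "LDD",
                       "SERD_analog", "siRNA", "none")
.modalities <- c("RNAseq", "microarray")
.constructions <- c("GE", "OE", "natural", "none")
.resistance_sections <- c("TamR", "LTED", "ESR1mut")

.match_enum <- function(x, levels, field) {
  hit <- match(tolower(x), tolower(levels))
  if (anyNA(hit & !is.na(x))) {
    bad <- unique(x[is.na(hit) & !is.na(x)])
    stop("invalid value(s) for ", field, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- levels[hit]
  out
}

#' Parse a dose string into nanomolar units
#'
#' Accepts numbers with units nM, nmol/L, uM, μM, umol/L, μmol/L
#' (case-insensitive); bare numbers are taken as nM. Unparseable strings give
#' NA with a warning.
#'
#' @param x character or numeric vector of doses.
#' @return numeric vector of doses in nM (NA where unparseable).
#' @export
parse_dose_nM <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    s <- trimws(x[i])
    if (is.na(s) || s == "" || toupper(s) == "NA") next
    m <- regmatches(s, regexec(
      "^([0-9]*\\.?[0-9]+)\\s*(nM|nmol/L|uM|μM|umol/L|μmol/L|)$",
      s, ignore.case = TRUE))[[1]]
    if (length(m) == 0) {
      warning("unparseable dose '", s, "' set to NA", call. = FALSE)
      next
    }
    val <- as.numeric(m[2])
    unit <- tolower(m[3])
    if (unit %in% c("um", "μm", "umol/l", "μmol/l")) val <- val * 1000
    out[i] <- val
  }
  out
}

#' Read the experiment metadata registry
#'
#' Reads a CSV with one row per harmonized comparison (treated vs control
#' contrast). Required columns: comparison_id, section, cell_line, modality,
#' batch_id. Optional: compound, compound_class, dose_nM, duration_h, variant,
#' construction. Enum columns are normalized case-insensitively; doses are
#' converted to nM with [parse_dose_nM()].
#'
#' For short-term treatment sections (E2, modulator) tamoxifen records whose
#' compound string does not distinguish tamoxifen from 4-hydroxytamoxifen are
#' flagged in the `tamoxifen_unspecified` column, since pooled analyses mix
#' both compounds.
#'
#' @param path path to the metadata CSV (header required).
#' @return data.frame of validated comparison metadata, one row per
#'   comparison.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("comparison_id", "section", "cell_line", "modality", "batch_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  dup <- unique(df$comparison_id[duplicated(df$comparison_id)])
  if (length(dup) > 0)
    stop("duplicate comparison_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(trimws(as.character(df$batch_id)))))
    stop("batch_id must be non-empty for every comparison", call. = FALSE)

  df$section <- .match_enum(df$section, .sections, "section")
  df$modality <- .match_enum(df$modality, .modalities, "modality")
  if (!"compound" %in% names(df)) df$compound <- NA_character_
  if ("compound_class" %in% names(df)) {
    filled <- !is.na(df$compound_class) & nzchar(df$compound_class)
    df$compound_class[!filled] <- "none"
    df$compound_class <- .match_enum(df$compound_class, .compound_classes,
                                     "compound_class")
  } else df$compound_class <- "none"
  df$dose_nM <- if ("dose_nM" %in% names(df)) parse_dose_nM(df$dose_nM) else NA_real_
  df$duration_h <- if ("duration_h" %in% names(df))
    suppressWarnings(as.numeric(df$duration_h)) else NA_real_
  if (!"variant" %in% names(df)) df$variant <- NA_character_
  if ("construction" %in% names(df)) {
    filled <- !is.na(df$construction) & nzchar(df$construction)
    df$construction[!filled] <- "none"
    df$construction <- .match_enum(df$construction, .constructions,
                                   "construction")
  } else df$construction <- "none"

  resist <- df$section %in% .resistance_sections
  if (any((is.na(df$dose_nM) | is.na(df$duration_h)) & !resist))
    stop("dose_nM and duration_h may be missing only for resistance-model ",
         "sections (TamR, LTED, ESR1mut)", call. = FALSE)
  neg <- !is.na(df$dose_nM) & df$dose_nM < 0
  if (any(neg)) stop("negative dose_nM", call. = FALSE)

  df$tamoxifen_unspecified <- grepl("^tam", tolower(ifelse(is.na(df$compound),
                                                           "", df$compound))) &
    !grepl("4.?oht|hydroxy", tolower(ifelse(is.na(df$compound), "", df$compound)))
  df
}

#' Read / write a per-comparison differential-expression table
#'
#' Three-column TSV: gene_id, log2fc, padj ("NA" allowed for padj).
#'
#' @param path TSV path.
#' @return data.frame with columns gene_id, log2fc, padj.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_de_table(df)
}

#' @rdname read_de_table
#' @param de a differential-expression data.frame.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de[, c("gene_id", "log2fc", "padj")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a differential-expression table
#'
#' Checks gene_id uniqueness, finite log2fc, padj in [0,1] or NA.
#'
#' @param de data.frame with gene_id, log2fc and optionally padj.
#' @return the validated data.frame (padj column added as NA if absent).
#' @export
validate_de_table <- function(de) {
  stopifnot(is.data.frame(de))
  if (!all(c("gene_id", "log2fc") %in% names(de)))
    stop("DE table needs columns gene_id and log2fc", call. = FALSE)
  if (!"padj" %in% names(de)) de[["padj"]] <- rep(NA_real_, nrow(de))
  dup <- unique(de$gene_id[duplicated(de$gene_id)])
  if (length(dup) > 0)
    stop("duplicate gene_id(s) in DE table: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  if (any(!is.finite(de$log2fc)))
    stop("non-finite log2fc for gene(s): ",
         paste(utils::head(de$gene_id[!is.finite(de$log2fc)], 5),
               collapse = ", "), call. = FALSE)
  bad <- !is.na(de$padj) & (de$padj < 0 | de$padj > 1)
  if (any(bad)) stop("padj outside [0,1]", call. = FALSE)
  de[, c("gene_id", "log2fc", "padj")]
}

#' Trimmed mean of M-values (TMM) scale factors
#'
#' Computes per-sample normalization factors by the trimmed mean of M-values
#' method: for each sample against a reference, gene-wise log ratios (M) and
#' average log abundances (A) are computed on library-size-scaled counts,
#' the upper and lower tails of both are trimmed, and the factor is the
#' weighted mean of the surviving M values (inverse asymptotic-variance
#' weights). Factors are renormalized so their geometric mean is 1. Genes
#' with zero counts in every sample are dropped first.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param trim_M fraction of M values trimmed from each tail (default 0.3).
#' @param trim_A fraction of A values trimmed from each tail (default 0.05).
#' @param ref reference sample (index or name); default is the sample whose
#'   upper-quartile count (of nonzero counts, scaled by library size) is
#'   closest to the mean upper quartile.
#' @return numeric vector of positive factors, one per sample, geometric
#'   mean 1.
#' @export
tmm_factors <- function(counts, trim_M = 0.3, trim_A = 0.05, ref = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("all-zero sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  lib <- colSums(counts)

  if (is.null(ref)) {
    uq <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
    ref <- which.min(abs(uq - mean(uq)))
  } else if (is.character(ref)) ref <- match(ref, colnames(counts))

  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_M, trim_A)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# One pairwise TMM factor (obs vs ref), on the 2^weighted-trimmed-mean scale.
.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_M, trim_A) {
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  M <- log2(p_obs[keep] / p_ref[keep])
  A <- (log2(p_obs[keep]) + log2(p_ref[keep])) / 2
  w <- (n_obs - obs[keep]) / (n_obs * obs[keep]) +
       (n_ref - ref[keep]) / (n_ref * ref[keep])
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_M) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1
  hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep2) || all(w[keep2] == 0)) return(1)
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' Fold changes from counts by TMM-normalized log2(CPM + 1)
#'
#' Fallback differential-expression path for experiments without replicates:
#' counts are converted to CPM on TMM-scaled library sizes, log2(CPM + 1) is
#' averaged within the control and treated groups, and the per-gene fold
#' change is the treated minus control mean. Genes with zero counts in every
#' sample are removed first; adjusted p-values are not available on this
#' path (padj = NA).
#'
#' @param counts non-negative integer matrix, genes x samples, with rownames.
#' @param groups character/factor per sample, values "control"/"treated".
#' @param trim_M,trim_A TMM trim fractions, see [tmm_factors()].
#' @return a DE table (gene_id, log2fc, padj = NA).
#' @export
log2cpm_fold_change <- function(counts, groups, trim_M = 0.3, trim_A = 0.05) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  if (length(groups) != ncol(counts))
    stop("groups length must match number of samples", call. = FALSE)
  if (!all(groups %in% c("control", "treated")))
    stop("groups must be 'control' or 'treated'", call. = FALSE)
  if (sum(groups == "control") == 0 || sum(groups == "treated") == 0)
    stop("need at least one control and one treated sample", call. = FALSE)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (nrow(counts) == 0) stop("no expressed genes", call. = FALSE)
  f <- tmm_factors(counts, trim_M, trim_A)
  eff_lib <- colSums(counts) * f
  cpm <- sweep(counts, 2, eff_lib / 1e6, "/")
  lg <- log2(cpm + 1)
  fc <- rowMeans(lg[, groups == "treated", drop = FALSE]) -
        rowMeans(lg[, groups == "control", drop = FALSE])
  data.frame(gene_id = rownames(counts), log2fc = unname(fc),
             padj = NA_real_, stringsAsFactors = FALSE)
}
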