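#' Read / write a peak set (BED 3-6 dialect)
#'
#' Tab-separated BED with 0-based half-open coordinates: chrom, start, end,
#' and optionally name, score, strand. Intervals are validated (start < end)
#' and sorted within chromosome on read.
#'
#' @param path BED path (no header).
#' @return data.frame (chrom, start, end, and any of name, score, strand)
#'   sorted by chrom then start.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(ncol(df))]
  validate_peaks(df)
}

#' @rdname read_bed
#' @param peaks a peak data.frame.
#' @export
write_bed <- function(peaks, path) {
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(peaks))
  utils::write.table(peaks[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate and normalize a peak set
#'
#' @param peaks data.frame with chrom, start, end (0-based half-open).
#' @return the peaks sorted by chromosome then start.
#' @export
validate_peaks <- function(peaks) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  peaks$start <- as.numeric(peaks$start)
  peaks$end <- as.numeric(peaks$end)
  bad <- which(!is.finite(peaks$start) | !is.finite(peaks$end) |
                 peaks$start < 0 | peaks$start >= peaks$end)
  if (length(bad) > 0)
    stop("malformed interval at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
}

.peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
}

#' Gained peaks: case peaks absent from a control set
#'
#' Returns the case peaks that overlap no control peak by at least
#' `min_overlap_bp` shared bases (both sets 0-based half-open).
#'
#' @param case,control peak data.frames.
#' @param min_overlap_bp minimum shared bases counting as overlap
#'   (default 1).
#' @return the gained subset of `case`, sorted.
#' @export
gained_peaks <- function(case, control, min_overlap_bp = 1) {
  case <- validate_peaks(case)
  if (nrow(case) == 0) return(case)
  if (is.null(control) || nrow(control) == 0) return(case)
  control <- validate_peaks(control)
  hits <- GenomicRanges::countOverlaps(.peaks_to_granges(case),
                                       .peaks_to_granges(control),
                                       minoverlap = min_overlap_bp)
  case[hits == 0, , drop = FALSE]
}

#' Read / write a TSS gene annotation table
#'
#' TSV with columns gene_id, chrom, tss, strand (one TSS per gene).
#'
#' @param path annotation TSV path (header required).
#' @return validated data.frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotation(ann)
}

#' @rdname read_annotation
#' @param ann annotation data.frame.
#' @export
validate_annotation <- function(ann) {
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(ann)))
  if (anyDuplicated(ann$gene_id))
    stop("more than one TSS for gene(s): ",
         paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "),
         call. = FALSE)
  if (any(ann$tss < 0)) stop("negative TSS position", call. = FALSE)
  if (!all(ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  ann
}

#' TSS-window regulatory potential of a peak set
#'
#' Per-gene regulatory potential: the sum over peaks whose midpoint lies
#' within +/- `window_bp` of the gene's TSS of a distance-decayed weight
#' w(d) = exp(-(0.5 + 4 d)) with d = |midpoint - TSS| / window_bp, so a peak
#' centered on the TSS contributes exp(-0.5) and a peak at the window edge
#' contributes exp(-4.5); peaks beyond the window contribute nothing.
#' Alternative kernels: "linear" (1 - d) and "flat" (1 inside the window).
#'
#' @param peaks peak data.frame.
#' @param ann TSS annotation data.frame (gene_id, chrom, tss, strand).
#' @param window_bp half-window around the TSS in bp (default 1e5).
#' @param kernel "exp" (default), "linear", or "flat".
#' @return named numeric vector of scores, one per annotated gene (0 when no
#'   peak is in the window). Peaks on chromosomes absent from the annotation
#'   are skipped; their count is reported in the `skipped_peaks` attribute.
#' @export
regulatory_potential <- function(peaks, ann, window_bp = 1e5,
                                 kernel = c("exp", "linear", "flat")) {
  kernel <- match.arg(kernel)
  if (window_bp <= 0) stop("window_bp must be positive", call. = FALSE)
  peaks <- validate_peaks(peaks)
  ann <- validate_annotation(ann)
  centers <- (peaks$start + peaks$end) / 2
  known <- peaks$chrom %in% unique(ann$chrom)
  scores <- stats::setNames(numeric(nrow(ann)), ann$gene_id)
  for (i in seq_len(nrow(ann))) {
    on_chr <- which(peaks$chrom == ann$chrom[i] & known)
    if (length(on_chr) == 0) next
    d <- abs(centers[on_chr] - ann$tss[i]) / window_bp
    d <- d[d <= 1]
    if (length(d) == 0) next
    w <- switch(kernel,
                exp = exp(-(0.5 + 4 * d)),
                linear = 1 - d,
                flat = rep(1, length(d)))
    scores[i] <- sum(w)
  }
  attr(scores, "skipped_peaks") <- sum(!known)
  scores
}

#' Average regulatory-potential score across peak sets
#'
#' Per-gene mean over the tables in which the gene is scored (a gene absent
#' from a table does not enter that table's denominator).
#'
#' @param score_tables list of named numeric vectors from
#'   [regulatory_potential()].
#' @return named numeric vector of per-gene means.
#' @export
average_score <- function(score_tables) {
  if (length(score_tables) == 0) stop("need at least 1 score table",
                                      call. = FALSE)
  genes <- sort(unique(unlist(lapply(score_tables, names))))
  acc <- stats::setNames(numeric(length(genes)), genes)
  cnt <- stats::setNames(integer(length(genes)), genes)
  for (tab in score_tables) {
    acc[names(tab)] <- acc[names(tab)] + tab
    cnt[names(tab)] <- cnt[names(tab)] + 1L
  }
  acc / cnt
}

#' Peaks around a gene's TSS with strand-aware offsets
#'
#' Lists the peaks whose midpoint falls within +/- `window_bp` of the gene's
#' TSS, with signed offsets (negative = upstream of the TSS in the gene's
#' orientation, i.e. the sign flips on the minus strand) and the full peak
#' coordinates.
#'
#' @param peaks peak data.frame (optionally with a score column used as
#'   intensity).
#' @param gene gene id present in the annotation.
#' @param ann TSS annotation data.frame.
#' @param window_bp half-window (default 2e5).
#' @return data.frame (chrom, start, end, center, offset, intensity), empty
#'   when no peak is in the window.
#' @export
tss_window_peaks <- function(peaks, gene, ann, window_bp = 2e5) {
  ann <- validate_annotation(ann)
  row <- ann[ann$gene_id == gene, , drop = FALSE]
  if (nrow(row) == 0) stop("unknown gene: ", gene, call. = FALSE)
  peaks <- validate_peaks(peaks)
  centers <- (peaks$start + peaks$end) / 2
  sel <- peaks$chrom == row$chrom & abs(centers - row$tss) <= window_bp
  hit <- peaks[sel, , drop = FALSE]
  center <- centers[sel]
  offset <- center - row$tss
  if (row$strand == "-") offset <- -offset
  data.frame(chrom = hit$chrom, start = hit$start, end = hit$end,
             center = center, offset = offset,
             intensity = if ("score" %in% names(hit)) hit$score
                         else rep(NA_real_, nrow(hit)),
             row.names = NULL)
}
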