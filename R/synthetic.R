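#' Deterministic child seed from a master seed
#'
#' One master seed fans out to independent per-artifact streams:
#' child = (master x 7919 + k x 104729) mod (2^31 - 1), with k the artifact
#' index. The rule is fixed so a dataset is fully reproducible from the
#' master seed alone.
#'
#' @param master master seed (integer).
#' @param k artifact index (integer >= 0).
#' @return integer child seed in [1, 2^31 - 2].
#' @export
child_seed <- function(master, k) {
  as.integer((as.numeric(master) %% 2147483647 * 7919 +
                as.numeric(k) * 104729) %% 2147483646 + 1)
}

.default_classes <- c(SERM = -1, SERD = -1.5)

#' Simulate a collection of differential-expression comparisons
#'
#' Generates per-comparison DE tables with a known regulatory structure
#' emulating a curated ER-modulator experiment registry: a core ER-response
#' program (up- and down-regulated gene sets scaled by a per-class effect
#' multiplier), bidirectionally regulated genes whose strong effect flips
#' sign across comparisons, cell-line-cluster effects, a dose term, batch
#' draws, and i.i.d. noise:
#'
#' log2fc = class_mult x loading + cellline_effect +
#'          dose_coef x log10(dose/100) x loading + batch_draw + N(0, sd)
#'
#' Bidirectional genes carry their own effect (independent of drug class):
#' +effect in exactly `round(bid_up_frac x n)` comparisons, -effect in
#' exactly `round(bid_down_frac x n)` others, 0 elsewhere. Microarray
#' comparisons observe a random subset of the gene universe to emulate
#' platform differences. Effect sizes are on the log2 fold-change scale
#' (percentiles are a pipeline output, not an input). Deterministic given
#' the seed.
#'
#' @param n_genes number of genes (>= 200; default 2000).
#' @param n_comparisons number of comparisons (default 40).
#' @param frac_up,frac_down,frac_bidirectional role fractions (defaults
#'   0.03, 0.03, 0.02; must sum to <= 1).
#' @param effect_size core-program |loading| location on the log2fc scale
#'   (default 3; per-gene loadings are jittered by U(0.8, 1.2)).
#' @param bid_effect bidirectional effect magnitude (default = effect_size).
#' @param bid_up_frac,bid_down_frac fractions of comparisons in which a
#'   bidirectional gene is actively up / down (defaults 0.3 / 0.2).
#' @param classes named numeric vector of per-compound-class effect
#'   multipliers (default SERM -1, SERD -1.5; positive multipliers emulate
#'   activating conditions such as ESR1-mutant models).
#' @param dose_coef dose-response coefficient (default 0.2); doses are drawn
#'   from 100 / 1000 nM.
#' @param n_cell_lines,n_clusters cell lines and response clusters
#'   (defaults 4 / 2); a per-gene, per-cluster effect N(0, cellline_sd)
#'   gives cell-line structure.
#' @param cellline_sd,batch_sd,noise_sd perturbation scales on log2fc
#'   (defaults 0.3, 0.2, 0.5).
#' @param n_batches number of batch ids (default 8).
#' @param array_frac fraction of comparisons assigned to the microarray
#'   modality (default 0.25).
#' @param array_coverage fraction of genes observed on an array comparison
#'   (default 0.9).
#' @param section section label for the metadata (default "modulator").
#' @param seed master seed.
#' @return list with `de_tables` (named list of DE data.frames), `metas`
#'   (metadata data.frame), and `truth` (role gene sets and the full design).
#' @export
generate_comparisons <- function(n_genes = 2000, n_comparisons = 40,
                                 frac_up = 0.03, frac_down = 0.03,
                                 frac_bidirectional = 0.02,
                                 effect_size = 3, bid_effect = effect_size,
                                 bid_up_frac = 0.3, bid_down_frac = 0.2,
                                 classes = .default_classes,
                                 dose_coef = 0.2,
                                 n_cell_lines = 4, n_clusters = 2,
                                 cellline_sd = 0.3, batch_sd = 0.2,
                                 noise_sd = 0.5, n_batches = 8,
                                 array_frac = 0.25, array_coverage = 0.9,
                                 section = "modulator", seed = 1) {
  if (n_genes < 200) stop("n_genes must be at least 200", call. = FALSE)
  if (frac_up + frac_down + frac_bidirectional > 1)
    stop("role fractions must sum to at most 1", call. = FALSE)
  if (bid_up_frac + bid_down_frac > 1)
    stop("bidirectional activity fractions must sum to at most 1",
         call. = FALSE)
  if (is.null(names(classes)) || length(classes) == 0)
    stop("classes must be a named numeric vector", call. = FALSE)

  genes <- sprintf("G%04d", seq_len(n_genes))
  n_up <- round(frac_up * n_genes)
  n_dn <- round(frac_down * n_genes)
  n_bid <- round(frac_bidirectional * n_genes)
  roles <- list(er_up = genes[seq_len(n_up)],
                er_down = genes[n_up + seq_len(n_dn)],
                bidirectional = genes[n_up + n_dn + seq_len(n_bid)])
  roles$null <- setdiff(genes, unlist(roles))

  withr_seed <- child_seed(seed, 1)
  set.seed(withr_seed)
  loading <- stats::setNames(numeric(n_genes), genes)
  loading[roles$er_up] <- effect_size * stats::runif(n_up, 0.8, 1.2)
  loading[roles$er_down] <- -effect_size * stats::runif(n_dn, 0.8, 1.2)

  # per-comparison design
  cls <- sample(names(classes), n_comparisons, replace = TRUE)
  cell_line <- sample(sprintf("CL%02d", seq_len(n_cell_lines)),
                      n_comparisons, replace = TRUE)
  cluster <- (match(cell_line, sprintf("CL%02d", seq_len(n_cell_lines))) - 1) %%
    n_clusters + 1
  dose <- sample(c(100, 1000), n_comparisons, replace = TRUE)
  duration <- sample(c(6, 24, 48), n_comparisons, replace = TRUE)
  modality <- ifelse(stats::runif(n_comparisons) < array_frac,
                     "microarray", "RNAseq")
  batch <- sample(sprintf("B%02d", seq_len(n_batches)), n_comparisons,
                  replace = TRUE)
  ids <- sprintf("C%03d", seq_len(n_comparisons))

  cl_eff <- matrix(stats::rnorm(n_genes * n_clusters, 0, cellline_sd),
                   n_genes, n_clusters, dimnames = list(genes, NULL))
  batch_eff <- matrix(stats::rnorm(n_genes * n_batches, 0, batch_sd),
                      n_genes, n_batches,
                      dimnames = list(genes, sprintf("B%02d",
                                                     seq_len(n_batches))))

  # exact-count bidirectional activity assignment
  n_bu <- round(bid_up_frac * n_comparisons)
  n_bd <- round(bid_down_frac * n_comparisons)
  bid_state <- matrix(0, n_bid, n_comparisons,
                      dimnames = list(roles$bidirectional, ids))
  for (g in seq_len(n_bid)) {
    pick <- sample.int(n_comparisons, n_bu + n_bd)
    bid_state[g, pick[seq_len(n_bu)]] <- 1
    bid_state[g, pick[n_bu + seq_len(n_bd)]] <- -1
  }

  de_tables <- vector("list", n_comparisons)
  names(de_tables) <- ids
  fc_design <- matrix(NA_real_, n_genes, n_comparisons,
                      dimnames = list(genes, ids))
  for (j in seq_len(n_comparisons)) {
    mult <- classes[[cls[j]]]
    fc <- mult * loading +
      cl_eff[, cluster[j]] +
      dose_coef * log10(dose[j] / 100) * mult * loading +
      batch_eff[, batch[j]] +
      stats::rnorm(n_genes, 0, noise_sd)
    if (n_bid > 0)
      fc[roles$bidirectional] <- fc[roles$bidirectional] +
        bid_state[, j] * bid_effect
    fc_design[, j] <- fc
    obs <- if (modality[j] == "microarray")
      sort(sample.int(n_genes, round(array_coverage * n_genes))) else
        seq_len(n_genes)
    de_tables[[j]] <- data.frame(gene_id = genes[obs],
                                 log2fc = unname(fc[obs]),
                                 padj = NA_real_, stringsAsFactors = FALSE)
  }

  # class labels land in the metadata field they belong to: drug classes in
  # compound_class, cell-engineering labels (GE/OE/natural) in construction
  con_labels <- c("GE", "OE", "natural")
  as_construction <- all(names(classes) %in% con_labels)
  metas <- data.frame(comparison_id = ids, section = section,
                      cell_line = cell_line,
                      compound = if (as_construction) NA_character_ else cls,
                      compound_class = if (as_construction) "none" else cls,
                      dose_nM = dose,
                      duration_h = duration, modality = modality,
                      batch_id = batch,
                      variant = if (as_construction)
                        sample(c("Y537S", "D538G"), n_comparisons,
                               replace = TRUE) else NA_character_,
                      construction = if (as_construction) cls else "none",
                      tamoxifen_unspecified = FALSE,
                      stringsAsFactors = FALSE)

  truth <- list(roles = roles, loading = loading, classes = classes,
                bid_state = bid_state, fc_design = fc_design,
                cluster = cluster, seed = seed,
                params = list(effect_size = effect_size,
                              bid_up_frac = bid_up_frac,
                              bid_down_frac = bid_down_frac,
                              noise_sd = noise_sd))
  list(de_tables = de_tables, metas = metas, truth = truth)
}

#' Simulate two drug classes with a designed effect-profile correlation
#'
#' Two compound classes perturb every gene with continuous Gaussian loadings
#' N(0, effect^2); a fraction `share` of genes carries identical loadings in
#' both classes, the rest are independent. Between the two class-average
#' log2fc profiles the design (population) Pearson correlation is
#' share x v / (v + noise_sd^2 / n_per_class) with v = effect^2 the
#' per-gene loading variance. The continuous loading distribution keeps the
#' rank-to-percentile transform close to affine, so the correlation of the
#' percentile profiles sits near the same value.
#'
#' @param n_genes genes (default 2000).
#' @param n_per_class comparisons per class (default 10).
#' @param share shared fraction of genes (default 0.5).
#' @param effect loading standard deviation (default 2).
#' @param noise_sd i.i.d. per-comparison noise sd (default 0.5).
#' @param seed master seed.
#' @return list with `de_tables`, `metas`, and `truth` (including
#'   `design_correlation`, the closed-form value above).
#' @export
generate_shared_effect_classes <- function(n_genes = 2000, n_per_class = 10,
                                           share = 0.5,
                                           effect = 2, noise_sd = 0.5,
                                           seed = 1) {
  set.seed(child_seed(seed, 2))
  genes <- sprintf("G%04d", seq_len(n_genes))
  n_shared <- round(share * n_genes)
  shared <- genes[seq_len(n_shared)]

  la <- stats::setNames(stats::rnorm(n_genes, 0, effect), genes)
  lb <- stats::setNames(stats::rnorm(n_genes, 0, effect), genes)
  lb[shared] <- la[shared]

  ids <- sprintf("C%03d", seq_len(2 * n_per_class))
  cls <- rep(c("classA", "classB"), each = n_per_class)
  de_tables <- vector("list", length(ids)); names(de_tables) <- ids
  for (j in seq_along(ids)) {
    lo <- if (cls[j] == "classA") la else lb
    fc <- lo + stats::rnorm(n_genes, 0, noise_sd)
    de_tables[[j]] <- data.frame(gene_id = genes, log2fc = unname(fc),
                                 padj = NA_real_, stringsAsFactors = FALSE)
  }
  metas <- data.frame(comparison_id = ids, section = "modulator",
                      cell_line = "CL01", compound = cls,
                      compound_class = "SERD", dose_nM = 100,
                      duration_h = 24, modality = "RNAseq",
                      batch_id = rep(sprintf("B%02d", seq_len(2)),
                                     each = n_per_class),
                      stringsAsFactors = FALSE)
  v <- effect^2
  rho <- share * v / (v + noise_sd^2 / n_per_class)
  list(de_tables = de_tables, metas = metas,
       truth = list(loading_a = la, loading_b = lb, share = share,
                    design_correlation = rho, seed = seed))
}

#' Simulate percentile responses for the per-gene regression stage
#'
#' Generates gene x comparison percentile-scale responses directly on a
#' given experimental design: for affected genes
#' y = drug_effect x I(class == reference class) + batch intercept +
#' N(0, noise_sd); unaffected genes omit the drug term. With drug_effect = 0
#' this is the null generator used for p-value calibration.
#'
#' @param metas metadata data.frame (uses compound_class and batch_id).
#' @param n_genes total genes (default 100).
#' @param n_affected genes carrying the drug effect (default n_genes / 2).
#' @param drug_effect percentile-scale effect of the second compound class
#'   (default 30).
#' @param noise_sd residual sd (default 10).
#' @param batch_sd batch random-intercept sd (default 5).
#' @param seed seed.
#' @return list with `y` (matrix genes x comparisons) and `truth`
#'   (affected gene ids and effect sign).
#' @export
simulate_percentile_response <- function(metas, n_genes = 100,
                                         n_affected = floor(n_genes / 2),
                                         drug_effect = 30, noise_sd = 10,
                                         batch_sd = 5, seed = 1) {
  set.seed(child_seed(seed, 3))
  n <- nrow(metas)
  genes <- sprintf("RG%04d", seq_len(n_genes))
  affected <- genes[seq_len(n_affected)]
  cls <- factor(metas$compound_class)
  if (nlevels(cls) < 2)
    stop("design needs at least two compound classes", call. = FALSE)
  indicator <- as.numeric(cls == levels(cls)[2])
  batches <- unique(metas$batch_id)
  y <- matrix(NA_real_, n_genes, n, dimnames = list(genes,
                                                    metas$comparison_id))
  for (g in seq_len(n_genes)) {
    b_int <- stats::setNames(stats::rnorm(length(batches), 0, batch_sd),
                             batches)
    mu <- b_int[metas$batch_id] +
      if (genes[g] %in% affected) drug_effect * indicator else 0
    y[g, ] <- mu + stats::rnorm(n, 0, noise_sd)
  }
  list(y = y, truth = list(affected = affected, drug_effect = drug_effect,
                           effect_term_level = levels(cls)[2]))
}

#' Simulate count matrices for the no-replicate fallback path
#'
#' Negative-binomial counts with gene-level dispersion: baseline relative
#' abundances are log-normal, library depths are Poisson around `depth`, and
#' treated-sample means are the control means scaled by 2^log2fc from the
#' supplied design.
#'
#' @param log2fc named numeric vector of designed per-gene log2 fold
#'   changes.
#' @param n_control,n_treated samples per group (default 1 / 1, the
#'   no-replicate case).
#' @param depth mean library depth (>= 1e5; default 1e6).
#' @param dispersion NB dispersion (size = 1/dispersion; default 0.05; 0
#'   gives Poisson).
#' @param seed seed.
#' @return list with `counts` (genes x samples), `groups`, and `truth`.
#' @export
generate_counts <- function(log2fc, n_control = 1, n_treated = 1,
                            depth = 1e6, dispersion = 0.05, seed = 1) {
  if (depth < 1e5) stop("mean depth must be at least 1e5", call. = FALSE)
  if (is.null(names(log2fc))) stop("log2fc must be named", call. = FALSE)
  set.seed(child_seed(seed, 4))
  n_genes <- length(log2fc)
  base <- exp(stats::rnorm(n_genes, 0, 1.2))
  base <- base / sum(base)
  groups <- c(rep("control", n_control), rep("treated", n_treated))
  counts <- matrix(0L, n_genes, length(groups),
                   dimnames = list(names(log2fc),
                                   paste0(groups, seq_along(groups))))
  for (s in seq_along(groups)) {
    rel <- if (groups[s] == "treated") base * 2^log2fc else base
    mu <- rel / sum(rel) * depth
    counts[, s] <- if (dispersion > 0)
      stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
    else stats::rpois(n_genes, mu)
  }
  list(counts = counts, groups = groups,
       truth = list(log2fc = log2fc, depth = depth,
                    dispersion = dispersion, seed = seed))
}

#' Simulate a labeled expression cohort
#'
#' Log-normal baseline expression for `n_samples` samples; case samples are
#' shifted by +effect (in units of the per-gene log sd) on the activation
#' set and -effect on the repression set. Emulates a merged clinical cohort
#' with mutant and wild-type samples.
#'
#' @param n_samples total samples (default 100).
#' @param case_frac fraction of case (e.g. ESR1-mutant) samples
#'   (default 0.21, the mutant prevalence of the merged clinical cohorts).
#' @param n_genes background genes (default 1000).
#' @param n_set genes per signature set (default 50).
#' @param effect shift in log-sd units (default 1).
#' @param log_sd per-gene biological log sd (default 0.5).
#' @param seed seed.
#' @return list with `expr` (genes x samples, positive), `labels` (logical,
#'   TRUE = case), `up_set`, `down_set`, `truth`.
#' @export
generate_cohort <- function(n_samples = 100, case_frac = 0.21,
                            n_genes = 1000, n_set = 50, effect = 1,
                            log_sd = 0.5, seed = 1) {
  n_case <- round(case_frac * n_samples)
  if (n_case < 5 || n_samples - n_case < 5)
    stop("both classes need at least 5 samples", call. = FALSE)
  set.seed(child_seed(seed, 5))
  genes <- sprintf("CG%04d", seq_len(n_genes))
  up_set <- genes[seq_len(n_set)]
  down_set <- genes[n_set + seq_len(n_set)]
  labels <- sample(rep(c(TRUE, FALSE), c(n_case, n_samples - n_case)))
  base_mu <- stats::rnorm(n_genes, 5, 1)
  shift <- numeric(n_genes)
  shift[genes %in% up_set] <- effect * log_sd
  shift[genes %in% down_set] <- -effect * log_sd
  logx <- matrix(stats::rnorm(n_genes * n_samples, base_mu, log_sd),
                 n_genes, n_samples)
  logx <- logx + outer(shift, as.numeric(labels))
  expr <- exp(logx)
  dimnames(expr) <- list(genes, sprintf("S%03d", seq_len(n_samples)))
  list(expr = expr, labels = labels, up_set = up_set, down_set = down_set,
       truth = list(effect = effect, case_frac = case_frac, seed = seed))
}

#' Simulate WT / mutant peak sets with planted TSS-proximal gains
#'
#' Builds a toy single-chromosome genome with uniformly placed gene TSSs and
#' uniform background peaks; the mutant peak set is the WT set plus planted
#' peaks within `link_window` of the TSSs of `n_target` chosen genes (the
#' planted peak-to-gene links) plus a few mutant-only background peaks.
#'
#' @param genome_length chromosome length (>= 1e6; default 1e7).
#' @param n_genes annotated genes (default 100).
#' @param n_background WT background peaks (default 200).
#' @param n_target genes with planted gained binding (default 10).
#' @param peaks_per_target planted peaks per target gene (default 3).
#' @param link_window planted-peak distance bound from the TSS (default
#'   1e4: tightly TSS-proximal gained binding, well inside the 100 kb
#'   scoring window, emulating clear direct-target loci).
#' @param n_mut_background mutant-only background peaks (default 20).
#' @param peak_width peak width in bp (default 400).
#' @param seed seed.
#' @return list with `wt`, `mutant` (peak data.frames), `annotation`, and
#'   `truth` (target gene ids and planted peak coordinates).
#' @export
generate_peaks <- function(genome_length = 1e7, n_genes = 100,
                           n_background = 200, n_target = 10,
                           peaks_per_target = 3, link_window = 1e4,
                           n_mut_background = 20, peak_width = 400,
                           seed = 1) {
  if (genome_length < 1e6) stop("genome length must be at least 1e6",
                                call. = FALSE)
  set.seed(child_seed(seed, 6))
  margin <- 2e5
  genes <- sprintf("PG%03d", seq_len(n_genes))
  # TSSs on a jittered grid: gene loci keep a guaranteed minimum spacing so
  # a planted proximal cluster is attributable to one gene, not a pile-up
  spacing <- (genome_length - 2 * margin) / n_genes
  tss <- sort(round(margin + spacing * (seq_len(n_genes) - 0.5) +
                      stats::runif(n_genes, -0.2 * spacing, 0.2 * spacing)))
  ann <- data.frame(gene_id = genes, chrom = "chr1", tss = tss,
                    strand = sample(c("+", "-"), n_genes, replace = TRUE),
                    stringsAsFactors = FALSE)
  mk_peaks <- function(centers) {
    if (length(centers) == 0)
      return(data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), stringsAsFactors = FALSE))
    data.frame(chrom = "chr1",
               start = pmax(0, round(centers - peak_width / 2)),
               end = round(centers + peak_width / 2),
               stringsAsFactors = FALSE)
  }
  wt <- mk_peaks(round(stats::runif(n_background, peak_width,
                                    genome_length - peak_width)))
  targets <- sample(genes, n_target)
  # planted peaks must genuinely be gained: redraw any center whose peak
  # would overlap a WT background peak (else the truth label would be wrong)
  clear_of_wt <- function(center) {
    all(center + peak_width / 2 <= wt$start |
          center - peak_width / 2 >= wt$end)
  }
  planted_centers <- unlist(lapply(ann$tss[match(targets, ann$gene_id)],
                                   function(t0) {
    vapply(seq_len(peaks_per_target), function(i) {
      for (try in 1:50) {
        cc <- round(t0 + stats::runif(1, -link_window, link_window))
        if (clear_of_wt(cc)) return(cc)
      }
      cc
    }, numeric(1))
  }))
  mut_bg <- mk_peaks(round(stats::runif(n_mut_background, peak_width,
                                        genome_length - peak_width)))
  planted <- mk_peaks(planted_centers)
  mutant <- rbind(wt, planted, mut_bg)
  list(wt = validate_peaks(wt), mutant = validate_peaks(mutant),
       annotation = ann,
       truth = list(targets = targets, planted = planted, seed = seed))
}

#' Build a percentile matrix straight from a generated comparison set
#'
#' Convenience wrapper: percentile-transforms every generated DE table and
#' assembles the matrix (see [percentile_rank()] and [build_matrix()]).
#'
#' @param sim output of [generate_comparisons()] or
#'   [generate_shared_effect_classes()].
#' @return percentile matrix, genes x comparisons.
#' @export
simulated_percentile_matrix <- function(sim) {
  cols <- lapply(sim$de_tables, percentile_rank)
  build_matrix(cols, sim$metas)
}
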