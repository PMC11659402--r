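#!/usr/bin/env Rscript

# Step 1 — simulate the study inputs.
#
# Builds a synthetic experiment registry with known ground truth, emulating
# the structure of a curated ER-modulator database: a repressive short-term
# modulator section (SERM/SERD), an activating ESR1-mutant section (GE/OE
# construction), a no-replicate count experiment, a labeled clinical-style
# cohort, and WT/mutant ChIP peak sets with planted TSS-proximal gains.
# Everything downstream (02-06) reads only the files written here.

suppressMessages(library(estromeld))

master_seed <- 11
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## short-term modulator section (repressive drug classes)
mod <- generate_comparisons(section = "modulator",
                            seed = child_seed(master_seed, 1))
## ESR1-mutant section (activating, genome-edited vs overexpression)
mut <- generate_comparisons(classes = c(GE = 1, OE = 0.8),
                            section = "ESR1mut",
                            seed = child_seed(master_seed, 2))
mut$metas$comparison_id <- sub("^C", "M", mut$metas$comparison_id)
names(mut$de_tables) <- mut$metas$comparison_id

metas <- rbind(mod$metas, mut$metas)
write.csv(metas[, setdiff(names(metas), "tamoxifen_unspecified")],
          file.path(out, "metadata.csv"), row.names = FALSE)
dir.create(file.path(out, "de_tables"), showWarnings = FALSE)
for (id in names(mod$de_tables))
  write_de_table(mod$de_tables[[id]],
                 file.path(out, "de_tables", paste0(id, ".tsv")))
for (id in names(mut$de_tables))
  write_de_table(mut$de_tables[[id]],
                 file.path(out, "de_tables", paste0(id, ".tsv")))

## no-replicate count experiment driven by the first modulator design column
lfc <- mod$truth$fc_design[, 1]
cc <- generate_counts(lfc, seed = child_seed(master_seed, 3))
write.table(data.frame(gene_id = rownames(cc$counts), cc$counts),
            file.path(out, "counts_norep.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## clinical-style cohort (21% mutant prevalence, effect 1 sd)
coh <- generate_cohort(n_samples = 100, seed = child_seed(master_seed, 4))
write.table(data.frame(gene_id = rownames(coh$expr), coh$expr),
            file.path(out, "cohort_expr.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample = colnames(coh$expr),
                       label = as.integer(coh$labels)),
            file.path(out, "cohort_labels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## WT / mutant peak sets and annotation
pk <- generate_peaks(seed = child_seed(master_seed, 5))
write_bed(pk$wt, file.path(out, "peaks_wt.bed"))
write_bed(pk$mutant, file.path(out, "peaks_mutant.bed"))
write.table(pk$annotation, file.path(out, "tss_annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## serialized ground truth for the recovery checks in later steps
truth <- list(
  master_seed = master_seed,
  modulator_roles = mod$truth$roles[c("er_up", "er_down", "bidirectional")],
  esr1mut_roles = mut$truth$roles[c("er_up", "er_down", "bidirectional")],
  counts_log2fc = as.list(round(lfc, 6)),
  cohort = list(up_set = coh$up_set, down_set = coh$down_set,
                effect = coh$truth$effect),
  peak_targets = pk$truth$targets)
jsonlite::write_json(truth, file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat("simulated", nrow(metas), "comparisons,",
    length(mod$truth$roles$bidirectional), "planted bidirectional genes,",
    length(pk$truth$targets), "peak-linked target genes\n")
cat("inputs written under", out, "\n")
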