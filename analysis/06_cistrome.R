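#!/usr/bin/env Rscript

# Step 6 — gained-peak regulatory potential.
#
# Intersects the mutant peak set against the WT control to obtain gained
# peaks, scores every annotated gene by the 100 kb TSS-window decay kernel,
# and checks that the planted peak-linked target genes top the ranking;
# also emits the browser-style +/-200 kb TSS window view for the strongest
# target.

suppressMessages(library(estromeld))

wt <- read_bed("results/data/peaks_wt.bed")
mut <- read_bed("results/data/peaks_mutant.bed")
ann <- read_annotation("results/data/tss_annotation.tsv")
truth <- jsonlite::read_json("results/data/ground_truth.json",
                             simplifyVector = TRUE)

gained <- gained_peaks(mut, wt)
cat(sprintf("gained peaks: %d of %d mutant peaks absent from WT\n",
            nrow(gained), nrow(mut)))
write_bed(gained, "results/peaks_gained.bed")

score <- average_score(list(regulatory_potential(gained, ann,
                                                 window_bp = 1e5)))
ranked <- sort(score, decreasing = TRUE)
in_top_decile <- mean(score[truth$peak_targets] >=
                        quantile(score, 0.9))
cat(sprintf("regulatory potential: %.0f%% of planted targets in the top decile\n",
            100 * in_top_decile))
write.table(data.frame(gene_id = names(ranked), score = unname(ranked),
                       planted = names(ranked) %in% truth$peak_targets),
            "results/regulatory_potential.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

top_gene <- names(ranked)[1]
win <- tss_window_peaks(gained, top_gene, ann, window_bp = 2e5)
cat(sprintf("TSS window of %s: %d gained peaks, offsets %s bp\n",
            top_gene, nrow(win),
            paste(sort(win$offset), collapse = ", ")))
write.table(win, "results/tss_window_top_gene.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
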