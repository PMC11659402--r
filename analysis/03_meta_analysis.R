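#!/usr/bin/env Rscript

# Step 3 — cross-comparison meta-statistics.
#
# On the harmonized percentile matrices from step 2: per-gene heterogeneity
# (log10 CV^2) contrasted between drug classes, class-profile correlation,
# concordance/discordance between the class average profiles, bidirectional
# and consensus gene calls checked against the planted ground truth, the
# ligand-dependence gate, and per-gene mixed-effect regressions on the
# experimental covariates.

suppressMessages(library(estromeld))

metas <- read_metadata("results/data/metadata.csv")
truth <- jsonlite::read_json("results/data/ground_truth.json",
                             simplifyVector = TRUE)
m_mod <- read_percentile_matrix("results/percentiles_modulator.tsv")
m_mut <- read_percentile_matrix("results/percentiles_ESR1mut.tsv")

pr <- function(called, planted)
  c(precision = length(intersect(called, planted)) / max(length(called), 1),
    recall = length(intersect(called, planted)) / max(length(planted), 1))

## heterogeneity: SERM vs SERD comparisons
serm <- metas$comparison_id[metas$compound_class == "SERM" &
                              metas$section == "modulator"]
serd <- metas$comparison_id[metas$compound_class == "SERD" &
                              metas$section == "modulator"]
het <- heterogeneity_test(m_mod, serm, serd)
cat(sprintf("heterogeneity log10(CV^2): SERM median %.2f vs SERD median %.2f (Mann-Whitney p = %.3g)\n",
            het$median_a, het$median_b, het$p))

## class-profile correlation with clustering order
pc <- pairwise_correlation(m_mod, list(SERM = serm, SERD = serd))
cat(sprintf("SERM-vs-SERD average-profile correlation r = %.2f\n",
            pc$r["SERM", "SERD"]))

## concordance quadrants (cut 25) between the class averages
q <- concordance_quadrants(average_percentile(m_mod, serm),
                           average_percentile(m_mod, serd), cut = 25)
cat(sprintf("concordance quadrants: up-up %d, down-down %d, discordant %d + %d genes\n",
            length(q$up_up$genes), length(q$down_down$genes),
            length(q$x_up_y_down$genes), length(q$x_down_y_up$genes)))

## construction-preferential genes in the mutant section (delta cut 70)
ge <- metas$comparison_id[metas$construction == "GE"]
oe <- metas$comparison_id[metas$construction == "OE"]
disc <- discordance_genes(average_percentile(m_mut, ge),
                          average_percentile(m_mut, oe), delta_cut = 70)
cat(sprintf("construction-preferential genes (|delta| > 70): %d GE, %d OE\n",
            length(disc$a_pref$genes), length(disc$b_pref$genes)))

## bidirectional genes in the modulator section vs planted truth
bid <- bidirectional_genes(m_mod)
bid_pr <- pr(bid$genes, truth$modulator_roles$bidirectional)
cat(sprintf("bidirectional genes: %d called, precision %.2f, recall %.2f\n",
            length(bid$genes), bid_pr["precision"], bid_pr["recall"]))

## consensus upregulated targets in the mutant section vs planted truth
ct <- consensus_targets(m_mut, direction = "up", min_frac = 0.5)
ct_pr <- pr(ct$gene_id, truth$esr1mut_roles$er_up)
cat(sprintf("consensus up targets (top decile in >= 50%%): %d called, precision %.2f, recall %.2f\n",
            nrow(ct), ct_pr["precision"], ct_pr["recall"]))
write.table(ct, "results/consensus_targets.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## ligand-dependence gate: mutant average vs an activating reference (the
## modulator section is repressive, so its negated average plays the E2 role)
gate <- ligand_dependence_gate(average_percentile(m_mut),
                               -average_percentile(m_mod),
                               high_cut = 50, null_band = 15)
cat(sprintf("ligand gate: %d ligand-independent up, %d down, %d de novo\n",
            length(gate$ligand_up$genes), length(gate$ligand_down$genes),
            length(gate$de_novo$genes)))

## per-gene mixed models on the modulator section (top consensus genes)
scope <- metas[metas$section == "modulator", ]
genes <- head(rownames(m_mod)[order(-abs(average_percentile(m_mod)))], 20)
fits <- lapply(genes, function(g)
  suppressWarnings(fit_gene_mixed_model(m_mod[g, ], scope)))
drug_term <- grep("^drug", names(fits[[1]]$p), value = TRUE)[1]
tab <- data.frame(gene_id = genes,
                  drug_coef = vapply(fits, function(f)
                    f$coef[[drug_term]], numeric(1)),
                  drug_p = vapply(fits, function(f)
                    f$p[[drug_term]], numeric(1)))
tab$drug_padj <- p.adjust(tab$drug_p, "BH")
write.table(tab, "results/mixed_model_top_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("mixed models: %d/%d top genes with BH-significant drug-class term\n",
            sum(tab$drug_padj < 0.05), nrow(tab)))

## similarity search around the strongest consensus gene
res <- similar_genes(m_mut, ct$gene_id[1])
cat(sprintf("genes co-regulated with %s (r > 0.5, padj < 0.05): %d\n",
            ct$gene_id[1], sum(res$r > 0.5 & res$padj < 0.05)))

## set intersections across the call sets
venn <- intersect_sets(list(bidirectional = bid$genes,
                            consensus_up = ct$gene_id,
                            de_novo = gate$de_novo$genes))
write.table(venn$regions, "results/call_set_overlaps.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
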