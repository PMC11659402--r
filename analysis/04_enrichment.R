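#!/usr/bin/env Rscript

# Step 4 — gene-set statistics on the harmonized sections.
#
# Builds a small gene-set collection from the planted programs plus random
# decoys, then runs Fisher over-representation of the consensus calls,
# preranked GSEA (1000 permutations, seed 6) on the average percentile
# ranking, and the Oncotype DX weighted-impact formula on group-level
# percentiles derived from the two sections.

suppressMessages(library(estromeld))

truth <- jsonlite::read_json("results/data/ground_truth.json",
                             simplifyVector = TRUE)
m_mod <- read_percentile_matrix("results/percentiles_modulator.tsv")
m_mut <- read_percentile_matrix("results/percentiles_ESR1mut.tsv")

## gene-set collection: planted programs + size-matched random decoys
set.seed(2)
universe <- rownames(m_mut)
coll <- list(er_up_program = intersect(truth$esr1mut_roles$er_up, universe),
             er_down_program = intersect(truth$esr1mut_roles$er_down,
                                         universe))
for (k in 1:8)
  coll[[sprintf("decoy_%02d", k)]] <- sample(universe, 60)
write_gmt(list(sets = coll, category = "synthetic"),
          "results/synthetic_programs.gmt")

## ORA of the consensus-up call against the collection
ct <- read.delim("results/consensus_targets.tsv")
ora <- fisher_ora(ct$gene_id, coll, universe)
write.table(ora, "results/ora_consensus.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("ORA: top term '%s' (odds ratio %.1f, padj = %.2g)\n",
            ora$term[1], ora$odds_ratio[1], ora$padj[1]))

## preranked GSEA on each section's average percentile ranking
for (nm in c("modulator", "ESR1mut")) {
  m <- if (nm == "modulator") m_mod else m_mut
  avg <- average_percentile(m)
  avg <- avg[!is.na(avg)]
  enr <- preranked_gsea(avg, coll, n_perm = 1000, seed = 6)
  enr <- enr[order(enr$fdr, -abs(enr$nes)), ]
  write.table(enr, sprintf("results/gsea_%s.tsv", nm), sep = "\t",
              quote = FALSE, row.names = FALSE)
  top <- enr[1, ]
  cat(sprintf("GSEA %s: '%s' NES = %.2f, FDR = %.3f\n",
              nm, top$term, top$nes, top$fdr))
}

## Oncotype DX weighted impact from group-level average percentiles:
## proliferation/ER-linked groups follow the planted program average of each
## section, remaining groups sit at the section's background average
impact <- vapply(list(modulator = m_mod, ESR1mut = m_mut), function(m) {
  avg <- average_percentile(m)
  prog_up <- mean(avg[intersect(truth$esr1mut_roles$er_up, names(avg))],
                  na.rm = TRUE)
  bg <- mean(avg, na.rm = TRUE)
  oncotype_weighted_impact(c(HER2 = bg, ER = prog_up,
                             Proliferation = prog_up, Invasion = bg,
                             CD68 = bg, GSTM1 = bg, BAG1 = bg))
}, numeric(1))
cat(sprintf("Oncotype weighted impact: modulator %.1f, ESR1mut %.1f\n",
            impact["modulator"], impact["ESR1mut"]))
writeLines(sprintf("%s\t%.4f", names(impact), impact),
           "results/oncotype_weighted_impact.tsv")
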