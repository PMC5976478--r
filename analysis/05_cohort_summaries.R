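#!/usr/bin/env Rscript
# Stage 5: cohort-level cross-tabulations over the packaged reference
# tables with the 37-tumor denominator (8 in-house + 29 literature/COSMIC):
# the DNA-repair pathway cross-tab, the truncating-variant summary, gene
# mutation frequencies, and driver-candidate counts per tumor.

suppressPackageStartupMessages(library(lumdriver))

cohort_size <- 37

# DNA-repair cross-tab -------------------------------------------------------
tab2 <- read_repair_table()
ct <- repair_crosstab(gene_lists_from_table(tab2), load_packaged_pathway_map(),
                      cohort_size = cohort_size)
utils::write.table(ct$rows, "results/repair_crosstab.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("DNA-repair SNVs in %d/%d tumors (%.1f%%; unrounded %.4f)",
                ct$n_samples_affected, cohort_size, ct$percent_affected,
                ct$fraction_affected))

# truncating variants vs curated sets ---------------------------------------
tab3 <- read_truncating_table()
ts <- summarize_truncating_table(tab3, cohort_size = cohort_size)
utils::write.table(tab3, "results/truncating_summary.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("truncating variant in an expression-regulation gene: %d/%d tumors (%.0f%%)",
                ts$n_samples_with_expr_gene, cohort_size, ts$percent))

# gene frequencies over the simulated cohort --------------------------------
cohort <- read_variant_table("results/cohort_variants.tsv")
lists <- cohort_gene_lists(cohort, consequences = setdiff(consequence_levels(),
                                                          silent_consequences()))
gf <- gene_frequency(lists, cohort_size = length(lists))
utils::write.table(gf, "results/gene_frequency.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("most recurrently mutated simulated gene: %s (%d/%d samples)",
                gf$gene[1], gf$count[1], length(lists)))

# driver-candidate counts among the truncating gene lists -------------------
trunc_lists <- lapply(strsplit(tab3$truncating_genes, ";"),
                      function(g) g[g != ""])
names(trunc_lists) <- tab3$sample_id
dc <- driver_count_per_tumor(trunc_lists,
                             load_packaged_gene_set("cgc_table1"),
                             load_packaged_gene_set("ccgd_a"),
                             load_packaged_gene_set("ccgd_b"))
message(sprintf("curated driver genes among truncating variants: median %.1f per tumor (%d-%d)",
                dc$median, dc$minimum, dc$maximum))
message("wrote results/repair_crosstab.tsv, results/truncating_summary.tsv, results/gene_frequency.tsv")
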