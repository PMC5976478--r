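#!/usr/bin/env Rscript
# Stage 2: mutational-spectrum profiling of the simulated cohort — the 96
# trinucleotide categories, per-sample load/rate statistics and the
# cross-sample recurrence collapse.

suppressPackageStartupMessages(library(lumdriver))

cohort <- read_variant_table("results/cohort_variants.tsv")

sp <- build_spectrum(cohort)
utils::write.table(as.data.frame(sp), "results/spectrum.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
frac_ct <- sp$class_counts[["C>T"]] / sum(sp$class_counts)
message(sprintf("spectrum over %d SNVs: C>T fraction %.3f (generator target 0.39)",
                sp$n, frac_ct))
top <- names(sort(sp$context_counts, decreasing = TRUE))[1:3]
message("most populated trinucleotide categories: ", paste(top, collapse = ", "))

st <- load_stats(cohort)
load_tab <- data.frame(sample_id = names(st$per_sample_counts),
                       n_snvs = unname(st$per_sample_counts),
                       rate_per_mbp = unname(mutation_rate(st$per_sample_counts,
                                                           cohort$territory_mbp)))
utils::write.table(load_tab, "results/loadstats.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("load: median %.1f (%d-%d); mean total rate %.2f/Mbp, non-silent %.2f/Mbp",
                st$median, st$minimum, st$maximum,
                st$total_rate_per_mbp, st$nonsilent_rate_per_mbp))

rc <- collapse_recurrence(cohort)
rec_tab <- data.frame(samples_sharing = names(rc$multiplicity_histogram),
                      n_variants = unname(rc$multiplicity_histogram))
utils::write.table(rec_tab, "results/recurrence.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("recurrence: %d observations collapse to %d unique variants",
                rc$total_observations, rc$unique_variants))
message("wrote results/spectrum.tsv, results/loadstats.tsv, results/recurrence.tsv")
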