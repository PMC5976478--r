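#!/usr/bin/env Rscript
# Stage 1: generate the synthetic 8-sample exome cohort used by the
# downstream stages, together with its evidence table, and write both to
# results/. The generator's defaults emulate the study conditions: loads of
# 19-74 SNVs per tumor, a 39% C>T spectrum, five variants shared by two
# samples and one shared by three, over a 62 Mbp territory.

suppressPackageStartupMessages(library(lumdriver))

seed <- 17
dir.create("results", showWarnings = FALSE)

params <- simulation_params(seed = seed)
cohort <- simulate_cohort(params)
evidence <- simulate_evidence(cohort, params)

write_variant_table(cohort, "results/cohort_variants.tsv")
write_evidence_table(evidence, "results/cohort_evidence.tsv")

st <- load_stats(cohort)
message(sprintf("simulated %d SNV observations in %d samples (seed %d)",
                nrow(cohort$records), length(st$per_sample_counts), seed))
message(sprintf("per-sample loads: median %.1f, range %d-%d",
                st$median, st$minimum, st$maximum))
message(sprintf("evidence records for %d missense/nonsense variants",
                nrow(evidence)))
message("wrote results/cohort_variants.tsv and results/cohort_evidence.tsv")
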