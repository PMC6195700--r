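#!/usr/bin/env Rscript
# Stage 4: winner-turnover census on the longitudinal cohort. Pairs of
# (subject, group) need two time points with > 0.5% group abundance to be
# eligible; turnover means two time points with different > 90% winners.
# Detected turnovers are compared against the generator's planted log.

suppressPackageStartupMessages(library(lotterymb))

inp <- read_otu_table("results/simulated/longitudinal_counts.tsv")
metadata <- read_sample_metadata("results/simulated/longitudinal_metadata.tsv")
rel <- to_relative(inp$table)
groups <- build_groups(inp$lineage, "genus")
cen <- turnover_census(rel, groups, metadata)
utils::write.table(cen$records, "results/turnover_records.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("Turnover in %d of %d eligible individual-group pairs\n",
            cen$n_pairs_with_turnover, cen$n_pairs_examined))

planted <- utils::read.delim("results/simulated/longitudinal_planted.tsv")
planted$group <- paste0("g__", planted$group)  # census keys on genus names
m <- merge(cen$records, planted, by = c("subject_id", "group"))
cat(sprintf("Planted turnovers: %d; detected among planted: %d (sensitivity %.2f)\n",
            sum(m$turnover.y), sum(m$turnover.x & m$turnover.y),
            sum(m$turnover.x & m$turnover.y) / max(sum(m$turnover.y), 1)))
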