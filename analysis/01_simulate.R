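#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data every later stage consumes.
#
# One cross-sectional cohort (500 samples, Poisson counts at depth 20000)
# with a mix of lottery / fixed-winner / coexistence genera nested inside a
# two-family, two-phylum taxonomy; a replication cohort drawn from the same
# community spec with an independent seed; a longitudinal infant-style
# cohort with planted winner turnovers; and a per-species genome gene-count
# table with a planted streamlined-genome effect in lottery-like genera.

suppressPackageStartupMessages(library(lotterymb))
seed <- 20240917L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

lineages <- list(
  Akk = c(kingdom = "k__Bacteria", phylum = "p__Verru", class = "c__Verru",
          order = "o__Verru", family = "f__Verru", genus = "g__Akk"),
  Ser = c(kingdom = "k__Bacteria", phylum = "p__Proteo", class = "c__Gamma",
          order = "o__Entero", family = "f__Entero", genus = "g__Ser"),
  Kle = c(kingdom = "k__Bacteria", phylum = "p__Proteo", class = "c__Gamma",
          order = "o__Entero", family = "f__Entero", genus = "g__Kle"),
  Hae = c(kingdom = "k__Bacteria", phylum = "p__Proteo", class = "c__Gamma",
          order = "o__Pasteur", family = "f__Pasteur", genus = "g__Hae"),
  Bla = c(kingdom = "k__Bacteria", phylum = "p__Firm", class = "c__Clost",
          order = "o__Clost", family = "f__Lachno", genus = "g__Bla"),
  Fae = c(kingdom = "k__Bacteria", phylum = "p__Firm", class = "c__Clost",
          order = "o__Clost", family = "f__Rumino", genus = "g__Fae"))

schemas <- list(
  Akk = schema_spec("lottery", 4),                 # classic lottery genus
  Ser = schema_spec("lottery", 6),
  Kle = schema_spec("lottery", 3,
                    winner_distribution = c(0.6, 0.25, 0.15)),
  Hae = schema_spec("fixed_winner", 4),            # one permanent winner
  # coexisting genera with occasional chance dominance (winner prevalence
  # around 0.1-0.2, like the abundant well-mixed gut genera)
  Bla = schema_spec("coexistence", 6, coexistence_concentration = 0.2),
  Fae = schema_spec("coexistence", 4, coexistence_concentration = 0.3))

spec <- community_spec(schemas, n_samples = 500, read_depth = 20000,
                       lineages = lineages)

sim <- simulate_community(spec, seed = seed)
write_otu_table(sim$table, file.path(out, "cohortA_counts.tsv"),
                lineage = sim$lineage)
utils::write.table(sim$truth, file.path(out, "cohortA_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

simB <- simulate_community(spec, seed = seed + 1L)
write_otu_table(simB$table, file.path(out, "cohortB_counts.tsv"),
                lineage = simB$lineage)

lsim <- simulate_longitudinal(
  community_spec(schemas[c("Akk", "Ser", "Bla")], n_samples = 1,
                 read_depth = 20000,
                 lineages = lineages[c("Akk", "Ser", "Bla")]),
  n_subjects = 30, timepoints_per_subject = 4, turnover_rate = 0.25,
  seed = seed + 2L)
write_otu_table(lsim$table, file.path(out, "longitudinal_counts.tsv"),
                lineage = lsim$lineage)
utils::write.table(lsim$metadata, file.path(out, "longitudinal_metadata.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(lsim$planted, file.path(out, "longitudinal_planted.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

classes <- c(g__Akk = "lottery_like", g__Ser = "lottery_like",
             g__Bla = "non_lottery", g__Fae = "non_lottery")
genes <- simulate_gene_counts(classes, n_species_per_genus = 8,
                              seed = seed + 3L)
utils::write.table(genes, file.path(out, "genome_gene_counts.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated:", length(schemas), "genera x 500 samples (2 cohorts),",
    "30 subjects x 4 time points,",
    sum(lsim$planted$turnover), "planted turnovers,",
    nrow(genes), "species gene-count rows ->", out, "\n")
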