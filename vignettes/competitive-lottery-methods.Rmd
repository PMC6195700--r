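---
title: "Detecting competitive-lottery assembly in microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting competitive-lottery assembly in microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lotterymb)
```

## The model

In a competitive lottery, a group of ecologically near-equivalent taxa
competes for a shared niche, and in each community a single member —
essentially at random — captures the niche nearly completely. Applied to the
gut microbiome, the "group" is a taxonomic unit (a genus over its OTUs, or a
family over its genera) and the "community" is one sample. If a genus is
assembled by a lottery, two signatures should be visible across a large
cohort: in most samples one member holds almost all of the group's
abundance, and the identity of that member varies from sample to sample.

`lotterymb` quantifies these two signatures per group:

* **Winner prevalence.** In each sample where the group's summed relative
  abundance exceeds an inclusion floor (default 0.5%), the member whose
  *within-group* fraction strictly exceeds a cutoff (default 0.9) is the
  sample's *winner*. Winner prevalence is the fraction of included samples
  that have a winner. Because the cutoff exceeds 0.5, at most one winner can
  exist per sample.
* **Winner diversity.** Let $p_i$ be the frequency with which member $i$ is
  the winner, over the samples that have one. The normalized winner
  diversity is $H / \log_2 m$ with $H = -\sum_i p_i \log_2 p_i$ and $m$ the
  number of distinct winners, so it ranges over $[0, 1]$.

A group is called **lottery-like** when prevalence $> 0.75$ *and* normalized
diversity $> 0.25$; high prevalence with at-threshold-or-lower diversity is a
**fixed winner** (the same member dominates everywhere, which a lottery does
not require but also does not predict); everything else is **non-lottery**.
All three thresholds are strict inequalities, and all are exposed in
`metric_config()`.

Two conventions close gaps in the normalization. With a single distinct
winner $\log_2 1 = 0$, so diversity is defined as 0 — the same member always
wins, the least diverse outcome. With no winners at all the diversity is
reported as missing (`NA`), not 0, and the classification is non-lottery.

## Why 0.9 and 0.5%

The 0.9 cutoff sits far above what chance partitions produce. Under a
broken-stick null for a two-member group the probability that the larger
piece exceeds 0.9 is exactly 0.2, and it falls rapidly with more members;
`stick_breaking_abundances()` exposes both this null and the GEM
(sequential Beta) variant so the cutoff can be re-examined
(`analysis/05_noise_sweep.R` does).

The 0.5% group-abundance floor guards against a different artifact: read
sampling. When a group's members are all at truly equal abundance, perfect
measurements would never show a winner, but Poisson counting noise at low
coverage routinely does. `poisson_noise_sweep()` simulates exactly this
situation: at an expected half a read per member more than half of all
samples show a spurious winner, while at the floor (0.5% abundance at a
5000-read depth, i.e. 25 expected reads per member) the artifact is
indistinguishable from zero. Sample-level winner calls below the floor are
therefore never made.

## Inclusion filters

`prepare_grouped_table()` runs the standard cascade: samples with fewer than
5000 reads are dropped (on counts); counts become relative abundances over
the full retained feature set; OTUs are dropped unless strictly above 0.05%
abundance in at least `max(10, ceiling(0.5% of samples))` samples; groups
are built from the lineage at the requested rank; groups are dropped by the
same rule at a 0.5% threshold (or, for very large cohorts, an absolute
`group_min_samples_override`). Columns are *not* renormalized after feature
removal — within-group fractions are ratios of member abundances, so they
are unaffected by the removal of unrelated features, and this choice keeps
the group statistics independent of how aggressively the rest of the table
was filtered. The ceiling (rather than floor) in the sample-count rule means
"0.5% of samples" can never be satisfied by rounding down; every abundance
comparison in the package is strict.

Features whose lineage is empty, `unclassified`, or truncated at some rank
are *unannotated* from that rank down (the cascade is enforced at parse
time) and join no group at those ranks: pooling unknown lineages would
create pseudo-groups whose "members" share nothing.

## Ranks above the base

At a higher rank each group's *subgroups* — its child-rank taxa — are
treated as single entities whose abundance is the sum of their members'.
Statistics at a rank therefore never depend on how abundance is distributed
within a subgroup (`hierarchical_lottery_scan()` verifies nothing else
enters by construction; the test suite reshuffles abundance within subgroups
and checks invariance). Features annotated at the parent rank but not at the
child rank are dropped from the aggregation. Groups with a single subgroup
are skipped — the subgroup count is assessed *after* feature filtering, since
the filtered table defines what can be analyzed. The group filter is
re-applied independently at every rank.

## Longitudinal turnover

For a (subject, group) pair with at least two time points above the 0.5%
floor (the pair is then *eligible*), a turnover is two time points with
different winners under the same 0.9 cutoff. The predicate is existential:
a winner that reverts to the initial member still counts, and time points
without a winner never create turnover. `turnover_census()` enumerates all
eligible pairs and flags turnovers; the dominance question is evaluated on
within-group fractions, consistent with every other statistic in the
package.

## The synthetic-data generator

`simulate_community()` implements the two-step assembly model the analysis
presumes: per sample, total abundance is first allocated among groups by a
symmetric Dirichlet (concentration 5 by default, so each of a handful of
groups sits comfortably above the 0.5% floor in essentially every sample);
each group's share is then split among members by its schema:

* **lottery** — a winner drawn from a configurable winner distribution takes
  a fraction drawn `Uniform(0.92, 1)` (entirely above the 0.9 cutoff, so a
  noise-free lottery group has prevalence exactly 1); the remainder goes to
  the losers by stick breaking (GEM, θ = 1) by default, giving the losers a
  heavy-tailed residual structure, or by symmetric Dirichlet.
* **fixed winner** — the same with a point-mass winner distribution.
* **coexistence** — symmetric Dirichlet over all members, concentration 10
  (strongly even; lower it to emulate the occasional chance dominance seen
  in abundant, well-mixed genera).

Finite `read_depth` applies independent per-feature Poisson sampling of
counts around `abundance × depth`, so total depth varies around its target —
the appropriate model for read counting, and the regime the noise sweep
studies. `simulate_longitudinal()` keeps each subject's lottery winner
fixed over time except for planted switches (probability `turnover_rate`
per step, always to a different member), and logs every planted (subject,
group) turnover for ground-truth comparison. `simulate_gene_counts()` plants
a genome-size effect between assembly classes (defaults 2000 vs 4000 genes,
SD 300) for calibrating the gene-content comparison.

What the generator does *not* emulate: cohort-specific effects (sample
preservation, primer and pipeline bias), phylogenetic correlation between
groups, compositional coupling beyond the shared Dirichlet allocation, and
strain-level structure below the feature. Passing tests on synthetic data
therefore demonstrate that the statistics recover the generating schema
under the model's own assumptions — not that any real genus is assembled by
a lottery.

## Cross-dataset and genome comparisons

`compare_datasets()` computes a Spearman correlation of a lottery parameter
over the groups shared by two result tables; groups filtered out of either
dataset are excluded rather than imputed. `select_genome_comparison_groups()`
reproduces the two-dataset selection rule: genera with winner diversity
> 0.25 in the primary dataset are split into a high class (prevalence > 0.75
in the primary *and* in at least one other dataset) and a low class
(< 0.75 in the primary); genera exactly at a threshold, or high in the
primary only, stay unclassified. `compare_gene_counts()` then compares
per-species gene counts between classes with a two-sided Mann–Whitney
rank-sum test — chosen for robustness to the skewed gene-count
distributions; Welch's *t* is available behind a flag — run separately for
total, KO-annotated and unannotated genes, with no multiple-testing
correction across the three fields (reported as raw p-values). The
OTU-to-genome mapping itself (BLAST at 97% identity in the original
workflow) is represented only as the validated input contract
(`validate_genome_table()`); no aligner is run.

## Numerical choices and edge cases

* Entropy uses base 2 throughout with $0 \log 0 := 0$.
* Ties — for the most abundant member, in display block sizes, in top-k
  selection — break lexicographically by member id (then sample id), making
  every ordering reproducible.
* `top_k` ranks members by mean relative abundance over included samples,
  then renormalizes within the subset; restricting to a subset can only
  raise the maximum fraction, so prevalence is non-decreasing under the
  restriction (a property the tests verify by brute force).
* A sample in which a group (or a top-k subset) has zero abundance carries
  no defined fractions and is excluded from that group's statistics rather
  than raising an error; a group below the inclusion floor in *all* samples
  is an error.
* All generators take explicit integer seeds and restore the caller's RNG
  state (`withr::with_seed`); identical seeds give bit-identical output.

## Problem sizes

The validation workflow uses sizes at which the checks are decisive but
quick: parameter recovery on 10 groups × 1000 noise-free samples; oracle
equivalence on 200 random tables of up to 15 features × 100 samples; the
broken-stick null at 100,000 replicates (Monte-Carlo SE ≈ 0.0013 against
the closed-form 0.2); the noise sweep at 20,000 replicates per abundance;
and 1000 replicates each for the gene-count type-I and power calibrations.
The analysis scripts simulate 6-genus cohorts of 500 samples at a read
depth of 20,000.

## Known limitations

Winner prevalence depends on group size (more members make a > 90% share
harder to reach by chance *and* harder to hold); the top-k sweep is the tool
for separating that effect from genuine exclusion. The classification
thresholds are descriptive cutoffs, not significance tests — the package
deliberately reports no p-value for "lottery-likeness", since the
interesting quantity is the parameter pair itself. Winner diversity is
sensitive to cohort composition and sampling, so cross-cohort agreement is
expected to be weaker for diversity than for prevalence.
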