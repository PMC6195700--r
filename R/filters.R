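#' Inclusion filters for samples, features and taxonomic groups
#'
#' Defaults follow the standard processing of large 16S cohorts: samples
#' need at least 5000 reads; an OTU must exceed 0.05% relative abundance in
#' at least 0.5% of samples (minimum 10 samples); a group must exceed 0.5%
#' abundance in at least 0.5% of samples (minimum 10), with an optional
#' absolute override (e.g. 200 samples) for very large cohorts. All abundance
#' thresholds are strict (`>`); the sample-count floor is
#' `max(floor, ceiling(fraction * n_samples))`.
#'
#' @param min_reads_per_sample minimum column sum for a sample to be kept.
#' @param otu_min_abundance relative-abundance threshold for OTU retention.
#' @param otu_min_sample_fraction fraction of samples an OTU must qualify in.
#' @param otu_min_samples_floor absolute minimum number of qualifying samples.
#' @param group_min_abundance,group_min_sample_fraction,group_min_samples_floor
#'   same three parameters applied to summed group abundance.
#' @param group_min_samples_override when set, a group is kept iff it
#'   qualifies in strictly more than this many samples (replaces the
#'   fraction/floor rule).
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_reads_per_sample = 5000,
                          otu_min_abundance = 0.0005,
                          otu_min_sample_fraction = 0.005,
                          otu_min_samples_floor = 10,
                          group_min_abundance = 0.005,
                          group_min_sample_fraction = 0.005,
                          group_min_samples_floor = 10,
                          group_min_samples_override = NULL) {
  cfg <- list(min_reads_per_sample = as.integer(min_reads_per_sample),
              otu_min_abundance = otu_min_abundance,
              otu_min_sample_fraction = otu_min_sample_fraction,
              otu_min_samples_floor = as.integer(otu_min_samples_floor),
              group_min_abundance = group_min_abundance,
              group_min_sample_fraction = group_min_sample_fraction,
              group_min_samples_floor = as.integer(group_min_samples_floor),
              group_min_samples_override =
                if (is.null(group_min_samples_override)) NULL
                else as.integer(group_min_samples_override))
  fracs <- c(cfg$otu_min_abundance, cfg$otu_min_sample_fraction,
             cfg$group_min_abundance, cfg$group_min_sample_fraction)
  if (any(fracs <= 0 | fracs >= 1)) stop("fractions must lie in (0, 1)")
  ints <- c(cfg$min_reads_per_sample, cfg$otu_min_samples_floor,
            cfg$group_min_samples_floor, cfg$group_min_samples_override)
  if (any(ints < 1L)) stop("integer thresholds must be >= 1")
  structure(cfg, class = "filter_config")
}

min_qualifying_samples <- function(floor, fraction, n) {
  max(floor, as.integer(ceiling(fraction * n)))
}

#' Drop low-depth samples from a count table
#'
#' Samples whose total count is strictly below `min_reads_per_sample` are
#' removed; survivor order is preserved.
#'
#' @param table an `abundance_table` of counts.
#' @param cfg a [filter_config()].
#' @return the filtered `abundance_table`.
#' @export
filter_samples <- function(table, cfg = filter_config()) {
  if (!is_counts(table)) stop("filter_samples expects a table of counts")
  keep <- colSums(table$values) >= cfg$min_reads_per_sample
  if (!any(keep)) stop("no sample reaches ", cfg$min_reads_per_sample,
                       " reads")
  abundance_table(table$values[, keep, drop = FALSE], "counts")
}

#' Convert counts to relative abundances
#'
#' Each sample column is divided by its own total over the features retained
#' at the time of the call; columns are not renormalized by any later feature
#' filtering.
#'
#' @param table an `abundance_table` of counts with positive column sums.
#' @return an `abundance_table` with `value_kind = "relative"`.
#' @export
to_relative <- function(table) {
  if (!is_counts(table))
    stop("to_relative expects counts; table is already relative")
  cs <- colSums(table$values)
  if (any(cs == 0))
    stop("zero-sum sample column: ", sample_ids(table)[cs == 0][1L])
  abundance_table(sweep(table$values, 2L, cs, "/"), "relative")
}

#' Drop rare features from a relative-abundance table
#'
#' A feature is retained iff its relative abundance strictly exceeds
#' `otu_min_abundance` in at least
#' `max(otu_min_samples_floor, ceiling(otu_min_sample_fraction * n_samples))`
#' samples. Columns are not renormalized afterwards, so within-group
#' fractions are unaffected by the removal of unrelated features.
#'
#' @inheritParams filter_samples
#' @return the filtered `abundance_table` (possibly with zero features, with
#'   a warning).
#' @export
filter_features <- function(table, cfg = filter_config()) {
  if (is_counts(table)) stop("filter_features expects relative abundances")
  need <- min_qualifying_samples(cfg$otu_min_samples_floor,
                                 cfg$otu_min_sample_fraction,
                                 n_samples(table))
  keep <- rowSums(table$values > cfg$otu_min_abundance) >= need
  if (!any(keep)) warning("all features removed by abundance filter")
  abundance_table(table$values[keep, , drop = FALSE], "relative")
}

#' Group features by their annotation at a taxonomic rank
#'
#' One group per distinct annotated name at `rank`; features unannotated at
#' that rank belong to no group (unknown lineages are never pooled into
#' pseudo-groups).
#'
#' @param lineage lineage data.frame ([parse_lineage_strings()]).
#' @param rank one of [TAXONOMIC_RANKS].
#' @return named list mapping group name to member feature ids, with
#'   attribute `rank`.
#' @export
build_groups <- function(lineage, rank) {
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  ann <- !is.na(lineage[[rank]])
  groups <- split(rownames(lineage)[ann], lineage[[rank]][ann])
  structure(groups[order(names(groups))], rank = rank)
}

group_abundance <- function(table, members) {
  colSums(table$values[members, , drop = FALSE])
}

#' Drop groups that are rarely abundant
#'
#' Group abundance in a sample is the sum of its members' relative
#' abundances. A group is retained iff its abundance strictly exceeds
#' `group_min_abundance` in at least
#' `max(group_min_samples_floor, ceiling(group_min_sample_fraction * n))`
#' samples — or, when `group_min_samples_override` is set, in strictly more
#' than that many samples.
#'
#' @param table a relative `abundance_table` the groups were built from.
#' @param groups named member list from [build_groups()].
#' @param cfg a [filter_config()].
#' @return the surviving subset of `groups` (same structure).
#' @export
filter_groups <- function(table, groups, cfg = filter_config()) {
  if (is_counts(table)) stop("filter_groups expects relative abundances")
  qualifying <- vapply(groups, function(members) {
    sum(group_abundance(table, members) > cfg$group_min_abundance)
  }, numeric(1L))
  keep <- if (!is.null(cfg$group_min_samples_override)) {
    qualifying > cfg$group_min_samples_override
  } else {
    qualifying >= min_qualifying_samples(cfg$group_min_samples_floor,
                                         cfg$group_min_sample_fraction,
                                         n_samples(table))
  }
  structure(groups[keep], rank = attr(groups, "rank"))
}

#' Run the full inclusion-filter cascade on a count table
#'
#' Order: sample depth filter (on counts), conversion to relative abundances
#' (on the full retained feature set), rare-feature filter, group
#' construction at `rank`, rare-group filter.
#'
#' @param table an `abundance_table` of counts.
#' @param lineage lineage data.frame.
#' @param rank rank at which groups are built.
#' @param cfg a [filter_config()].
#' @return list with `table` (filtered, relative) and `groups`.
#' @export
prepare_grouped_table <- function(table, lineage, rank = "genus",
                                  cfg = filter_config()) {
  tab <- filter_samples(table, cfg)
  tab <- to_relative(tab)
  tab <- filter_features(tab, cfg)
  groups <- build_groups(lineage[feature_ids(tab), , drop = FALSE], rank)
  list(table = tab, groups = filter_groups(tab, groups, cfg))
}
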